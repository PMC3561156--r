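# Brute-force graph oracles, written directly against the adjacency list with
# none of the package's graph machinery (no igraph, no leaf pruning, no
# Horton search). They are deliberately slow and simple: every definition is
# applied literally, by exhaustive enumeration, on small molecules.

# ---- plain graph helpers ---------------------------------------------------

o_adj <- function(mol) {
  n <- length(mol$elem)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  adj
}

# connected components by BFS over an explicit bond list
o_components <- function(n, bonds) {
  comp <- integer(n); cur <- 0L
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(bonds) > 0) for (k in seq_len(nrow(bonds))) {
    adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], bonds[k, 2])
    adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], bonds[k, 1])
  }
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

# bridge bonds by definition: removing the bond increases the component count
o_bridges <- function(mol) {
  n <- length(mol$elem); b <- mol$bonds
  base <- max(o_components(n, b))
  which(vapply(seq_len(nrow(b)), function(k)
    max(o_components(n, b[-k, , drop = FALSE])) > base, logical(1)))
}

o_ring_bonds <- function(mol) setdiff(seq_len(nrow(mol$bonds)), o_bridges(mol))

o_ring_atoms <- function(mol) {
  rb <- o_ring_bonds(mol)
  if (length(rb) == 0) return(integer(0))
  sort(unique(as.integer(mol$bonds[rb, 1:2])))
}

# every simple cycle, as a sorted vector of bond ids (exhaustive DFS)
o_all_cycles <- function(mol) {
  b <- mol$bonds; n <- length(mol$elem)
  adjb <- vector("list", n)
  for (i in seq_len(n)) adjb[[i]] <- list()
  for (k in seq_len(nrow(b))) {
    adjb[[b[k, 1]]] <- c(adjb[[b[k, 1]]], list(c(b[k, 2], k)))
    adjb[[b[k, 2]]] <- c(adjb[[b[k, 2]]], list(c(b[k, 1], k)))
  }
  seen <- new.env(parent = emptyenv())
  cycles <- list()
  walk <- function(start, v, visited, bonds_used) {
    for (e in adjb[[v]]) {
      w <- e[1]; k <- e[2]
      if (k %in% bonds_used) next
      if (w == start && length(bonds_used) >= 2) {
        key <- paste(sort(c(bonds_used, k)), collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          cycles[[length(cycles) + 1]] <<- sort(c(bonds_used, k))
        }
      } else if (!(w %in% visited) && w > start) {
        # only enumerate cycles whose smallest vertex is `start`
        walk(start, w, c(visited, w), c(bonds_used, k))
      }
    }
  }
  for (s in seq_len(n)) walk(s, s, s, integer(0))
  cycles
}

# minimum cycle basis by greedy GF(2) selection over ALL cycles sorted by size
o_mcb <- function(mol) {
  cycles <- o_all_cycles(mol)
  if (length(cycles) == 0) return(list())
  ord <- order(lengths(cycles),
               vapply(cycles, function(x) paste(x, collapse = ","), character(1)))
  cycles <- cycles[ord]
  nb <- nrow(mol$bonds)
  rank <- nb - length(mol$elem) + max(o_components(length(mol$elem), mol$bonds))
  basis <- list(); rows <- matrix(FALSE, 0, nb)
  for (cyc in cycles) {
    w <- logical(nb); w[cyc] <- TRUE
    if (nrow(rows) > 0) for (r in seq_len(nrow(rows))) {
      piv <- which(rows[r, ])[1]
      if (w[piv]) w <- xor(w, rows[r, ])
    }
    if (any(w)) {
      basis[[length(basis) + 1]] <- cyc
      rows <- rbind(rows, w)
      rows <- rows[order(apply(rows, 1, function(x) which(x)[1])), , drop = FALSE]
      if (length(basis) == rank) break
    }
  }
  basis
}

# ---- decomposition oracles -------------------------------------------------

# linker atoms by the literal definition: acyclic atom whose removal leaves
# >= 2 components that contain ring atoms
o_linker_atoms <- function(mol) {
  n <- length(mol$elem)
  ring <- logical(n); ring[o_ring_atoms(mol)] <- TRUE
  out <- integer(0)
  for (a in which(!ring)) {
    b <- mol$bonds
    keep <- b[, 1] != a & b[, 2] != a
    comp <- o_components(n, b[keep, , drop = FALSE])
    comp[a] <- NA
    if (length(unique(comp[ring & !is.na(comp)])) >= 2) out <- c(out, a)
  }
  out
}

# linker fragment atoms: linker atoms plus exocyclic double-bond partners
# attached to them
o_linker_frag_atoms <- function(mol) {
  la <- o_linker_atoms(mol)
  if (length(la) == 0) return(integer(0))
  core <- union(o_ring_atoms(mol), la)
  b <- mol$bonds
  exo <- integer(0)
  for (k in which(b[, 3] >= 2)) {
    if (b[k, 1] %in% la && !(b[k, 2] %in% core)) exo <- c(exo, b[k, 2])
    if (b[k, 2] %in% la && !(b[k, 1] %in% core)) exo <- c(exo, b[k, 1])
  }
  sort(unique(c(la, exo)))
}

# murcko keep-set: ring + linker + atoms double/triple-bonded to them
o_murcko_atoms <- function(mol) {
  n <- length(mol$elem)
  ring <- o_ring_atoms(mol)
  if (length(ring) == 0) return(integer(0))
  core <- union(ring, o_linker_atoms(mol))
  exo <- integer(0)
  b <- mol$bonds
  for (k in which(b[, 3] >= 2)) {
    if (b[k, 1] %in% core && !(b[k, 2] %in% core)) exo <- c(exo, b[k, 2])
    if (b[k, 2] %in% core && !(b[k, 1] %in% core)) exo <- c(exo, b[k, 1])
  }
  sort(unique(c(core, exo)))
}

# ring systems as atom sets: components of the ring-bond subgraph
o_ring_systems <- function(mol) {
  rb <- o_ring_bonds(mol)
  if (length(rb) == 0) return(list())
  n <- length(mol$elem)
  comp <- o_components(n, mol$bonds[rb, , drop = FALSE])
  ratoms <- o_ring_atoms(mol)
  unname(split(ratoms, comp[ratoms]))
}

# side-chain atom sets: components of everything outside the murcko keep-set
o_side_chain_atoms <- function(mol) {
  n <- length(mol$elem)
  keep <- o_murcko_atoms(mol)
  if (length(keep) == 0) return(list())
  rest <- setdiff(seq_len(n), keep)
  if (length(rest) == 0) return(list())
  b <- mol$bonds
  inside <- b[, 1] %in% rest & b[, 2] %in% rest
  comp <- o_components(n, b[inside, , drop = FALSE])
  unname(split(rest, comp[rest]))
}

# does any pair of minimum-cycle-basis rings share >= 2 bonds?
o_has_bridge <- function(mol) {
  rings <- o_mcb(mol)
  if (length(rings) < 2) return(FALSE)
  for (i in seq_len(length(rings) - 1)) for (j in seq(i + 1, length(rings))) {
    if (length(intersect(rings[[i]], rings[[j]])) >= 2) return(TRUE)
  }
  FALSE
}

# ---- scaffold tree oracle --------------------------------------------------

# independent chain construction: enumerate every ring of the oracle MCB,
# remove its exclusive bonds, re-prune with the oracle murcko set, keep the
# candidates that stay connected and drop the rank by one, then apply the
# prioritization cascade (3-membered heteroring first, fewest acyclic bonds
# deleted, fewest heteroatoms, larger ring, smallest parent SMILES)
o_chain <- function(smiles) {
  mol <- parse_smiles(smiles)[[1]]
  keep <- o_murcko_atoms(mol)
  if (length(keep) == 0) return(NULL)
  cur <- scaffscape:::submol(mol, keep)
  cur_smi <- mol_to_smiles(cur)
  rp <- parse_smiles(cur_smi)[[1]]
  if (!is.null(rp)) cur <- rp
  chain <- cur_smi
  rank_of <- function(m) nrow(m$bonds) - length(m$elem) +
    max(o_components(length(m$elem), m$bonds))
  while (rank_of(cur) > 1) {
    rings <- o_mcb(cur)
    cand <- list()
    for (r in seq_along(rings)) {
      excl <- setdiff(rings[[r]], unlist(rings[-r]))
      if (length(excl) == 0) next
      interim <- scaffscape:::submol(cur, seq_along(cur$elem),
                                     bond_ids = setdiff(seq_len(nrow(cur$bonds)), excl))
      katoms <- o_murcko_atoms(interim)
      if (length(katoms) == 0) next
      parent <- scaffscape:::submol(interim, katoms)
      if (max(o_components(length(parent$elem), parent$bonds)) != 1) next
      if (rank_of(parent) != rank_of(cur) - 1) next
      relems <- cur$elem[sort(unique(as.integer(cur$bonds[rings[[r]], 1:2])))]
      cand[[length(cand) + 1]] <- list(
        parent = parent,
        size = length(rings[[r]]),
        het = sum(!(relems %in% c("C", "*"))),
        is3het = length(rings[[r]]) == 3 && any(!(relems %in% c("C", "*"))),
        acyc = (nrow(cur$bonds) - nrow(parent$bonds)) - length(excl),
        smi = mol_to_smiles(parent))
    }
    if (length(cand) == 0) break
    sc <- data.frame(is3het = sapply(cand, `[[`, "is3het"),
                     acyc = sapply(cand, `[[`, "acyc"),
                     het = sapply(cand, `[[`, "het"),
                     size = sapply(cand, `[[`, "size"),
                     smi = sapply(cand, `[[`, "smi"))
    ord <- order(-sc$is3het, sc$acyc, sc$het, -sc$size, sc$smi)
    pick <- cand[[ord[1]]]
    nxt <- parse_smiles(pick$smi)[[1]]
    cur <- if (!is.null(nxt)) nxt else pick$parent
    chain <- c(chain, pick$smi)
  }
  rev(chain)
}

# ---- shared fixture --------------------------------------------------------

fixture_smiles <- c(
  # acyclic
  butane = "CCCC", isobutane = "CC(C)C", neopentane = "CC(C)(C)C",
  hexane = "CCCCCC", ethanol = "CCO", acetic_acid = "CC(=O)O",
  acetone = "CC(C)=O", diethyl_ether = "CCOCC", trimethylamine = "CN(C)C",
  glycine = "NCC(=O)O",
  # monocyclic aromatics
  benzene = "c1ccccc1", toluene = "Cc1ccccc1", p_xylene = "Cc1ccc(C)cc1",
  o_xylene = "Cc1ccccc1C", phenol = "Oc1ccccc1", aniline = "Nc1ccccc1",
  anisole = "COc1ccccc1", styrene = "C=Cc1ccccc1",
  ethylbenzene = "CCc1ccccc1", chlorobenzene = "Clc1ccccc1",
  benzaldehyde = "O=Cc1ccccc1", benzonitrile = "N#Cc1ccccc1",
  benzoic_acid = "OC(=O)c1ccccc1", acetophenone = "CC(=O)c1ccccc1",
  pyridine = "c1ccncc1", pyrimidine = "c1cncnc1", pyrrole = "c1cc[nH]c1",
  furan = "c1ccoc1", thiophene = "c1ccsc1", imidazole = "c1c[nH]cn1",
  pyrazole = "c1cc[nH]n1", oxazole = "c1cnco1", picoline = "Cc1ccccn1",
  # monocyclic aliphatics
  cyclopropane = "C1CC1", oxirane = "C1CO1", aziridine = "C1CN1",
  cyclobutane = "C1CCC1", cyclopentane = "C1CCCC1", cyclohexane = "C1CCCCC1",
  methylcyclohexane = "CC1CCCCC1", cyclohexanone = "O=C1CCCCC1",
  cyclohexanol = "OC1CCCCC1", thf = "C1CCOC1", piperidine = "C1CCNCC1",
  morpholine = "C1COCCN1", piperazine = "C1CNCCN1", pyrrolidine = "C1CCNC1",
  methylenecyclohexane = "C=C1CCCCC1",
  # fused / bridged / spiro
  naphthalene = "c1ccc2ccccc2c1", azulene_skel = "C1CCC2CCCC2C1",
  indole = "c1ccc2[nH]ccc2c1", quinoline = "c1ccc2ncccc2c1",
  benzofuran = "c1ccc2occc2c1", benzimidazole = "c1ccc2[nH]cnc2c1",
  indane = "C1Cc2ccccc2C1", decalin = "C1CCC2CCCCC2C1",
  coumarin = "O=c1ccc2ccccc2o1", norbornane = "C1CC2CCC1C2",
  bicyclo222octane = "C1CC2CCC1CC2", adamantane = "C1C2CC3CC1CC(C2)C3",
  cubane = "C12C3C4C1C5C2C3C45", spiro44nonane = "C1CCC2(CCCC2)C1",
  spiro55undecane = "C1CCC2(CC1)CCCCC2",
  # multi-ring with linkers / substituents
  biphenyl = "c1ccc(-c2ccccc2)cc1", diphenylmethane = "c1ccc(Cc2ccccc2)cc1",
  bibenzyl = "c1ccc(CCc2ccccc2)cc1", ethylbiphenyl = "CCc1ccc(-c2ccccc2)cc1",
  phenoxybenzene = "c1ccc(Oc2ccccc2)cc1", benzylpyridine = "c1ccc(Cc2ccccn2)cc1",
  anthracene = "c1ccc2cc3ccccc3cc2c1", phenanthrene_skel = "C1CCC2C(C1)CCC1CCCCC12",
  npa = "O=C(Nc1ccccc1)c1ccccc1", benzophenone = "O=C(c1ccccc1)c1ccccc1",
  phenylimidazole = "c1ccc(-c2cnc[nH]2)cc1"
)

# parsed once for the whole suite
FIXTURE_MOLS <- local({
  mols <- parse_smiles(unname(fixture_smiles))
  names(mols) <- names(fixture_smiles)
  mols
})

ring_bearing_fixture <- function() {
  keep <- vapply(FIXTURE_MOLS, function(m) scaffscape:::circuit_rank(m) > 0L, logical(1))
  FIXTURE_MOLS[keep]
}
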