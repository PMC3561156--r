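# ---------------------------------------------------------------------------
# Bemis-Murcko style partition of a molecule into:
#   murcko framework  = ring systems + linkers (+ retained exocyclic
#                       double-bond atoms such as carbonyl oxygens)
#   graph framework   = murcko with every atom carbon, every bond single
#   rings             = individual SSSR rings
#   ring assemblies   = contiguous ring systems (components after deleting
#                       all non-ring bonds), with retained exocyclic atoms
#   bridge assemblies = assemblies in which some SSSR ring pair shares >= 2 bonds
#   linkers           = acyclic atoms on a direct path between two ring systems
#   side chains       = the remaining acyclic substituents
# ---------------------------------------------------------------------------

# classify atoms of a molecule: returns list with logical vectors
#   ring, linker, exo (retained exocyclic double-bond partner), plus ring bond ids
atom_roles <- function(mol) {
  n <- n_atoms(mol)
  rb <- ring_bond_ids(mol)
  ring <- logical(n); ring[ring_atom_ids(mol, rb)] <- TRUE
  linker <- logical(n)
  if (any(ring) && any(!ring)) {
    # iterative leaf pruning: repeatedly delete acyclic terminal atoms; what
    # survives outside the rings is exactly the atoms sitting on a path
    # between two ring systems
    deg <- atom_degree(mol)
    adj <- adjacency(mol)
    alive <- rep(TRUE, n)
    repeat {
      leaves <- which(alive & !ring & deg <= 1L)
      if (length(leaves) == 0L) break
      alive[leaves] <- FALSE
      for (a in leaves) {
        nb <- adj[[a]]$nbr
        deg[nb] <- deg[nb] - 1L
      }
      deg[leaves] <- 0L
    }
    linker <- alive & !ring
  }
  exo <- logical(n)
  if (n_bonds(mol) > 0L) {
    core <- ring | linker
    b <- mol$bonds
    dbl <- which(b[, 3L] >= 2L)
    for (k in dbl) {
      i <- b[k, 1L]; j <- b[k, 2L]
      if (core[i] && !core[j] && !ring[j]) exo[j] <- TRUE
      if (core[j] && !core[i] && !ring[i]) exo[i] <- TRUE
    }
  }
  list(ring = ring, linker = linker, exo = exo, ring_bonds = rb)
}

#' Murcko framework of a molecule
#'
#' The union of all ring systems and the linkers connecting them, i.e. the
#' molecule with every terminal side chain pruned. Atoms attached to a ring or
#' linker atom by a double (or triple) bond — carbonyl oxygens being the
#' typical case — are retained as part of the framework, matching the
#' Scaffold Tree convention of keeping functionalized ring systems intact.
#'
#' @param mol a molecule object from [parse_smiles()].
#' @return a molecule object, or `NULL` for acyclic molecules.
#' @examples
#' m <- parse_smiles("Cc1ccccc1")[[1]]
#' mol_to_smiles(murcko_framework(m))  # "c1ccccc1"
#' @export
murcko_framework <- function(mol) {
  if (is.null(mol) || circuit_rank(mol) == 0L) return(NULL)
  roles <- atom_roles(mol)
  keep <- which(roles$ring | roles$linker | roles$exo)
  submol(mol, keep)
}

#' Graph framework (topological skeleton) of a scaffold
#'
#' Every atom is relabeled carbon, every formal charge cleared and every bond
#' order set to single, leaving a pure connectivity signature.
#'
#' @param scaffold a non-empty molecule object.
#' @return a molecule object.
#' @export
graph_framework <- function(scaffold) {
  stopifnot(!is.null(scaffold), n_atoms(scaffold) > 0L)
  b <- scaffold$bonds
  if (nrow(b) > 0L) b[, 3L] <- 1L
  new_mol(rep("C", n_atoms(scaffold)), integer(n_atoms(scaffold)), b)
}

#' Individual SSSR rings of a molecule
#'
#' One molecule object per ring of a smallest set of smallest rings; bond
#' orders are inherited from the parent, so a single ring cut out of a fused
#' kekulized aromatic keeps its parent bond pattern.
#'
#' @param mol a molecule object.
#' @return list of molecule objects (empty for acyclic molecules).
#' @export
extract_rings <- function(mol) {
  if (is.null(mol) || circuit_rank(mol) == 0L) return(list())
  rings <- sssr_bonds(mol)
  lapply(rings, function(bids)
    submol(mol, unique(as.integer(mol$bonds[bids, 1:2])), bond_ids = bids))
}

#' Ring assemblies (contiguous ring systems)
#'
#' Deletes every bond not in a ring and returns each connected component that
#' contains a ring, together with exocyclic double-bond atoms attached to its
#' ring atoms.
#'
#' @param mol a molecule object.
#' @return list of molecule objects.
#' @export
extract_ring_assemblies <- function(mol) {
  if (is.null(mol) || circuit_rank(mol) == 0L) return(list())
  rb <- ring_bond_ids(mol)
  ratoms <- ring_atom_ids(mol, rb)
  # components of the ring-bond subgraph
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  g <- igraph::add_edges(g, t(mol$bonds[rb, 1:2, drop = FALSE]))
  memb <- igraph::components(g)$membership
  systems <- split(ratoms, memb[ratoms])
  b <- mol$bonds
  lapply(unname(systems), function(atoms) {
    inside <- logical(n_atoms(mol)); inside[atoms] <- TRUE
    exo <- integer(0); exo_b <- integer(0)
    if (nrow(b) > 0L) {
      for (k in which(b[, 3L] >= 2L)) {
        i <- b[k, 1L]; j <- b[k, 2L]
        if (inside[i] && !inside[j] && !(j %in% ratoms)) { exo <- c(exo, j); exo_b <- c(exo_b, k) }
        if (inside[j] && !inside[i] && !(i %in% ratoms)) { exo <- c(exo, i); exo_b <- c(exo_b, k) }
      }
    }
    keep_bonds <- c(rb[rb %in% which(inside[b[, 1L]] & inside[b[, 2L]])], exo_b)
    submol(mol, c(atoms, exo), bond_ids = keep_bonds)
  })
}

#' Bridge assemblies
#'
#' The subset of ring assemblies in which at least one pair of SSSR rings
#' shares two or more bonds (bridged or ortho-and-peri fused systems, e.g.
#' norbornane; plain fused bicyclics like naphthalene share only one bond and
#' do not qualify).
#'
#' @param mol a molecule object.
#' @return list of molecule objects (a subset of [extract_ring_assemblies()]).
#' @export
extract_bridge_assemblies <- function(mol) {
  assemblies <- extract_ring_assemblies(mol)
  if (length(assemblies) == 0L) return(list())
  keep <- vapply(assemblies, function(a) {
    rings <- sssr_bonds(a)
    if (length(rings) < 2L) return(FALSE)
    for (i in seq_len(length(rings) - 1L)) {
      for (j in seq(i + 1L, length(rings))) {
        if (length(intersect(rings[[i]], rings[[j]])) >= 2L) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  assemblies[keep]
}

#' Linkers and side chains of a molecule
#'
#' Linkers are maximal acyclic fragments whose atoms all lie on a direct path
#' between two ring systems; a direct ring-ring single bond contributes no
#' linker fragment. Side chains are the remaining acyclic substituents, each
#' reported with its attachment point marked by a dummy atom (`*`). Retained
#' exocyclic double-bond atoms belong to the framework and are not side
#' chains. Acyclic molecules yield neither.
#'
#' @param mol a molecule object.
#' @return list with elements `linkers` and `side_chains`, each a list of
#'   molecule objects.
#' @export
extract_acyclic_parts <- function(mol) {
  none <- list(linkers = list(), side_chains = list())
  if (is.null(mol) || circuit_rank(mol) == 0L) return(none)
  roles <- atom_roles(mol)
  n <- n_atoms(mol)
  # linker fragments: components of the linker-atom induced subgraph, each
  # with its retained exocyclic double-bond atoms (an amide linker keeps its
  # carbonyl oxygen)
  linkers <- list()
  la <- which(roles$linker)
  if (length(la) > 0L) {
    sm <- submol(mol, la)
    memb <- mol_components(sm)
    b <- mol$bonds
    for (cmp in unique(memb)) {
      atoms <- attr(sm, "parent_atoms")[memb == cmp]
      exo <- integer(0)
      for (k in which(b[, 3L] >= 2L)) {
        if (b[k, 1L] %in% atoms && roles$exo[b[k, 2L]]) exo <- c(exo, b[k, 2L])
        if (b[k, 2L] %in% atoms && roles$exo[b[k, 1L]]) exo <- c(exo, b[k, 1L])
      }
      linkers[[length(linkers) + 1L]] <- submol(mol, c(atoms, exo))
    }
  }
  # side chains: components of everything outside the framework keep-set
  side <- list()
  keep <- roles$ring | roles$linker | roles$exo
  sa <- which(!keep)
  if (length(sa) > 0L) {
    sm <- submol(mol, sa)
    memb <- mol_components(sm)
    b <- mol$bonds
    for (cmp in unique(memb)) {
      atoms <- attr(sm, "parent_atoms")[memb == cmp]
      frag <- submol(mol, atoms)
      # attachment bond back to the framework -> add a dummy atom
      att <- which((b[, 1L] %in% atoms & keep[b[, 2L]]) |
                   (b[, 2L] %in% atoms & keep[b[, 1L]]))
      if (length(att) >= 1L) {
        k <- att[1L]
        inner <- if (b[k, 1L] %in% atoms) b[k, 1L] else b[k, 2L]
        pa <- attr(frag, "parent_atoms")
        pos <- match(inner, pa)
        frag <- new_mol(c(frag$elem, "*"), c(frag$charge, 0L),
                        rbind(frag$bonds,
                              c(pos, n_atoms(frag) + 1L, b[k, 3L])),
                        arom = c(frag$arom, FALSE),
                        hexp = c(frag$hexp, NA_integer_))
        attr(frag, "parent_atoms") <- pa  # the dummy marks the attachment only
      }
      side[[length(side) + 1L]] <- frag
    }
  }
  list(linkers = linkers, side_chains = side)
}

#' Full scaffold decomposition of one molecule
#'
#' @param mol a molecule object.
#' @return an object of class `scaff_decomposition`: a list with `murcko`,
#'   `graph_framework` (molecule objects or `NULL`), and `rings`,
#'   `ring_assemblies`, `bridge_assemblies`, `linkers`, `side_chains`
#'   (lists of molecule objects).
#' @export
decompose <- function(mol) {
  murcko <- murcko_framework(mol)
  parts <- extract_acyclic_parts(mol)
  structure(list(
    murcko = murcko,
    graph_framework = if (is.null(murcko)) NULL else graph_framework(murcko),
    rings = extract_rings(mol),
    ring_assemblies = extract_ring_assemblies(mol),
    bridge_assemblies = extract_bridge_assemblies(mol),
    linkers = parts$linkers,
    side_chains = parts$side_chains
  ), class = "scaff_decomposition")
}

#' @export
print.scaff_decomposition <- function(x, ...) {
  cat("<scaff_decomposition>\n")
  cat("  murcko:           ", if (is.null(x$murcko)) "(acyclic)" else mol_to_smiles(x$murcko), "\n")
  for (nm in c("rings", "ring_assemblies", "bridge_assemblies", "linkers", "side_chains"))
    cat("  ", format(nm, width = 18), length(x[[nm]]), " fragment(s)\n", sep = "")
  invisible(x)
}

#' Decompose every molecule of a library
#'
#' @param lib a `scaff_library` (see [read_library()]).
#' @return tibble with columns `molecule_id`, `representation` (one of
#'   `murcko`, `graph_framework`, `ring`, `ring_assembly`, `bridge_assembly`,
#'   `linker`, `side_chain`) and `smiles` (stereo-free canonical SMILES of the
#'   fragment); one row per fragment occurrence.
#' @export
decompose_library <- function(lib) {
  stopifnot(inherits(lib, "scaff_library"))
  rows_id <- character(0); rows_rep <- character(0); frags <- list()
  for (i in seq_len(nrow(lib))) {
    d <- decompose(lib$mol[[i]])
    add <- function(rep, ms) {
      if (length(ms) == 0L) return()
      rows_id <<- c(rows_id, rep(lib$id[i], length(ms)))
      rows_rep <<- c(rows_rep, rep(rep, length(ms)))
      frags[seq(length(frags) + 1L, length.out = length(ms))] <<- ms
    }
    if (!is.null(d$murcko)) add("murcko", list(d$murcko))
    if (!is.null(d$graph_framework)) add("graph_framework", list(d$graph_framework))
    add("ring", d$rings)
    add("ring_assembly", d$ring_assemblies)
    add("bridge_assembly", d$bridge_assemblies)
    add("linker", d$linkers)
    add("side_chain", d$side_chains)
  }
  smiles <- if (length(frags) > 0L) mol_to_smiles(frags) else character(0)
  tibble::tibble(molecule_id = rows_id, representation = rows_rep, smiles = smiles)
}

#' Table-2 style fragment census of a decomposition
#'
#' @param decomp output of [decompose_library()].
#' @return tibble with `representation`, `n_total`, `n_unique`.
#' @export
decomposition_census <- function(decomp) {
  decomp |>
    dplyr::group_by(.data$representation) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_unique = dplyr::n_distinct(.data$smiles), .groups = "drop")
}
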