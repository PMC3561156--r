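#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange group_by summarise mutate filter select ungroup n desc left_join bind_rows distinct
#' @importFrom rlang .data
NULL

# ---------------------------------------------------------------------------
# Internal molecular-graph representation.
#
# A molecule is a plain list:
#   elem   - character vector of element symbols ("*" marks an attachment point)
#   charge - integer vector of formal charges
#   hexp   - integer vector: explicit hydrogen count from a SMILES bracket
#            atom (NA when implicit); needed so pyrrole-type [nH] survives
#            fragment extraction and re-kekulization
#   bonds  - integer matrix with columns a1, a2, order (kekulized: 1, 2, 3)
#   arom   - logical vector, one flag per bond: bond belongs to an aromatic
#            ring. Aromatic bonds are exported as MDL type 4 so OpenBabel
#            re-kekulizes fragments whose inherited kekule pattern is broken
#            (e.g. the naphthalene left after cutting one anthracene ring).
# ---------------------------------------------------------------------------

new_mol <- function(elem, charge = integer(length(elem)), bonds = empty_bonds(),
                    arom = NULL, hexp = NULL) {
  stopifnot(length(elem) == length(charge))
  if (is.null(bonds) || nrow(bonds) == 0L) bonds <- empty_bonds()
  storage.mode(bonds) <- "integer"
  if (is.null(arom)) arom <- logical(nrow(bonds))
  if (is.null(hexp)) hexp <- rep(NA_integer_, length(elem))
  stopifnot(length(arom) == nrow(bonds), length(hexp) == length(elem))
  structure(list(elem = as.character(elem), charge = as.integer(charge),
                 hexp = as.integer(hexp), bonds = bonds,
                 arom = as.logical(arom)), class = "scaff_mol")
}

empty_bonds <- function() {
  matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("a1", "a2", "order")))
}

n_atoms <- function(mol) length(mol$elem)
n_bonds <- function(mol) nrow(mol$bonds)

#' @export
print.scaff_mol <- function(x, ...) {
  cat("<scaff_mol> ", n_atoms(x), " heavy atoms, ", n_bonds(x), " bonds: ",
      mol_to_smiles(x), "\n", sep = "")
  invisible(x)
}

mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (n_bonds(mol) > 0L) g <- igraph::add_edges(g, t(mol$bonds[, 1:2, drop = FALSE]))
  g
}

# degree of every atom (heavy-atom graph)
atom_degree <- function(mol) {
  d <- integer(n_atoms(mol))
  if (n_bonds(mol) > 0L) {
    t1 <- tabulate(mol$bonds[, 1L], nbins = n_atoms(mol))
    t2 <- tabulate(mol$bonds[, 2L], nbins = n_atoms(mol))
    d <- t1 + t2
  }
  d
}

# adjacency list: for each atom, data.frame-free list of (nbr, order, bond id)
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  if (n_bonds(mol) == 0L) return(lapply(adj, function(x) list(nbr = integer(0), order = integer(0), bond = integer(0))))
  for (i in seq_len(n_atoms(mol))) adj[[i]] <- list(nbr = integer(0), order = integer(0), bond = integer(0))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1L]; j <- b[k, 2L]; o <- b[k, 3L]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$order <- c(adj[[i]]$order, o); adj[[i]]$bond <- c(adj[[i]]$bond, k)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$order <- c(adj[[j]]$order, o); adj[[j]]$bond <- c(adj[[j]]$bond, k)
  }
  adj
}

mol_components <- function(mol) {
  if (n_atoms(mol) == 0L) return(integer(0))
  igraph::components(mol_graph(mol))$membership
}

#' Circuit rank (number of independent rings) of a molecule
#'
#' bonds - atoms + connected components of the heavy-atom graph; equals the
#' size of any smallest set of smallest rings.
#'
#' @param mol an internal molecule object (see [parse_smiles()]).
#' @return non-negative integer.
#' @keywords internal
circuit_rank <- function(mol) {
  if (n_atoms(mol) == 0L) return(0L)
  n_bonds(mol) - n_atoms(mol) + length(unique(mol_components(mol)))
}

# bond indices that sit in at least one ring (= non-bridge edges)
ring_bond_ids <- function(mol) {
  if (n_bonds(mol) == 0L) return(integer(0))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  setdiff(seq_len(n_bonds(mol)), as.integer(br))
}

ring_atom_ids <- function(mol, rb = ring_bond_ids(mol)) {
  if (length(rb) == 0L) return(integer(0))
  sort(unique(as.integer(mol$bonds[rb, 1:2])))
}

# induced submolecule on an atom subset; bonds restricted to `bond_ids`
# (defaults to all bonds with both ends inside). Returns mol + atom map.
submol <- function(mol, atoms, bond_ids = NULL) {
  atoms <- sort(unique(as.integer(atoms)))
  keep <- logical(n_atoms(mol)); keep[atoms] <- TRUE
  b <- mol$bonds
  sel <- keep[b[, 1L]] & keep[b[, 2L]]
  if (!is.null(bond_ids)) {
    sel2 <- logical(nrow(b)); sel2[bond_ids] <- TRUE
    sel <- sel & sel2
  }
  map <- integer(n_atoms(mol)); map[atoms] <- seq_along(atoms)
  nb <- b[sel, , drop = FALSE]
  if (nrow(nb) > 0L) { nb[, 1L] <- map[nb[, 1L]]; nb[, 2L] <- map[nb[, 2L]] }
  m <- new_mol(mol$elem[atoms], mol$charge[atoms], nb,
               arom = mol$arom[sel], hexp = mol$hexp[atoms])
  # an aromatic flag only survives while the bond still sits in a ring
  if (any(m$arom)) {
    rb <- ring_bond_ids(m)
    inring <- logical(n_bonds(m)); inring[rb] <- TRUE
    m$arom <- m$arom & inring
  }
  attr(m, "parent_atoms") <- atoms
  m
}

# ---------------------------------------------------------------------------
# Implicit hydrogens / molecular weight
# ---------------------------------------------------------------------------

.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1, "*" = 0)

.atomic_mass <- c(H = 1.00794, B = 10.811, C = 12.0107, N = 14.0067, O = 15.9994,
                  F = 18.9984, Si = 28.0855, P = 30.9738, S = 32.065,
                  Cl = 35.453, Br = 79.904, I = 126.9045, "*" = 0,
                  Na = 22.9898, K = 39.0983, Li = 6.941, Ca = 40.078,
                  Mg = 24.305, Fe = 55.845, Zn = 65.38, Se = 78.96, As = 74.9216)

# implicit hydrogen count per atom under a fixed valence model: charge raises
# the valence of N and lowers that of O (ammonium, alkoxide); other elements
# never receive implicit H once their standard valence is exhausted.
implicit_h <- function(mol) {
  val <- .default_valence[mol$elem]
  val[is.na(val)] <- 0
  val <- val + ifelse(mol$elem == "N", mol$charge, 0)
  val <- val + ifelse(mol$elem == "O", mol$charge, 0)
  ords <- numeric(n_atoms(mol))
  if (n_bonds(mol) > 0L) {
    b <- mol$bonds
    for (k in seq_len(nrow(b))) {
      ords[b[k, 1L]] <- ords[b[k, 1L]] + b[k, 3L]
      ords[b[k, 2L]] <- ords[b[k, 2L]] + b[k, 3L]
    }
  }
  pmax(0, round(val - ords))
}

# average molecular weight including implicit hydrogens
mol_mw <- function(mol) {
  m <- .atomic_mass[mol$elem]
  m[is.na(m)] <- 0
  sum(m) + sum(implicit_h(mol)) * .atomic_mass[["H"]]
}

n_heteroatoms <- function(mol, atoms = seq_len(n_atoms(mol))) {
  sum(!(mol$elem[atoms] %in% c("C", "H", "*")))
}

has_carbon <- function(mol) any(mol$elem == "C")

# ---------------------------------------------------------------------------
# SMILES I/O through ChemmineOB (OpenBabel)
# ---------------------------------------------------------------------------

ob_convert <- function(from, to, source) {
  ChemmineOB::convertFormat(from, to, source = source)
}

# batch-canonicalize SMILES; OpenBabel stops a batch at the first unparsable
# record, so still-missing entries are retried in ever-smaller batches with
# the offending record dropped each round. NA marks unparsable entries.
ob_can_batch <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  fill <- function(idx) {
    src <- paste0(smiles[idx], " i", idx, collapse = "\n")
    can <- tryCatch(ob_convert("SMI", "CAN", src), error = function(e) "")
    for (ln in strsplit(can, "\n", fixed = TRUE)[[1]]) {
      if (!nzchar(ln)) next
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      i <- suppressWarnings(as.integer(sub("^i", "", parts[2])))
      if (!is.na(i) && nzchar(trimws(parts[1]))) out[i] <<- trimws(parts[1])
    }
  }
  todo <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  while (length(todo) > 0L) {
    fill(todo)
    missing <- todo[is.na(out[todo])]
    if (length(missing) == 0L) break
    todo <- missing[-1L]  # first missing entry is unparsable: drop, retry rest
  }
  out
}

# charge codes of the V2000 atom line (old-style field parsed by ChemmineR)
.mdl_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# last-resort parse of one V2000 block from its raw lines; only needed for
# degenerate records (e.g. single atoms) whose blocks ChemmineR collapses
mol_from_v2000_lines <- function(lines) {
  counts <- grep("V2000", lines, fixed = TRUE)[1]
  if (is.na(counts)) return(NULL)
  na <- as.integer(substr(lines[counts], 1L, 3L))
  nb <- as.integer(substr(lines[counts], 4L, 6L))
  if (is.na(na) || na < 1L) return(NULL)
  atom_lines <- lines[counts + seq_len(na)]
  elem <- trimws(substr(atom_lines, 32L, 34L))
  bonds <- empty_bonds()
  if (!is.na(nb) && nb > 0L) {
    bond_lines <- lines[counts + na + seq_len(nb)]
    bonds <- cbind(a1 = as.integer(substr(bond_lines, 1L, 3L)),
                   a2 = as.integer(substr(bond_lines, 4L, 6L)),
                   order = pmin(as.integer(substr(bond_lines, 7L, 9L)), 3L))
  }
  chg <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    k <- as.integer(substr(ln, 7L, 9L))
    for (g in seq_len(k)) {
      at <- as.integer(substr(ln, 10L + (g - 1L) * 8L, 13L + (g - 1L) * 8L))
      cv <- as.integer(substr(ln, 14L + (g - 1L) * 8L, 17L + (g - 1L) * 8L))
      chg[at] <- cv
    }
  }
  new_mol(elem, chg, bonds)
}

# split raw SDF text into one character vector of lines per record
split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(i) lines[starts[i]:ends[i]])
}

# `raw`: optional list of raw record lines, positionally aligned with the
# SDFset, used to recover records whose blocks ChemmineR collapses (single
# atoms, zero bonds)
sdfset_to_mols <- function(sdfset, raw = NULL) {
  ids <- ChemmineR::cid(sdfset)
  lapply(seq_along(ids), function(k) {
    sdf <- sdfset[[ids[k]]]
    ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
    bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
    elem <- gsub("_\\d+$", "", rownames(ab))
    if (length(elem) == 0L || !all(grepl("^[A-Za-z*]", elem))) {
      if (!is.null(raw) && k <= length(raw))
        return(tryCatch(mol_from_v2000_lines(raw[[k]]), error = function(e) NULL))
      return(NULL)
    }
    chg <- rep(0L, length(elem))
    if ("C6" %in% colnames(ab)) {
      code <- as.character(as.integer(ab[, "C6"]))
      chg <- unname(.mdl_charge[code])
      chg[is.na(chg)] <- 0L
    }
    bonds <- empty_bonds()
    # ChemmineR drops the matrix class for degenerate blocks
    if (!is.null(bb) && is.null(dim(bb)) && length(bb) >= 3L) bb <- matrix(bb, nrow = 1L)
    if (!is.null(bb) && length(dim(bb)) == 2L && nrow(bb) > 0L && ncol(bb) >= 3L) {
      ord <- as.integer(bb[, 3L])
      ord[ord > 3L] <- 1L  # defensive: aromatic flag 4 should not occur
      bonds <- cbind(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]), order = ord)
    }
    new_mol(elem, chg, bonds)
  })
}

read_sdf_text <- function(sdf_text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_text, tf)
  suppressWarnings(ChemmineR::read.SDFset(tf))
}

# Lex the atom tokens of a SMILES string, in order, returning per-atom
# aromatic flags and bracket explicit-H counts (NA = implicit). OpenBabel
# writes SDF atoms in SMILES token order, which lets these flags be attached
# to the parsed connection table. Only atom tokens are recognized; bonds,
# branches and ring-closure digits are skipped.
smiles_atom_info <- function(smiles) {
  arom <- logical(0); hexp <- integer(0)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- sub("^[0-9]*", "", tok)              # strip isotope
      m <- regmatches(body, regexpr("^(se|as|te|[A-Z][a-z]?|[bcnops]|\\*)", body))
      rest <- substring(body, nchar(m) + 1L)
      h <- 0L
      hm <- regmatches(rest, regexpr("H[0-9]*", rest))
      if (length(hm) == 1L && nzchar(hm)) {
        d <- sub("^H", "", hm)
        h <- if (nzchar(d)) as.integer(d) else 1L
      }
      arom <- c(arom, substr(m, 1L, 1L) %in% letters)
      hexp <- c(hexp, h)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      arom <- c(arom, FALSE); hexp <- c(hexp, NA_integer_); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      arom <- c(arom, FALSE); hexp <- c(hexp, NA_integer_); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      arom <- c(arom, TRUE); hexp <- c(hexp, NA_integer_); i <- i + 1L
    } else if (ch == "*") {
      arom <- c(arom, FALSE); hexp <- c(hexp, NA_integer_); i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  list(arom = arom, hexp = hexp)
}

# attach aromatic/hexp annotations from a canonical SMILES to a parsed mol
annotate_from_smiles <- function(mol, cansmi) {
  info <- smiles_atom_info(cansmi)
  if (length(info$arom) != n_atoms(mol)) return(mol)  # defensive: leave plain
  mol$hexp <- info$hexp
  if (n_bonds(mol) > 0L && any(info$arom)) {
    rb <- ring_bond_ids(mol)
    inring <- logical(n_bonds(mol)); inring[rb] <- TRUE
    mol$arom <- inring & info$arom[mol$bonds[, 1L]] & info$arom[mol$bonds[, 2L]]
  }
  mol
}

# Parse SMILES strings into internal molecule objects.
# Atom order is taken from OpenBabel's canonical SMILES, so identical
# structures yield identical atom orderings regardless of input writing.
# Returns a list, NULL for entries OpenBabel cannot parse.
#' Parse SMILES into internal molecule objects
#'
#' Each SMILES string is canonicalized with OpenBabel and re-read, so the
#' resulting atom ordering is writing-invariant. Unparsable entries yield
#' `NULL`.
#'
#' @param smiles character vector of SMILES strings.
#' @return a list of molecule objects (or `NULL` per failed entry), with the
#'   canonical SMILES of each entry in attribute `"cansmi"`.
#' @examples
#' m <- parse_smiles("c1ccccc1")[[1]]
#' @export
parse_smiles <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  cans <- ob_can_batch(smiles)
  {
    good <- which(!is.na(cans) & nzchar(cans))
    if (length(good) > 0L) {
      src2 <- paste0(cans[good], " i", good, collapse = "\n")
      sdftxt <- ob_convert("SMI", "SDF", src2)
      raw <- split_sdf_records(strsplit(sdftxt, "\n", fixed = TRUE)[[1]])
      sdfset <- read_sdf_text(sdftxt)
      mols <- sdfset_to_mols(sdfset, raw = raw)
      titles <- vapply(ChemmineR::cid(sdfset), function(id)
        as.character(ChemmineR::header(sdfset[[id]])[["Molecule_Name"]]), character(1))
      idxs <- as.integer(sub("^i", "", titles))
      for (k in seq_along(idxs)) {
        if (!is.na(idxs[k]) && !is.null(mols[[k]]))
          out[[idxs[k]]] <- annotate_from_smiles(mols[[k]], cans[idxs[k]])
      }
    }
  }
  attr(out, "cansmi") <- cans
  out
}

# Minimal V2000 MOL block for a molecule (coordinates zeroed, isotopes never
# written, charges carried on M CHG lines). Aromatic bonds are exported as
# MDL type 4 so OpenBabel re-kekulizes them; bracket-H atoms (pyrrole [nH])
# are written as explicit hydrogens, without which kekulization of
# five-membered heteroaromatics fails. `kekule = TRUE` forces the stored
# kekule orders instead (fallback when re-kekulization is impossible).
mol_to_molblock <- function(mol, title = "", kekule = FALSE) {
  elem <- mol$elem; chgv <- mol$charge
  b <- mol$bonds
  ords <- if (n_bonds(mol) > 0L) b[, 3L] else integer(0)
  if (!kekule && any(mol$arom)) ords[mol$arom] <- 4L
  # explicit hydrogens for bracket-H atoms on aromatic bonds
  if (!kekule) {
    arom_atom <- logical(length(elem))
    if (any(mol$arom)) arom_atom[unique(as.integer(b[mol$arom, 1:2]))] <- TRUE
    hs <- which(!is.na(mol$hexp) & mol$hexp > 0L & arom_atom)
    for (a in hs) {
      for (h in seq_len(mol$hexp[a])) {
        elem <- c(elem, "H"); chgv <- c(chgv, 0L)
        b <- rbind(b, c(a, length(elem), 1L)); ords <- c(ords, 1L)
      }
    }
  }
  na <- length(elem); nb <- length(ords)
  header <- c(title, " scaffscape", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  atoms <- vapply(seq_len(na), function(i)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, elem[i]), character(1))
  bonds <- character(0)
  if (nb > 0L) {
    bonds <- vapply(seq_len(nb), function(k)
      sprintf("%3d%3d%3d  0", b[k, 1L], b[k, 2L], ords[k]), character(1))
  }
  chg <- which(chgv != 0L)
  chglines <- character(0)
  if (length(chg) > 0L) {
    for (start in seq(1L, length(chg), by = 8L)) {
      grp <- chg[start:min(start + 7L, length(chg))]
      chglines <- c(chglines, paste0("M  CHG", sprintf("%3d", length(grp)),
                                     paste0(sprintf("%4d%4d", grp, chgv[grp]), collapse = "")))
    }
  }
  paste(c(header, counts, atoms, bonds, chglines, "M  END", "$$$$"), collapse = "\n")
}

#' Canonical SMILES of molecule objects
#'
#' Emits each molecule as a V2000 block and canonicalizes it with OpenBabel in
#' one batched call. Molecule objects carry no stereo descriptors, so the
#' result is always a stereo-free canonical SMILES.
#'
#' @param mols a single molecule object or a list of them (`NULL` entries give
#'   `NA`).
#' @return character vector of canonical SMILES.
#' @export
mol_to_smiles <- function(mols) {
  single <- inherits(mols, "scaff_mol")
  if (single) mols <- list(mols)
  out <- rep(NA_character_, length(mols))
  live <- which(vapply(mols, function(m) !is.null(m) && n_atoms(m) > 0L, logical(1)))
  convert_batch <- function(idx, kekule) {
    blocks <- vapply(idx, function(i)
      mol_to_molblock(mols[[i]], paste0("i", i), kekule = kekule), character(1))
    can <- ob_convert("SDF", "CAN", paste(blocks, collapse = "\n"))
    lines <- strsplit(can, "\n", fixed = TRUE)[[1]]
    for (ln in lines[nzchar(lines)]) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      i <- suppressWarnings(as.integer(sub("^i", "", trimws(parts[2]))))
      if (!is.na(i) && nzchar(trimws(parts[1]))) out[i] <<- trimws(parts[1])
    }
  }
  if (length(live) > 0L) {
    convert_batch(live, kekule = FALSE)
    failed <- live[is.na(out[live])]
    # fragments whose aromatic system cannot be re-kekulized fall back to the
    # inherited kekule bond orders
    if (length(failed) > 0L) convert_batch(failed, kekule = TRUE)
  }
  if (single) out[1] else out
}

#' Canonicalize SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param strip_stereo drop stereo descriptors (`@`, `/`, `\`) before
#'   canonicalizing; scaffold identity in this package is stereo-free while
#'   molecule identity keeps stereochemistry.
#' @return canonical SMILES (`NA` where parsing fails).
#' @export
canonical_smiles <- function(smiles, strip_stereo = FALSE) {
  if (strip_stereo) smiles <- gsub("[@/\\\\]", "", smiles)
  ob_can_batch(smiles)
}

# ---------------------------------------------------------------------------
# Smallest set of smallest rings
# ---------------------------------------------------------------------------

#' Smallest set of smallest rings
#'
#' Horton-style minimum cycle basis of the heavy-atom graph: candidate cycles
#' are built from shortest paths within each ring system, sorted by length
#' (ties by bond-id string for determinism), and reduced greedily over GF(2)
#' until the circuit rank is reached.
#'
#' @param mol a molecule object.
#' @return list of integer vectors, each the bond ids of one SSSR ring.
#' @keywords internal
sssr_bonds <- function(mol) {
  rank <- circuit_rank(mol)
  if (rank == 0L) return(list())
  rb <- ring_bond_ids(mol)
  # process each ring system (component of the ring-bond subgraph) separately
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  g <- igraph::add_edges(g, t(mol$bonds[rb, 1:2, drop = FALSE]))
  memb <- igraph::components(g)$membership
  ratoms <- ring_atom_ids(mol, rb)
  basis <- list()
  for (sys in unique(memb[ratoms])) {
    atoms <- ratoms[memb[ratoms] == sys]
    sys_rb <- rb[mol$bonds[rb, 1L] %in% atoms]
    sub_rank <- length(sys_rb) - length(atoms) + 1L
    sg <- igraph::induced_subgraph(g, atoms)
    # edge <-> bond correspondence inside the subsystem
    ends <- igraph::ends(sg, igraph::E(sg))
    pos <- match(atoms, atoms)  # identity; vertex names below map back
    vmap <- atoms               # subgraph vertex i corresponds to atom vmap[i]
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    bond_lookup <- stats::setNames(sys_rb,
      edge_key(mol$bonds[sys_rb, 1L], mol$bonds[sys_rb, 2L]))
    ge_bond <- unname(bond_lookup[edge_key(vmap[ends[, 1L]], vmap[ends[, 2L]])])
    # Horton candidates: for each vertex v and edge (x,y), cycle =
    # SP(v,x) + SP(v,y) + (x,y) when the two shortest paths are edge-disjoint
    cand <- list(); seen <- character(0)
    nv <- igraph::vcount(sg)
    for (v in seq_len(nv)) {
      epaths <- igraph::shortest_paths(sg, from = v, to = seq_len(nv),
                                       output = "epath")$epath
      for (k in seq_along(ge_bond)) {
        x <- ends[k, 1L]; y <- ends[k, 2L]
        ex <- as.integer(epaths[[x]]); ey <- as.integer(epaths[[y]])
        if (x != v && length(ex) == 0L) next
        if (y != v && length(ey) == 0L) next
        if (length(intersect(ex, ey)) > 0L) next
        eids <- c(ex, ey, k)
        if (anyDuplicated(eids)) next
        bids <- ge_bond[eids]
        at <- as.integer(mol$bonds[bids, 1:2])
        tab <- tabulate(at, nbins = n_atoms(mol))
        if (any(tab != 0L & tab != 2L)) next  # must be a simple cycle
        bids <- sort(bids)
        key <- paste(bids, collapse = ",")
        if (!(key %in% seen)) { seen <- c(seen, key); cand[[length(cand) + 1L]] <- bids }
      }
    }
    ord <- order(vapply(cand, length, integer(1)),
                 vapply(cand, function(b) paste(b, collapse = ","), character(1)))
    cand <- cand[ord]
    # greedy GF(2) independence over bond-incidence vectors
    nb <- n_bonds(mol)
    sel <- list(); rowspace <- matrix(FALSE, nrow = 0L, ncol = nb)
    for (cyc in cand) {
      w <- logical(nb); w[cyc] <- TRUE
      if (nrow(rowspace) > 0L) {
        for (r in seq_len(nrow(rowspace))) {
          piv <- which(rowspace[r, ])[1L]
          if (w[piv]) w <- xor(w, rowspace[r, ])
        }
      }
      if (any(w)) {
        sel[[length(sel) + 1L]] <- cyc
        rowspace <- rbind(rowspace, w)
        rowspace <- rowspace[order(apply(rowspace, 1L, function(x) which(x)[1L])), ,
                             drop = FALSE]
        if (length(sel) == sub_rank) break
      }
    }
    if (length(sel) != sub_rank)
      stop("SSSR search failed to reach circuit rank; molecule graph inconsistent")
    basis <- c(basis, sel)
  }
  basis
}

# atoms of each SSSR ring
sssr_atoms <- function(mol, rings = sssr_bonds(mol)) {
  lapply(rings, function(bids) sort(unique(as.integer(mol$bonds[bids, 1:2]))))
}
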