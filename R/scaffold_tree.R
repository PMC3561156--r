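# ---------------------------------------------------------------------------
# Scaffold Tree: per-molecule chain of scaffolds obtained from the Murcko
# framework by removing one peripheral ring at a time until a single ring
# remains. Level k holds k+1 rings (circuit-rank count); the top level is the
# Murcko framework itself.
#
# Ring removal deletes the bonds exclusive to the chosen SSSR ring and then
# re-prunes the result to a framework, which drops newly dangling linkers and
# exocyclic atoms. A ring is peripheral when this leaves a single connected
# scaffold whose circuit rank dropped by exactly one.
#
# Prioritization cascade among peripheral rings (deterministic, documented):
#   1. remove 3-membered heterorings first
#   2. remove the ring whose removal deletes the fewest acyclic linker bonds
#   3. remove the ring with the fewest heteroatoms
#   4. remove the larger ring
#   5. tie-break: lexicographically smallest canonical SMILES of the parent
# ---------------------------------------------------------------------------

# one removal step: returns list of candidates, each
#   list(mol, ring_size, n_hetero, is_3het, n_acyclic_deleted)
peripheral_candidates <- function(scaffold) {
  rank <- circuit_rank(scaffold)
  rings <- sssr_bonds(scaffold)
  ratoms <- sssr_atoms(scaffold, rings)
  all_ring_bonds <- rings
  out <- list()
  for (r in seq_along(rings)) {
    others <- unlist(all_ring_bonds[-r], use.names = FALSE)
    excl <- setdiff(rings[[r]], others)
    if (length(excl) == 0L) next  # every bond shared: not removable
    keep_bonds <- setdiff(seq_len(n_bonds(scaffold)), excl)
    interim <- submol(scaffold, seq_len(n_atoms(scaffold)), bond_ids = keep_bonds)
    # re-pruning to a framework drops the cut ring's leftover atoms together
    # with any linker or exocyclic atom that dangles once the ring is gone
    cand <- murcko_framework(interim)
    if (is.null(cand)) next
    if (length(unique(mol_components(cand))) != 1L) next
    if (circuit_rank(cand) != rank - 1L) next
    ring_elems <- scaffold$elem[ratoms[[r]]]
    out[[length(out) + 1L]] <- list(
      mol = cand,
      ring_size = length(rings[[r]]),
      n_hetero = sum(!(ring_elems %in% c("C", "*"))),
      is_3het = length(rings[[r]]) == 3L && any(!(ring_elems %in% c("C", "*"))),
      n_acyclic_deleted = (n_bonds(scaffold) - n_bonds(cand)) - length(excl)
    )
  }
  out
}

# pick one candidate by the cascade; canonical SMILES computed lazily (batch)
# Returns list(mol, smiles)
pick_candidate <- function(cands) {
  stopifnot(length(cands) > 0L)
  score <- data.frame(
    is_3het = vapply(cands, function(x) x$is_3het, logical(1)),
    n_acyc = vapply(cands, function(x) x$n_acyclic_deleted, numeric(1)),
    n_het = vapply(cands, function(x) x$n_hetero, numeric(1)),
    size = vapply(cands, function(x) x$ring_size, numeric(1))
  )
  ord <- order(-score$is_3het, score$n_acyc, score$n_het, -score$size)
  best <- score[ord[1L], ]
  tied <- ord[score$is_3het[ord] == best$is_3het & score$n_acyc[ord] == best$n_acyc &
              score$n_het[ord] == best$n_het & score$size[ord] == best$size]
  if (length(tied) == 1L) {
    return(list(mol = cands[[tied]]$mol, smiles = mol_to_smiles(cands[[tied]]$mol)))
  }
  smis <- mol_to_smiles(lapply(tied, function(i) cands[[i]]$mol))
  j <- tied[order(smis)[1L]]
  list(mol = cands[[j]]$mol, smiles = sort(smis)[1L])
}

#' Build the Scaffold Tree chain of a molecule
#'
#' Starting from the Murcko framework, one peripheral ring is removed at a
#' time under the package's prioritization cascade until a single ring
#' remains. The chain is returned bottom-up: element 1 is Level 0 (one ring),
#' the last element is the Murcko framework (Level n-1 for an n-ring
#' framework).
#'
#' @param mol a molecule object, or a SMILES string.
#' @param molecule_id identifier stored in the chain.
#' @return an object of class `scaff_chain`: list with `molecule_id`,
#'   `levels` (character vector of canonical scaffold SMILES, index k+1 =
#'   Level k), `mols` (matching molecule objects) and `n_levels`; `NULL` for
#'   acyclic molecules.
#' @examples
#' ch <- build_chain("c1ccc(-c2ccccc2)cc1")
#' ch$levels  # benzene, then biphenyl
#' @export
build_chain <- function(mol, molecule_id = NA_character_) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  murcko <- murcko_framework(mol)
  if (is.null(murcko)) return(NULL)
  # canonicalize atom order before any rule evaluation so the chain does not
  # depend on how the input molecule happened to be written
  msmi <- mol_to_smiles(murcko)
  if (!is.na(msmi)) {
    reparsed <- parse_smiles(msmi)[[1]]
    if (!is.null(reparsed)) murcko <- reparsed
  }
  chain_mols <- list(murcko)
  chain_smis <- msmi
  cur <- murcko
  while (circuit_rank(cur) > 1L) {
    cands <- peripheral_candidates(cur)
    if (length(cands) == 0L) break  # fully bridged core: no removable ring
    sel <- pick_candidate(cands)
    # re-parse from the canonical SMILES: restores a clean kekule pattern and
    # canonical atom order before the next round of rule evaluation
    if (!is.na(sel$smiles)) {
      reparsed <- parse_smiles(sel$smiles)[[1]]
      cur <- if (!is.null(reparsed)) reparsed else sel$mol
    } else cur <- sel$mol
    chain_mols <- c(chain_mols, list(cur))
    chain_smis <- c(chain_smis, sel$smiles)
  }
  structure(list(molecule_id = molecule_id,
                 levels = rev(chain_smis),
                 mols = rev(chain_mols),
                 n_levels = length(chain_smis)),
            class = "scaff_chain")
}

#' @export
print.scaff_chain <- function(x, ...) {
  cat("<scaff_chain> ", x$n_levels, " level(s)", sep = "")
  if (!is.na(x$molecule_id)) cat(" [", x$molecule_id, "]", sep = "")
  cat("\n")
  for (k in seq_along(x$levels)) cat("  Level ", k - 1L, ": ", x$levels[k], "\n", sep = "")
  invisible(x)
}

#' Scaffold at a given Scaffold Tree level
#'
#' @param chain a `scaff_chain` from [build_chain()].
#' @param k level index (0-based; Level k has k+1 rings).
#' @return the canonical SMILES of the Level-k scaffold, or `NA` when the
#'   molecule has no Level k (fewer than k+1 rings).
#' @export
get_level <- function(chain, k) {
  if (k < 0L) stop("level index must be non-negative")
  if (is.null(chain) || k >= chain$n_levels) return(NA_character_)
  chain$levels[k + 1L]
}

#' Scaffold Tree chains for a whole library
#'
#' Chains are computed once per distinct Murcko framework and joined back to
#' molecules, so heavily populated scaffolds cost a single chain construction.
#'
#' @param lib a `scaff_library`.
#' @return tibble with `molecule_id`, `level`, `smiles` (one row per molecule
#'   per level); molecules without rings contribute no rows. The number of
#'   molecules in the library is kept in attribute `"n_molecules"`.
#' @export
scaffold_chains <- function(lib) {
  stopifnot(inherits(lib, "scaff_library"))
  murckos <- lapply(lib$mol, murcko_framework)
  has_ring <- !vapply(murckos, is.null, logical(1))
  msmi <- rep(NA_character_, nrow(lib))
  if (any(has_ring)) msmi[has_ring] <- mol_to_smiles(murckos[has_ring])
  uniq <- unique(msmi[has_ring])
  chain_by_murcko <- lapply(uniq, function(s) {
    i <- which(msmi == s)[1L]
    build_chain(murckos[[i]])
  })
  names(chain_by_murcko) <- uniq
  rows <- lapply(which(has_ring), function(i) {
    ch <- chain_by_murcko[[msmi[i]]]
    tibble::tibble(molecule_id = lib$id[i],
                   level = seq_len(ch$n_levels) - 1L,
                   smiles = ch$levels)
  })
  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(molecule_id = character(0), level = integer(0), smiles = character(0))
  attr(out, "n_molecules") <- nrow(lib)
  out
}

#' Table-1 style census of Scaffold Tree levels
#'
#' @param chains either the tibble from [scaffold_chains()] or a list of
#'   `scaff_chain` objects.
#' @return tibble with `level`, `n_total` (molecules possessing a Level-k
#'   scaffold) and `n_unique` (distinct Level-k scaffold structures).
#' @export
level_census <- function(chains) {
  if (!is.data.frame(chains)) {
    chains <- chains[!vapply(chains, is.null, logical(1))]
    if (length(chains) == 0L)
      return(tibble::tibble(level = integer(0), n_total = integer(0), n_unique = integer(0)))
    chains <- dplyr::bind_rows(lapply(chains, function(ch)
      tibble::tibble(molecule_id = ch$molecule_id,
                     level = seq_len(ch$n_levels) - 1L, smiles = ch$levels)))
  }
  if (nrow(chains) == 0L)
    return(tibble::tibble(level = integer(0), n_total = integer(0), n_unique = integer(0)))
  chains |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_unique = dplyr::n_distinct(.data$smiles), .groups = "drop") |>
    dplyr::arrange(.data$level)
}
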