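# ---------------------------------------------------------------------------
# Synthetic compound libraries with planted, fully known scaffold structure.
#
# Molecules are assembled as linear chains of ring units drawn from a curated
# pool (simple monocycles, fused bicyclics, bridged cages, spiro systems),
# joined by linker fragments (or direct bonds) and decorated with acyclic
# side chains at atoms with free valence. Because assembly is linear and side
# chains attach by single bonds, the planted scaffold (ring units + linkers)
# is exactly the molecule's Murcko framework, and the ground-truth manifest
# records it together with the implied Scaffold Tree chain.
# ---------------------------------------------------------------------------

pool_path <- function(file) system.file("extdata", file, package = "scaffscape")

read_pool <- function(path) {
  d <- utils::read.delim(path, na.strings = NULL, stringsAsFactors = FALSE)
  d$smiles[is.na(d$smiles)] <- ""
  tibble::as_tibble(d)
}

#' Load the fragment pools of the synthetic generator
#'
#' @param ring_units,linkers,side_chains optional paths to TSV pool files
#'   (columns `name`, `smiles`; attachment points written as `*`); defaults to
#'   the pools shipped with the package.
#' @return list of three tibbles with parsed fragment molecules and derived
#'   metadata (`n_rings`, `n_sites`).
#' @export
load_pools <- function(ring_units = NULL, linkers = NULL, side_chains = NULL) {
  paths <- c(ring_units = ring_units %||% pool_path("ring_units.tsv"),
             linkers = linkers %||% pool_path("linkers.tsv"),
             side_chains = side_chains %||% pool_path("side_chains.tsv"))
  out <- lapply(paths, function(p) {
    d <- read_pool(p)
    mols <- vector("list", nrow(d))
    live <- which(nzchar(d$smiles))
    if (length(live) > 0L) {
      parsed <- parse_smiles(d$smiles[live])
      bad <- live[vapply(parsed, is.null, logical(1))]
      if (length(bad) > 0L) stop("invalid pool entries: ", paste(d$name[bad], collapse = ", "))
      mols[live] <- parsed
    }
    d$mol <- mols
    d$n_rings <- vapply(mols, function(m) if (is.null(m)) 0L else circuit_rank(m), integer(1))
    d$n_sites <- vapply(mols, function(m) if (is.null(m)) 0L else sum(m$elem == "*"), integer(1))
    d
  })
  names(out) <- names(paths)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- graph grafting --------------------------------------------------------

first_dummy <- function(mol) which(mol$elem == "*")[1L]

dummy_neighbor <- function(mol, dummy) {
  b <- mol$bonds
  hit <- which(b[, 1L] == dummy | b[, 2L] == dummy)[1L]
  if (b[hit, 1L] == dummy) b[hit, 2L] else b[hit, 1L]
}

# join two fragments by bonding the attachment neighbors of one dummy in
# each: the growing chain `a` is extended at its most recently added open
# site (highest dummy index), so assembly stays a linear chain and linkers
# are never left dangling
join_frags <- function(a, b) {
  da <- max(which(a$elem == "*")); db <- first_dummy(b)
  stopifnot(!is.na(da), !is.na(db))
  an <- dummy_neighbor(a, da); bn <- dummy_neighbor(b, db)
  a2 <- submol(a, setdiff(seq_len(n_atoms(a)), da))
  b2 <- submol(b, setdiff(seq_len(n_atoms(b)), db))
  an2 <- match(an, attr(a2, "parent_atoms"))
  bn2 <- match(bn, attr(b2, "parent_atoms"))
  off <- n_atoms(a2)
  nb <- b2$bonds
  if (nrow(nb) > 0L) { nb[, 1L] <- nb[, 1L] + off; nb[, 2L] <- nb[, 2L] + off }
  new_mol(c(a2$elem, b2$elem), c(a2$charge, b2$charge),
          rbind(a2$bonds, nb, c(an2, bn2 + off, 1L)),
          arom = c(a2$arom, b2$arom, FALSE),
          hexp = c(a2$hexp, b2$hexp))
}

# attach a one-dummy fragment to a specific atom of mol by a single bond
attach_at <- function(mol, atom, frag) {
  df <- first_dummy(frag)
  fn <- dummy_neighbor(frag, df)
  f2 <- submol(frag, setdiff(seq_len(n_atoms(frag)), df))
  fn2 <- match(fn, attr(f2, "parent_atoms"))
  off <- n_atoms(mol)
  nb <- f2$bonds
  if (nrow(nb) > 0L) { nb[, 1L] <- nb[, 1L] + off; nb[, 2L] <- nb[, 2L] + off }
  hexp <- c(mol$hexp, f2$hexp)
  # attaching to a bracket-H atom (pyrrole NH) consumes that hydrogen
  if (!is.na(hexp[atom]) && hexp[atom] > 0L) hexp[atom] <- hexp[atom] - 1L
  new_mol(c(mol$elem, f2$elem), c(mol$charge, f2$charge),
          rbind(mol$bonds, nb, c(atom, fn2 + off, 1L)),
          arom = c(mol$arom, f2$arom, FALSE),
          hexp = hexp)
}

strip_dummies <- function(mol) {
  keep <- which(mol$elem != "*")
  if (length(keep) == n_atoms(mol)) mol else submol(mol, keep)
}

# ---- configuration ---------------------------------------------------------

#' Configuration for the synthetic library generator
#'
#' The defaults emulate a drug-like screening library: a few thousand
#' molecules over a limited scaffold vocabulary with a Zipf frequency law
#' (few heavily populated scaffolds plus a long tail), one to six rings per
#' molecule with proportions chosen so that roughly 93% of molecules have at
#' least two rings and 70% at least three, and on average about one acyclic
#' substituent per molecule.
#'
#' @param n_molecules library size.
#' @param n_scaffolds number of distinct planted scaffolds.
#' @param frequency_law `"zipf"` (probability of scaffold i proportional to
#'   i^-s) or `"uniform"`.
#' @param zipf_s Zipf exponent (default 1.2).
#' @param rings_law named probability vector over ring counts 1..6 per
#'   scaffold.
#' @param sidechain_lambda Poisson mean of the number of side chains per
#'   molecule.
#' @param mw_target optional target MW histogram: a list with `breaks`
#'   (ascending, in Da) and `probs` (one per bin); decoration then steers each
#'   molecule toward a bin drawn from `probs` (best effort).
#' @param pools fragment pools from [load_pools()].
#' @param seed integer RNG seed.
#' @return a list of class `scaff_genconfig`.
#' @export
generator_config <- function(n_molecules = 1000L,
                             n_scaffolds = 50L,
                             frequency_law = c("zipf", "uniform"),
                             zipf_s = 1.2,
                             rings_law = c(`1` = 0.07, `2` = 0.23, `3` = 0.30,
                                           `4` = 0.20, `5` = 0.12, `6` = 0.08),
                             sidechain_lambda = 1.2,
                             mw_target = NULL,
                             pools = load_pools(),
                             seed = 1L) {
  frequency_law <- match.arg(frequency_law)
  stopifnot(n_molecules >= 1L, n_scaffolds >= 1L, zipf_s > 0,
            all(rings_law >= 0), sum(rings_law) > 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_scaffolds = as.integer(n_scaffolds),
                 frequency_law = frequency_law, zipf_s = zipf_s,
                 rings_law = rings_law / sum(rings_law),
                 sidechain_lambda = sidechain_lambda,
                 mw_target = mw_target, pools = pools, seed = as.integer(seed)),
            class = "scaff_genconfig")
}

#' Read a generator configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [generator_config()]; pool paths
#' may be given under `pools: {ring_units: ..., linkers: ..., side_chains: ...}`.
#'
#' @param path YAML file.
#' @return a `scaff_genconfig`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  pools <- if (!is.null(y$pools))
    load_pools(y$pools$ring_units, y$pools$linkers, y$pools$side_chains)
  else load_pools()
  rings_law <- if (!is.null(y$rings_law)) {
    v <- unlist(y$rings_law); stats::setNames(as.numeric(v), names(v))
  } else eval(formals(generator_config)$rings_law)
  generator_config(
    n_molecules = y$n_molecules %||% 1000L,
    n_scaffolds = y$n_scaffolds %||% 50L,
    frequency_law = y$frequency_law %||% "zipf",
    zipf_s = y$zipf_s %||% 1.2,
    rings_law = rings_law,
    sidechain_lambda = y$sidechain_lambda %||% 1.2,
    mw_target = y$mw_target,
    pools = pools,
    seed = y$seed %||% 1L)
}

# ---- generation ------------------------------------------------------------

# assemble one scaffold as a linear chain of ring units totalling
# `target_rings` basis rings; returns NULL when assembly is impossible
assemble_scaffold <- function(ru, li, target_rings) {
  budget <- target_rings
  cur <- NULL
  units <- character(0); links <- character(0)
  while (budget > 0L) {
    cand <- which(ru$n_rings > 0L & ru$n_rings <= budget)
    # a unit that does not exhaust the budget must keep a second open site
    cand2 <- cand[ru$n_rings[cand] == budget | ru$n_sites[cand] >= 2L]
    if (length(cand2) == 0L) cand2 <- cand
    if (length(cand2) == 0L) return(NULL)
    pick <- cand2[sample.int(length(cand2), 1L)]
    unit <- ru$mol[[pick]]
    units <- c(units, ru$name[pick])
    if (is.null(cur)) {
      cur <- unit
    } else {
      lk <- sample.int(nrow(li), 1L)
      links <- c(links, li$name[lk])
      if (nzchar(li$smiles[lk])) cur <- join_frags(cur, li$mol[[lk]])
      cur <- join_frags(cur, unit)
    }
    budget <- budget - ru$n_rings[pick]
    if (budget > 0L && !any(cur$elem == "*")) return(NULL)  # no open site left
  }
  list(mol = strip_dummies(cur), units = units, links = links)
}

# decorate a scaffold with side chains at atoms with free valence
decorate <- function(scaffold, sc, n_side) {
  mol <- scaffold
  chains <- character(0)
  for (k in seq_len(n_side)) {
    caps <- implicit_h(mol)
    caps[mol$elem %in% c("O", "S", "F", "Cl", "Br", "I")] <- 0L  # substitutable C/N only
    caps[-seq_len(n_atoms(scaffold))] <- 0L  # attach to the framework only
    # never substitute an aromatic NH: pruning such a side chain back off
    # would leave the tautomer assignment to the toolkit and break planted
    # scaffold identity
    if (any(mol$arom)) {
      arom_atom <- unique(as.integer(mol$bonds[mol$arom, 1:2]))
      caps[intersect(arom_atom, which(!is.na(mol$hexp) & mol$hexp > 0L))] <- 0L
    }
    sites <- rep(seq_len(n_atoms(mol)), pmax(0L, caps))
    if (length(sites) == 0L) break
    at <- sites[sample.int(length(sites), 1L)]
    pick <- sample.int(nrow(sc), 1L)
    mol <- attach_at(mol, at, sc$mol[[pick]])
    chains <- c(chains, sc$name[pick])
  }
  list(mol = mol, chains = chains)
}

# assemble `n_target` distinct, self-consistent scaffolds; all OpenBabel
# conversions are batched so large scaffold vocabularies stay fast
make_scaffolds <- function(ru, li, rings_law, n_target) {
  defs <- list(); smis <- character(0)
  rounds <- 0L
  while (length(defs) < n_target && rounds < 50L) {
    rounds <- rounds + 1L
    need <- n_target - length(defs)
    ks <- as.integer(sample(names(rings_law), ceiling(need * 1.4) + 4L,
                            replace = TRUE, prob = rings_law))
    cand <- list()
    for (k in ks) {
      asm <- assemble_scaffold(ru, li, k)
      if (!is.null(asm)) cand[[length(cand) + 1L]] <- asm
    }
    if (length(cand) == 0L) next
    csmi <- mol_to_smiles(lapply(cand, `[[`, "mol"))
    ok <- !is.na(csmi) & !duplicated(csmi) & !(csmi %in% smis)
    cand <- cand[ok]; csmi <- csmi[ok]
    if (length(cand) == 0L) next
    # a planted scaffold must be its own Murcko framework (rings + linkers
    # only, nothing prunable) and survive a SMILES round trip
    rt <- parse_smiles(csmi)
    mur <- lapply(rt, function(m) if (is.null(m)) NULL else murcko_framework(m))
    msmi <- mol_to_smiles(mur)
    ok2 <- which(!is.na(msmi) & msmi == csmi)
    for (i in ok2) {
      if (length(defs) >= n_target) break
      cand[[i]]$smiles <- csmi[i]
      defs[[length(defs) + 1L]] <- cand[[i]]
      smis <- c(smis, csmi[i])
    }
  }
  if (length(defs) < n_target)
    stop("could not assemble ", n_target, " distinct scaffolds")
  defs
}

#' Generate a synthetic compound library with planted ground truth
#'
#' @param config a `scaff_genconfig` from [generator_config()].
#' @param chains also record the implied Scaffold Tree chain of every planted
#'   scaffold in the manifest (default `TRUE`; chain construction is the
#'   expensive part for very large scaffold vocabularies).
#' @return list with `library` (a `scaff_library`) and `manifest` (a tibble
#'   with one row per molecule: `id`, `smiles`, `scaffold_id`, `scaffold`
#'   — the planted Murcko framework —, `n_levels`, and list-columns `chain`
#'   — Level-0..n-1 scaffold SMILES —, `ring_units`, `linkers`,
#'   `side_chains`). Deterministic for a fixed seed.
#' @export
generate_library <- function(config, chains = TRUE) {
  stopifnot(inherits(config, "scaff_genconfig"))
  ru <- config$pools$ring_units; li <- config$pools$linkers; sc <- config$pools$side_chains
  withr::with_seed(config$seed, {
    # 1. unique planted scaffolds
    defs <- make_scaffolds(ru, li, config$rings_law, config$n_scaffolds)
    smis <- vapply(defs, `[[`, character(1), "smiles")
    # 2. scaffold frequency law
    p <- switch(config$frequency_law,
                zipf = (seq_len(config$n_scaffolds))^(-config$zipf_s),
                uniform = rep(1, config$n_scaffolds))
    draw <- sample.int(config$n_scaffolds, config$n_molecules, replace = TRUE,
                       prob = p / sum(p))
    # 3. decoration
    n_side <- stats::rpois(config$n_molecules, config$sidechain_lambda)
    mw_bin <- NULL
    if (!is.null(config$mw_target))
      mw_bin <- sample.int(length(config$mw_target$probs), config$n_molecules,
                           replace = TRUE, prob = config$mw_target$probs)
    mols <- vector("list", config$n_molecules)
    chains_used <- vector("list", config$n_molecules)
    for (i in seq_len(config$n_molecules)) {
      scaf <- defs[[draw[i]]]$mol
      if (is.null(mw_bin)) {
        dec <- decorate(scaf, sc, n_side[i])
      } else {
        lo <- config$mw_target$breaks[mw_bin[i]]
        hi <- config$mw_target$breaks[mw_bin[i] + 1L]
        best <- NULL; bestgap <- Inf
        for (t in seq_len(8L)) {
          cand <- decorate(scaf, sc, n_side[i])
          mw <- mol_mw(cand$mol)
          gap <- if (mw >= lo && mw < hi) 0 else min(abs(mw - lo), abs(mw - hi))
          if (gap < bestgap) { best <- cand; bestgap <- gap }
          if (gap == 0) break
        }
        dec <- best
      }
      mols[[i]] <- dec$mol
      chains_used[[i]] <- dec$chains
    }
    mol_smiles <- mol_to_smiles(mols)
    if (anyNA(mol_smiles)) stop("generator produced an unwritable molecule")
    # 4. implied Scaffold Tree chain, once per unique planted scaffold
    chain_list <- if (chains) {
      lapply(defs, function(d) build_chain(d$smiles)$levels)
    } else {
      rep(list(NULL), length(defs))
    }
    manifest <- tibble::tibble(
      id = sprintf("S%05d", seq_len(config$n_molecules)),
      smiles = mol_smiles,
      scaffold_id = draw,
      scaffold = smis[draw],
      n_levels = if (chains) lengths(chain_list)[draw] else NA_integer_,
      chain = chain_list[draw],
      ring_units = lapply(draw, function(d) defs[[d]]$units),
      linkers = lapply(draw, function(d) defs[[d]]$links),
      side_chains = chains_used
    )
    lib <- library_from_smiles(manifest$smiles, manifest$id, name = "synthetic")
    list(library = lib, manifest = manifest)
  })
}

#' Frequency table from the generator manifest
#'
#' Aggregates the planted Level-k (or Murcko) scaffolds straight from the
#' manifest, independently of the analysis pipeline, for planted-recovery
#' checks.
#'
#' @param manifest the manifest tibble from [generate_library()].
#' @param level integer Scaffold Tree level, or `"murcko"`.
#' @return a `scaff_freq` table.
#' @export
manifest_census <- function(manifest, level = "murcko") {
  if (identical(level, "murcko")) {
    frag <- tibble::tibble(molecule_id = manifest$id, smiles = manifest$scaffold)
  } else {
    stopifnot(is.numeric(level), level >= 0)
    has <- manifest$n_levels > level
    frag <- tibble::tibble(
      molecule_id = manifest$id[has],
      smiles = vapply(manifest$chain[has], function(ch) ch[[level + 1L]], character(1)))
  }
  count_frequencies(frag, n_molecules = nrow(manifest),
                    representation = if (identical(level, "murcko")) "murcko"
                                     else paste0("level", level))
}
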