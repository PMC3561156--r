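# ---------------------------------------------------------------------------
# Reading, standardizing, filtering and subsampling compound libraries.
#
# A scaff_library is a tibble with one row per molecule:
#   id, smiles (canonical, stereo kept), mw, n_rings, source, mol (list-column)
# plus attributes `name` and `log` (per-stage record accounting).
# ---------------------------------------------------------------------------

new_library <- function(records, name, log = list()) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$id)) stop("record IDs must be unique within a library")
  structure(tibble::as_tibble(records),
            name = name, log = log,
            class = c("scaff_library", class(tibble::tibble())))
}

#' @export
print.scaff_library <- function(x, ...) {
  cat("<scaff_library> '", attr(x, "name"), "': ", nrow(x), " molecules\n", sep = "")
  print(tibble::as_tibble(x)[, setdiff(names(x), "mol")], ...)
  invisible(x)
}

#' Library name
#' @param lib a `scaff_library`.
#' @return the library's name string.
#' @export
library_name <- function(lib) attr(lib, "name")

# rebuild a library from a row subset, preserving attributes
lib_subset <- function(lib, idx, log_entry = NULL) {
  out <- tibble::as_tibble(lib)[idx, , drop = FALSE]
  log <- attr(lib, "log")
  if (!is.null(log_entry)) log[[length(log) + 1L]] <- log_entry
  new_library(out, attr(lib, "name"), log)
}

# assemble library records from parsed molecules
records_from_mols <- function(ids, mols, cansmi, source) {
  keep <- which(!vapply(mols, is.null, logical(1)))
  tibble::tibble(
    id = ids[keep],
    smiles = cansmi[keep],
    mw = vapply(mols[keep], mol_mw, numeric(1)),
    n_rings = vapply(mols[keep], circuit_rank, integer(1)),
    source = source,
    mol = mols[keep]
  )
}

#' Read a compound library from SMILES or SDF
#'
#' SMILES files hold one record per line: a SMILES string optionally followed
#' by whitespace and an identifier (a generated `M<row>` id is used when
#' absent). SDF input is parsed with ChemmineR and each record's title used as
#' id.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`.
#' @param name library name (defaults to the file name without extension).
#' @param strict abort on the first unparsable record instead of skipping it.
#' @return a `scaff_library`.
#' @export
read_library <- function(path, format = c("smiles", "sdf"), name = NULL,
                         strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty library: ", path)
    parts <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(parts, `[`, character(1), 1L)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("M", i), character(1))
    mols <- parse_smiles(smi)
    cansmi <- attr(mols, "cansmi")
    bad <- which(vapply(mols, is.null, logical(1)))
    if (length(bad) > 0L) {
      if (strict) stop("unparsable record(s) at line(s): ", paste(bad, collapse = ", "))
      message("read_library: skipped ", length(bad), " unparsable record(s) (lines ",
              paste(utils::head(bad, 10L), collapse = ", "),
              if (length(bad) > 10L) ", ..." else "", ")")
    }
    recs <- records_from_mols(ids, mols, cansmi, name)
  } else {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    if (length(sdfset) == 0L) stop("empty library: ", path)
    valid <- ChemmineR::validSDF(sdfset)
    # validSDF() also rejects legitimate single-atom records; keep those
    natoms <- vapply(seq_along(sdfset), function(i)
      tryCatch(nrow(ChemmineR::atomblock(sdfset[[i]])), error = function(e) 0L),
      integer(1))
    valid <- valid | natoms >= 1L
    if (any(!valid)) {
      if (strict) stop("unparsable SDF record(s) at position(s): ",
                       paste(which(!valid), collapse = ", "))
      message("read_library: skipped ", sum(!valid), " invalid SDF record(s)")
      sdfset <- sdfset[valid]
    }
    raw <- split_sdf_records(readLines(path, warn = FALSE))
    if (any(!valid)) raw <- raw[valid]
    mols <- sdfset_to_mols(sdfset, raw = raw)
    ids <- vapply(seq_along(sdfset), function(i) {
      ttl <- as.character(ChemmineR::header(sdfset[[i]])[["Molecule_Name"]])
      if (nzchar(trimws(ttl))) trimws(ttl) else paste0("M", i)
    }, character(1))
    cansmi <- mol_to_smiles(mols)
    recs <- records_from_mols(ids, mols, cansmi, name)
  }
  if (nrow(recs) == 0L) stop("empty library after parsing: ", path)
  recs$id <- make.unique(recs$id, sep = "_")
  new_library(recs, name,
              list(list(stage = "read", parsed = nrow(recs))))
}

#' Build a library directly from SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers (default `M1`, `M2`, ...).
#' @param name library name.
#' @return a `scaff_library` (unparsable entries are dropped with a message).
#' @export
library_from_smiles <- function(smiles, ids = NULL, name = "library") {
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  mols <- parse_smiles(smiles)
  bad <- sum(vapply(mols, is.null, logical(1)))
  if (bad > 0L) message("library_from_smiles: dropped ", bad, " unparsable entr(y/ies)")
  recs <- records_from_mols(ids, mols, attr(mols, "cansmi"), name)
  if (nrow(recs) == 0L) stop("no parsable molecules")
  new_library(recs, name, list(list(stage = "read", parsed = nrow(recs))))
}

#' Standardize a library
#'
#' Keeps the largest covalently connected fragment of each record (salt
#' stripping), removes records with no carbon atom (inorganics), clears
#' isotopic labels and recanonicalizes. Records whose standardization fails
#' are dropped and counted in the library log.
#'
#' @param lib a `scaff_library`.
#' @return the standardized `scaff_library`.
#' @export
standardize_library <- function(lib) {
  stopifnot(inherits(lib, "scaff_library"))
  keep <- logical(nrow(lib))
  mols <- vector("list", nrow(lib))
  for (i in seq_len(nrow(lib))) {
    m <- standardize_mol(lib$mol[[i]])
    if (!is.null(m)) { keep[i] <- TRUE; mols[[i]] <- m }
  }
  smi <- mol_to_smiles_stereo(lib$smiles[keep], mols[keep])
  ok2 <- !is.na(smi)
  idx <- which(keep)[ok2]
  recs <- tibble::tibble(
    id = lib$id[idx],
    smiles = smi[ok2],
    mw = vapply(mols[idx], mol_mw, numeric(1)),
    n_rings = vapply(mols[idx], circuit_rank, integer(1)),
    source = lib$source[idx],
    mol = mols[idx]
  )
  dropped <- nrow(lib) - nrow(recs)
  if (dropped > 0L) message("standardize_library: dropped ", dropped, " record(s)")
  log <- attr(lib, "log"); log[[length(log) + 1L]] <-
    list(stage = "standardize", kept = nrow(recs), dropped = dropped)
  new_library(recs, attr(lib, "name"), log)
}

# largest fragment + organic filter on a molecule object (stereo-free graph)
standardize_mol <- function(mol) {
  if (is.null(mol) || n_atoms(mol) == 0L) return(NULL)
  memb <- mol_components(mol)
  if (length(unique(memb)) > 1L) {
    sizes <- tabulate(memb)
    # largest fragment; ties broken by MW, then by atom order for determinism
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      mws <- vapply(best, function(cmp) mol_mw(submol(mol, which(memb == cmp))), numeric(1))
      best <- best[order(-mws)][1L]
    } else best <- best[1L]
    mol <- submol(mol, which(memb == best))
  }
  if (!has_carbon(mol)) return(NULL)
  mol
}

# standardized molecule identity keeps stereo: re-derive the canonical SMILES
# of the kept fragment from the original (stereo-bearing) record SMILES by
# picking its largest organic fragment at SMILES level; falls back to the
# stereo-free graph SMILES when the textual split disagrees.
mol_to_smiles_stereo <- function(orig_smiles, mols) {
  graph_smi <- mol_to_smiles(mols)
  out <- graph_smi
  multi <- grepl(".", orig_smiles, fixed = TRUE) |
    grepl("[@/\\\\]", orig_smiles)
  if (!any(multi)) return(out)
  cand <- character(sum(multi))
  mi <- which(multi)
  for (k in seq_along(mi)) {
    frags <- strsplit(orig_smiles[mi[k]], ".", fixed = TRUE)[[1]]
    cand[k] <- frags[which.max(nchar(frags))]
  }
  cand <- gsub("\\[[0-9]+", "[", cand)  # clear isotopic labels
  can <- canonical_smiles(cand)
  for (k in seq_along(mi)) {
    # accept the stereo-bearing fragment only if it matches the kept graph
    if (!is.na(can[k]) &&
        identical(canonical_smiles(can[k], strip_stereo = TRUE), graph_smi[mi[k]]))
      out[mi[k]] <- can[k]
  }
  out
}

#' Filter a library by molecular weight
#'
#' Retains exactly the records with `mw < max_mw` (strict inequality: a
#' record weighing exactly the cutoff is excluded); order preserved.
#'
#' @param lib a `scaff_library`.
#' @param max_mw cutoff in Da (default 600).
#' @return the filtered `scaff_library`.
#' @export
filter_by_mw <- function(lib, max_mw = 600) {
  stopifnot(inherits(lib, "scaff_library"))
  idx <- which(lib$mw < max_mw)
  lib_subset(lib, idx, list(stage = "filter_mw", max_mw = max_mw,
                            kept = length(idx), dropped = nrow(lib) - length(idx)))
}

#' Remove duplicate molecules
#'
#' One record per distinct stereo-bearing canonical SMILES; the first
#' occurrence wins.
#'
#' @param lib a `scaff_library`.
#' @return the deduplicated `scaff_library`.
#' @export
deduplicate <- function(lib) {
  stopifnot(inherits(lib, "scaff_library"))
  idx <- which(!duplicated(lib$smiles))
  lib_subset(lib, idx, list(stage = "deduplicate", kept = length(idx),
                            dropped = nrow(lib) - length(idx)))
}

#' Uniform random subsample of a library
#'
#' @param lib a `scaff_library`.
#' @param n sample size (must not exceed the library size).
#' @param seed integer RNG seed; identical seeds give identical samples.
#' @return a `scaff_library` of `n` records.
#' @export
subsample_random <- function(lib, n, seed) {
  stopifnot(inherits(lib, "scaff_library"))
  if (n > nrow(lib)) stop("requested sample of ", n, " from a library of ", nrow(lib))
  idx <- withr::with_seed(seed, sample.int(nrow(lib), n))
  lib_subset(lib, idx, list(stage = "subsample", n = n, seed = seed))
}

#' Sample a library to match a target molecular weight distribution
#'
#' Draws `n` records from `source` so that the binned MW histogram (fixed
#' `bin_width` bins over \[0, 600)) matches the target's bin proportions as
#' closely as integer quotas allow; per-bin draws are uniform without
#' replacement. When a bin cannot supply its quota the shortfall is
#' redistributed to the nearest bins with spare records (with a warning).
#'
#' @param source library to sample from.
#' @param target library whose MW distribution is to be matched.
#' @param n sample size.
#' @param bin_width histogram bin width in Da (default 25).
#' @param seed integer RNG seed.
#' @return a `scaff_library` of (up to) `n` records, with the achieved
#'   Kolmogorov-Smirnov distance between sampled and target MW empirical
#'   distributions in attribute `"ks_distance"`.
#' @export
match_mw_distribution <- function(source, target, n, bin_width = 25, seed = 1L) {
  stopifnot(inherits(source, "scaff_library"), inherits(target, "scaff_library"))
  if (n > nrow(source)) stop("requested sample of ", n, " from a source of ", nrow(source))
  breaks <- seq(0, max(600, max(source$mw), max(target$mw)) + bin_width, by = bin_width)
  src_bin <- findInterval(source$mw, breaks, rightmost.closed = TRUE)
  tgt_bin <- findInterval(target$mw, breaks, rightmost.closed = TRUE)
  nbin <- length(breaks) - 1L
  tgt_n <- tabulate(tgt_bin, nbins = nbin)
  src_n <- tabulate(src_bin, nbins = nbin)
  # largest-remainder integer quotas proportional to the target histogram
  raw <- n * tgt_n / sum(tgt_n)
  quota <- floor(raw)
  rem <- n - sum(quota)
  if (rem > 0L) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  # truncate infeasible quotas, push shortfall to nearest bins with capacity
  short <- pmax(0L, quota - src_n)
  quota <- pmin(quota, src_n)
  deficit <- sum(short)
  if (deficit > 0L) {
    warning("match_mw_distribution: ", deficit,
            " draw(s) redistributed to adjacent bins (source bins exhausted)")
    for (b in which(short > 0L)) {
      need <- short[b]
      others <- order(abs(seq_len(nbin) - b))
      for (o in others) {
        if (need == 0L) break
        cap <- src_n[o] - quota[o]
        if (cap > 0L) { take <- min(cap, need); quota[o] <- quota[o] + take; need <- need - take }
      }
    }
  }
  idx <- withr::with_seed(seed, {
    unlist(lapply(which(quota > 0L), function(b) {
      pool <- which(src_bin == b)
      pool[sample.int(length(pool), quota[b])]
    }))
  })
  idx <- sort(idx)
  out <- lib_subset(source, idx,
                    list(stage = "match_mw", n = length(idx), bin_width = bin_width, seed = seed))
  ks <- suppressWarnings(stats::ks.test(out$mw, target$mw)$statistic)
  attr(out, "ks_distance") <- unname(ks)
  out
}

#' Write a prepared library to disk
#'
#' Emits a SMILES file (`<name>.smi`: smiles + id per line) and a sidecar TSV
#' (`<name>.tsv`: id, canonical_smiles, mw, n_rings, source).
#'
#' @param lib a `scaff_library`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "scaff_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- attr(lib, "name")
  smi_path <- file.path(dir, paste0(nm, ".smi"))
  tsv_path <- file.path(dir, paste0(nm, ".tsv"))
  writeLines(paste(lib$smiles, lib$id), smi_path)
  utils::write.table(
    data.frame(id = lib$id, canonical_smiles = lib$smiles, mw = round(lib$mw, 4),
               n_rings = lib$n_rings, source = lib$source),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(smi = smi_path, tsv = tsv_path))
}
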