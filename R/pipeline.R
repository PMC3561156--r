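# ---------------------------------------------------------------------------
# End-to-end orchestration: prepare -> decompose -> scaffold tree -> census ->
# CSF -> pairwise overlap -> cluster -> treemap, with a report bundle whose
# tables mirror the published layouts (level census, fragment census, overlap
# tables, CSF curves, treemaps).
# ---------------------------------------------------------------------------

#' Configuration for a full pipeline run
#'
#' @param libraries named list describing the input libraries: each element
#'   either a `scaff_library` or a list with `path` and `format`.
#' @param max_mw molecular weight cutoff in Da (strict `<`; default 600).
#' @param equalize_sizes subsample every library to the smallest prepared
#'   size.
#' @param mw_match_reference name of the library whose MW distribution the
#'   others are matched to (`NULL` to skip matching).
#' @param levels Scaffold Tree levels to analyze (default 1 and 2; the
#'   Level-0 census is always included in the level census output).
#' @param top_n CSF curve depth (default 1000).
#' @param cutoff_grid descending similarity cutoffs for overlap tables.
#' @param target_avg_cluster_size maxmin clustering target (default 50).
#' @param seed integer seed driving every random stage.
#' @param out_dir output directory.
#' @return a list of class `scaff_runconfig`.
#' @export
run_config <- function(libraries, max_mw = 600, equalize_sizes = FALSE,
                       mw_match_reference = NULL, levels = c(1L, 2L),
                       top_n = 1000L, cutoff_grid = seq(1, 0, by = -0.1),
                       target_avg_cluster_size = 50L, seed = 1L,
                       out_dir = tempfile("scaffscape_run")) {
  stopifnot(length(libraries) >= 1L, !is.null(names(libraries)))
  if (!is.null(mw_match_reference) && !mw_match_reference %in% names(libraries))
    stop("mw_match_reference must name one of the libraries")
  structure(list(libraries = libraries, max_mw = max_mw,
                 equalize_sizes = equalize_sizes,
                 mw_match_reference = mw_match_reference,
                 levels = as.integer(levels), top_n = as.integer(top_n),
                 cutoff_grid = cutoff_grid,
                 target_avg_cluster_size = as.integer(target_avg_cluster_size),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "scaff_runconfig")
}

#' Read a pipeline configuration from YAML
#'
#' Expects `libraries:` as a list of `{name, path, format}` entries plus any
#' of the [run_config()] scalar options.
#'
#' @param path YAML file.
#' @return a `scaff_runconfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  libs <- stats::setNames(
    lapply(y$libraries, function(l) list(path = l$path, format = l$format %||% "smiles")),
    vapply(y$libraries, function(l) l$name, character(1)))
  run_config(libraries = libs,
             max_mw = y$max_mw %||% 600,
             equalize_sizes = isTRUE(y$equalize_sizes),
             mw_match_reference = y$mw_match_reference,
             levels = unlist(y$levels) %||% c(1L, 2L),
             top_n = y$top_n %||% 1000L,
             cutoff_grid = unlist(y$cutoff_grid) %||% seq(1, 0, by = -0.1),
             target_avg_cluster_size = y$target_avg_cluster_size %||% 50L,
             seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% "scaffscape_out")
}

write_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  path
}

save_plot <- function(p, path, width = 7, height = 5) {
  grDevices::pdf(path, width = width, height = height)
  print(p)
  grDevices::dev.off()
  path
}

#' Run the full scaffold-architecture pipeline
#'
#' Prepares every library (standardize, MW filter, deduplicate, optional
#' MW-distribution matching and size equalization), decomposes it, builds
#' Scaffold Tree chains, writes level and fragment censuses, CSF curves and
#' plots, pairwise fingerprint overlap tables (when at least two libraries
#' are given), clusters the Level-1 scaffolds and writes treemap layouts,
#' JSON and figures, plus a machine-readable run log.
#'
#' @param config a `scaff_runconfig` from [run_config()].
#' @return invisibly, a list with the prepared libraries, censuses, frequency
#'   tables, overlap tables, cluster models and treemap layouts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "scaff_runconfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("scaffscape")),
              stages = list())
  note <- function(stage, ...) {
    message("[", stage, "] ", ...)
    log$stages[[length(log$stages) + 1L]] <<- list(stage = stage, info = paste0(...))
  }

  # ---- prepare -------------------------------------------------------------
  libs <- list()
  for (nm in names(config$libraries)) {
    spec <- config$libraries[[nm]]
    lib <- if (inherits(spec, "scaff_library")) spec
           else read_library(spec$path, spec$format %||% "smiles", name = nm)
    attr(lib, "name") <- nm
    n0 <- nrow(lib)
    lib <- standardize_library(lib)
    lib <- filter_by_mw(lib, config$max_mw)
    lib <- deduplicate(lib)
    note("prepare", nm, ": ", n0, " read -> ", nrow(lib), " prepared")
    libs[[nm]] <- lib
  }
  if (!is.null(config$mw_match_reference)) {
    ref <- libs[[config$mw_match_reference]]
    for (nm in setdiff(names(libs), config$mw_match_reference)) {
      n <- min(nrow(libs[[nm]]), nrow(ref))
      libs[[nm]] <- match_mw_distribution(libs[[nm]], ref, n, seed = config$seed)
      note("mw_match", nm, ": matched to ", config$mw_match_reference,
           ", KS = ", signif(attr(libs[[nm]], "ks_distance"), 3))
    }
  }
  if (isTRUE(config$equalize_sizes)) {
    n <- min(vapply(libs, nrow, integer(1)))
    for (nm in names(libs)) {
      if (nrow(libs[[nm]]) > n)
        libs[[nm]] <- subsample_random(libs[[nm]], n, seed = config$seed)
    }
    note("equalize", "all libraries subsampled to ", n, " molecules")
  }
  for (lib in libs) write_library(lib, file.path(config$out_dir, "prepared"))

  # ---- decomposition + scaffold tree --------------------------------------
  decomp <- list(); chains <- list(); censuses <- list()
  for (nm in names(libs)) {
    d <- decompose_library(libs[[nm]])
    utils::write.table(d, file.path(config$out_dir, paste0("fragments_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ch <- scaffold_chains(libs[[nm]])
    utils::write.table(ch, file.path(config$out_dir, paste0("chains_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_table(decomposition_census(d),
                file.path(config$out_dir, paste0("fragment_census_", nm, ".csv")))
    write_table(level_census(ch),
                file.path(config$out_dir, paste0("level_census_", nm, ".csv")))
    decomp[[nm]] <- d; chains[[nm]] <- ch
    note("decompose", nm, ": ", nrow(d), " fragments, ",
         length(unique(ch$molecule_id)), " ring-bearing molecules")
  }

  # ---- frequency tables + CSF ---------------------------------------------
  freq <- list(); curves <- list()
  reps <- c("murcko", paste0("level", config$levels))
  for (rep_ in reps) {
    freq[[rep_]] <- list(); curves[[rep_]] <- list()
    for (nm in names(libs)) {
      frag <- if (rep_ == "murcko") {
        dplyr::filter(decomp[[nm]], .data$representation == "murcko")
      } else {
        lv <- as.integer(sub("level", "", rep_))
        dplyr::filter(chains[[nm]], .data$level == lv)
      }
      tab <- count_frequencies(frag, n_molecules = nrow(libs[[nm]]),
                               representation = rep_)
      freq[[rep_]][[nm]] <- tab
      if (nrow(tab) > 0L) {
        cv <- csf_curve(tab, config$top_n)
        curves[[rep_]][[nm]] <- cv
        write_table(cv, file.path(config$out_dir, paste0("csf_", rep_, "_", nm, ".csv")))
      }
    }
    if (length(curves[[rep_]]) > 0L)
      save_plot(plot_csf(curves[[rep_]]),
                file.path(config$out_dir, paste0("csf_", rep_, ".pdf")))
  }
  note("csf", "curves written for ", paste(reps, collapse = ", "))

  # ---- overlap tables ------------------------------------------------------
  overlaps <- list()
  if (length(libs) >= 2L) {
    for (rep_ in reps) {
      sets <- lapply(freq[[rep_]], function(t) t$scaffold)
      sets <- sets[vapply(sets, length, integer(1)) > 0L]
      if (length(sets) >= 2L) {
        ot <- overlap_table(sets, config$cutoff_grid)
        overlaps[[rep_]] <- ot
        write_table(ot, file.path(config$out_dir, paste0("overlap_", rep_, ".csv")))
      }
    }
    note("overlap", "pairwise tables for ", length(libs), " libraries")
  } else {
    note("overlap", "skipped: a single library was given")
  }

  # ---- clustering + treemaps ----------------------------------------------
  models <- list(); layouts <- list()
  for (nm in names(libs)) {
    tab <- freq[["level1"]][[nm]]
    if (is.null(tab)) tab <- freq[["murcko"]][[nm]]
    if (is.null(tab) || nrow(tab) == 0L) next
    model <- cluster_scaffolds(tab, config$target_avg_cluster_size, seed = config$seed)
    layout <- layout_treemap(model)
    write_table(model, file.path(config$out_dir, paste0("clusters_", nm, ".csv")))
    write_treemap_json(layout, file.path(config$out_dir, paste0("treemap_", nm, ".json")))
    save_plot(plot_treemap(layout),
              file.path(config$out_dir, paste0("treemap_", nm, ".pdf")),
              width = 8, height = 6.4)
    models[[nm]] <- model; layouts[[nm]] <- layout
    note("cluster", nm, ": ", length(attr(model, "centers")), " clusters for ",
         nrow(model), " scaffolds")
  }

  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(libraries = libs, decompositions = decomp, chains = chains,
                 frequencies = freq, curves = curves, overlaps = overlaps,
                 clusters = models, treemaps = layouts, log = log))
}
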