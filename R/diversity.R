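# ---------------------------------------------------------------------------
# Scaffold frequency census and cumulative scaffold frequency (CSF) curves.
#
# A frequency table maps scaffold -> occurrence count for one representation
# of one library; the CSF curve sorts the counts descending and accumulates
# them as a percentage of the library size. The denominator is always the
# number of molecules in the prepared library, so a representation that not
# every molecule possesses (e.g. Level 2) caps its curve below 100%.
# ---------------------------------------------------------------------------

#' Scaffold frequency table
#'
#' @param fragments tibble or data.frame with columns `molecule_id` and
#'   `smiles` — one row per fragment occurrence of a single representation of
#'   a single library (e.g. the Murcko rows of [decompose_library()], or one
#'   level of [scaffold_chains()]).
#' @param n_molecules number of molecules in the library (percentage
#'   denominator).
#' @param representation label stored with the table.
#' @return an object of class `scaff_freq`: tibble with `scaffold` and
#'   `count`, sorted by descending count (ties by scaffold string), with
#'   attributes `n_molecules` and `representation`.
#' @export
count_frequencies <- function(fragments, n_molecules,
                              representation = "scaffold") {
  stopifnot(n_molecules >= 0)
  if (nrow(fragments) == 0L) {
    tab <- tibble::tibble(scaffold = character(0), count = integer(0))
  } else {
    tab <- fragments |>
      dplyr::count(.data$smiles, name = "count") |>
      dplyr::rename(scaffold = "smiles") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$scaffold)
  }
  structure(tab, n_molecules = as.integer(n_molecules),
            representation = representation,
            class = c("scaff_freq", class(tibble::tibble())))
}

#' Number of distinct scaffolds in a frequency table
#' @param table a `scaff_freq`.
#' @return integer count of unique scaffolds.
#' @export
n_unique_scaffolds <- function(table) nrow(table)

#' Cumulative scaffold frequency curve
#'
#' Counts are sorted from most to least frequent (ties broken by the scaffold
#' canonical string so the curve is deterministic), truncated to the `top_n`
#' most frequent scaffolds, and accumulated as percentages of the library
#' size.
#'
#' @param table a `scaff_freq` from [count_frequencies()].
#' @param top_n curve depth (default 1000).
#' @return an object of class `scaff_csf`: tibble with `rank`, `scaffold`,
#'   `count`, `cumulative_pct`.
#' @export
csf_curve <- function(table, top_n = 1000L) {
  stopifnot(inherits(table, "scaff_freq"))
  if (top_n <= 0L) stop("top_n must be positive")
  if (nrow(table) == 0L) stop("cannot build a CSF curve from an empty table")
  n_mol <- attr(table, "n_molecules")
  k <- min(top_n, nrow(table))
  out <- tibble::tibble(
    rank = seq_len(k),
    scaffold = table$scaffold[seq_len(k)],
    count = table$count[seq_len(k)],
    cumulative_pct = cumsum(table$count[seq_len(k)]) / n_mol * 100
  )
  structure(out, n_molecules = n_mol,
            representation = attr(table, "representation"),
            class = c("scaff_csf", class(tibble::tibble())))
}

#' Cumulative coverage at a given rank
#'
#' Percentage of the library's molecules represented by the `n` most frequent
#' scaffolds (rank capped at the number of distinct scaffolds).
#'
#' @param table a `scaff_freq`.
#' @param n rank.
#' @return percentage in \[0, 100\].
#' @export
coverage_at <- function(table, n) {
  stopifnot(inherits(table, "scaff_freq"))
  if (nrow(table) == 0L) return(0)
  k <- min(n, nrow(table))
  if (k <= 0L) return(0)
  sum(table$count[seq_len(k)]) / attr(table, "n_molecules") * 100
}

#' Plot CSF curves
#'
#' @param curves a named list of `scaff_csf` objects (names become the legend
#'   labels), or a single curve.
#' @return a ggplot object in the style of a top-N cumulative frequency plot.
#' @export
plot_csf <- function(curves) {
  if (inherits(curves, "scaff_csf")) curves <- list(library = curves)
  df <- dplyr::bind_rows(lapply(names(curves), function(nm)
    tibble::tibble(library = nm, rank = curves[[nm]]$rank,
                   cumulative_pct = curves[[nm]]$cumulative_pct)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cumulative_pct,
                                   colour = .data$library)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Number of most frequent scaffolds",
                  y = "Cumulative scaffold frequency (% of molecules)",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_bw()
}
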