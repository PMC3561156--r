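# ---------------------------------------------------------------------------
# Maxmin clustering of unique scaffolds and squarified treemap layout.
#
# Cluster count is fixed at ceil(N / target_avg_size). The first center is
# drawn uniformly under the seed; each further center is the scaffold whose
# minimum 1 - Tanimoto distance to all chosen centers is largest (ties broken
# by scaffold canonical string). Every non-center joins its nearest center,
# ties toward the lower cluster index. Clustering sees each unique scaffold
# once; frequencies only size the display.
# ---------------------------------------------------------------------------

#' Maxmin clustering of scaffolds
#'
#' @param scaffolds a `scaff_freq` table, or a tibble with columns `scaffold`
#'   and `count` (unique scaffolds with frequencies).
#' @param target_avg_size target average cluster size (default 50); the
#'   number of centers is `ceil(N / target_avg_size)`.
#' @param seed integer RNG seed (first-center choice).
#' @param diameter fingerprint diameter.
#' @return an object of class `scaff_clusters`: tibble with `scaffold`,
#'   `frequency`, `cluster` (1-based), `is_center`, `cluster_size`,
#'   `distance_to_closest` (1 - Tanimoto to the own cluster center; 0 for
#'   centers), plus attributes `centers` (scaffold strings) and `seed`.
#' @export
cluster_scaffolds <- function(scaffolds, target_avg_size = 50L, seed = 1L,
                              diameter = 6L) {
  if (target_avg_size <= 0L) stop("target_avg_size must be positive")
  stopifnot(all(c("scaffold", "count") %in% names(scaffolds)))
  if (anyDuplicated(scaffolds$scaffold)) stop("scaffolds must be unique")
  smis <- scaffolds$scaffold
  freq <- scaffolds$count
  N <- length(smis)
  if (N == 0L) stop("no scaffolds to cluster")
  k <- as.integer(ceiling(N / target_avg_size))
  fps <- fingerprint_set(smis, diameter)
  D <- 1 - tanimoto_matrix(fps, fps)
  centers <- integer(k)
  centers[1L] <- withr::with_seed(seed, sample.int(N, 1L))
  if (k > 1L) {
    mind <- D[, centers[1L]]
    for (j in seq(2L, k)) {
      best <- max(mind)
      tied <- which(mind >= best - 1e-12)
      centers[j] <- tied[order(smis[tied])][1L]
      mind <- pmin(mind, D[, centers[j]])
    }
  }
  dc <- D[, centers, drop = FALSE]
  assign <- apply(dc, 1L, which.min)  # ties to the lower cluster index
  assign[centers] <- seq_len(k)       # a center belongs to its own cluster
  dmin <- dc[cbind(seq_len(N), assign)]
  dmin[centers] <- 0
  sizes <- tabulate(assign, nbins = k)
  out <- tibble::tibble(
    scaffold = smis, frequency = freq, cluster = as.integer(assign),
    is_center = seq_len(N) %in% centers,
    cluster_size = sizes[assign],
    distance_to_closest = dmin
  )
  structure(out, centers = smis[centers], seed = seed,
            class = c("scaff_clusters", class(tibble::tibble())))
}

# ---------------------------------------------------------------------------
# Squarified treemap (Bruls, Huizing & van Wijk): areas proportional to
# weights; at each step a row of rectangles is laid along the shorter side of
# the free rectangle while that improves the worst aspect ratio.
# ---------------------------------------------------------------------------

squarify <- function(values, x, y, w, h) {
  stopifnot(all(values > 0))
  n <- length(values)
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0)))
  areas <- values / sum(values) * (w * h)
  out <- matrix(NA_real_, nrow = n, ncol = 4L)
  i <- 1L
  worst <- function(row, side) {
    s <- sum(row)
    mx <- max(row); mn <- min(row)
    max((side^2 * mx) / s^2, s^2 / (side^2 * mn))
  }
  while (i <= n) {
    side <- min(w, h)
    row <- areas[i]
    j <- i
    while (j < n) {
      if (worst(c(row, areas[j + 1L]), side) <= worst(row, side)) {
        j <- j + 1L; row <- c(row, areas[j])
      } else break
    }
    thick <- sum(row) / side
    off <- 0
    for (t in seq_along(row)) {
      len <- row[t] / thick
      if (w <= h) {  # lay the row horizontally along the top
        out[i + t - 1L, ] <- c(x + off, y, len, thick)
      } else {       # lay the row vertically along the left edge
        out[i + t - 1L, ] <- c(x, y + off, thick, len)
      }
      off <- off + len
    }
    if (w <= h) { y <- y + thick; h <- h - thick } else { x <- x + thick; w <- w - thick }
    i <- j + 1L
  }
  data.frame(x = out[, 1L], y = out[, 2L], w = out[, 3L], h = out[, 4L])
}

#' Frequency-weighted treemap layout of a cluster model
#'
#' Nested squarified rectangles: the canvas is tiled by one region per
#' cluster (area proportional to the cluster's summed scaffold frequency),
#' and each cluster region is tiled by one rectangle per scaffold (area
#' proportional to its frequency). Continuous coordinates keep area ratios
#' exactly proportional to frequency ratios.
#'
#' @param model a `scaff_clusters` from [cluster_scaffolds()] (carries the
#'   frequencies).
#' @param width,height canvas size (default 1000 x 800).
#' @return an object of class `scaff_treemap`: tibble with `scaffold`,
#'   `cluster`, `is_center`, `cluster_size`, `distance_to_closest`,
#'   `frequency`, `x`, `y`, `w`, `h`.
#' @export
layout_treemap <- function(model, width = 1000, height = 800) {
  stopifnot(inherits(model, "scaff_clusters"))
  if (sum(model$frequency) <= 0) stop("total scaffold frequency must be positive")
  cl <- model |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(total = sum(.data$frequency), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$cluster)
  crects <- squarify(cl$total, 0, 0, width, height)
  rows <- lapply(seq_len(nrow(cl)), function(ci) {
    members <- model |>
      dplyr::filter(.data$cluster == cl$cluster[ci]) |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$scaffold)
    r <- squarify(members$frequency, crects$x[ci], crects$y[ci],
                  crects$w[ci], crects$h[ci])
    dplyr::bind_cols(members, tibble::as_tibble(r))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, width = width, height = height, seed = attr(model, "seed"),
            class = c("scaff_treemap", class(tibble::tibble())))
}

#' Plot a treemap layout
#'
#' Scaffold rectangles are filled by frequency (log scale); cluster
#' boundaries are drawn as heavy outlines.
#'
#' @param layout a `scaff_treemap`.
#' @return a ggplot object.
#' @export
plot_treemap <- function(layout) {
  stopifnot(inherits(layout, "scaff_treemap"))
  cl_bounds <- layout |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(xmin = min(.data$x), ymin = min(.data$y),
                     xmax = max(.data$x + .data$w), ymax = max(.data$y + .data$h),
                     .groups = "drop")
  ggplot2::ggplot(layout) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$x, ymin = .data$y,
                                    xmax = .data$x + .data$w, ymax = .data$y + .data$h,
                                    fill = .data$frequency),
                       colour = "white", linewidth = 0.1) +
    ggplot2::geom_rect(data = cl_bounds,
                       ggplot2::aes(xmin = .data$xmin, ymin = .data$ymin,
                                    xmax = .data$xmax, ymax = .data$ymax),
                       fill = NA, colour = "grey30", linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "Scaffold\nfrequency")
}

#' Export a treemap layout as JSON
#'
#' @param layout a `scaff_treemap`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_treemap_json <- function(layout, path) {
  stopifnot(inherits(layout, "scaff_treemap"))
  recs <- lapply(seq_len(nrow(layout)), function(i) list(
    scaffold = layout$scaffold[i], cluster_number = layout$cluster[i],
    is_center = layout$is_center[i], cluster_size = layout$cluster_size[i],
    distance_to_closest = layout$distance_to_closest[i],
    frequency = layout$frequency[i],
    x = layout$x[i], y = layout$y[i], w = layout$w[i], h = layout$h[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
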