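spot_coords <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    return(unname(points))
  }
  nm <- names(points)
  cols <- if (all(c("x_um", "y_um", "z_um") %in% nm)) {
    c("x_um", "y_um", "z_um")
  } else if (all(c("x", "y", "z") %in% nm)) {
    c("x", "y", "z")
  } else {
    stop("points need columns x_um/y_um/z_um (or x/y/z)")
  }
  unname(as.matrix(points[, cols]))
}

#' Mean distance to the k nearest neighbours of each spot
#'
#' For every 3D spot, the mean Euclidean distance to its `k` nearest other
#' spots (the spot itself excluded; default k = 9, matching the published
#' spheroid analysis). Spots whose mean exceeds `cutoff` are flagged -- the
#' rule used to highlight spots more than 60 micrometres from their 9 nearest
#' neighbours.
#'
#' @param points A tibble/data frame with coordinate columns `x_um`, `y_um`,
#'   `z_um` (or `x`, `y`, `z`), or a 3-column matrix, in micrometres.
#' @param k Number of nearest neighbours (default 9); needs at least `k + 1`
#'   spots.
#' @param cutoff Flagging threshold in micrometres (default 60).
#' @return The input rows as a tibble with added `mean_distance` and `flagged`
#'   columns.
#' @export
knn_mean_distances <- function(points, k = 9, cutoff = 60) {
  xyz <- spot_coords(points)
  n <- nrow(xyz)
  if (n < k + 1) {
    stop("need at least k + 1 = ", k + 1, " spots, got ", n)
  }
  d <- as.matrix(stats::dist(xyz))
  md <- vapply(seq_len(n), function(i) {
    mean(sort(d[i, -i], partial = seq_len(k))[seq_len(k)])
  }, numeric(1))
  base <- if (is.matrix(points)) {
    tibble::tibble(x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3])
  } else {
    tibble::as_tibble(points)
  }
  dplyr::mutate(base, mean_distance = md, flagged = md > cutoff)
}

#' Per-spot distances grouped by spheroid
#'
#' Applies [knn_mean_distances()] within each spheroid of a spot table.
#'
#' @param spots Tibble with a `spheroid` column and coordinate columns.
#' @inheritParams knn_mean_distances
#' @return The input tibble with `mean_distance` and `flagged` added.
#' @export
spot_distances_by_spheroid <- function(spots, k = 9, cutoff = 60) {
  stopifnot("spheroid" %in% names(spots))
  spots |>
    dplyr::group_by(.data$spheroid) |>
    dplyr::group_modify(~ knn_mean_distances(.x, k = k, cutoff = cutoff)) |>
    dplyr::ungroup()
}

#' Pooled distance statistics across spheroids
#'
#' Per-spheroid n / mean / SD of the per-spot mean distances, plus the pooled
#' statistics computed from group totals: the total mean is the total sum of
#' distances over the total number of spots, and the total SD comes from the
#' total sum of squared deviations about the pooled mean (sample convention,
#' n - 1), exactly as the published spheroid comparisons pool their 8
#' spheroids per condition.
#'
#' @param spots A tibble with columns `spheroid` and `mean_distance` (e.g.
#'   from [spot_distances_by_spheroid()]), or a list of per-spheroid numeric
#'   vectors.
#' @return A `pooled_stats` object; see [tidy()] for the per-spheroid table
#'   and [glance()] for the pooled row.
#' @export
pooled_stats <- function(spots) {
  if (is.list(spots) && !is.data.frame(spots)) {
    if (length(spots) == 0) stop("no spheroids supplied")
    nm <- names(spots)
    if (is.null(nm)) nm <- paste0("spheroid_", seq_along(spots))
    spots <- purrr::map2_dfr(spots, nm, function(v, id) {
      tibble::tibble(spheroid = id, mean_distance = as.numeric(v))
    })
  }
  stopifnot(all(c("spheroid", "mean_distance") %in% names(spots)))
  if (nrow(spots) == 0) stop("no spots supplied")
  per <- spots |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$mean_distance),
                     sd = sd(.data$mean_distance),
                     .by = "spheroid")
  total_n <- sum(per$n)
  total_mean <- sum(per$n * per$mean) / total_n
  ss <- sum((per$n - 1) * ifelse(is.na(per$sd), 0, per$sd)^2 +
              per$n * (per$mean - total_mean)^2)
  total_sd <- if (total_n > 1) sqrt(ss / (total_n - 1)) else NA_real_
  structure(list(per_spheroid = per, total_n = total_n,
                 total_mean = total_mean, total_sd = total_sd,
                 total_ss = ss),
            class = "pooled_stats")
}

#' @export
print.pooled_stats <- function(x, ...) {
  cat("<pooled_stats> ", nrow(x$per_spheroid), " spheroid(s), ",
      x$total_n, " spots: pooled mean ", signif(x$total_mean, 5),
      ", pooled sd ", signif(x$total_sd, 5), "\n", sep = "")
  invisible(x)
}

#' @describeIn pooled_stats Per-spheroid n / mean / SD.
#' @param x A `pooled_stats` object.
#' @param ... Unused.
#' @export
tidy.pooled_stats <- function(x, ...) {
  x$per_spheroid
}

#' @describeIn pooled_stats One-row pooled summary.
#' @export
glance.pooled_stats <- function(x, ...) {
  tibble::tibble(total_n = x$total_n, total_mean = x$total_mean,
                 total_sd = x$total_sd, n_spheroids = nrow(x$per_spheroid))
}

#' Two-sample t and F tests from pooled totals
#'
#' Student's t statistic (pooled-variance form by default, Welch by flag) and
#' the variance-ratio F statistic (larger variance in the numerator, n - 1
#' degrees of freedom each, two-sided p as twice the smaller tail) computed
#' from the groups' total counts, pooled means and pooled SDs -- the
#' summary-statistics form used for the spheroid distance comparisons.
#'
#' @param a,b `pooled_stats` objects (or lists with `total_n`, `total_mean`,
#'   `total_sd`).
#' @param var_equal Pooled-variance Student's t (default) or Welch's t.
#' @return One-row tibble: `t_statistic`, `t_df`, `t_p`, `f_statistic`,
#'   `f_df1`, `f_df2`, `f_p`.
#' @export
two_sample_tests_from_totals <- function(a, b, var_equal = TRUE) {
  n1 <- a$total_n; m1 <- a$total_mean; s1 <- a$total_sd
  n2 <- b$total_n; m2 <- b$total_mean; s2 <- b$total_sd
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 == 0 && s2 == 0) stop("both groups have zero variance")
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    t_df <- n1 + n2 - 2
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    t_stat <- (m1 - m2) / sqrt(se2)
    t_df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  t_p <- 2 * pt(-abs(t_stat), df = t_df)
  if (s1 >= s2) {
    f_stat <- s1^2 / s2^2; f_df1 <- n1 - 1; f_df2 <- n2 - 1
  } else {
    f_stat <- s2^2 / s1^2; f_df1 <- n2 - 1; f_df2 <- n1 - 1
  }
  lower <- pf(f_stat, f_df1, f_df2, lower.tail = TRUE)
  upper <- pf(f_stat, f_df1, f_df2, lower.tail = FALSE)
  f_p <- 2 * min(lower, upper)
  tibble::tibble(t_statistic = t_stat, t_df = t_df, t_p = t_p,
                 f_statistic = f_stat, f_df1 = f_df1, f_df2 = f_df2,
                 f_p = f_p)
}

#' Read or write a spot coordinate table
#'
#' CSV with header `spheroid,x_um,y_um,z_um` (coordinates in micrometres).
#'
#' @param path CSV path.
#' @param spots Tibble with those columns.
#' @return `read_spots()` returns a tibble.
#' @export
read_spots <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("spheroid", "x_um", "y_um", "z_um") %in% names(df)))
  tibble::as_tibble(df)
}

#' @rdname read_spots
#' @export
write_spots <- function(spots, path) {
  stopifnot(all(c("spheroid", "x_um", "y_um", "z_um") %in% names(spots)))
  write.csv(spots[, c("spheroid", "x_um", "y_um", "z_um")], path,
            row.names = FALSE)
  invisible(path)
}
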