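#' Synthetic spheroid masks with known ground truth
#'
#' Generates binary masks emulating spheroid silhouettes: smooth `"circle"`
#' masks (like knockdown spheroids without protrusions) and `"star"` masks
#' whose radius is modulated by `n_arms` cosine protrusions of amplitude
#' `arm_length` (like protrusion-bearing control spheroids). The returned
#' ground truth records the exact pixel area and the protrusion count, so
#' quantification round-trips can be checked.
#'
#' @param kind `"circle"` or `"star"`.
#' @param radius Base radius in pixels (>= 3).
#' @param n_arms Number of protrusions (star only).
#' @param arm_length Protrusion amplitude in pixels (star only).
#' @param margin Background border width.
#' @return A list with `mask` (logical matrix) and `truth` (one-row tibble:
#'   `kind`, `radius`, `n_arms`, `arm_length`, `area_px`).
#' @export
make_mask <- function(kind = c("circle", "star"), radius = 50, n_arms = 8,
                      arm_length = radius / 2, margin = 5) {
  kind <- match.arg(kind)
  if (radius < 3) stop("radius too small to rasterise (need >= 3)")
  rmax <- if (kind == "star") radius + arm_length else radius
  side <- 2L * as.integer(ceiling(rmax + margin)) + 1L
  ctr <- (side + 1) / 2
  x <- matrix(seq_len(side), side, side) - ctr
  y <- matrix(seq_len(side), side, side, byrow = TRUE) - ctr
  r <- sqrt(x^2 + y^2)
  mask <- if (kind == "circle") {
    r <= radius
  } else {
    theta <- atan2(y, x)
    r <= radius + arm_length * (0.5 + 0.5 * cos(n_arms * theta))
  }
  list(
    mask = mask,
    truth = tibble::tibble(
      kind = kind, radius = radius,
      n_arms = if (kind == "star") as.integer(n_arms) else NA_integer_,
      arm_length = if (kind == "star") arm_length else NA_real_,
      area_px = sum(mask)
    )
  )
}

#' Synthetic marker/region mask pair with a known positive fraction
#'
#' Builds a square region of `region_size` pixels and places exactly
#' `round(positive_fraction * region_size)` marker pixels inside it (uniformly
#' at random), so [positive_ratio()] recovers the fraction exactly.
#'
#' @param positive_fraction Target marker-positive fraction in `[0, 1]`.
#' @param region_size Region size in pixels (a perfect square gives a square
#'   region; otherwise the last row is partial).
#' @param margin Background border width.
#' @param seed Optional RNG seed for reproducible marker placement.
#' @return A list with `marker`, `region` (logical matrices) and `truth`
#'   (one-row tibble: `region_px`, `marker_px`, `true_fraction`).
#' @export
make_marker_pair <- function(positive_fraction, region_size = 400, margin = 5,
                             seed = NULL) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1, region_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  side <- as.integer(ceiling(sqrt(region_size)))
  dim_out <- side + 2L * margin
  region <- matrix(FALSE, dim_out, dim_out)
  cells <- arrayInd(seq_len(region_size), c(side, side))
  region[cbind(cells[, 1] + margin, cells[, 2] + margin)] <- TRUE
  n_marker <- round(positive_fraction * region_size)
  marker <- matrix(FALSE, dim_out, dim_out)
  if (n_marker > 0) {
    pick <- sample.int(region_size, n_marker)
    marker[cbind(cells[pick, 1] + margin, cells[pick, 2] + margin)] <- TRUE
  }
  list(marker = marker, region = region,
       truth = tibble::tibble(region_px = region_size, marker_px = n_marker,
                              true_fraction = n_marker / region_size))
}

runif_sphere <- function(n, radius) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  r <- radius * runif(n)^(1 / 3)
  v * r
}

#' Synthetic 3D spot sets: uniform vs clustered
#'
#' Emulates the pre-stained mixed-spheroid geometries: group A is uniform in a
#' sphere (evenly distributed cells), group B places `1 - background_fraction`
#' of its spots in tight Gaussian clusters plus a uniform background (patchy,
#' peripheral cells). At matched n, the clustered set has a wider spread of
#' per-spot k-nearest-neighbour means, which the F test on pooled statistics
#' detects.
#'
#' @param n_points Spots per set.
#' @param radius Sphere radius in micrometres (default 200).
#' @param n_clusters Gaussian clusters in the clustered set (default 4).
#' @param cluster_sd Cluster SD in micrometres (default 15).
#' @param background_fraction Fraction of clustered-set spots scattered
#'   uniformly (default 0.2).
#' @param spheroid Label stamped on both sets.
#' @param seed Optional RNG seed.
#' @return A list with `uniform` and `clustered` spot tibbles (`spheroid`,
#'   `x_um`, `y_um`, `z_um`) and `truth` (the generating parameters).
#' @export
make_spots <- function(n_points = 500, radius = 200, n_clusters = 4,
                       cluster_sd = 15, background_fraction = 0.2,
                       spheroid = "S1", seed = NULL) {
  stopifnot(n_points > 10, radius > 0, n_clusters >= 1)
  if (!is.null(seed)) set.seed(seed)
  as_spots <- function(m) {
    tibble::tibble(spheroid = spheroid, x_um = m[, 1], y_um = m[, 2],
                   z_um = m[, 3])
  }
  uniform <- runif_sphere(n_points, radius)
  n_bg <- round(background_fraction * n_points)
  n_cl <- n_points - n_bg
  centers <- runif_sphere(n_clusters, 0.6 * radius)
  assign <- sample.int(n_clusters, n_cl, replace = TRUE)
  clustered <- centers[assign, , drop = FALSE] +
    matrix(stats::rnorm(3 * n_cl, sd = cluster_sd), ncol = 3)
  clustered <- rbind(clustered, runif_sphere(n_bg, radius))
  list(uniform = as_spots(uniform), clustered = as_spots(clustered),
       truth = tibble::tibble(n_points = n_points, radius = radius,
                              n_clusters = n_clusters, cluster_sd = cluster_sd,
                              background_fraction = background_fraction))
}
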