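preset_names <- c("base_ppa", "mpa_growth3x", "mpa_low_adhesion",
                  "spa_growth10x", "spa_low_polarity", "spa_uniform_j",
                  "apa_mucus", "lpa_v1", "lpa_v2", "ppa_stromal_growth",
                  "spheroid_mixture")

#' Named model presets
#'
#' Returns the fully-resolved configuration of one of the eleven published
#' model variants. All presets are deltas from the base (papillary) model:
#' cancer growth rate 0.03, contact energy of tumor-basal to stromal cells and
#' matrix 3, contact energy of tumor-apical and tumor-basal to the other tumor
#' sub-compartments 40, run for 4000 MCS.
#'
#' * `base_ppa` -- the base papillary model.
#' * `mpa_growth3x` -- growth 0.09, 1400 MCS (micropapillary via 3x growth).
#' * `mpa_low_adhesion` -- J(tumor-basal, stroma/matrix) = 30, 4000 MCS.
#' * `spa_growth10x` -- growth 0.3, 600 MCS (solid via 10x growth).
#' * `spa_low_polarity` -- J(tumor-apical/basal, other tumor subdomains) = 10.
#' * `spa_uniform_j` -- every tumor subdomain pair at J = 10.
#' * `apa_mucus` -- base plus apical mucus secretion (acinar).
#' * `lpa_v1` -- growth 0.022, cancer death 0.00065, normal death 0.0001,
#'   40000 MCS (first lepidic model).
#' * `lpa_v2` -- growth 0.3 with 0.997 contact inhibition, cancer death 0.002,
#'   normal death 0.001, 37500 MCS (second lepidic model).
#' * `ppa_stromal_growth` -- base plus stromal/matrix growth 0.02 beneath the
#'   cancer cells, 6000 MCS.
#' * `spheroid_mixture` -- 50:50 disc of cancer and stromal cells, both
#'   growing at the base rate, 4000 MCS; `adhesion` selects the contact-energy
#'   profile (`"base"`, `"low_adhesion"` or `"low_polarity"`).
#'
#' @param name Preset name.
#' @param adhesion Adhesion profile for `spheroid_mixture`.
#' @return A `cpm_config` list: lattice size, Potts parameters, contact
#'   energies, behaviour rates and flags, geometry, steps and replicate count.
#' @examples
#' preset("base_ppa")$rates$growth_rate[1]  # 0.03
#' @export
preset <- function(name, adhesion = c("base", "low_adhesion", "low_polarity")) {
  if (!is.character(name) || length(name) != 1 || !(name %in% preset_names)) {
    stop("unknown preset; valid names: ", paste(preset_names, collapse = ", "))
  }
  adhesion <- match.arg(adhesion)
  J <- default_contact_energies()
  cfg <- list(
    preset_name = name,
    width = 500L, height = 500L,
    temperature = 10, neighbor_order = 3L, boundary = "fixed",
    connectivity_guard = TRUE,
    J = J,
    lambda = 2,
    lambda_membrane = 2,
    growth_margin = 50,
    growth_unit = 10,
    rates = behavior_rates(cancer_growth = 0.03),
    contact_inhibition = list(enabled = FALSE, factor = 0.997),
    mucus = list(enabled = FALSE, rate = 0.05, max_target = 9),
    stromal_growth = list(enabled = FALSE, rate = 0.02),
    n_steps = 4000L,
    snapshot_interval = NULL,
    replicates = 10L,
    geometry = list(cell_width = 10L, cell_height = 30L, n_cancer = 5L,
                    bed_depth = 80L, stromal_size = 10L, ecm_size = 5L,
                    disc_radius = 120L),
    seed = NULL
  )
  set_growth <- function(cfg, g) {
    cfg$rates$growth_rate[cfg$rates$cell_type == "cancer"] <- g
    cfg
  }
  low_adhesion <- function(J) {
    J |>
      set_contact_energy("cancer.basal", "stromal.generic", 30) |>
      set_contact_energy("cancer.basal", "ecm.generic", 30)
  }
  low_polarity <- function(J) {
    for (s in c("basal", "lateral", "cytosol")) {
      J <- set_contact_energy(J, "cancer.apical", paste0("cancer.", s), 10)
    }
    for (s in c("lateral", "cytosol")) {
      J <- set_contact_energy(J, "cancer.basal", paste0("cancer.", s), 10)
    }
    J
  }
  cfg <- switch(
    name,
    base_ppa = cfg,
    mpa_growth3x = {
      cfg <- set_growth(cfg, 0.09); cfg$n_steps <- 1400L; cfg
    },
    mpa_low_adhesion = {
      cfg$J <- low_adhesion(cfg$J); cfg
    },
    spa_growth10x = {
      cfg <- set_growth(cfg, 0.3); cfg$n_steps <- 600L; cfg
    },
    spa_low_polarity = {
      cfg$J <- low_polarity(cfg$J); cfg
    },
    spa_uniform_j = {
      subs <- paste0("cancer.", c("apical", "basal", "lateral", "cytosol"))
      for (a in subs) for (b in subs) {
        cfg$J <- set_contact_energy(cfg$J, a, b, 10)
      }
      cfg
    },
    apa_mucus = {
      cfg$mucus$enabled <- TRUE; cfg
    },
    lpa_v1 = {
      cfg <- set_growth(cfg, 0.022)
      cfg$rates$death_rate[cfg$rates$cell_type == "cancer"] <- 0.00065
      cfg$rates$death_rate[cfg$rates$cell_type == "normal_epithelial"] <- 0.0001
      cfg$n_steps <- 40000L
      cfg
    },
    lpa_v2 = {
      cfg <- set_growth(cfg, 0.3)
      cfg$rates$death_rate[cfg$rates$cell_type == "cancer"] <- 0.002
      cfg$rates$death_rate[cfg$rates$cell_type == "normal_epithelial"] <- 0.001
      cfg$contact_inhibition$enabled <- TRUE
      cfg$n_steps <- 37500L
      cfg
    },
    ppa_stromal_growth = {
      cfg$stromal_growth$enabled <- TRUE
      cfg$n_steps <- 6000L
      cfg
    },
    spheroid_mixture = {
      g <- cfg$rates$growth_rate[cfg$rates$cell_type == "cancer"]
      cfg$rates$growth_rate[cfg$rates$cell_type == "stromal"] <- g
      cfg$J <- switch(adhesion, base = cfg$J,
                      low_adhesion = low_adhesion(cfg$J),
                      low_polarity = low_polarity(cfg$J))
      cfg$adhesion_profile <- adhesion
      cfg
    }
  )
  class(cfg) <- "cpm_config"
  cfg
}

#' @export
print.cpm_config <- function(x, ...) {
  cat("<cpm_config> preset ", x$preset_name, ": ", x$width, "x", x$height,
      " lattice, T = ", x$temperature, ", ", x$n_steps, " MCS, ",
      x$replicates, " replicates\n", sep = "")
  invisible(x)
}

#' Scale a configuration down for desk-scale runs
#'
#' Shrinks the lattice by `factor`, the cell geometry by `cell_factor` and
#' divides the step count by `step_factor`. The growth volume unit is
#' rescaled by `cell_factor^2 * step_factor`, so each cell completes the same
#' number of division cycles over the scaled run as at full scale. The
#' package's standard desk scale -- used throughout the tests and the
#' reproduction script -- is a 150 x 150 lattice (factor 0.3) of 5 x 15-pixel
#' columnar cells (cell factor 0.5, small enough for tissue-level dynamics,
#' large enough that sub-compartments stay robust at T = 10) with steps
#' divided by 4; those factors leave the growth unit unchanged.
#'
#' @param config A `cpm_config`.
#' @param factor Linear scale factor for the lattice.
#' @param cell_factor Linear scale factor for cell geometry.
#' @param step_factor Divisor applied to `n_steps`.
#' @return The scaled configuration.
#' @export
desk_scale <- function(config, factor = 0.3, cell_factor = 0.5,
                       step_factor = 4) {
  sc <- function(x, f, lo = 1L) pmax(lo, as.integer(round(x * f)))
  config$width <- sc(config$width, factor)
  config$height <- sc(config$height, factor)
  config$n_steps <- max(1L, as.integer(config$n_steps / step_factor))
  g <- config$geometry
  g$cell_width <- sc(g$cell_width, cell_factor, lo = 3L)
  g$cell_height <- sc(g$cell_height, cell_factor, lo = 5L)
  g$bed_depth <- sc(g$bed_depth, factor)
  g$stromal_size <- sc(g$stromal_size, cell_factor, lo = 2L)
  g$ecm_size <- sc(g$ecm_size, cell_factor, lo = 2L)
  g$disc_radius <- sc(g$disc_radius, factor)
  config$geometry <- g
  config$growth_unit <- config$growth_unit * cell_factor^2 * step_factor
  config
}

empty_state_from_config <- function(config) {
  new_cpm_state(config$width, config$height,
                temperature = config$temperature,
                neighbor_order = config$neighbor_order,
                boundary = config$boundary, J = config$J,
                connectivity_guard = config$connectivity_guard)
}

#' Build the initial epithelial-monolayer lattice
#'
#' The bottom band of the lattice is a stromal bed (10x10 stromal cells
#' interleaved with 5x5 matrix pseudo-cells); above it sits a single row of
#' columnar epithelial cells (nominally 10 pixels wide and 30 tall) spanning
#' the width, each built from basal pixels facing the stroma, apical pixels
#' facing the lumen, one-pixel lateral strips on the cell-cell sides and a
#' cytosolic core. The centred `n_cancer` cells (5 in the published setup) are
#' cancer cells; everything above is medium (lumen). All compartments start at
#' their target volume.
#'
#' @param config A `cpm_config` (see [preset()] and [desk_scale()]).
#' @return A `cpm_state`.
#' @export
build_initial_epithelium <- function(config) {
  g <- config$geometry
  W <- config$width; H <- config$height
  cw <- g$cell_width; ch <- g$cell_height
  bed <- g$bed_depth
  if (H < bed + ch + 10) {
    stop("lattice height must be at least bed_depth + cell height + 10 = ",
         bed + ch + 10)
  }
  n_cells <- W %/% cw
  if (n_cells < g$n_cancer) stop("lattice too narrow for ", g$n_cancer,
                                 " cancer cells")
  state <- empty_state_from_config(config)
  lam <- config$lambda
  lam_mem <- if (is.null(config$lambda_membrane)) 2 else config$lambda_membrane

  # stromal bed: alternating column strips of stromal cells and ecm
  # pseudo-cells
  ss <- g$stromal_size; es <- g$ecm_size
  x0 <- 1L
  strip <- 0L
  while (x0 <= W) {
    wseg <- min(ss, W - x0 + 1L)
    use_ecm <- strip %% 2L == 1L
    size <- if (use_ecm) es else ss
    for (xx in seq(x0, x0 + wseg - 1L, by = size)) {
      for (yy in seq(1L, bed, by = size)) {
        px <- expand.grid(x = xx:min(xx + size - 1L, x0 + wseg - 1L),
                          y = yy:min(yy + size - 1L, bed))
        place_cell(state, if (use_ecm) "ecm" else "stromal", as.matrix(px),
                   lambda = lam)
      }
    }
    x0 <- x0 + ss
    strip <- strip + 1L
  }

  # columnar epithelial layer
  first_cancer <- (n_cells - g$n_cancer) %/% 2L + 1L
  cancer_cols <- seq(first_cancer, length.out = g$n_cancer)
  for (i in seq_len(n_cells)) {
    type <- if (i %in% cancer_cols) "cancer" else "normal_epithelial"
    xs <- ((i - 1L) * cw + 1L):(i * cw)
    ys <- (bed + 1L):(bed + ch)
    build_columnar_cell(state, type, xs, ys, lam, lam_mem)
  }
  validate_state(state)
  state
}

build_columnar_cell <- function(state, type, xs, ys, lambda,
                                lambda_membrane = 2) {
  # membrane sub-compartments keep their own volume constraint; growth scales
  # every compartment's target pro-rata, so the films expand with the cell
  # and the whole surface carries the outward pressure
  cl <- add_cluster(state, type)
  y_basal <- ys[1:2]
  y_apical <- ys[(length(ys) - 1):length(ys)]
  y_mid <- ys[3:(length(ys) - 2)]
  x_lat <- c(xs[1], xs[length(xs)])
  x_mid <- xs[2:(length(xs) - 1)]
  grid <- function(x, y) as.matrix(expand.grid(x = x, y = y))
  add_compartment(state, cl, "basal", grid(xs, y_basal),
                  lambda = lambda_membrane)
  add_compartment(state, cl, "apical", grid(xs, y_apical),
                  lambda = lambda_membrane)
  add_compartment(state, cl, "lateral", grid(x_lat, y_mid),
                  lambda = lambda_membrane)
  add_compartment(state, cl, "cytosol", grid(x_mid, y_mid), lambda = lambda)
  state$clus_ref_volume[cl] <- length(xs) * length(ys)
  cl
}

#' Build the spheroid-mixture initial lattice
#'
#' A disc of randomly interleaved cancer and stromal cells (50:50 by count,
#' difference at most one) surrounded by medium, emulating a mixed spheroid
#' culture; both cell types are assigned identical growth rates by the
#' `spheroid_mixture` preset. Cancer cells are compartmental with their apical
#' side facing radially outward.
#'
#' @param config A `cpm_config` with preset `spheroid_mixture`.
#' @return A `cpm_state`.
#' @export
build_initial_spheroid_mixture <- function(config) {
  g <- config$geometry
  W <- config$width; H <- config$height
  r <- g$disc_radius
  cs <- g$stromal_size  # cell block size
  if (2 * r > min(W, H)) stop("disc diameter exceeds the lattice")
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  state <- empty_state_from_config(config)
  lam <- config$lambda

  # candidate blocks fully inside the disc
  bx <- seq(1L, W - cs + 1L, by = cs)
  by <- seq(1L, H - cs + 1L, by = cs)
  blocks <- expand.grid(x = bx, y = by)
  cxs <- blocks$x + (cs - 1) / 2
  cys <- blocks$y + (cs - 1) / 2
  keep <- (cxs - cx)^2 + (cys - cy)^2 <= (r - cs / 2)^2
  blocks <- blocks[keep, , drop = FALSE]
  n <- nrow(blocks)
  if (n < 2) stop("disc too small for the cell size")
  types <- rep(c("cancer", "stromal"), length.out = n)
  types <- sample(types)
  for (i in seq_len(n)) {
    xs <- blocks$x[i]:(blocks$x[i] + cs - 1L)
    ys <- blocks$y[i]:(blocks$y[i] + cs - 1L)
    if (types[i] == "stromal") {
      px <- as.matrix(expand.grid(x = xs, y = ys))
      place_cell(state, "stromal", px, lambda = lam)
    } else {
      build_radial_cell(state, xs, ys, c(cx, cy), lam)
    }
  }
  validate_state(state)
  state
}

# compartmental cancer cell in a square block, apical facing away from `center`
build_radial_cell <- function(state, xs, ys, center, lambda) {
  px <- as.matrix(expand.grid(x = xs, y = ys))
  ctr <- colMeans(px)
  u <- ctr - center
  if (sum(u^2) < 1e-9) u <- c(0, 1)
  u <- u / sqrt(sum(u^2))
  w <- c(-u[2], u[1])
  n <- nrow(px)
  vol_frac <- c(apical = 0.15, basal = 0.15, lateral = 0.2)
  sets <- split_polarity(sweep(px, 2, ctr), u, w, vol_frac)
  sets <- lapply(sets, function(m) sweep(m, 2, -ctr))
  cl <- add_cluster(state, "cancer")
  for (tp in c("apical", "basal", "lateral", "cytosol")) {
    lam_tp <- lambda
    add_compartment(state, cl, tp, round(sets[[tp]]), lambda = lam_tp)
  }
  state$clus_ref_volume[cl] <- n
  cl
}

#' Build the initial lattice of a configuration
#'
#' @param config A `cpm_config`.
#' @return A `cpm_state`: the spheroid-mixture disc for that preset, the
#'   epithelial monolayer otherwise.
#' @export
build_initial_state <- function(config) {
  if (identical(config$preset_name, "spheroid_mixture")) {
    build_initial_spheroid_mixture(config)
  } else {
    build_initial_epithelium(config)
  }
}

#' Run one preset simulation
#'
#' Builds the preset's initial lattice and runs its Monte Carlo loop with the
#' standard behaviour hooks. Reproducible: the same `(config, seed)` pair gives
#' a bit-identical trajectory.
#'
#' @param config A preset name or a `cpm_config`.
#' @param seed RNG seed.
#' @param steps Optional override of the configured step count.
#' @param scale Apply [desk_scale()] before running.
#' @param ... Passed to [run_mcs()] (e.g. `record_interval`,
#'   `snapshot_interval`).
#' @return A `cpm_trajectory`.
#' @export
simulate_preset <- function(config, seed = 1L, steps = NULL, scale = FALSE,
                            ...) {
  if (is.character(config)) config <- preset(config)
  if (scale) config <- desk_scale(config)
  if (!is.null(steps)) config$n_steps <- as.integer(steps)
  config$seed <- as.integer(seed)
  set.seed(config$seed)
  state <- build_initial_state(config)
  run_mcs(state, n_steps = config$n_steps, hooks = standard_hooks(config),
          config = config, ...)
}
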