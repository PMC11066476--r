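epithelium_fixture <- function(width = 60, height = 60) {
  cfg <- desk_scale(preset("base_ppa"))
  cfg$width <- as.integer(width)
  cfg$height <- as.integer(height)
  set.seed(1)
  build_initial_epithelium(cfg)
}

test_that("the contact-inhibition factor scales the growth rate exactly", {
  expect_identical(effective_growth_rate(0.3, TRUE, 0.997), 0.3 * 0.997)
  expect_equal(effective_growth_rate(0.3, TRUE, 0.997), 0.2991,
               tolerance = 1e-12)
  expect_identical(effective_growth_rate(0.3, FALSE, 0.997), 0.3)
  expect_equal(effective_growth_rate(c(0.1, 0.1), c(TRUE, FALSE), 0.5),
               c(0.05, 0.1))
  expect_error(effective_growth_rate(0.3, TRUE, 0))
})

test_that("growth increments target volumes by rate x unit, with caps", {
  st <- epithelium_fixture()
  rates <- behavior_rates(cancer_growth = 0.03)
  idx <- seq_len(st$n_comp)
  total_target <- function(k) {
    sum(st$comp_target[idx][st$comp_in_use[idx] &
                              st$comp_cluster[idx] == k])
  }
  cancer <- alive_clusters(st, "cancer")
  t0 <- vapply(cancer, total_target, numeric(1))
  apply_growth(st, rates, unit = 10)
  t1 <- vapply(cancer, total_target, numeric(1))
  expect_equal(t1 - t0, rep(0.03 * 10, length(cancer)), tolerance = 1e-12)
  # zero rate leaves every target untouched
  st2 <- epithelium_fixture()
  before <- st2$comp_target[seq_len(st2$n_comp)]
  apply_growth(st2, behavior_rates(cancer_growth = 0))
  expect_identical(st2$comp_target[seq_len(st2$n_comp)], before)
  # the cap holds the total target at 2.2x the reference volume
  st3 <- epithelium_fixture()
  for (i in 1:5000) apply_growth(st3, behavior_rates(cancer_growth = 0.3),
                                 margin = Inf, unit = 10)
  k <- alive_clusters(st3, "cancer")[1]
  tt <- sum(st3$comp_target[seq_len(st3$n_comp)][
    st3$comp_in_use[seq_len(st3$n_comp)] &
      st3$comp_cluster[seq_len(st3$n_comp)] == k])
  expect_lte(tt, 2.2 * st3$clus_ref_volume[k] + 1e-9)
})

test_that("contact inhibition applies only to cells touching other epithelium", {
  st <- epithelium_fixture()
  # add an isolated compartmental cancer cell in the lumen
  iso <- luadmorph:::build_columnar_cell(st, "cancer", 30:34, 48:56, 2)
  rates <- behavior_rates(cancer_growth = 0.1)
  idx <- seq_len(st$n_comp)
  total_target <- function(k) {
    sum(st$comp_target[idx][st$comp_in_use[idx] &
                              st$comp_cluster[idx] == k])
  }
  touching <- alive_clusters(st, "cancer")
  touching <- setdiff(touching, iso)
  t0_iso <- total_target(iso)
  t0_touch <- total_target(touching[1])
  apply_growth(st, rates, contact_inhibition = TRUE, ci_factor = 0.5,
               unit = 10)
  expect_equal(total_target(iso) - t0_iso, 0.1 * 10, tolerance = 1e-12)
  expect_equal(total_target(touching[1]) - t0_touch, 0.1 * 0.5 * 10,
               tolerance = 1e-12)
})

test_that("death-free and certain-death limits behave exactly", {
  st <- epithelium_fixture()
  apply_death(st, behavior_rates())  # all death rates zero
  expect_true(all(st$clus_alive[alive_clusters(st)]))
  st2 <- epithelium_fixture()
  cancer <- alive_clusters(st2, "cancer")
  apply_death(st2, behavior_rates(cancer_death = 1))
  expect_true(all(!st2$clus_alive[cancer]))
  comp <- unlist(lapply(cancer, luadmorph:::cluster_compartments, state = st2))
  expect_true(all(st2$comp_target[comp] == 0))
  # normal cells untouched by a cancer-only death rate
  expect_gt(length(alive_clusters(st2, "normal_epithelial")), 0)
})

test_that("survival under a constant death rate tracks (1 - d)^t", {
  # 100 independent pseudo-cells, d = 0.002, 1000 steps; registry-level check
  set.seed(123)
  st <- fixture_state(110, 20)
  for (i in 1:100) {
    place_cell(st, "stromal", cbind(i + (i - 1) %% 10, 2 + (i - 1) %/% 10))
  }
  rates <- behavior_rates()
  rates$death_rate[rates$cell_type == "stromal"] <- 0.002
  for (t in 1:1000) apply_death(st, rates)
  surviving <- length(alive_clusters(st, "stromal"))
  p <- (1 - 0.002)^1000
  se <- sqrt(p * (1 - p) / 100)
  expect_lt(abs(surviving / 100 - p), 3 * se + 1e-9)
})

test_that("mitosis splits a doubled columnar cell into two complete daughters", {
  st <- fixture_state(40, 80)
  cl <- luadmorph:::build_columnar_cell(st, "cancer", 11:20, 11:70, 2)
  st$clus_ref_volume[cl] <- 300  # cell currently holds 600 pixels
  div <- apply_mitosis(st, mcs = 1)
  expect_equal(nrow(div), 1)
  expect_equal(div$parent, cl)
  d <- div$daughter
  va <- cluster_volumes(st)[cl]
  vb <- cluster_volumes(st)[d]
  expect_equal(va + vb, 600)
  expect_lt(abs(va - 300) / 300, 0.1)
  expect_lt(abs(vb - 300) / 300, 0.1)
  for (k in c(cl, d)) {
    types <- sort(st$comp_type[luadmorph:::cluster_compartments(st, k)])
    expect_identical(types, c("apical", "basal", "cytosol", "lateral"))
    expect_equal(st$clus_ref_volume[k], cluster_volumes(st)[k])
  }
  # daughters are born at mechanical equilibrium: targets equal volumes
  comp <- c(luadmorph:::cluster_compartments(st, cl),
            luadmorph:::cluster_compartments(st, d))
  expect_equal(st$comp_target[comp], as.numeric(st$comp_volume[comp]))
  expect_true(validate_state(st))
})

test_that("epithelial daughters sit side by side across the apico-basal axis", {
  st <- fixture_state(40, 80)
  cl <- luadmorph:::build_columnar_cell(st, "cancer", 11:20, 11:70, 2)
  st$clus_ref_volume[cl] <- 300
  div <- apply_mitosis(st, mcs = 1)
  d <- div$daughter
  pa <- luadmorph:::cluster_pixels(st, cl)
  pb <- luadmorph:::cluster_pixels(st, d)
  # the cut runs along the (vertical) apico-basal axis: daughters separate in
  # x, and both span the full original height
  expect_true(mean(pa[, 1]) != mean(pb[, 1]))
  expect_lt(abs(mean(pa[, 2]) - mean(pb[, 2])), 2)
  expect_equal(range(pa[, 2]), c(11, 70))
  expect_equal(range(pb[, 2]), c(11, 70))
})

test_that("sub-threshold and pseudo-cell divisions behave as specified", {
  st <- fixture_state(40, 60)
  cl <- luadmorph:::build_columnar_cell(st, "cancer", 11:20, 11:40, 2)
  st$clus_ref_volume[cl] <- 300 / 1.9  # cell at 1.9x reference
  expect_equal(nrow(apply_mitosis(st)), 0)
  # non-compartmental pseudo-cell at 2x splits into two generic daughters
  st2 <- fixture_state(40, 40)
  cl2 <- place_cell(st2, "stromal",
                    as.matrix(expand.grid(x = 11:20, y = 11:30)))
  st2$clus_ref_volume[cl2] <- 100
  div <- apply_mitosis(st2)
  expect_equal(nrow(div), 1)
  expect_identical(st2$comp_type[luadmorph:::cluster_compartments(
    st2, div$daughter)], "generic")
  expect_equal(sum(cluster_volumes(st2)[c(cl2, div$daughter)]), 200)
})

test_that("pixel count is conserved by every behaviour", {
  set.seed(5)
  st <- epithelium_fixture()
  n_px <- nrow(st$sid) * ncol(st$sid)
  rates <- behavior_rates(cancer_growth = 0.3, cancer_death = 0.05)
  for (i in 1:30) {
    apply_growth(st, rates)
    apply_death(st, rates)
    secrete_mucus(st, rate = 0.5)
    apply_mitosis(st)
    expect_equal(sum(tabulate(st$sid[st$sid > 0], nbins = st$n_comp)) +
                   sum(st$sid == 0), n_px)
  }
})

test_that("mucus appears at the configured rate on the apical side only", {
  st <- epithelium_fixture()
  expect_identical(secrete_mucus(st, rate = 0), 0L)
  created <- 0L
  for (i in 1:50) created <- created + secrete_mucus(st, rate = 1, mcs = i)
  n_cancer <- length(alive_clusters(st, "cancer"))
  expect_equal(created, 50L * n_cancer)
  mucus <- alive_clusters(st, "mucus")
  expect_gt(length(mucus), 0)
  expect_equal(sum(cluster_volumes(st)[mucus]), created)
  # every mucus pixel lies strictly above the epithelial apical band
  apical_top <- max(which(apply(st$sid, 2, function(col) {
    any(col > 0 & st$comp_type[pmax(col, 1)] == "apical" &
          st$comp_cluster[pmax(col, 1)] > 0)
  })))
  mucus_comp <- unlist(lapply(mucus, luadmorph:::cluster_compartments,
                              state = st))
  lin <- which(matrix(st$sid %in% mucus_comp, nrow = nrow(st$sid)))
  ys <- (lin - 1L) %/% nrow(st$sid) + 1L
  bed <- desk_scale(preset("base_ppa"))$geometry$bed_depth
  expect_true(all(ys > bed))  # never on the stromal side
})

test_that("stromal growth requires contact with cancer basal surfaces", {
  st <- epithelium_fixture()
  idx <- seq_len(st$n_comp)
  stroma <- alive_clusters(st, c("stromal", "ecm"))
  t0 <- st$comp_target[idx]
  hit <- proliferate_stroma(st, rate = 0.02, unit = 10)
  expect_gt(length(hit), 0)
  expect_true(all(st$clus_cell_type[hit] %in% c("stromal", "ecm")))
  # only clusters under the (centred) cancer cells were incremented
  changed <- which(st$comp_target[idx] != t0)
  expect_setequal(unique(st$comp_cluster[changed]), hit)
  delta <- sum(st$comp_target[idx] - t0)
  expect_equal(delta, 0.02 * 10 * length(hit), tolerance = 1e-9)
  # zero rate is a no-op
  t1 <- st$comp_target[idx]
  proliferate_stroma(st, rate = 0)
  expect_identical(st$comp_target[idx], t1)
})

test_that("contact inhibition desynchronises division timing", {
  run_ages <- function(seed, ci) {
    cfg <- desk_scale(preset("base_ppa"))
    cfg$width <- 60L
    cfg$height <- 60L
    cfg$rates$growth_rate[cfg$rates$cell_type == "cancer"] <- 0.3
    cfg$contact_inhibition <- list(enabled = ci, factor = 0.5)
    cfg$n_steps <- 250L
    tr <- simulate_preset(cfg, seed = seed, record_interval = Inf)
    ev <- event_log(tr)
    div <- ev[ev$event == "division", ]
    if (nrow(div) < 3) return(NA_real_)
    birth <- stats::setNames(div$mcs, div$detail)
    b <- birth[as.character(div$cluster)]
    b[is.na(b)] <- 0  # clusters present from the start
    ages <- div$mcs - b
    var(ages, na.rm = TRUE)
  }
  vs <- vapply(1:3, function(s) {
    c(on = run_ages(s, TRUE), off = run_ages(s, FALSE))
  }, numeric(2))
  expect_gt(mean(vs["on", ], na.rm = TRUE), mean(vs["off", ], na.rm = TRUE))
})
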