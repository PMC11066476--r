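# Fixture: hand-placed tissue scenarios with known contact categories.
# Cancer cells are small compartmental cells (4 x 6 px); stroma and mucus are
# generic pseudo-cells.
category_fixture <- function() {
  st <- fixture_state(60, 40)
  out <- list(st = st)
  # scenario A: cancer column with stroma below, medium above, cancer beside
  out$stromaA <- place_cell(st, "stromal",
                            as.matrix(expand.grid(x = 2:12, y = 2:4)))
  out$cancerA1 <- fixture_cell(st, "cancer", 3, 5)
  out$cancerA2 <- fixture_cell(st, "cancer", 7, 5)
  # scenario B: lone cancer cell in pure medium
  out$cancerB <- fixture_cell(st, "cancer", 30, 20)
  # scenario C: cancer cell fully surrounded by cancer cells
  for (dx in c(-4, 0, 4)) {
    for (dy in c(-6, 0, 6)) {
      id <- fixture_cell(st, "cancer", 40 + dx, 20 + dy)
      if (dx == 0 && dy == 0) out$cancerC <- id
    }
  }
  # scenario D: cancer pair touching only medium (no stroma side)
  out$cancerD1 <- fixture_cell(st, "cancer", 3, 30)
  out$cancerD2 <- fixture_cell(st, "cancer", 7, 30)
  # scenario E: cancer pair embedded in stroma (no medium contact)
  out$stromaE <- place_cell(st, "stromal", as.matrix(rbind(
    expand.grid(x = 18:29, y = 2:3),
    expand.grid(x = 18:29, y = 10:11),
    expand.grid(x = 18:19, y = 4:9),
    expand.grid(x = 28:29, y = 4:9)
  )))
  out$cancerE1 <- fixture_cell(st, "cancer", 20, 4)
  out$cancerE2 <- fixture_cell(st, "cancer", 24, 4)
  out
}

test_that("cluster contact tables match the brute-force oracle", {
  for (seed in 1:3) {
    st <- random_raw_state(W = 16, H = 16, n_comp = 8, seed = seed * 7)
    got <- cluster_contacts(st) |> dplyr::arrange(cluster_a, cluster_b)
    want <- oracle_cluster_contacts(st)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
  # and the fixture scenarios agree too
  fx <- category_fixture()
  got <- cluster_contacts(fx$st) |> dplyr::arrange(cluster_a, cluster_b)
  want <- oracle_cluster_contacts(fx$st)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("cluster_neighbors reports symmetric shared boundaries", {
  fx <- category_fixture()
  nb1 <- cluster_neighbors(fx$st, fx$cancerA1)
  expect_true(0 %in% nb1$neighbor)  # medium counts as a neighbour
  expect_true(fx$stromaA %in% nb1$neighbor)
  nb2 <- cluster_neighbors(fx$st, fx$cancerA2)
  b12 <- nb1$boundary[nb1$neighbor == fx$cancerA2]
  b21 <- nb2$boundary[nb2$neighbor == fx$cancerA1]
  expect_equal(b12, b21)
  expect_gt(b12, 0)
  expect_error(cluster_neighbors(fx$st, 999), "unknown cluster")
})

test_that("contact categories implement the five-way partition", {
  fx <- category_fixture()
  st <- fx$st
  expect_equal(contact_category(st, fx$cancerA1), 1L)  # lumen + stroma
  expect_equal(contact_category(st, fx$cancerB), 4L)   # no cancer contact
  expect_equal(contact_category(st, fx$cancerC), 5L)   # only cancer
  expect_equal(contact_category(st, fx$cancerD1), 2L)  # lumen, no stroma side
  expect_equal(contact_category(st, fx$cancerE1), 3L)  # stroma, no lumen
  expect_error(contact_category(st, fx$stromaA), "not a cancer")
})

test_that("normal epithelium counts toward the stromal side", {
  st <- fixture_state(30, 30)
  # cancer pair wrapped in normal epithelium, no medium reachable
  for (dx in c(-4, 4)) {
    for (dy in c(-6, 0, 6)) {
      if (dx == 4 && dy == 0) next  # spot reserved for the cancer neighbour
      fixture_cell(st, "normal_epithelial", 14 + dx, 14 + dy)
    }
  }
  fixture_cell(st, "normal_epithelial", 14, 8)
  fixture_cell(st, "normal_epithelial", 14, 20)
  target <- fixture_cell(st, "cancer", 14, 14)
  side <- fixture_cell(st, "cancer", 18, 14)
  expect_equal(contact_category(st, target), 3L)
})

test_that("category fractions partition the cancer population", {
  fx <- category_fixture()
  fr <- category_fractions(fx$st)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(attr(fr, "n_cancer"), 16L)
  # no cancer cells: zero vector, flagged via the attribute
  st <- fixture_state(20, 20)
  place_cell(st, "stromal", as.matrix(expand.grid(x = 5:8, y = 5:8)))
  fr0 <- category_fractions(st)
  expect_equal(unname(as.numeric(fr0)), rep(0, 5))
  expect_equal(attr(fr0, "n_cancer"), 0L)
})

test_that("the built epithelium scores all cancer cells as category 1", {
  cfg <- desk_scale(preset("base_ppa"))
  set.seed(1)
  st <- build_initial_epithelium(cfg)
  fr <- category_fractions(st)
  expect_equal(unname(fr[["cat1"]]), 1)
  hist <- neighbor_count_histogram(st)
  # a 5-cell strip: two ends with 1 cancer neighbour, three interior with 2
  expect_equal(hist$n[hist$cancer_neighbors == 1], 2L)
  expect_equal(hist$n[hist$cancer_neighbors == 2], 3L)
  expect_equal(sum(hist$n), 5L)
})

test_that("neighbour histograms count distinct cancer neighbours", {
  fx <- category_fixture()
  hist <- neighbor_count_histogram(fx$st)
  expect_equal(sum(hist$n), 16L)
  expect_gte(min(hist$cancer_neighbors), 0)
  st <- fixture_state(20, 20)
  fixture_cell(st, "cancer", 8, 8)
  h1 <- neighbor_count_histogram(st)
  expect_equal(as.data.frame(h1),
               data.frame(cancer_neighbors = 0L, n = 1L))
})

test_that("metrics agree with a naive recomputation on simulated snapshots", {
  cfg <- desk_scale(preset("base_ppa"))
  cfg$width <- 60L
  cfg$height <- 60L
  cfg$n_steps <- 30L
  tr <- simulate_preset(cfg, seed = 2)
  st <- tr$state
  got <- cluster_contacts(st) |> dplyr::arrange(cluster_a, cluster_b)
  want <- oracle_cluster_contacts(st)
  expect_equal(as.data.frame(got), as.data.frame(want))
  fr <- category_fractions(st)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  hist <- neighbor_count_histogram(st)
  expect_equal(sum(hist$n), attr(fr, "n_cancer"))
})

test_that("replicate aggregation is an element-wise mean and sd", {
  cfg <- desk_scale(preset("base_ppa"))
  cfg$width <- 60L
  cfg$height <- 60L
  set.seed(1)
  st <- build_initial_epithelium(cfg)
  rec <- metrics_record(st, mcs = 0)
  agg <- aggregate_replicates(list(rec, rec, rec))
  expect_true(all(agg$sd == 0))
  expect_equal(agg$mean[agg$metric == "category" & agg$bin == 1], 1)
  # two opposite extremes average to 0.5
  r1 <- rec
  r2 <- rec
  r1[paste0("cat", 1:5)] <- as.list(c(1, 0, 0, 0, 0))
  r2[paste0("cat", 1:5)] <- as.list(c(0, 0, 0, 0, 1))
  agg2 <- aggregate_replicates(list(r1, r2))
  expect_equal(agg2$mean[agg2$metric == "category" & agg2$bin %in% c(1, 5)],
               c(0.5, 0.5))
  # random records against direct arithmetic
  set.seed(9)
  recs <- lapply(1:6, function(i) {
    r <- rec
    f <- runif(5)
    r[paste0("cat", 1:5)] <- as.list(f / sum(f))
    r
  })
  agg3 <- aggregate_replicates(recs)
  mat <- t(vapply(recs, function(r) unlist(r[paste0("cat", 1:5)]),
                  numeric(5)))
  expect_equal(agg3$mean[agg3$metric == "category"],
               unname(colMeans(mat)), tolerance = 1e-12)
  expect_equal(agg3$sd[agg3$metric == "category"],
               unname(apply(mat, 2, sd)), tolerance = 1e-12)
  # mixed schemas are rejected
  bad <- rec[, setdiff(names(rec), "cat5")]
  expect_error(aggregate_replicates(list(rec, bad)), "schema")
})

test_that("the rule-based classifier labels the constructed extremes", {
  h <- function(...) {
    v <- c(...)
    tibble::tibble(cancer_neighbors = seq_along(v) - 1L, n = as.integer(v))
  }
  # solid: only-cancer contacts with many neighbours
  expect_equal(classify_subtype(c(0, 0, 0, 0, 1), h(0, 0, 0, 0, 0, 2, 8)),
               "SPA-like")
  # papillary vs lepidic disambiguated by the cancer count
  expect_equal(classify_subtype(c(1, 0, 0, 0, 0), h(0, 2, 50, 30),
                                monolayer_capacity = 30),
               "PPA-like")
  expect_equal(classify_subtype(c(1, 0, 0, 0, 0), h(0, 10, 20),
                                monolayer_capacity = 30),
               "LPA-like")
  # micropapillary: lumen-or-stroma contacts with intermediate neighbours
  expect_equal(classify_subtype(c(0.1, 0.5, 0.3, 0, 0.1), h(0, 2, 6, 4)),
               "MPA-like")
  # no dominance: indeterminate
  expect_equal(classify_subtype(rep(0.2, 5), h(1, 1, 1)), "indeterminate")
  expect_equal(classify_subtype(c(0, 0, 0, 0, 0), h()), "indeterminate")
})

test_that("classification recovers the generating preset on scaled runs", {
  labels <- vapply(1:5, function(seed) {
    tr <- simulate_preset("base_ppa", seed = seed, scale = TRUE,
                          record_interval = Inf)
    r <- tail(tidy(tr), 1)
    cfg <- desk_scale(preset("base_ppa"))
    classify_subtype(unlist(r[paste0("cat", 1:5)]),
                     r$neighbor_histogram[[1]],
                     monolayer_capacity = cfg$width %/% cfg$geometry$cell_width)
  }, character(1))
  expect_gte(sum(labels == "PPA-like"), 4)
})
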