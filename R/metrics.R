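state_comp_adjacency <- function(state) {
  adj <- cpp_comp_adjacency(state$sid, state$offx, state$offy, state$periodic)
  tibble::tibble(comp_a = adj[, "comp_a"], comp_b = adj[, "comp_b"],
                 boundary = adj[, "boundary"])
}

comp_to_cluster <- function(state, comp_id) {
  ifelse(comp_id > 0L, state$comp_cluster[pmax(comp_id, 1L)], 0L)
}

#' Cluster-level contact table
#'
#' Two clusters are neighbours iff any pixel of one lies within the neighbour
#' order of a pixel of the other; the shared boundary length is the count of
#' such neighbour pairs. The medium counts as neighbour label 0.
#'
#' @param state A `cpm_state`.
#' @return Tibble `cluster_a`, `cluster_b` (`cluster_a < cluster_b`),
#'   `boundary`.
#' @export
cluster_contacts <- function(state) {
  adj <- state_comp_adjacency(state)
  ca <- comp_to_cluster(state, adj$comp_a)
  cb <- comp_to_cluster(state, adj$comp_b)
  keep <- ca != cb
  tibble::tibble(cluster_a = pmin(ca, cb)[keep],
                 cluster_b = pmax(ca, cb)[keep],
                 boundary = adj$boundary[keep]) |>
    dplyr::summarise(boundary = sum(.data$boundary),
                     .by = c("cluster_a", "cluster_b"))
}

#' Neighbours of one cluster
#'
#' @param state A `cpm_state`.
#' @param cluster_id Cluster of interest.
#' @param contacts Optional precomputed [cluster_contacts()] table.
#' @return Tibble `neighbor` (cluster id, 0 = medium), `cell_type`,
#'   `boundary`.
#' @export
cluster_neighbors <- function(state, cluster_id, contacts = NULL) {
  if (cluster_id < 1 || cluster_id > state$n_clus ||
      !state$clus_in_use[cluster_id]) {
    stop("unknown cluster: ", cluster_id)
  }
  if (is.null(contacts)) contacts <- cluster_contacts(state)
  hit <- contacts$cluster_a == cluster_id | contacts$cluster_b == cluster_id
  nb <- ifelse(contacts$cluster_a[hit] == cluster_id,
               contacts$cluster_b[hit], contacts$cluster_a[hit])
  tibble::tibble(
    neighbor = nb,
    cell_type = ifelse(nb == 0L, "medium", state$clus_cell_type[pmax(nb, 1L)]),
    boundary = contacts$boundary[hit]
  ) |>
    dplyr::arrange(.data$neighbor)
}

category_of <- function(has_cancer, only_cancer, has_medium, has_stroma_side) {
  dplyr::case_when(
    !has_cancer ~ 4L,
    only_cancer ~ 5L,
    has_medium & has_stroma_side ~ 1L,
    has_medium ~ 2L,
    TRUE ~ 3L
  )
}

cancer_contact_summary <- function(state, contacts = NULL) {
  if (is.null(contacts)) contacts <- cluster_contacts(state)
  cancer <- alive_clusters(state, "cancer")
  if (length(cancer) == 0) {
    return(tibble::tibble(cluster = integer(), n_cancer_neighbors = integer(),
                          category = integer()))
  }
  long <- dplyr::bind_rows(
    tibble::tibble(cluster = contacts$cluster_a, neighbor = contacts$cluster_b),
    tibble::tibble(cluster = contacts$cluster_b, neighbor = contacts$cluster_a)
  ) |>
    dplyr::filter(.data$cluster %in% cancer)
  type_of <- function(nb) {
    ifelse(nb == 0L, "medium", state$clus_cell_type[pmax(nb, 1L)])
  }
  long$nb_type <- type_of(long$neighbor)
  stroma_side <- c("stromal", "ecm", "mucus", "normal_epithelial")
  summ <- long |>
    dplyr::summarise(
      n_cancer_neighbors = sum(.data$nb_type == "cancer"),
      has_medium = any(.data$nb_type == "medium"),
      has_stroma_side = any(.data$nb_type %in% stroma_side),
      n_total = dplyr::n(),
      .by = "cluster"
    )
  # alive cancer cells with no contacts at all (isolated by guard edge cases)
  missing <- setdiff(cancer, summ$cluster)
  if (length(missing) > 0) {
    summ <- dplyr::bind_rows(summ, tibble::tibble(
      cluster = missing, n_cancer_neighbors = 0L, has_medium = FALSE,
      has_stroma_side = FALSE, n_total = 0L))
  }
  summ$category <- category_of(summ$n_cancer_neighbors > 0,
                               summ$n_cancer_neighbors == summ$n_total,
                               summ$has_medium, summ$has_stroma_side)
  summ[, c("cluster", "n_cancer_neighbors", "category")]
}

#' Contact category of one cancer cell
#'
#' Each alive cancer cell is assigned exactly one of five connection
#' categories: 1 = touches both luminal space and stromal tissue / mucus
#' (the polarised monolayer configuration), 2 = luminal space but no stromal
#' side, 3 = stromal side but no lumen, 4 = no contact with other cancer
#' cells, 5 = contact with cancer cells only. Categories 4 and 5 take
#' precedence, making the five categories a partition; contact with normal
#' epithelium counts towards the stromal (non-lumen) side.
#'
#' @param state A `cpm_state`.
#' @param cluster_id An alive cancer cluster.
#' @param contacts Optional precomputed [cluster_contacts()] table.
#' @return Integer category in 1..5.
#' @export
contact_category <- function(state, cluster_id, contacts = NULL) {
  if (cluster_id < 1 || cluster_id > state$n_clus ||
      !state$clus_in_use[cluster_id] ||
      state$clus_cell_type[cluster_id] != "cancer") {
    stop("cluster ", cluster_id, " is not a cancer cluster")
  }
  summ <- cancer_contact_summary(state, contacts)
  out <- summ$category[summ$cluster == cluster_id]
  if (length(out) == 0) stop("cluster ", cluster_id, " is not alive")
  out
}

#' Connection-category fractions over cancer cells
#'
#' @param state A `cpm_state`.
#' @param contacts Optional precomputed [cluster_contacts()] table.
#' @return Named numeric vector `cat1`..`cat5` of fractions over alive cancer
#'   cells (sums to 1); all zero with attribute `n_cancer = 0` when no cancer
#'   cell exists.
#' @export
category_fractions <- function(state, contacts = NULL) {
  summ <- cancer_contact_summary(state, contacts)
  out <- setNames(numeric(5), paste0("cat", 1:5))
  if (nrow(summ) > 0) {
    tab <- tabulate(summ$category, nbins = 5)
    out[] <- tab / nrow(summ)
  }
  attr(out, "n_cancer") <- nrow(summ)
  out
}

#' Histogram of cancer-neighbour counts
#'
#' For each alive cancer cell, the number of distinct neighbouring cancer
#' clusters.
#'
#' @inheritParams category_fractions
#' @return Tibble `cancer_neighbors`, `n`; the `n` column sums to the number
#'   of alive cancer cells.
#' @export
neighbor_count_histogram <- function(state, contacts = NULL) {
  summ <- cancer_contact_summary(state, contacts)
  summ |>
    dplyr::count(cancer_neighbors = .data$n_cancer_neighbors)
}

#' One morphology-metrics record
#'
#' @param state A `cpm_state`.
#' @param mcs Step index stamped on the record.
#' @return One-row tibble: `mcs`, category fractions `cat1`..`cat5`, mean and
#'   modal cancer-neighbour count, the neighbour histogram (list column) and
#'   alive-cell counts per type.
#' @export
metrics_record <- function(state, mcs = NA_integer_) {
  contacts <- cluster_contacts(state)
  summ <- cancer_contact_summary(state, contacts)
  fr <- category_fractions(state, contacts)
  hist <- summ |> dplyr::count(cancer_neighbors = .data$n_cancer_neighbors)
  cc <- cell_counts(state)
  n_of <- function(tp) {
    n <- cc$n[cc$cell_type == tp]
    if (length(n) == 0) 0L else n
  }
  tibble::tibble(
    mcs = as.integer(mcs),
    cat1 = fr[["cat1"]], cat2 = fr[["cat2"]], cat3 = fr[["cat3"]],
    cat4 = fr[["cat4"]], cat5 = fr[["cat5"]],
    mean_cancer_neighbors = if (nrow(summ) > 0) {
      mean(summ$n_cancer_neighbors)
    } else NA_real_,
    modal_cancer_neighbors = if (nrow(summ) > 0) {
      hist$cancer_neighbors[which.max(hist$n)]
    } else NA_integer_,
    neighbor_histogram = list(hist),
    n_cancer = n_of("cancer"),
    n_normal_epithelial = n_of("normal_epithelial"),
    n_stromal = n_of("stromal"),
    n_ecm = n_of("ecm"),
    n_mucus = n_of("mucus")
  )
}

#' Aggregate metrics records across replicates
#'
#' Element-wise mean and standard deviation of the category fractions and of
#' the neighbour-count distribution (as fractions of cancer cells) across
#' replicate records -- the replicate-averaged heatmap tables.
#'
#' @param records A list of one-row [metrics_record()] tibbles (or a tibble
#'   with one row per replicate), all with the same schema.
#' @return A tidy tibble `metric` (`"category"` or `"cancer_neighbors"`),
#'   `bin`, `mean`, `sd`.
#' @export
aggregate_replicates <- function(records) {
  if (inherits(records, "data.frame")) {
    records <- split(records, seq_len(nrow(records)))
  }
  if (length(records) == 0) stop("no records to aggregate")
  cols <- lapply(records, names)
  if (!all(vapply(cols, identical, logical(1), y = cols[[1]]))) {
    stop("records have mixed schemas")
  }
  need <- c(paste0("cat", 1:5), "neighbor_histogram")
  if (!all(need %in% cols[[1]])) stop("records have mixed schemas")
  cats <- purrr::map_dfr(records, function(r) {
    tibble::tibble(bin = 1:5,
                   value = c(r$cat1, r$cat2, r$cat3, r$cat4, r$cat5))
  }, .id = "replicate")
  cat_out <- cats |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     .by = "bin") |>
    dplyr::mutate(metric = "category", .before = 1)
  hists <- purrr::map_dfr(records, function(r) {
    h <- r$neighbor_histogram[[1]]
    tot <- sum(h$n)
    tibble::tibble(bin = h$cancer_neighbors,
                   value = if (tot > 0) h$n / tot else 0)
  }, .id = "replicate")
  bins <- if (nrow(hists) > 0) sort(unique(hists$bin)) else integer()
  hist_out <- hists |>
    tidyr::complete(replicate = unique(hists$replicate), bin = bins,
                    fill = list(value = 0)) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     .by = "bin") |>
    dplyr::mutate(metric = "cancer_neighbors", .before = 1)
  dplyr::bind_rows(cat_out, hist_out) |>
    dplyr::arrange(.data$metric, .data$bin)
}

#' Classification thresholds for tissue-architecture subtyping
#'
#' Package-declared, tunable cut-offs: a category group is dominant when its
#' fraction is at least `dominance_min` and at least `dominance_ratio` times
#' the runner-up; `high_neighbors`/`low_neighbors` split the modal
#' cancer-neighbour count; `monolayer_slack` scales the monolayer capacity
#' used to separate lepidic from papillary architectures.
#'
#' @param dominance_min,dominance_ratio,high_neighbors,low_neighbors,monolayer_slack
#'   Numeric cut-offs.
#' @return A named list.
#' @export
subtype_thresholds <- function(dominance_min = 0.4, dominance_ratio = 1.5,
                               high_neighbors = 5, low_neighbors = 2,
                               monolayer_slack = 1.5) {
  list(dominance_min = dominance_min, dominance_ratio = dominance_ratio,
       high_neighbors = high_neighbors, low_neighbors = low_neighbors,
       monolayer_slack = monolayer_slack)
}

#' Rule-based LUAD-subtype classification of a simulated architecture
#'
#' Labels a metrics record by the published score logic: category-1 dominance
#' with moderate neighbour counts reads as papillary (stroma-cored papillae);
#' category-2/3 dominance with intermediate neighbour counts as micropapillary
#' (stroma-free protrusions); category-5 dominance with high neighbour counts
#' as solid (cancer-only aggregates); category-1 dominance with low neighbour
#' counts and a near-monolayer cancer count as lepidic. Anything else is
#' indeterminate.
#'
#' @param fractions 5-vector of category fractions (see
#'   [category_fractions()]).
#' @param histogram Neighbour-count histogram tibble (see
#'   [neighbor_count_histogram()]).
#' @param monolayer_capacity Number of cancer cells a single replaced
#'   monolayer would hold (lattice width / cell width); used to disambiguate
#'   lepidic from papillary. When `NULL` the lepidic branch is unavailable.
#' @param thresholds See [subtype_thresholds()].
#' @return One of `"PPA-like"`, `"MPA-like"`, `"SPA-like"`, `"LPA-like"`,
#'   `"indeterminate"`.
#' @export
classify_subtype <- function(fractions, histogram,
                             monolayer_capacity = NULL,
                             thresholds = subtype_thresholds()) {
  f <- as.numeric(fractions)
  stopifnot(length(f) == 5)
  if (sum(f) == 0 || nrow(histogram) == 0) return("indeterminate")
  groups <- c(g1 = f[1], g23 = f[2] + f[3], g4 = f[4], g5 = f[5])
  ord <- order(groups, decreasing = TRUE)
  top <- groups[ord[1]]
  second <- groups[ord[2]]
  dominant <- top >= thresholds$dominance_min &&
    (second == 0 || top >= thresholds$dominance_ratio * second)
  if (!dominant) return("indeterminate")
  modal <- histogram$cancer_neighbors[which.max(histogram$n)]
  n_cancer <- sum(histogram$n)
  g <- names(groups)[ord[1]]
  if (g == "g5") {
    if (modal >= thresholds$high_neighbors) return("SPA-like")
    return("indeterminate")
  }
  if (g == "g23") {
    if (modal >= 1 && modal < thresholds$high_neighbors) return("MPA-like")
    return("indeterminate")
  }
  if (g == "g1") {
    near_monolayer <- !is.null(monolayer_capacity) &&
      n_cancer <= thresholds$monolayer_slack * monolayer_capacity
    if (modal <= thresholds$low_neighbors && near_monolayer) {
      return("LPA-like")
    }
    return("PPA-like")
  }
  "indeterminate"
}
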