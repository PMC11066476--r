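#' Write a label-image snapshot with a JSON sidecar
#'
#' The site map is written as a 16-bit single-channel TIFF (one compartment id
#' per pixel) and a JSON sidecar maps each id to its cluster, cell type and
#' compartment type.
#'
#' @param state A `cpm_state`.
#' @param path_prefix Output prefix; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_snapshot <- function(state, path_prefix) {
  tif <- paste0(path_prefix, ".tif")
  js <- paste0(path_prefix, ".json")
  if (max(state$sid) > 65535L) stop("more than 65535 compartments")
  tiff::writeTIFF(state$sid / 65535, tif, bits.per.sample = 16L)
  idx <- which(state$comp_in_use[seq_len(state$n_comp)])
  sidecar <- tibble::tibble(
    id = idx,
    cluster = state$comp_cluster[idx],
    cell_type = state$clus_cell_type[state$comp_cluster[idx]],
    compartment_type = state$comp_type[idx]
  )
  jsonlite::write_json(list(width = nrow(state$sid), height = ncol(state$sid),
                            compartments = sidecar),
                       js, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(tif, js))
}

#' Read a label-image snapshot
#'
#' @param path_prefix Prefix used by [write_snapshot()].
#' @return A list with `sid` (integer matrix) and `compartments` (tibble).
#' @export
read_snapshot <- function(path_prefix) {
  img <- tiff::readTIFF(paste0(path_prefix, ".tif"))
  raw <- jsonlite::read_json(paste0(path_prefix, ".json"),
                             simplifyVector = TRUE)
  list(sid = matrix(as.integer(round(img * 65535)), nrow = nrow(img)),
       compartments = tibble::as_tibble(raw$compartments))
}

#' Write trajectory outputs to a directory
#'
#' Writes the per-record morphology metrics as TSV (one row per recorded MCS;
#' the neighbour histogram flattened to `nbr<k>` fraction columns), the event
#' log as CSV and a run-manifest JSON holding the resolved configuration
#' including the seed.
#'
#' @param traj A `cpm_trajectory`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- traj$records
  hist_cols <- purrr::map_dfr(rec$neighbor_histogram, function(h) {
    tot <- sum(h$n)
    if (nrow(h) == 0) return(tibble::tibble(.rows = 1))
    out <- as.list(setNames(h$n / max(tot, 1),
                            paste0("nbr", h$cancer_neighbors)))
    tibble::as_tibble(out)
  })
  flat <- dplyr::bind_cols(rec[setdiff(names(rec), "neighbor_histogram")],
                           hist_cols)
  flat[is.na(flat)] <- 0
  utils::write.table(flat, file.path(dir, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(event_log(traj), file.path(dir, "events.csv"),
                   row.names = FALSE)
  cfg <- traj$config
  manifest <- list(n_steps = traj$n_steps,
                   attempts_per_mcs = traj$attempts_per_mcs)
  if (!is.null(cfg)) {
    manifest$config <- cfg[c("preset_name", "width", "height", "temperature",
                             "neighbor_order", "boundary",
                             "connectivity_guard", "lambda", "n_steps",
                             "replicates", "seed")]
    manifest$config$rates <- cfg$rates
    manifest$config$contact_inhibition <- cfg$contact_inhibition
    manifest$config$mucus <- cfg$mucus
    manifest$config$stromal_growth <- cfg$stromal_growth
    manifest$config$geometry <- cfg$geometry
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
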