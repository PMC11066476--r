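#' Create an empty CPM lattice state
#'
#' The state holds the site map (an integer matrix of compartment ids, 0 =
#' medium), the compartment registry (label, cluster, volume, target volume,
#' volume-constraint strength lambda per compartment) and the cluster registry
#' (cell type, alive flag, reference volume at birth). It is an environment:
#' the engine and the behaviour hooks update it in place.
#'
#' @param width,height Lattice dimensions in pixels.
#' @param temperature Potts temperature (energy units), default 10.
#' @param neighbor_order Neighbour order 1-3; the default 3 gives each pixel
#'   12 neighbours.
#' @param boundary `"fixed"` (no-flux) or `"periodic"`.
#' @param J A [contact_energies()] object.
#' @param connectivity_guard Reject copy attempts that would split a
#'   compartment locally, or remove the last pixel of a compartment whose
#'   target volume is positive. Off by default; the shipped presets enable it
#'   to preserve columnar cell integrity.
#' @return An object of class `cpm_state`.
#' @export
new_cpm_state <- function(width, height, temperature = 10, neighbor_order = 3,
                          boundary = c("fixed", "periodic"),
                          J = default_contact_energies(),
                          connectivity_guard = FALSE) {
  boundary <- match.arg(boundary)
  stopifnot(width >= 3, height >= 3, temperature > 0)
  off <- neighbor_offsets(neighbor_order)
  s <- new.env(parent = emptyenv())
  s$sid <- matrix(0L, nrow = width, ncol = height)
  s$labels <- J$labels
  s$Jext <- J$external
  s$Jint <- J$internal
  s$temperature <- temperature
  s$neighbor_order <- neighbor_order
  s$offx <- as.integer(off[, "dx"])
  s$offy <- as.integer(off[, "dy"])
  s$periodic <- boundary == "periodic"
  s$boundary_mode <- boundary
  s$guard <- connectivity_guard
  cap <- 64L
  s$n_comp <- 0L
  s$comp_label <- integer(cap)
  s$comp_cluster <- integer(cap)
  s$comp_volume <- integer(cap)
  s$comp_target <- numeric(cap)
  s$comp_lambda <- numeric(cap)
  s$comp_type <- character(cap)
  s$comp_guard <- logical(cap)
  s$comp_in_use <- logical(cap)
  s$n_clus <- 0L
  s$clus_cell_type <- character(cap)
  s$clus_alive <- logical(cap)
  s$clus_ref_volume <- numeric(cap)
  s$clus_in_use <- logical(cap)
  s$clus_mucus_acc <- numeric(cap)
  s$events <- list()
  s$attempts <- 0
  s$accepted <- 0
  class(s) <- "cpm_state"
  s
}

#' @export
print.cpm_state <- function(x, ...) {
  cc <- cell_counts(x)
  cat("<cpm_state> ", nrow(x$sid), "x", ncol(x$sid),
      " lattice, T = ", x$temperature,
      ", neighbor order ", x$neighbor_order,
      ", boundary ", x$boundary_mode, "\n", sep = "")
  cat("  alive clusters:",
      paste(sprintf("%s=%d", cc$cell_type, cc$n), collapse = ", "), "\n")
  invisible(x)
}

grow_comp <- function(state, need) {
  cap <- length(state$comp_label)
  if (need <= cap) return(invisible(state))
  new_cap <- max(need, cap * 2L)
  add <- new_cap - cap
  state$comp_label <- c(state$comp_label, integer(add))
  state$comp_cluster <- c(state$comp_cluster, integer(add))
  state$comp_volume <- c(state$comp_volume, integer(add))
  state$comp_target <- c(state$comp_target, numeric(add))
  state$comp_lambda <- c(state$comp_lambda, numeric(add))
  state$comp_type <- c(state$comp_type, character(add))
  state$comp_guard <- c(state$comp_guard, logical(add))
  state$comp_in_use <- c(state$comp_in_use, logical(add))
  invisible(state)
}

grow_clus <- function(state, need) {
  cap <- length(state$clus_cell_type)
  if (need <= cap) return(invisible(state))
  new_cap <- max(need, cap * 2L)
  add <- new_cap - cap
  state$clus_cell_type <- c(state$clus_cell_type, character(add))
  state$clus_alive <- c(state$clus_alive, logical(add))
  state$clus_ref_volume <- c(state$clus_ref_volume, numeric(add))
  state$clus_in_use <- c(state$clus_in_use, logical(add))
  state$clus_mucus_acc <- c(state$clus_mucus_acc, numeric(add))
  invisible(state)
}

#' Register a new cluster (cell)
#'
#' @param state A `cpm_state`.
#' @param cell_type One of `"cancer"`, `"normal_epithelial"`, `"stromal"`,
#'   `"ecm"`, `"mucus"`.
#' @param ref_volume Reference (birth) volume used by the mitosis trigger;
#'   may be set later once compartments are placed.
#' @return The new cluster id.
#' @export
add_cluster <- function(state, cell_type, ref_volume = NA_real_) {
  stopifnot(cell_type %in% unique(state$labels$cell_type))
  id <- state$n_clus + 1L
  grow_clus(state, id)
  state$n_clus <- id
  state$clus_cell_type[id] <- cell_type
  state$clus_alive[id] <- TRUE
  state$clus_ref_volume[id] <- ref_volume
  state$clus_in_use[id] <- TRUE
  state$clus_mucus_acc[id] <- 0
  id
}

label_code <- function(state, cell_type, compartment_type) {
  i <- which(state$labels$cell_type == cell_type &
               state$labels$compartment_type == compartment_type)
  if (length(i) != 1) {
    stop("no label for cell type '", cell_type, "' and compartment type '",
         compartment_type, "'")
  }
  state$labels$code[i]
}

#' Add a compartment to a cluster and paint its pixels
#'
#' @param state A `cpm_state`.
#' @param cluster_id Owning cluster (from [add_cluster()]).
#' @param compartment_type `"apical"`, `"basal"`, `"lateral"`, `"cytosol"` or
#'   `"generic"`.
#' @param pixels Two-column matrix of (x, y) lattice coordinates, currently
#'   medium.
#' @param target_volume Target volume in pixels; defaults to the pixel count.
#' @param lambda Volume-constraint strength (energy / pixel^2), default 2.
#' @return The new compartment id.
#' @export
add_compartment <- function(state, cluster_id, compartment_type, pixels,
                            target_volume = NULL, lambda = 2) {
  stopifnot(cluster_id >= 1, cluster_id <= state$n_clus,
            state$clus_in_use[cluster_id])
  pixels <- matrix(as.integer(pixels), ncol = 2)
  if (nrow(pixels) == 0) stop("a compartment needs at least one pixel")
  idx <- cbind(pixels[, 1], pixels[, 2])
  if (any(state$sid[idx] != 0L)) stop("pixels are already occupied")
  id <- state$n_comp + 1L
  grow_comp(state, id)
  state$n_comp <- id
  ct <- state$clus_cell_type[cluster_id]
  state$comp_label[id] <- label_code(state, ct, compartment_type)
  state$comp_cluster[id] <- cluster_id
  state$comp_volume[id] <- nrow(pixels)
  state$comp_target[id] <- if (is.null(target_volume)) nrow(pixels) else target_volume
  state$comp_lambda[id] <- lambda
  state$comp_type[id] <- compartment_type
  state$comp_guard[id] <- TRUE
  state$comp_in_use[id] <- TRUE
  state$sid[idx] <- id
  id
}

#' Place a single non-compartmental cell
#'
#' Convenience wrapper: one cluster with one `generic` compartment.
#'
#' @inheritParams add_compartment
#' @param cell_type Cluster cell type.
#' @return The new cluster id.
#' @export
place_cell <- function(state, cell_type, pixels, target_volume = NULL,
                       lambda = 2) {
  cl <- add_cluster(state, cell_type)
  add_compartment(state, cl, "generic", pixels, target_volume, lambda)
  state$clus_ref_volume[cl] <- nrow(matrix(pixels, ncol = 2))
  cl
}

cluster_compartments <- function(state, cluster_id) {
  which(state$comp_in_use[seq_len(state$n_comp)] &
          state$comp_cluster[seq_len(state$n_comp)] == cluster_id)
}

#' Total pixel volume of each cluster
#'
#' @param state A `cpm_state`.
#' @return Numeric vector indexed by cluster id (0 for unused slots).
#' @export
cluster_volumes <- function(state) {
  n <- state$n_clus
  v <- numeric(n)
  if (state$n_comp > 0) {
    idx <- seq_len(state$n_comp)
    keep <- state$comp_in_use[idx]
    agg <- rowsum(as.numeric(state$comp_volume[idx][keep]),
                  group = state$comp_cluster[idx][keep])
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  v
}

#' Ids of alive clusters, optionally filtered by cell type
#'
#' @param state A `cpm_state`.
#' @param cell_types Optional character vector of cell types to keep.
#' @return Integer vector of cluster ids.
#' @export
alive_clusters <- function(state, cell_types = NULL) {
  idx <- seq_len(state$n_clus)
  keep <- state$clus_in_use[idx] & state$clus_alive[idx]
  if (!is.null(cell_types)) keep <- keep & state$clus_cell_type[idx] %in% cell_types
  idx[keep]
}

#' Count alive cells per cell type
#'
#' @param state A `cpm_state`.
#' @return A tibble with columns `cell_type`, `n`.
#' @export
cell_counts <- function(state) {
  idx <- alive_clusters(state)
  tibble::tibble(cell_type = state$clus_cell_type[idx]) |>
    dplyr::count(.data$cell_type)
}

log_event <- function(state, mcs, event, cluster_id, detail = NA_character_) {
  state$events[[length(state$events) + 1L]] <-
    list(mcs = mcs, event = event, cluster = cluster_id, detail = detail)
  invisible(state)
}

#' Event log of a state or trajectory
#'
#' @param x A `cpm_state` or `cpm_trajectory`.
#' @return Tibble with columns `mcs`, `event`, `cluster`, `detail`.
#' @export
event_log <- function(x) {
  ev <- if (inherits(x, "cpm_trajectory")) x$events else x$events
  if (length(ev) == 0) {
    return(tibble::tibble(mcs = integer(), event = character(),
                          cluster = integer(), detail = character()))
  }
  dplyr::bind_rows(lapply(ev, tibble::as_tibble))
}

#' Check the internal consistency of a lattice state
#'
#' Verifies the structural invariants: every non-zero site id is a registered
#' compartment; every compartment's cached volume equals its pixel count; every
#' compartment belongs to exactly one in-use cluster; alive epithelial clusters
#' carry the four polarity compartments; contact-energy matrices are complete
#' for all labels present.
#'
#' @param state A `cpm_state`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_state <- function(state) {
  ids <- unique(as.vector(state$sid))
  ids <- ids[ids != 0L]
  if (length(ids) > 0 &&
      (any(ids > state$n_comp) || !all(state$comp_in_use[ids]))) {
    stop("site map contains unregistered compartment ids")
  }
  counts <- tabulate(state$sid[state$sid != 0L], nbins = state$n_comp)
  idx <- seq_len(state$n_comp)
  reg <- state$comp_volume[idx]
  reg[!state$comp_in_use[idx]] <- 0L
  if (!identical(as.integer(counts), as.integer(reg))) {
    bad <- which(counts != reg)
    stop("cached volume differs from pixel count for compartment(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  cl <- state$comp_cluster[idx][state$comp_in_use[idx]]
  if (any(cl < 1 | cl > state$n_clus) || !all(state$clus_in_use[cl])) {
    stop("compartment assigned to an unregistered cluster")
  }
  for (k in alive_clusters(state, c("cancer", "normal_epithelial"))) {
    comp <- cluster_compartments(state, k)
    types <- sort(state$comp_type[comp])
    if (!identical(types, c("apical", "basal", "cytosol", "lateral"))) {
      stop("alive epithelial cluster ", k,
           " does not have exactly the four polarity compartments")
    }
  }
  present <- sort(unique(c(0L, state$comp_label[idx][state$comp_in_use[idx]])))
  sub_ext <- state$Jext[present + 1L, present + 1L, drop = FALSE]
  sub_int <- state$Jint[present + 1L, present + 1L, drop = FALSE]
  if (anyNA(sub_ext) || anyNA(sub_int)) {
    m <- if (anyNA(sub_ext)) sub_ext else sub_int
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing contact energy for label pair (",
         rownames(m)[bad[1]], ", ", colnames(m)[bad[2]], ")")
  }
  invisible(TRUE)
}
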