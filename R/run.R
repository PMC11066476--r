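#' Run the Monte Carlo loop
#'
#' One Monte Carlo step (MCS) is `width * height` random copy attempts through
#' the Metropolis rule at the state's Potts temperature. After each attempt
#' sweep the behaviour hooks fire in their listed order, then clusters whose
#' volume reached zero are removed from the registries. Morphology metrics are
#' recorded at a fixed interval. Runs are fully reproducible from the state,
#' the hooks and the RNG seed (set a seed with [set.seed()] before calling, or
#' use [simulate_preset()]).
#'
#' @param state A `cpm_state`; modified in place.
#' @param n_steps Number of MCS (> 0).
#' @param hooks List of behaviour callbacks `function(state, mcs)`, fired in
#'   order after each attempt sweep; see [standard_hooks()].
#' @param record_interval Record a [metrics_record()] every this many MCS
#'   (default: ~25 records per run). Use `Inf` to record only the final state.
#' @param snapshot_interval Optionally store label-image snapshots (copies of
#'   the site map) every this many MCS.
#' @param config Optional `cpm_config`, stored in the trajectory for
#'   provenance.
#' @return A `cpm_trajectory`: records tibble, event log, snapshots, attempt
#'   accounting and the final state.
#' @export
run_mcs <- function(state, n_steps, hooks = list(), record_interval = NULL,
                    snapshot_interval = NULL, config = NULL) {
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps <= 0) {
    stop("`n_steps` must be a positive number of MCS")
  }
  n_steps <- as.integer(n_steps)
  if (is.null(record_interval)) record_interval <- max(1L, n_steps %/% 25L)
  n_attempts <- nrow(state$sid) * ncol(state$sid)
  records <- list(metrics_record(state, mcs = 0L))
  snapshots <- list()
  accepted <- integer(n_steps)
  for (mcs in seq_len(n_steps)) {
    accepted[mcs] <- cpp_mcs(state$sid, state$comp_label, state$comp_cluster,
                             state$comp_volume, state$comp_target,
                             state$comp_lambda,
                             unname(state$Jext), unname(state$Jint),
                             state$temperature, state$offx, state$offy,
                             state$periodic, state$guard, state$comp_guard,
                             n_attempts)
    state$attempts <- state$attempts + n_attempts
    state$accepted <- state$accepted + accepted[mcs]
    for (h in hooks) h(state, mcs)
    remove_empty_clusters(state, mcs)
    if (mcs == n_steps || (is.finite(record_interval) &&
                           mcs %% record_interval == 0)) {
      records[[length(records) + 1L]] <- metrics_record(state, mcs = mcs)
    }
    if (!is.null(snapshot_interval) && mcs %% snapshot_interval == 0) {
      snapshots[[as.character(mcs)]] <- state$sid + 0L
    }
  }
  structure(
    list(records = dplyr::bind_rows(records), events = state$events,
         snapshots = snapshots, accepted = accepted,
         attempts_per_mcs = n_attempts, n_steps = n_steps,
         config = config, state = state),
    class = "cpm_trajectory"
  )
}

remove_empty_clusters <- function(state, mcs) {
  vols <- cluster_volumes(state)
  idx <- which(state$clus_in_use[seq_len(state$n_clus)] & vols == 0)
  for (k in idx) {
    state$clus_in_use[k] <- FALSE
    state$clus_alive[k] <- FALSE
    comp <- cluster_compartments(state, k)
    state$comp_in_use[comp] <- FALSE
    state$comp_target[comp] <- 0
    state$comp_lambda[comp] <- 0
    log_event(state, mcs, "removed", k)
  }
  invisible(state)
}

#' @export
print.cpm_trajectory <- function(x, ...) {
  cat("<cpm_trajectory> ", x$n_steps, " MCS (",
      simulated_time(x$n_steps), " simulated hours), ",
      nrow(x$records), " records, ", length(x$events), " events\n", sep = "")
  print(tail(x$records, 1))
  invisible(x)
}

#' @describeIn run_mcs Tidy the per-record morphology metrics of a trajectory.
#' @param x A `cpm_trajectory`.
#' @param ... Unused.
#' @export
tidy.cpm_trajectory <- function(x, ...) {
  x$records
}

#' @describeIn run_mcs One-row summary of the final recorded state.
#' @export
glance.cpm_trajectory <- function(x, ...) {
  last <- tail(x$records, 1)
  tibble::tibble(
    n_steps = x$n_steps,
    simulated_hours = simulated_time(x$n_steps),
    n_cancer = last$n_cancer,
    n_normal = last$n_normal_epithelial,
    dominant_category = which.max(c(last$cat1, last$cat2, last$cat3,
                                    last$cat4, last$cat5)),
    mean_cancer_neighbors = last$mean_cancer_neighbors,
    acceptance_rate = sum(x$accepted) / (x$n_steps * x$attempts_per_mcs)
  )
}
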