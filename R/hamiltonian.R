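#' Total Hamiltonian of a lattice state
#'
#' Sum over unordered neighbour pairs (within the state's neighbour order) of
#' the contact energy between distinct compartments, plus the volume-constraint
#' term `lambda * (volume - target)^2` summed over compartments. The medium has
#' no volume constraint.
#'
#' @param state A `cpm_state`.
#' @return Total energy (scalar).
#' @export
total_hamiltonian <- function(state) {
  validate_state(state)
  cpp_total_hamiltonian(state$sid, state$comp_label, state$comp_cluster,
                        state$comp_volume, state$comp_target, state$comp_lambda,
                        unname(state$Jext), unname(state$Jint),
                        state$offx, state$offy, state$periodic)
}

#' Energy change of a proposed copy attempt
#'
#' Computes `H(after) - H(before)` locally for the copy that would overwrite
#' the compartment id at `target` with the id at `source`; only boundary terms
#' touching the target site and the two affected volume terms are evaluated.
#'
#' @param state A `cpm_state`.
#' @param source,target Length-2 integer vectors `(x, y)`; must be neighbours
#'   within the state's neighbour order.
#' @return A list with `dh` (energy change) and `null_move` (`TRUE` when the
#'   two sites already belong to the same compartment, in which case `dh` is
#'   0).
#' @export
delta_hamiltonian <- function(state, source, target) {
  check_neighbors(state, source, target)
  cpp_delta_hamiltonian(state$sid, state$comp_label, state$comp_cluster,
                        state$comp_volume, state$comp_target, state$comp_lambda,
                        unname(state$Jext), unname(state$Jint),
                        state$offx, state$offy, state$periodic,
                        source[1] - 1L, source[2] - 1L,
                        target[1] - 1L, target[2] - 1L)
}

check_neighbors <- function(state, source, target) {
  stopifnot(length(source) == 2, length(target) == 2)
  W <- nrow(state$sid); H <- ncol(state$sid)
  if (any(source < 1) || any(target < 1) || source[1] > W || target[1] > W ||
      source[2] > H || target[2] > H) {
    stop("source and target must lie on the lattice")
  }
  d <- target - source
  if (state$periodic) {
    d[1] <- ((d[1] + W / 2) %% W) - W / 2
    d[2] <- ((d[2] + H / 2) %% H) - H / 2
  }
  ok <- any(state$offx == d[1] & state$offy == d[2])
  if (!ok) stop("source and target are not neighbours at order ",
                state$neighbor_order)
  invisible(TRUE)
}

#' Perform one Metropolis copy attempt
#'
#' Picks a random site and a random neighbour (or uses the supplied pair); if
#' their compartment ids differ, the copy (source id overwrites the target
#' site) is accepted with probability `min(1, exp(-dH / T))`. On acceptance the
#' site map and the volume registry are updated in place.
#'
#' @param state A `cpm_state`.
#' @param source,target Optional forced `(x, y)` site pair; both random when
#'   omitted.
#' @param commit Apply the move on acceptance (set `FALSE` to sample the
#'   acceptance decision without changing the state).
#' @return A list with `accepted`, `dh`, `null_move`, `source`, `target`.
#' @export
attempt_copy <- function(state, source = NULL, target = NULL, commit = TRUE) {
  W <- nrow(state$sid); H <- ncol(state$sid)
  if (is.null(target)) {
    target <- c(sample.int(W, 1), sample.int(H, 1))
  }
  if (is.null(source)) {
    k <- sample.int(length(state$offx), 1)
    source <- c(target[1] + state$offx[k], target[2] + state$offy[k])
    if (state$periodic) {
      source <- c((source[1] - 1) %% W + 1, (source[2] - 1) %% H + 1)
    } else if (any(source < 1) || source[1] > W || source[2] > H) {
      return(list(accepted = FALSE, dh = NA_real_, null_move = FALSE,
                  source = source, target = target))
    }
  } else {
    check_neighbors(state, source, target)
  }
  res <- cpp_try_copy(state$sid, state$comp_label, state$comp_cluster,
                      state$comp_volume, state$comp_target, state$comp_lambda,
                      unname(state$Jext), unname(state$Jint), state$temperature,
                      state$offx, state$offy, state$periodic, state$guard,
                      state$comp_guard,
                      source[1] - 1L, source[2] - 1L,
                      target[1] - 1L, target[2] - 1L, commit)
  c(res, list(source = source, target = target))
}
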