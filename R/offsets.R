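#' Neighbourhood offsets for a square lattice
#'
#' Returns the lattice offsets whose squared Euclidean length falls within the
#' first `order` distinct distance shells of the 2D square lattice: shell 1 is
#' the 4 edge neighbours (distance 1), shell 2 adds the 4 diagonals (sqrt(2)),
#' shell 3 adds the 4 offsets at distance 2, for 12 neighbours in total --
#' the neighbourhood used throughout the simulator at its default order 3.
#'
#' @param order Neighbour order, one of 1, 2 or 3.
#' @return An integer matrix with columns `dx`, `dy`, one row per offset,
#'   excluding the null offset.
#' @examples
#' nrow(neighbor_offsets(3))  # 12
#' @export
neighbor_offsets <- function(order = 3) {
  if (!is.numeric(order) || length(order) != 1 || !(order %in% c(1, 2, 3))) {
    stop("`order` must be one of 1, 2, 3")
  }
  shells <- list(
    cbind(dx = c(1L, -1L, 0L, 0L), dy = c(0L, 0L, 1L, -1L)),
    cbind(dx = c(1L, 1L, -1L, -1L), dy = c(1L, -1L, 1L, -1L)),
    cbind(dx = c(2L, -2L, 0L, 0L), dy = c(0L, 0L, 2L, -2L))
  )
  do.call(rbind, shells[seq_len(order)])
}

#' Simulated time represented by a number of Monte Carlo steps
#'
#' One Monte Carlo step (MCS) represents approximately 2 hours of simulated
#' time; the model's key calibration is a 24-hour mitosis cycle (12 MCS).
#'
#' @param n_steps Number of MCS (non-negative).
#' @return Simulated time in hours.
#' @examples
#' simulated_time(12)  # 24 h, one nominal mitosis cycle
#' @export
simulated_time <- function(n_steps) {
  stopifnot(is.numeric(n_steps), all(n_steps >= 0))
  n_steps * 2
}
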