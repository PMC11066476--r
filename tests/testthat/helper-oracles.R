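# Independent oracles and raw-state fixtures used across the suite. The
# oracles re-derive quantities from their definitions (plain loops over sites
# and neighbour offsets), never through the engine's incremental code paths.

# Build a state directly from raw arrays, bypassing the constructors, so
# tests can create arbitrary (scattered-pixel) configurations.
make_raw_state <- function(sid, comp_label, comp_cluster, comp_target,
                           comp_lambda, Jext, Jint,
                           clus_cell_type = NULL,
                           temperature = 10, neighbor_order = 3,
                           boundary = "fixed", guard = FALSE) {
  labels <- cpm_label_table()
  st <- new_cpm_state(nrow(sid), ncol(sid), temperature = temperature,
                      neighbor_order = neighbor_order, boundary = boundary,
                      J = contact_energies(Jext, Jint, labels),
                      connectivity_guard = guard)
  n <- length(comp_label)
  luadmorph:::grow_comp(st, n)
  luadmorph:::grow_clus(st, max(comp_cluster))
  st$sid <- matrix(as.integer(sid), nrow = nrow(sid))
  st$n_comp <- as.integer(n)
  st$comp_label[seq_len(n)] <- as.integer(comp_label)
  st$comp_cluster[seq_len(n)] <- as.integer(comp_cluster)
  st$comp_volume[seq_len(n)] <-
    as.integer(tabulate(st$sid[st$sid > 0], nbins = n))
  st$comp_target[seq_len(n)] <- comp_target
  st$comp_lambda[seq_len(n)] <- comp_lambda
  st$comp_type[seq_len(n)] <-
    labels$compartment_type[match(comp_label, labels$code)]
  st$comp_guard[seq_len(n)] <- TRUE
  st$comp_in_use[seq_len(n)] <- TRUE
  ncl <- max(comp_cluster)
  st$n_clus <- as.integer(ncl)
  if (is.null(clus_cell_type)) {
    clus_cell_type <- labels$cell_type[match(
      comp_label[match(seq_len(ncl), comp_cluster)], labels$code)]
  }
  st$clus_cell_type[seq_len(ncl)] <- clus_cell_type
  st$clus_alive[seq_len(ncl)] <- TRUE
  st$clus_in_use[seq_len(ncl)] <- TRUE
  st$clus_ref_volume[seq_len(ncl)] <- NA_real_
  st
}

# Random scattered-compartment lattice with random energies; compartments are
# grouped into clusters of up to 2 so both J tables get exercised.
random_raw_state <- function(W = 20, H = 20, n_comp = 6, seed = 1,
                             boundary = "fixed") {
  set.seed(seed)
  labels <- cpm_label_table()
  nm <- labels$label[order(labels$code)]
  nl <- length(nm)
  sym <- function() {
    m <- matrix(round(runif(nl * nl, 0, 30), 2), nl, nl,
                dimnames = list(nm, nm))
    (m + t(m)) / 2
  }
  sid <- matrix(sample.int(n_comp + 1L, W * H, replace = TRUE) - 1L, W, H)
  # make sure every compartment owns at least one pixel
  for (i in seq_len(n_comp)) if (!any(sid == i)) sid[sample(W * H, 1)] <- i
  comp_label <- sample(labels$code[labels$code > 0], n_comp, replace = TRUE)
  comp_cluster <- sample.int(ceiling(n_comp / 2), n_comp, replace = TRUE)
  make_raw_state(sid, comp_label, comp_cluster,
                 comp_target = round(runif(n_comp, 0, 60), 1),
                 comp_lambda = round(runif(n_comp, 0, 3), 2),
                 Jext = sym(), Jint = sym(),
                 clus_cell_type = rep("stromal", max(comp_cluster)),
                 boundary = boundary)
}

# Definition-level Hamiltonian: explicit loop over all sites and offsets.
oracle_total_hamiltonian <- function(state) {
  sid <- state$sid
  W <- nrow(sid); H <- ncol(sid)
  offx <- state$offx; offy <- state$offy
  contact <- 0
  for (x in seq_len(W)) {
    for (y in seq_len(H)) {
      a <- sid[x, y]
      for (k in seq_along(offx)) {
        nx <- x + offx[k]; ny <- y + offy[k]
        if (state$periodic) {
          nx <- (nx - 1) %% W + 1; ny <- (ny - 1) %% H + 1
        } else if (nx < 1 || nx > W || ny < 1 || ny > H) next
        b <- sid[nx, ny]
        if (a == b) next
        la <- if (a > 0) state$comp_label[a] else 0L
        lb <- if (b > 0) state$comp_label[b] else 0L
        same <- a > 0 && b > 0 &&
          state$comp_cluster[a] == state$comp_cluster[b]
        J <- if (same) state$Jint[la + 1, lb + 1] else state$Jext[la + 1, lb + 1]
        contact <- contact + J
      }
    }
  }
  idx <- seq_len(state$n_comp)
  vol <- sum(state$comp_lambda[idx] *
               (state$comp_volume[idx] - state$comp_target[idx])^2)
  contact / 2 + vol
}

# Deep copy so the oracle can recompute an "after" state without touching the
# original environment.
copy_state <- function(state) {
  st <- new.env(parent = emptyenv())
  for (nm in ls(state)) assign(nm, get(nm, envir = state), envir = st)
  st$sid <- state$sid + 0L
  st$comp_volume <- state$comp_volume + 0L
  class(st) <- class(state)
  st
}

# Apply a copy attempt by hand and return the full-recompute energy change.
oracle_delta_hamiltonian <- function(state, source, target) {
  before <- oracle_total_hamiltonian(state)
  st <- copy_state(state)
  a <- st$sid[source[1], source[2]]
  b <- st$sid[target[1], target[2]]
  st$sid[target[1], target[2]] <- a
  if (b > 0) st$comp_volume[b] <- st$comp_volume[b] - 1L
  if (a > 0) st$comp_volume[a] <- st$comp_volume[a] + 1L
  oracle_total_hamiltonian(st) - before
}

# Brute-force cluster adjacency: double loop over sites and offsets.
oracle_cluster_contacts <- function(state) {
  sid <- state$sid
  W <- nrow(sid); H <- ncol(sid)
  offx <- state$offx; offy <- state$offy
  counts <- new.env(parent = emptyenv())
  for (x in seq_len(W)) {
    for (y in seq_len(H)) {
      a <- sid[x, y]
      ca <- if (a > 0) state$comp_cluster[a] else 0L
      for (k in seq_along(offx)) {
        nx <- x + offx[k]; ny <- y + offy[k]
        if (state$periodic) {
          nx <- (nx - 1) %% W + 1; ny <- (ny - 1) %% H + 1
        } else if (nx < 1 || nx > W || ny < 1 || ny > H) next
        b <- sid[nx, ny]
        if (a == b) next
        cb <- if (b > 0) state$comp_cluster[b] else 0L
        if (ca == cb) next
        key <- paste(min(ca, cb), max(ca, cb))
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    return(tibble::tibble(cluster_a = integer(), cluster_b = integer(),
                          boundary = integer()))
  }
  parts <- do.call(rbind, strsplit(keys, " "))
  tib <- tibble::tibble(cluster_a = as.integer(parts[, 1]),
                        cluster_b = as.integer(parts[, 2]),
                        boundary = vapply(keys, function(k) counts[[k]],
                                          integer(1)) / 2L)
  dplyr::arrange(tib, cluster_a, cluster_b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small compartmental epithelial cell for metric fixtures (needs >= 4 x 6).
fixture_cell <- function(state, type, x0, y0, w = 4, h = 6) {
  luadmorph:::build_columnar_cell(state, type, x0:(x0 + w - 1),
                                  y0:(y0 + h - 1), lambda = 2)
}

# Bare state with the default energies, convenient for fixtures.
fixture_state <- function(W = 40, H = 40, guard = FALSE) {
  new_cpm_state(W, H, connectivity_guard = guard)
}

# Volume-only lattice engineered so a specific boundary removal has a
# chosen energy change: dh = lambda * (1 - 2 * (v - t)) with v = 9.
metropolis_fixture <- function(dh_target, temperature = 10) {
  # volume-only lattice engineered so removing a boundary pixel of the
  # compartment has exactly the requested energy change:
  # dh = lambda * (1 - 2 * (v - t)) with v = 9
  labels <- cpm_label_table()
  nm <- labels$label[order(labels$code)]
  Jz <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  lambda <- abs(dh_target) / 9
  if (dh_target == 0) {
    lambda <- 0
    t <- 9
  } else if (dh_target > 0) {
    t <- 9 + 4  # v - t = -4 -> dh = 9 * lambda
  } else {
    t <- 9 - 5  # v - t = 5 -> dh = -9 * lambda
  }
  sid <- matrix(0L, 7, 7)
  sid[3:5, 3:5] <- 1L
  st <- make_raw_state(sid, comp_label = 9L, comp_cluster = 1L,
                       comp_target = t, comp_lambda = lambda,
                       Jext = Jz, Jint = Jz, temperature = temperature)
  st
}

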