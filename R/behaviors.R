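#' Effective per-MCS growth rate under contact inhibition
#'
#' When contact inhibition is enabled and a cancer cell touches another
#' epithelial cell (cancer or normal), its growth rate is multiplied by the
#' contact-inhibition factor; the published lepidic model uses 0.997, i.e. the
#' inhibited growth rate is 99.7% of the set value.
#'
#' @param growth_rate Baseline growth rate (target-volume increment per MCS,
#'   in 10-pixel volume units; see [apply_growth()]).
#' @param inhibited Logical (vectorised): does the contact condition hold?
#' @param factor Contact-inhibition multiplier in (0, 1].
#' @return Effective rate(s).
#' @examples
#' effective_growth_rate(0.3, TRUE)  # 0.2991
#' @export
effective_growth_rate <- function(growth_rate, inhibited, factor = 0.997) {
  stopifnot(growth_rate >= 0, factor > 0, factor <= 1)
  growth_rate * ifelse(inhibited, factor, 1)
}

#' Behaviour-rate table
#'
#' @param cancer_growth,normal_growth,stromal_growth,ecm_growth Growth rates
#'   per cell type (10-pixel volume units per MCS).
#' @param cancer_death,normal_death Per-MCS apoptosis probabilities.
#' @return Tibble with columns `cell_type`, `growth_rate`, `death_rate`.
#' @export
behavior_rates <- function(cancer_growth = 0.03, normal_growth = 0,
                           stromal_growth = 0, ecm_growth = 0,
                           cancer_death = 0, normal_death = 0) {
  tibble::tibble(
    cell_type = c("cancer", "normal_epithelial", "stromal", "ecm", "mucus"),
    growth_rate = c(cancer_growth, normal_growth, stromal_growth, ecm_growth, 0),
    death_rate = c(cancer_death, normal_death, 0, 0, 0)
  )
}

growing_compartment <- function(state, clusters) {
  # the cytosol (compartmental cells) or generic compartment of each cluster
  idx <- seq_len(state$n_comp)
  ok <- state$comp_in_use[idx] & state$comp_type[idx] %in% c("cytosol", "generic")
  match(clusters, ifelse(ok, state$comp_cluster[idx], NA_integer_))
}

epithelial_contact_flags <- function(state) {
  idx <- seq_len(state$n_clus)
  is_epi <- state$clus_in_use[idx] & state$clus_alive[idx] &
    state$clus_cell_type[idx] %in% c("cancer", "normal_epithelial")
  cpp_epithelial_contact(state$sid, state$comp_cluster, is_epi,
                         state$offx, state$offy, state$periodic)
}

#' Growth: increment target volumes
#'
#' For each alive cluster of a type with a positive growth rate, the
#' cluster's target volume is incremented by `effective_rate * unit` pixels
#' per MCS, distributed over its compartments pro-rata to their current
#' targets (membranes grow with the cell), where the effective rate applies
#' the contact-inhibition factor when enabled and the cluster touches another
#' epithelial cluster. The volume unit defaults to 10 pixels (one cell-width
#' column of the nominal 10-pixel-wide columnar cell), which places the
#' published rate/step combinations in the regime of a few division cycles per
#' run. The cluster's total target volume is capped at 2.2 times its reference
#' volume (just above the 2x division requirement, which the actual volume
#' approaches from below under boundary-energy pressure).
#'
#' In addition, the target volume never runs more than `margin` pixels ahead
#' of the cluster's actual volume, so the outward pressure `2 * lambda *
#' margin` stays on the scale of the contact energies and tissue architecture
#' remains energy-dominated: growth is rate-limited for slow rates and
#' mechanics-limited for fast ones.
#'
#' @param state A `cpm_state`; modified in place.
#' @param rates A [behavior_rates()] tibble.
#' @param contact_inhibition Enable the contact-inhibition rule.
#' @param ci_factor Contact-inhibition multiplier (default 0.997).
#' @param margin Maximum lead of target over actual volume, in pixels.
#' @param unit Volume unit of the growth rate, in pixels per MCS per unit
#'   rate.
#' @return The state, invisibly.
#' @export
apply_growth <- function(state, rates, contact_inhibition = FALSE,
                         ci_factor = 0.997, margin = 50, unit = 10) {
  growing_types <- rates$cell_type[rates$growth_rate > 0]
  if (length(growing_types) == 0) return(invisible(state))
  cl <- alive_clusters(state, growing_types)
  if (length(cl) == 0) return(invisible(state))
  rate <- rates$growth_rate[match(state$clus_cell_type[cl], rates$cell_type)]
  inhibited <- rep(FALSE, length(cl))
  if (contact_inhibition) {
    touched <- epithelial_contact_flags(state)
    inhibited <- touched[cl]
  }
  inc <- effective_growth_rate(rate, inhibited, ci_factor) * unit
  gcomp <- growing_compartment(state, cl)
  ok <- !is.na(gcomp) & is.finite(state$clus_ref_volume[cl])
  if (!any(ok)) return(invisible(state))
  cl <- cl[ok]; inc <- inc[ok]; gcomp <- gcomp[ok]
  # cap total cluster target a little above the division requirement (2x
  # reference volume) so the actual volume, which equilibrates slightly below
  # target under contact-energy pressure, can still reach the 2x trigger
  idx <- seq_len(state$n_comp)
  keep <- state$comp_in_use[idx]
  tot <- rowsum(state$comp_target[idx][keep], state$comp_cluster[idx][keep])
  total_target <- tot[match(cl, as.integer(rownames(tot))), 1]
  vols <- cluster_volumes(state)[cl]
  cap <- pmin(2.2 * state$clus_ref_volume[cl], vols + margin)
  inc <- pmin(inc, pmax(0, cap - total_target))
  # distribute the increment over the cluster's compartments pro-rata to
  # their current targets, so the membrane films grow with the cell and the
  # whole surface shares the outward pressure
  ok2 <- total_target > 0 & inc > 0
  cl <- cl[ok2]; inc <- inc[ok2]; total_target <- total_target[ok2]
  if (length(cl) == 0) return(invisible(state))
  fac <- 1 + inc / total_target
  sel <- idx[keep & state$comp_cluster[idx] %in% cl]
  f <- fac[match(state$comp_cluster[sel], cl)]
  state$comp_target[sel] <- state$comp_target[sel] * f
  invisible(state)
}

#' Stochastic apoptosis
#'
#' Each alive cluster of a type with positive death rate independently enters
#' apoptosis with that per-MCS probability: all its compartments' target
#' volumes are set to 0 (lambda unchanged) so the Potts dynamics shrinks it;
#' clusters reaching zero volume are removed from the registries by the run
#' loop.
#'
#' @inheritParams apply_growth
#' @param mcs Current step, for the event log.
#' @return Integer vector of cluster ids that entered apoptosis.
#' @export
apply_death <- function(state, rates, mcs = NA_integer_) {
  dying_types <- rates$cell_type[rates$death_rate > 0]
  if (length(dying_types) == 0) return(invisible(integer()))
  cl <- alive_clusters(state, dying_types)
  if (length(cl) == 0) return(invisible(integer()))
  rate <- rates$death_rate[match(state$clus_cell_type[cl], rates$cell_type)]
  hit <- cl[runif(length(cl)) < rate]
  for (k in hit) {
    comp <- cluster_compartments(state, k)
    state$comp_target[comp] <- 0
    # membrane films have no volume constraint of their own; give them the
    # cluster's constraint strength so the whole cell shrinks away
    state$comp_lambda[comp] <- pmax(state$comp_lambda[comp], 2)
    state$clus_alive[k] <- FALSE
    log_event(state, mcs, "death", k)
  }
  invisible(hit)
}

#' Compartmental mitosis
#'
#' Any alive cluster whose actual total volume has reached twice its reference
#' (birth) volume is split by a cut through its centre of mass. Epithelial
#' cells divide in the plane of the layer (the cut line runs along the
#' apico-basal axis), so the daughters sit side by side and division lengthens
#' the layer -- the morphogenetic driver of papilla formation; each daughter
#' is rebuilt with the four polarity compartments by geometric reassignment
#' along the parent's apico-basal axis (pixels nearest the lumen-facing end
#' become apical, nearest the stroma-facing end basal, the side strips
#' lateral, the remainder cytosol). Pseudo-cells split perpendicular to their
#' longest principal axis into two generic daughters. Daughters are born at
#' mechanical equilibrium: each compartment's target volume is reset to its
#' actual birth volume, and the cluster reference volume to the daughter's
#' birth volume. Degenerate splits (an empty or too-small daughter) are
#' skipped and retried on a later step.
#'
#' @inheritParams apply_death
#' @return Tibble of `parent`, `daughter` cluster ids for completed divisions.
#' @export
apply_mitosis <- function(state, mcs = NA_integer_) {
  vols <- cluster_volumes(state)
  cand <- alive_clusters(state)
  cand <- cand[is.finite(state$clus_ref_volume[cand]) &
                 vols[cand] >= 2 * state$clus_ref_volume[cand]]
  out <- list()
  for (k in cand) {
    d <- divide_cluster(state, k, mcs)
    if (!is.null(d)) out[[length(out) + 1L]] <- tibble::tibble(parent = k,
                                                               daughter = d)
  }
  if (length(out) == 0) {
    return(invisible(tibble::tibble(parent = integer(), daughter = integer())))
  }
  invisible(dplyr::bind_rows(out))
}

cluster_pixels <- function(state, cluster_id) {
  comps <- cluster_compartments(state, cluster_id)
  lin <- which(matrix(state$sid %in% comps, nrow = nrow(state$sid)))
  W <- nrow(state$sid)
  cbind(x = (lin - 1L) %% W + 1L, y = (lin - 1L) %/% W + 1L)
}

divide_cluster <- function(state, k, mcs) {
  compartmental <- state$clus_cell_type[k] %in% c("cancer", "normal_epithelial")
  min_pixels <- if (compartmental) 4L else 1L
  coords <- cluster_pixels(state, k)
  n <- nrow(coords)
  if (n < 2 * min_pixels) return(NULL)
  ctr <- colMeans(coords)
  M <- sweep(coords, 2, ctr)
  ev <- eigen(crossprod(M) / n, symmetric = TRUE)
  comps <- cluster_compartments(state, k)
  u <- NULL
  if (compartmental) {
    # apico-basal axis from the parent's own compartments; epithelial cells
    # divide in the plane of the layer (cut line along this axis), so the two
    # daughters sit side by side, each spanning basal to apical, and division
    # lengthens the layer
    ap <- comps[state$comp_type[comps] == "apical"]
    ba <- comps[state$comp_type[comps] == "basal"]
    ap_ctr <- colMeans(coords[state$sid[coords] %in% ap, , drop = FALSE])
    ba_ctr <- colMeans(coords[state$sid[coords] %in% ba, , drop = FALSE])
    u <- ap_ctr - ba_ctr
    if (!all(is.finite(u)) || sum(u^2) < 1e-9) u <- ev$vectors[, 1]
    u <- u / sqrt(sum(u^2))
    cut_axis <- c(-u[2], u[1])
  } else {
    cut_axis <- ev$vectors[, 1]  # longest principal axis
  }
  proj <- as.vector(M %*% cut_axis)
  side_b <- proj > 0
  if (sum(side_b) < min_pixels || sum(!side_b) < min_pixels) return(NULL)

  parent_volume <- n

  daughter <- add_cluster(state, state$clus_cell_type[k])
  reset_comps <- comps
  if (!compartmental) {
    comp_b <- new_compartment_slot(state, daughter, "generic", target = 0,
                                   lambda = state$comp_lambda[comps[1]])
    paint_pixels(state, coords[side_b, , drop = FALSE], comp_b)
    state$clus_ref_volume[k] <- sum(!side_b)
    state$clus_ref_volume[daughter] <- sum(side_b)
    reset_comps <- c(comps, comp_b)
  } else {
    w <- c(-u[2], u[1])
    vol_frac <- vapply(c("apical", "basal", "lateral"), function(tp) {
      state$comp_volume[comps[state$comp_type[comps] == tp][1]] / parent_volume
    }, numeric(1))

    assign_sets <- function(D) split_polarity(D, u, w, vol_frac)
    A <- coords[!side_b, , drop = FALSE]
    B <- coords[side_b, , drop = FALSE]
    sets_a <- assign_sets(A)
    sets_b <- assign_sets(B)
    if (is.null(sets_a) || is.null(sets_b)) return(NULL)

    lam <- state$comp_lambda[comps[1]]
    for (tp in c("apical", "basal", "lateral", "cytosol")) {
      # daughter A reuses the parent's compartment ids
      comp_a <- comps[state$comp_type[comps] == tp][1]
      paint_pixels(state, sets_a[[tp]], comp_a)
      comp_b <- new_compartment_slot(state, daughter, tp, target = 0,
                                     lambda = lam)
      paint_pixels(state, sets_b[[tp]], comp_b)
      reset_comps <- c(reset_comps, comp_b)
    }
    state$clus_ref_volume[k] <- nrow(A)
    state$clus_ref_volume[daughter] <- nrow(B)
  }
  refresh_volumes(state)
  # daughters are born at mechanical equilibrium: targets equal the actual
  # birth volumes, relieving any pressure the parent accumulated
  state$comp_target[reset_comps] <- state$comp_volume[reset_comps]
  log_event(state, mcs, "division", k, detail = as.character(daughter))
  daughter
}

# allocate a compartment slot without painting pixels
new_compartment_slot <- function(state, cluster_id, compartment_type, target,
                                 lambda) {
  id <- state$n_comp + 1L
  grow_comp(state, id)
  state$n_comp <- id
  ct <- state$clus_cell_type[cluster_id]
  state$comp_label[id] <- label_code(state, ct, compartment_type)
  state$comp_cluster[id] <- cluster_id
  state$comp_volume[id] <- 0L
  state$comp_target[id] <- target
  state$comp_lambda[id] <- lambda
  state$comp_type[id] <- compartment_type
  state$comp_guard[id] <- TRUE
  state$comp_in_use[id] <- TRUE
  id
}

paint_pixels <- function(state, coords, comp_id) {
  if (nrow(coords) > 0) state$sid[coords] <- comp_id
  invisible(state)
}

refresh_volumes <- function(state) {
  counts <- tabulate(state$sid[state$sid != 0L], nbins = state$n_comp)
  vol <- state$comp_volume
  vol[seq_len(state$n_comp)] <- as.integer(counts)
  state$comp_volume <- vol
  invisible(state)
}

# split a daughter pixel set into the four polarity compartments along the
# apico-basal axis u (w is the in-plane perpendicular); vol_frac gives the
# parent's apical/basal/lateral volume fractions
split_polarity <- function(D, u, w, vol_frac) {
  n <- nrow(D)
  if (n < 4) return(NULL)
  na <- max(1L, round(n * vol_frac[["apical"]]))
  nb <- max(1L, round(n * vol_frac[["basal"]]))
  nl <- max(1L, round(n * vol_frac[["lateral"]]))
  while (na + nb + nl > n - 1L) {
    i <- which.max(c(na, nb, nl))
    if (i == 1) na <- na - 1L else if (i == 2) nb <- nb - 1L else nl <- nl - 1L
    if (na < 1 || nb < 1 || nl < 1) return(NULL)
  }
  pu <- as.vector(D %*% u)
  ord <- order(pu, decreasing = TRUE)
  apical <- ord[seq_len(na)]
  basal <- rev(ord)[seq_len(nb)]
  rest <- setdiff(seq_len(n), c(apical, basal))
  pw <- as.vector(D[rest, , drop = FALSE] %*% w)
  ow <- order(pw)
  half <- nl %/% 2L
  lat <- c(head(ow, half), tail(ow, nl - half))
  lateral <- rest[unique(lat)]
  cytosol <- setdiff(rest, lateral)
  if (length(cytosol) == 0) return(NULL)
  list(apical = D[apical, , drop = FALSE],
       basal = D[basal, , drop = FALSE],
       lateral = D[lateral, , drop = FALSE],
       cytosol = D[cytosol, , drop = FALSE])
}

#' Mucus secretion (acinar behaviour)
#'
#' Each alive cancer cluster accumulates secretion credit at `rate` pixels per
#' MCS; whole credits convert medium pixels adjacent to the cluster's apical
#' boundary into mucus pseudo-cell pixels, or -- once that boundary is fully
#' covered -- medium pixels adjacent to the existing mucus plume. Creation
#' events aggregate into small pseudo-cells (new pixels join an adjacent mucus
#' cell until it reaches `max_target` pixels, then seed a new one), so mucus
#' only ever appears on the apical (luminal) side, never the stromal side.
#' Cells with no reachable medium keep their credit.
#'
#' @inheritParams apply_death
#' @param rate Mucus pixels created per cancer cell per MCS.
#' @param max_target Pseudo-cell size at which new pixels seed a new cell.
#' @param lambda Volume-constraint strength for mucus pseudo-cells.
#' @return Number of mucus pixels created, invisibly.
#' @export
secrete_mucus <- function(state, rate, max_target = 9, lambda = 2,
                          mcs = NA_integer_) {
  if (rate <= 0) return(invisible(0L))
  cancer <- alive_clusters(state, "cancer")
  if (length(cancer) == 0) return(invisible(0L))
  state$clus_mucus_acc[cancer] <- state$clus_mucus_acc[cancer] + rate
  ready <- cancer[state$clus_mucus_acc[cancer] >= 1]
  if (length(ready) == 0) return(invisible(0L))

  is_apical <- logical(max(state$labels$code))
  apical_codes <- state$labels$code[state$labels$compartment_type == "apical"]
  is_apical[apical_codes] <- TRUE
  flag <- logical(state$n_clus)
  flag[ready] <- TRUE
  cand <- cpp_medium_adjacent_apical(state$sid, state$comp_label,
                                     state$comp_cluster, is_apical, flag,
                                     state$periodic)
  created <- 0L
  W <- nrow(state$sid)
  for (k in ready) {
    sites <- if (nrow(cand) > 0) cand[cand[, "cluster"] == k, "site"] else integer()
    while (state$clus_mucus_acc[k] >= 1) {
      if (length(sites) == 0) {
        # apical boundary fully covered: extend the mucus plume instead
        sites <- medium_adjacent_to_mucus(state)
        if (length(sites) == 0) break
      }
      i <- if (length(sites) == 1) 1L else sample.int(length(sites), 1)
      lin <- sites[i]
      sites <- sites[-i]
      x <- (lin - 1L) %% W + 1L
      y <- (lin - 1L) %/% W + 1L
      if (state$sid[x, y] != 0L) next  # consumed meanwhile
      host <- adjacent_mucus_comp(state, x, y, max_target)
      if (is.na(host)) {
        mc <- add_cluster(state, "mucus", ref_volume = Inf)
        host <- new_compartment_slot(state, mc, "generic", target = 0,
                                     lambda = lambda)
      }
      state$sid[x, y] <- host
      state$comp_volume[host] <- state$comp_volume[host] + 1L
      state$comp_target[host] <- state$comp_target[host] + 1
      state$clus_mucus_acc[k] <- state$clus_mucus_acc[k] - 1
      created <- created + 1L
      log_event(state, mcs, "secretion", k)
    }
  }
  invisible(created)
}

# medium sites 4-adjacent to any mucus pixel (linear indices)
medium_adjacent_to_mucus <- function(state) {
  idx <- seq_len(state$n_comp)
  mucus_comp <- idx[state$comp_in_use[idx] &
                      state$clus_cell_type[pmax(state$comp_cluster[idx], 1)] ==
                        "mucus"]
  if (length(mucus_comp) == 0) return(integer())
  W <- nrow(state$sid); H <- ncol(state$sid)
  m <- matrix(state$sid %in% mucus_comp, W, H)
  near <- matrix(FALSE, W, H)
  near[-1, ] <- near[-1, ] | m[-W, ]
  near[-W, ] <- near[-W, ] | m[-1, ]
  near[, -1] <- near[, -1] | m[, -H]
  near[, -H] <- near[, -H] | m[, -1]
  which(near & state$sid == 0L)
}

adjacent_mucus_comp <- function(state, x, y, max_target) {
  W <- nrow(state$sid); H <- ncol(state$sid)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nx <- x + d[1]; ny <- y + d[2]
    if (state$periodic) {
      nx <- (nx - 1) %% W + 1; ny <- (ny - 1) %% H + 1
    } else if (nx < 1 || nx > W || ny < 1 || ny > H) next
    id <- state$sid[nx, ny]
    if (id > 0 && state$comp_in_use[id] &&
        state$clus_cell_type[state$comp_cluster[id]] == "mucus" &&
        state$comp_target[id] < max_target) {
      return(id)
    }
  }
  NA_integer_
}

#' Stromal proliferation beneath cancer (papillary behaviour)
#'
#' Stromal and extracellular-matrix clusters in contact (within the neighbour
#' order) with cancer basal compartments receive target-volume increments of
#' `rate * unit` pixels per MCS (same semantics and caps as [apply_growth()]);
#' they divide through the same mitosis rule as other cells.
#'
#' @inheritParams apply_death
#' @param rate Stromal growth rate (10-pixel volume units per MCS).
#' @param unit Volume unit of the growth rate, in pixels.
#' @return Integer vector of incremented cluster ids, invisibly.
#' @export
proliferate_stroma <- function(state, rate, mcs = NA_integer_, unit = 10) {
  if (rate <= 0) return(invisible(integer()))
  adj <- cpp_comp_adjacency(state$sid, state$offx, state$offy, state$periodic)
  if (nrow(adj) == 0) return(invisible(integer()))
  basal_code <- label_code(state, "cancer", "basal")
  lab <- function(id) ifelse(id > 0, state$comp_label[pmax(id, 1)], 0L)
  cl <- function(id) ifelse(id > 0, state$comp_cluster[pmax(id, 1)], 0L)
  a <- adj[, "comp_a"]; b <- adj[, "comp_b"]
  hit_b <- lab(a) == basal_code & b > 0
  hit_a <- lab(b) == basal_code & a > 0
  touching <- unique(c(cl(b)[hit_b], cl(a)[hit_a]))
  touching <- touching[touching > 0]
  touching <- touching[state$clus_in_use[touching] & state$clus_alive[touching] &
                         state$clus_cell_type[touching] %in% c("stromal", "ecm")]
  if (length(touching) == 0) return(invisible(integer()))
  gcomp <- growing_compartment(state, touching)
  inc <- rate * unit
  tot <- state$comp_target[gcomp]
  cap <- pmin(2.2 * state$clus_ref_volume[touching],
              cluster_volumes(state)[touching] + 10)
  inc <- pmin(inc, pmax(0, cap - tot))
  state$comp_target[gcomp] <- tot + inc
  invisible(touching)
}

#' Assemble the per-MCS behaviour hooks of a model configuration
#'
#' Hook order within an MCS: growth, death, mucus secretion, stromal growth,
#' mitosis (mitosis last so daughters are consistent at snapshot time).
#'
#' @param config A `cpm_config` (see [preset()]).
#' @return A list of `function(state, mcs)` callbacks for [run_mcs()].
#' @export
standard_hooks <- function(config) {
  hooks <- list()
  margin <- if (is.null(config$growth_margin)) 10 else config$growth_margin
  unit <- if (is.null(config$growth_unit)) 10 else config$growth_unit
  hooks$growth <- function(state, mcs) {
    apply_growth(state, config$rates,
                 contact_inhibition = config$contact_inhibition$enabled,
                 ci_factor = config$contact_inhibition$factor,
                 margin = margin, unit = unit)
  }
  if (any(config$rates$death_rate > 0)) {
    hooks$death <- function(state, mcs) apply_death(state, config$rates, mcs)
  }
  if (config$mucus$enabled) {
    hooks$secretion <- function(state, mcs) {
      secrete_mucus(state, config$mucus$rate, config$mucus$max_target,
                    lambda = config$lambda, mcs = mcs)
    }
  }
  if (config$stromal_growth$enabled) {
    hooks$stroma <- function(state, mcs) {
      proliferate_stroma(state, config$stromal_growth$rate, mcs, unit = unit)
    }
  }
  hooks$mitosis <- function(state, mcs) apply_mitosis(state, mcs)
  unname(hooks)
}
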