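#' Label table for contact energies
#'
#' Every lattice compartment carries a label combining its cluster's cell type
#' and its compartment type (epithelial cells have apical / basal / lateral /
#' cytosol sub-compartments; stromal cells, extracellular-matrix and mucus
#' pseudo-cells are single generic compartments). The medium -- the luminal
#' space, a background label without volume constraint -- is label code 0.
#'
#' @return A tibble with columns `code`, `cell_type`, `compartment_type`,
#'   `label`.
#' @export
cpm_label_table <- function() {
  epi <- c("cancer", "normal_epithelial")
  sub <- c("apical", "basal", "lateral", "cytosol")
  tab <- rbind(
    data.frame(cell_type = rep(epi, each = length(sub)),
               compartment_type = rep(sub, times = length(epi)),
               stringsAsFactors = FALSE),
    data.frame(cell_type = c("stromal", "ecm", "mucus"),
               compartment_type = "generic", stringsAsFactors = FALSE)
  )
  tibble::tibble(
    code = seq_len(nrow(tab)),
    cell_type = tab$cell_type,
    compartment_type = tab$compartment_type,
    label = paste(tab$cell_type, tab$compartment_type, sep = ".")
  ) |>
    dplyr::bind_rows(tibble::tibble(code = 0L, cell_type = "medium",
                                    compartment_type = "medium",
                                    label = "medium")) |>
    dplyr::arrange(.data$code)
}

label_names <- function(labels) {
  # matrix dimnames in code order 0..n
  labels$label[order(labels$code)]
}

#' Construct a contact-energy table
#'
#' Contact energies J are keyed by unordered pairs of labels (see
#' [cpm_label_table()]); higher J means weaker effective adhesion because the
#' dynamics minimises energy. Two tables are kept: `external` applies between
#' compartments of different cells, `internal` between sub-compartments of the
#' same cell (low internal J keeps a cell's compartments attached).
#'
#' @param external,internal Square numeric matrices with dimnames equal to the
#'   label names (medium first).
#' @param labels Label table, by default [cpm_label_table()].
#' @return An object of class `contact_energies`.
#' @export
contact_energies <- function(external, internal, labels = cpm_label_table()) {
  nm <- label_names(labels)
  stopifnot(identical(rownames(external), nm), identical(colnames(external), nm),
            identical(rownames(internal), nm), identical(colnames(internal), nm))
  if (any(external != t(external), na.rm = TRUE) ||
      any(internal != t(internal), na.rm = TRUE)) {
    stop("contact-energy matrices must be symmetric")
  }
  structure(list(labels = labels, external = external, internal = internal),
            class = "contact_energies")
}

#' Default (base-model) contact energies
#'
#' The baseline matrix encodes the columnar epithelial architecture: strong
#' lateral-lateral adhesion (J = 2) binds neighbouring epithelial cells into a
#' layer, low apical-medium energy (J = 4) turns apical surfaces to the lumen,
#' basal-stroma and basal-matrix energy 3 anchors the layer to the stromal bed,
#' and high energy (J = 40) between apical or basal surfaces and the other
#' sub-compartments of epithelial cells maintains apico-basal polarity by
#' penalising cell stacking. Unlisted pairs take a neutral J = 16. All
#' intra-cell (internal) energies are 1 so sub-compartments cohere. Only the
#' deltas applied by the named presets are claims about the published models;
#' the baseline values themselves are declared package defaults.
#'
#' @return A `contact_energies` object.
#' @export
default_contact_energies <- function() {
  labels <- cpm_label_table()
  nm <- label_names(labels)
  n <- length(nm)
  ext <- matrix(16, n, n, dimnames = list(nm, nm))
  int <- matrix(1, n, n, dimnames = list(nm, nm))

  set <- function(m, a, b, v) {
    m[a, b] <- v
    m[b, a] <- v
    m
  }
  epi <- c("cancer", "normal_epithelial")
  for (x in epi) {
    for (y in epi) {
      for (s in c("basal", "lateral", "cytosol")) {
        ext <- set(ext, paste0(x, ".apical"), paste0(y, ".", s), 40)
      }
      for (s in c("lateral", "cytosol")) {
        ext <- set(ext, paste0(x, ".basal"), paste0(y, ".", s), 40)
      }
      ext <- set(ext, paste0(x, ".lateral"), paste0(y, ".lateral"), 2)
      ext <- set(ext, paste0(x, ".apical"), paste0(y, ".apical"), 4)
    }
    ext <- set(ext, paste0(x, ".apical"), "medium", 4)
    ext <- set(ext, paste0(x, ".apical"), "mucus.generic", 4)
    ext <- set(ext, paste0(x, ".basal"), "stromal.generic", 3)
    ext <- set(ext, paste0(x, ".basal"), "ecm.generic", 3)
    for (s in c("basal", "lateral", "cytosol")) {
      ext <- set(ext, paste0(x, ".", s), "medium", 20)
    }
  }
  ext <- set(ext, "stromal.generic", "stromal.generic", 6)
  ext <- set(ext, "stromal.generic", "ecm.generic", 6)
  ext <- set(ext, "ecm.generic", "ecm.generic", 6)
  ext <- set(ext, "stromal.generic", "medium", 20)
  ext <- set(ext, "ecm.generic", "medium", 20)
  ext <- set(ext, "mucus.generic", "mucus.generic", 2)
  ext <- set(ext, "mucus.generic", "medium", 6)
  ext <- set(ext, "mucus.generic", "stromal.generic", 20)
  ext <- set(ext, "mucus.generic", "ecm.generic", 20)
  ext <- set(ext, "medium", "medium", 0)

  contact_energies(ext, int, labels)
}

#' Get or set one contact-energy entry
#'
#' @param J A `contact_energies` object.
#' @param a,b Label names (e.g. `"cancer.basal"`, `"stromal.generic"`,
#'   `"medium"`).
#' @param value Replacement energy.
#' @param internal Address the intra-cell table instead of the between-cell
#'   table.
#' @return `contact_energy()` returns the scalar J; `set_contact_energy()`
#'   returns the modified object (set symmetrically).
#' @export
contact_energy <- function(J, a, b, internal = FALSE) {
  m <- if (internal) J$internal else J$external
  check_label <- function(x) {
    if (!x %in% rownames(m)) stop("unknown label: ", x)
  }
  check_label(a); check_label(b)
  m[a, b]
}

#' @rdname contact_energy
#' @export
set_contact_energy <- function(J, a, b, value, internal = FALSE) {
  which <- if (internal) "internal" else "external"
  m <- J[[which]]
  if (!a %in% rownames(m)) stop("unknown label: ", a)
  if (!b %in% rownames(m)) stop("unknown label: ", b)
  m[a, b] <- value
  m[b, a] <- value
  J[[which]] <- m
  J
}

#' @export
as.data.frame.contact_energies <- function(x, ...) {
  nm <- rownames(x$external)
  idx <- which(upper.tri(x$external, diag = TRUE), arr.ind = TRUE)
  data.frame(
    label_a = nm[idx[, 1]], label_b = nm[idx[, 2]],
    J_external = x$external[idx],
    J_internal = x$internal[idx],
    stringsAsFactors = FALSE
  )
}

#' Read or write a contact-energy table as JSON
#'
#' The full matrix ships with the package as a versioned configuration file
#' (`system.file("extdata", "contact_energies_base.json", package =
#' "luadmorph")`); presets override named entries of it.
#'
#' @param J A `contact_energies` object.
#' @param path File path.
#' @return `read_contact_energies()` returns a `contact_energies` object.
#' @export
write_contact_energies <- function(J, path) {
  jsonlite::write_json(
    list(version = 1L, labels = J$labels, pairs = as.data.frame(J)),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_contact_energies
#' @export
read_contact_energies <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- tibble::as_tibble(raw$labels)
  nm <- label_names(labels)
  n <- length(nm)
  ext <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  int <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  p <- raw$pairs
  for (i in seq_len(nrow(p))) {
    ext[p$label_a[i], p$label_b[i]] <- ext[p$label_b[i], p$label_a[i]] <- p$J_external[i]
    int[p$label_a[i], p$label_b[i]] <- int[p$label_b[i], p$label_a[i]] <- p$J_internal[i]
  }
  if (anyNA(ext) || anyNA(int)) stop("contact-energy file is missing entries")
  contact_energies(ext, int, labels)
}
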