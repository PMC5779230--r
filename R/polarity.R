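# Compartment-specific fluorescence quantification and polarity ratios.
#
# Every intensity is corrected by subtracting a paired control region
# adjacent to the ROI (non-specific staining). Windows are half-open
# [a, b) in um of traced arclength from the soma edge. The axon stem is
# 0-100 um of the axon; the dendrite signal averages the corrected
# 0-100 um intensity of the brightest three dendrites; distal axon
# signals come from the 350-450 and 750-850 um windows.

#' Background-corrected mean intensity over an arclength window
#'
#' Mean profile intensity over the half-open window `[a, b)` minus the
#' paired background. Negative corrected intensities are permitted but
#' flagged with a warning.
#'
#' @param profile Tibble with `arclength_um` and `intensity` for one
#'   neurite.
#' @param window_um Length-2 numeric, the `[a, b)` window in um.
#' @param background Paired background intensity for this region.
#'
#' @return The corrected intensity (scalar).
#' @export
#' @examples
#' p <- tibble::tibble(arclength_um = 0:100, intensity = 50)
#' corrected_intensity(p, c(0, 100), background = 10)
corrected_intensity <- function(profile, window_um, background) {
  stopifnot(length(window_um) == 2, window_um[1] < window_um[2])
  x <- profile$arclength_um
  if (window_um[1] < min(x) || window_um[2] > max(x) + 1) {
    abort(sprintf("window [%g, %g) outside profile extent [%g, %g]",
                  window_um[1], window_um[2], min(x), max(x)))
  }
  sel <- x >= window_um[1] & x < window_um[2]
  if (!any(sel)) abort("window contains no samples")
  out <- mean(profile$intensity[sel]) - background
  if (out < 0) {
    warn(sprintf("negative corrected intensity (%.3g) in [%g, %g)",
                 out, window_um[1], window_um[2]))
  }
  out
}

region_background <- function(regions, cid, region) {
  hit <- regions$background[regions$cell_id == cid &
                              regions$region == region]
  if (length(hit) != 1) {
    abort(sprintf("cell %s: expected one background for region '%s', got %d",
                  cid, region, length(hit)))
  }
  hit
}

#' Compute compartment signals for each cell
#'
#' For every cell: the axon stem signal (corrected 0-100 um of the single
#' axon), the dendrite signal (mean corrected 0-100 um over the brightest
#' three dendrites, ranked by corrected intensity with ties broken toward
#' the lowest neurite id), the corrected cell body signal, and the distal
#' axon signals from the 350-450 and 750-850 um windows when the axon is
#' long enough. Cells with more than one axon are rejected (multi-axon
#' neurons are excluded from polarity analysis), as are cells with fewer
#' than three dendrites.
#'
#' @param profiles Tibble (`cell_id`, `neurite_id`, `kind`,
#'   `arclength_um`, `intensity`).
#' @param regions Tibble (`cell_id`, `region`, `background`); regions are
#'   `axon_stem`, `axon_400`, `axon_800`, `cell_body` and
#'   `dendrite_<neurite_id>`.
#' @param cell_body Tibble (`cell_id`, `intensity`) of raw soma
#'   intensities, or `NULL` when unavailable.
#'
#' @return A tibble per cell: `axon_stem_signal`, `dendrite_signal`,
#'   `cell_body_signal`, `axon_400_signal`, `axon_800_signal` (`NA` when
#'   not measurable).
#' @export
compute_compartment_signals <- function(profiles, regions,
                                        cell_body = NULL) {
  rows <- lapply(split(profiles, profiles$cell_id), function(pc) {
    cid <- pc$cell_id[1]
    ax <- pc[pc$kind == "axon", ]
    n_ax <- length(unique(ax$neurite_id))
    if (n_ax != 1) {
      abort(sprintf("cell %s: expected exactly 1 axon, found %d", cid, n_ax))
    }
    dend_ids <- unique(pc$neurite_id[pc$kind == "dendrite"])
    if (length(dend_ids) < 3) {
      abort(sprintf("cell %s: need >= 3 dendrites, found %d", cid,
                    length(dend_ids)))
    }
    stem <- corrected_intensity(ax, c(0, 100),
                                region_background(regions, cid, "axon_stem"))
    dvals <- vapply(sort(dend_ids), function(d) {
      corrected_intensity(pc[pc$neurite_id == d, ], c(0, 100),
                          region_background(regions, cid,
                                            paste0("dendrite_", d)))
    }, numeric(1))
    # brightest three; sort() above fixed id order, so ties fall to the
    # lowest neurite id
    top3 <- head(order(dvals, decreasing = TRUE), 3)
    dend <- mean(dvals[top3])

    distal <- function(win, region) {
      if (max(ax$arclength_um) + 1 >= win[2]) {
        corrected_intensity(ax, win, region_background(regions, cid, region))
      } else NA_real_
    }
    cb <- NA_real_
    if (!is.null(cell_body)) {
      raw <- cell_body$intensity[cell_body$cell_id == cid]
      if (length(raw) == 1) {
        cb <- raw - region_background(regions, cid, "cell_body")
      }
    }
    tibble::tibble(
      cell_id = cid,
      axon_stem_signal = stem,
      dendrite_signal = dend,
      cell_body_signal = cb,
      axon_400_signal = distal(c(350, 450), "axon_400"),
      axon_800_signal = distal(c(750, 850), "axon_800")
    )
  })
  dplyr::bind_rows(rows)
}

#' Compute polarity ratios
#'
#' Fills the ratios from the compartment signals: axon stem / dendrite,
#' axon stem / cell body, dendrite / cell body, and the distal-to-stem
#' ratios used to quantify axonal exclusion. A ratio is `NA` (flagged
#' with a warning) when its denominator is not positive.
#'
#' @param signals Tibble from [compute_compartment_signals()].
#'
#' @return The input with `axon_dendrite_ratio`, `axon_cell_body_ratio`,
#'   `dendrite_cell_body_ratio`, `distal_400_over_stem`,
#'   `distal_800_over_stem` appended.
#' @export
compute_polarity_ratios <- function(signals) {
  safe_ratio <- function(num, den, what) {
    bad <- !is.na(den) & den <= 0 & !is.na(num)
    if (any(bad)) {
      warn(sprintf("%s undefined for: %s (denominator <= 0)", what,
                   paste(signals$cell_id[bad], collapse = ", ")))
    }
    ifelse(is.na(den) | den <= 0, NA_real_, num / den)
  }
  signals$axon_dendrite_ratio <-
    safe_ratio(signals$axon_stem_signal, signals$dendrite_signal,
               "axon/dendrite ratio")
  signals$axon_cell_body_ratio <-
    safe_ratio(signals$axon_stem_signal, signals$cell_body_signal,
               "axon/cell-body ratio")
  signals$dendrite_cell_body_ratio <-
    safe_ratio(signals$dendrite_signal, signals$cell_body_signal,
               "dendrite/cell-body ratio")
  signals$distal_400_over_stem <-
    safe_ratio(signals$axon_400_signal, signals$axon_stem_signal,
               "distal(400)/stem ratio")
  signals$distal_800_over_stem <-
    safe_ratio(signals$axon_800_signal, signals$axon_stem_signal,
               "distal(800)/stem ratio")
  signals
}
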