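# Scoring of post-axotomy outcomes and the six regeneration factors
# (retraction distance, bulb formation time, regeneration ratio,
# initiation time, regeneration length, growth-cone area) from tip
# trajectories. Only the first 10 hr after axotomy are used to classify
# the initial response; death and branch loss are excluded from factor
# computation.

# First frame of a stable stretch: k consecutive steps all below delta.
# Returns the frame index or NA.
stable_frame <- function(pos, t_hr, delta_um, k) {
  n <- length(pos)
  if (n < k + 1) return(NA_integer_)
  small <- abs(diff(pos)) < delta_um
  for (m in seq_len(n - k)) {
    if (all(small[m:(m + k - 1)])) return(m)
  }
  NA_integer_
}

#' Classify the initial response to axotomy
#'
#' Death if a disintegration or cell-disruption flag occurs within 10 hr
#' of the cut; otherwise branch loss if the tip retracts to within
#' `branch_tol_um` of the nearest proximal branch point (no retraction
#' bulb forms); otherwise bulb formation. Death and branch loss are
#' excluded from further factor analysis.
#'
#' @param tc An [axotomy_timecourse()].
#' @param branch_points_um Positions of axon branch points proximal to
#'   the cut (um from soma); may be `NULL` when the cell has none.
#' @param branch_tol_um Tolerance for "retracted to the branch point".
#' @param delta_stab_um,k_stab Bulb stabilization rule: the bulb forms at
#'   the first frame opening `k_stab` consecutive steps all smaller than
#'   `delta_stab_um`.
#'
#' @return A list: `initial_response` (`death` / `branch_loss` /
#'   `bulb_formation`), `excluded`, `bulb_frame` (index or `NA`),
#'   `ambiguous` (retraction reached the trajectory minimum with no
#'   branch-point list supplied).
#' @export
classify_initial_response <- function(tc, branch_points_um = NULL,
                                      branch_tol_um = 10,
                                      delta_stab_um = 10, k_stab = 2) {
  stopifnot(inherits(tc, "axotomy_timecourse"))
  fr <- tc$frames
  early <- fr$t_hr <= 10
  dead <- any(fr$flag[early] %in% c("disintegration", "cell_disruption"))
  if (dead) {
    return(list(initial_response = "death", excluded = TRUE,
                bulb_frame = NA_integer_, ambiguous = FALSE))
  }
  m <- stable_frame(fr$tip_position_um, fr$t_hr, delta_stab_um, k_stab)
  if (is.na(m)) {
    return(list(initial_response = "bulb_formation", excluded = TRUE,
                bulb_frame = NA_integer_, ambiguous = TRUE))
  }
  stable_pos <- mean(fr$tip_position_um[m:(m + k_stab)])
  bp <- branch_points_um[branch_points_um < tc$axotomy_um]
  if (length(bp) > 0 && min(abs(stable_pos - bp)) <= branch_tol_um) {
    return(list(initial_response = "branch_loss", excluded = TRUE,
                bulb_frame = NA_integer_, ambiguous = FALSE))
  }
  list(initial_response = "bulb_formation", excluded = FALSE,
       bulb_frame = m, ambiguous = FALSE)
}

#' Measure retraction distance and bulb formation time
#'
#' The bulb forms at the first frame opening `k_stab` consecutive
#' position steps all smaller than `delta_stab_um` (a positional proxy
#' for the morphological bulb). Bulb time is measured from axotomy (t =
#' 0); retraction distance is the axon length lost between the cut site
#' and the bulb, i.e. `axotomy_um` minus the stabilized tip position
#' (averaged over the stable frames to suppress measurement noise).
#'
#' @inheritParams classify_initial_response
#'
#' @return A list: `retraction_um`, `bulb_time_hr`, `bulb_position_um`,
#'   `bulb_frame`, `bulb_found`.
#' @export
measure_retraction <- function(tc, delta_stab_um = 10, k_stab = 2) {
  stopifnot(inherits(tc, "axotomy_timecourse"))
  fr <- tc$frames
  m <- stable_frame(fr$tip_position_um, fr$t_hr, delta_stab_um, k_stab)
  if (is.na(m) || fr$t_hr[m] > 10) {
    warn(sprintf("cell %s: no bulb stabilization within 10 hr", tc$cell_id))
    return(list(retraction_um = NA_real_, bulb_time_hr = NA_real_,
                bulb_position_um = NA_real_, bulb_frame = NA_integer_,
                bulb_found = FALSE))
  }
  bulb_pos <- mean(fr$tip_position_um[m:(m + k_stab)])
  list(retraction_um = tc$axotomy_um - bulb_pos,
       bulb_time_hr = fr$t_hr[m],
       bulb_position_um = bulb_pos,
       bulb_frame = m,
       bulb_found = TRUE)
}

#' Detect regeneration after bulb formation
#'
#' Scans the frames after bulb formation for the earliest time at which a
#' steady extension lasting more than `window_hr` begins: every step in
#' the following window must advance (beyond `-step_tolerance_um`) and
#' the net gain over the window must reach `v_min_um_hr`. If found, the
#' outcome is regeneration and the initiation time is measured from bulb
#' formation. Otherwise, a `new_branch` flag within
#' `ectopic_radius_um` of the bulb makes the outcome ectopic growth;
#' else no regeneration.
#'
#' @param tc An [axotomy_timecourse()].
#' @param bulb_time_hr,bulb_position_um Bulb measurements from
#'   [measure_retraction()].
#' @param v_min_um_hr Minimum net advance rate distinguishing steady
#'   extension from bulb motility (um/hr).
#' @param window_hr Persistence window (hr); the paper's rule is an
#'   extension lasting more than 1 hr.
#' @param step_tolerance_um Allowed per-step backward excursion (um);
#'   zero demands strictly advancing steps, useful for noise-free data.
#' @param ectopic_radius_um Radius around the bulb within which a new
#'   branch counts as ectopic growth (um).
#'
#' @return A list: `outcome` (`regeneration` / `ectopic` / `none`),
#'   `init_time_hr` (from bulb formation), `init_time_abs_hr`,
#'   `indeterminate` (an extension started but the trajectory ended
#'   before one full window).
#' @export
detect_regeneration <- function(tc, bulb_time_hr, bulb_position_um,
                                v_min_um_hr = 10, window_hr = 1,
                                step_tolerance_um = 0,
                                ectopic_radius_um = 100) {
  stopifnot(inherits(tc, "axotomy_timecourse"))
  fr <- tc$frames
  t <- fr$t_hr
  p <- fr$tip_position_um
  idx <- which(t >= bulb_time_hr)
  indeterminate <- FALSE
  for (j in idx) {
    in_w <- which(t > t[j] & t <= t[j] + window_hr)
    if (length(in_w) == 0) next
    # window must be fully covered by the recording
    if (max(t) < t[j] + window_hr) {
      steps <- diff(p[c(j, in_w)])
      if (all(steps > step_tolerance_um * -1) &&
          sum(steps) >= v_min_um_hr * (max(t) - t[j])) {
        indeterminate <- TRUE
      }
      break
    }
    steps <- diff(p[c(j, in_w)])
    gain <- stats::approx(t, p, xout = t[j] + window_hr)$y - p[j]
    if (all(steps > -step_tolerance_um) && gain >= v_min_um_hr * window_hr) {
      return(list(outcome = "regeneration",
                  init_time_hr = t[j] - bulb_time_hr,
                  init_time_abs_hr = t[j],
                  indeterminate = FALSE))
    }
  }
  nb <- which(fr$flag == "new_branch")
  if (length(nb) > 0 &&
      any(abs(fr$flag_position_um[nb] - bulb_position_um) <=
            ectopic_radius_um)) {
    return(list(outcome = "ectopic", init_time_hr = NA_real_,
                init_time_abs_hr = NA_real_, indeterminate = FALSE))
  }
  list(outcome = "none", init_time_hr = NA_real_,
       init_time_abs_hr = NA_real_, indeterminate = indeterminate)
}

#' Measure regrowth length and growth-cone area
#'
#' Regeneration length is the axon length extended within 2 hr of
#' regeneration initiation, taken as path length along the recorded
#' trajectory (advancing segments summed; positions at the window edges
#' are linearly interpolated). Growth-cone area averages the tip area at
#' the frames nearest 20, 40 and 60 min after initiation (or linearly
#' interpolated when `interpolate_area = TRUE`).
#'
#' @param tc An [axotomy_timecourse()].
#' @param init_time_abs_hr Absolute initiation time (hr after axotomy).
#' @param length_window_hr Regrowth window (hr).
#' @param probe_min Area probe times after initiation (min).
#' @param interpolate_area Linearly interpolate the area channel instead
#'   of nearest-frame matching.
#'
#' @return A list: `regen_length_um`, `gc_area_um2` (`NA` when the area
#'   channel is absent).
#' @export
measure_regrowth <- function(tc, init_time_abs_hr, length_window_hr = 2,
                             probe_min = c(20, 40, 60),
                             interpolate_area = FALSE) {
  stopifnot(inherits(tc, "axotomy_timecourse"))
  fr <- tc$frames
  t <- fr$t_hr
  p <- fr$tip_position_um
  t_end <- init_time_abs_hr + length_window_hr
  if (max(t) < t_end) abort("trajectory ends before the regrowth window")
  p0 <- stats::approx(t, p, xout = init_time_abs_hr)$y
  p1 <- stats::approx(t, p, xout = t_end)$y
  inside <- t > init_time_abs_hr & t < t_end
  path <- c(p0, p[inside], p1)
  regen_length <- sum(pmax(diff(path), 0))

  gc <- NA_real_
  if (any(is.finite(fr$tip_area_um2))) {
    probes <- init_time_abs_hr + probe_min / 60
    vals <- if (interpolate_area) {
      stats::approx(t, fr$tip_area_um2, xout = probes)$y
    } else {
      vapply(probes, function(tp) fr$tip_area_um2[which.min(abs(t - tp))],
             numeric(1))
    }
    gc <- mean(vals)
  }
  list(regen_length_um = regen_length, gc_area_um2 = gc)
}

#' Score one axotomy time course end to end
#'
#' Runs initial-response classification, bulb/retraction measurement,
#' regeneration detection and regrowth measurement, returning one
#' regeneration record.
#'
#' @inheritParams classify_initial_response
#' @inheritParams detect_regeneration
#' @inheritParams measure_regrowth
#'
#' @return A one-row tibble: identifiers, `initial_response`, `outcome`,
#'   the six factors, and flags.
#' @export
#' @examples
#' sim <- gen_axotomy_timecourse("regeneration", seed = 2)
#' analyze_timecourse(sim$tc)
analyze_timecourse <- function(tc, branch_points_um = NULL,
                               branch_tol_um = 10, delta_stab_um = 10,
                               k_stab = 2, v_min_um_hr = 10,
                               window_hr = 1, step_tolerance_um = 0,
                               ectopic_radius_um = 100,
                               length_window_hr = 2,
                               probe_min = c(20, 40, 60),
                               interpolate_area = FALSE) {
  stopifnot(inherits(tc, "axotomy_timecourse"))
  rec <- tibble::tibble(
    cell_id = tc$cell_id, div = tc$div, substrate = tc$substrate,
    axotomy_um = tc$axotomy_um,
    initial_response = NA_character_, outcome = NA_character_,
    retraction_um = NA_real_, bulb_time_hr = NA_real_,
    init_time_hr = NA_real_, regen_length_um = NA_real_,
    gc_area_um2 = NA_real_, excluded = FALSE, indeterminate = FALSE
  )
  ir <- classify_initial_response(tc, branch_points_um, branch_tol_um,
                                  delta_stab_um, k_stab)
  rec$initial_response <- ir$initial_response
  rec$excluded <- ir$excluded
  if (ir$excluded) {
    rec$outcome <- "excluded"
    return(rec)
  }
  mr <- measure_retraction(tc, delta_stab_um, k_stab)
  if (!mr$bulb_found) {
    rec$excluded <- TRUE
    rec$outcome <- "excluded"
    return(rec)
  }
  rec$retraction_um <- mr$retraction_um
  rec$bulb_time_hr <- mr$bulb_time_hr
  dr <- detect_regeneration(tc, mr$bulb_time_hr, mr$bulb_position_um,
                            v_min_um_hr, window_hr, step_tolerance_um,
                            ectopic_radius_um)
  rec$outcome <- dr$outcome
  rec$indeterminate <- dr$indeterminate
  if (dr$outcome == "regeneration") {
    rec$init_time_hr <- dr$init_time_hr
    if (max(tc$frames$t_hr) >= dr$init_time_abs_hr + length_window_hr) {
      gr <- measure_regrowth(tc, dr$init_time_abs_hr, length_window_hr,
                             probe_min, interpolate_area)
      rec$regen_length_um <- gr$regen_length_um
      rec$gc_area_um2 <- gr$gc_area_um2
    } else {
      # extension began but the recording ends inside the regrowth window
      rec$indeterminate <- TRUE
    }
  }
  rec
}

#' Categorize a regeneration record
#'
#' Fills the derived classes: `log10_retraction` (retraction distances
#' are log-normal, so statistics run on log10 values), the short/long
#' retraction class with the 70 um boundary inclusive on the long side,
#' the proximal/distal axotomy class, and the overall regeneration score
#' (regeneration and ectopic growth combined).
#'
#' @param records Tibble from [analyze_timecourse()] (one or more rows).
#' @param long_boundary_um Short/long retraction boundary (um); 70 um,
#'   with exactly 70 counting as long.
#' @param proximal_cut_um Axotomy distances at or beyond this are
#'   classed distal. The boundary is a configurable analysis default and
#'   is reported in output metadata.
#'
#' @return The records with `log10_retraction`, `retraction_class`,
#'   `axotomy_class`, `overall_regenerated` filled; the boundaries used
#'   are attached as attributes.
#' @export
categorize_record <- function(records, long_boundary_um = 70,
                              proximal_cut_um = 500) {
  r <- records$retraction_um
  bad <- !is.na(r) & r <= 0
  if (any(bad)) {
    warn(sprintf("non-positive retraction for: %s; log10 undefined",
                 paste(records$cell_id[bad], collapse = ", ")))
  }
  records$log10_retraction <- ifelse(is.na(r) | r <= 0, NA_real_, log10(r))
  records$retraction_class <- dplyr::case_when(
    is.na(r) ~ NA_character_,
    r >= long_boundary_um ~ "long",
    TRUE ~ "short"
  )
  records$axotomy_class <- ifelse(records$axotomy_um >= proximal_cut_um,
                                  "distal", "proximal")
  records$overall_regenerated <- records$outcome %in%
    c("regeneration", "ectopic")
  attr(records, "long_boundary_um") <- long_boundary_um
  attr(records, "proximal_cut_um") <- proximal_cut_um
  records
}

#' Summarize a regeneration cohort
#'
#' Per-group sample sizes, the regeneration ratio (regenerated neurons,
#' including ectopic growth, over all neurons that formed a retraction
#' bulb) and mean with s.e.m. of each factor (retraction on the log10
#' scale). With two or more groups, regeneration ratios are compared by
#' Fisher's exact test with Bonferroni correction over all group pairs,
#' and log10 retraction by the harness' selection logic (Student/Welch t
#' for two groups, ANOVA with a Bartlett-gated post hoc otherwise).
#'
#' @param records Categorized records from [categorize_record()].
#' @param group_vars Character vector of grouping columns.
#'
#' @return A list: `summary` (one row per group), `ratio_tests`
#'   (pairwise Fisher results, `NULL` for a single group),
#'   `retraction_tests`.
#' @export
summarize_cohort <- function(records,
                             group_vars = c("div", "retraction_class",
                                            "axotomy_class")) {
  bulbs <- records[!records$excluded & !is.na(records$retraction_um), ]
  if (nrow(bulbs) == 0) abort("no bulb-forming records to summarize")
  bulbs$group <- interaction(bulbs[group_vars], drop = TRUE, sep = "/")
  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  }
  mfin <- function(x) if (any(is.finite(x))) mean(x[is.finite(x)]) else NA_real_
  smry <- bulbs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarize(
      n_bulb = dplyr::n(),
      n_regenerated = sum(.data$overall_regenerated),
      regeneration_ratio = .data$n_regenerated / .data$n_bulb,
      log10_retraction_mean = mfin(.data$log10_retraction),
      log10_retraction_sem = sem(.data$log10_retraction),
      bulb_time_mean_hr = mfin(.data$bulb_time_hr),
      bulb_time_sem_hr = sem(.data$bulb_time_hr),
      init_time_mean_hr = mfin(.data$init_time_hr),
      init_time_sem_hr = sem(.data$init_time_hr),
      regen_length_mean_um = mfin(.data$regen_length_um),
      regen_length_sem_um = sem(.data$regen_length_um),
      gc_area_mean_um2 = mfin(.data$gc_area_um2),
      gc_area_sem_um2 = sem(.data$gc_area_um2),
      .groups = "drop"
    )

  ratio_tests <- NULL
  retraction_tests <- NULL
  lv <- levels(bulbs$group)
  if (length(lv) >= 2) {
    pairs <- combn(lv, 2)
    tabs <- lapply(seq_len(ncol(pairs)), function(i) {
      s1 <- smry[smry$group == pairs[1, i], ]
      s2 <- smry[smry$group == pairs[2, i], ]
      matrix(c(s1$n_regenerated, s1$n_bulb - s1$n_regenerated,
               s2$n_regenerated, s2$n_bulb - s2$n_regenerated),
             nrow = 2, byrow = TRUE)
    })
    ratio_tests <- fisher_exact_bonferroni(tabs)
    ratio_tests$group1 <- pairs[1, ]
    ratio_tests$group2 <- pairs[2, ]

    lr <- bulbs[is.finite(bulbs$log10_retraction), ]
    if (length(unique(lr$group)) == 2) {
      ab <- split(lr$log10_retraction, droplevels(lr$group))
      if (all(lengths(ab) >= 2)) {
        retraction_tests <- t_test_auto(ab[[1]], ab[[2]])
        retraction_tests$group1 <- names(ab)[1]
        retraction_tests$group2 <- names(ab)[2]
      }
    } else if (length(unique(lr$group)) > 2) {
      retraction_tests <- anova_posthoc(lr$log10_retraction,
                                        as.character(lr$group))$posthoc
    }
  }
  list(summary = smry, ratio_tests = ratio_tests,
       retraction_tests = retraction_tests)
}
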