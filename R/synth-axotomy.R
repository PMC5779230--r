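# Synthetic post-axotomy time courses with planted outcomes and factors.

#' Construct an axotomy time course
#'
#' Container for one cell's post-axotomy trajectory: the axon tip
#' position along its path from the soma, sampled every 20-30 min for at
#' least 10 hr after the cut at time zero, with optional tip-area channel
#' and event flags (`disintegration`, `cell_disruption`,
#' `new_branch` with a position).
#'
#' @param cell_id Cell identifier.
#' @param axotomy_um Distance of the cut from the axon stem (um), in
#'   `[250, 2000]`.
#' @param frames Tibble with `t_hr` (strictly increasing, spacing 20-30
#'   min), `tip_position_um`, and optionally `tip_area_um2`, `flag`,
#'   `flag_position_um`.
#' @param div Days-in-vitro maturity label.
#' @param substrate Substrate grouping label (passthrough).
#' @param spacing_tol_min Tolerance on the frame-spacing check (min).
#'
#' @return An object of class `axotomy_timecourse`.
#' @export
axotomy_timecourse <- function(cell_id, axotomy_um, frames, div = NA,
                               substrate = NA, spacing_tol_min = 2) {
  assert_scalar_num(axotomy_um, "axotomy_um", lower = 250, upper = 2000)
  stopifnot(is.data.frame(frames), all(c("t_hr", "tip_position_um") %in%
                                         names(frames)))
  if (!"tip_area_um2" %in% names(frames)) frames$tip_area_um2 <- NA_real_
  if (!"flag" %in% names(frames)) frames$flag <- NA_character_
  if (!"flag_position_um" %in% names(frames)) {
    frames$flag_position_um <- NA_real_
  }
  dt_min <- diff(frames$t_hr) * 60
  if (any(dt_min <= 0)) abort("frame times must be strictly increasing")
  if (any(dt_min < 20 - spacing_tol_min | dt_min > 30 + spacing_tol_min)) {
    abort("frame spacing must lie in [20, 30] min")
  }
  if (max(frames$t_hr) < 10) abort("trajectory must cover >= 10 hr")
  structure(list(cell_id = cell_id, axotomy_um = axotomy_um,
                 frames = tibble::as_tibble(frames), div = div,
                 substrate = substrate),
            class = "axotomy_timecourse")
}

#' @export
print.axotomy_timecourse <- function(x, ...) {
  cat(sprintf("<axotomy_timecourse> cell %s, cut at %.0f um, %d frames over %.1f hr\n",
              x$cell_id, x$axotomy_um, nrow(x$frames), max(x$frames$t_hr)))
  invisible(x)
}

#' Generate a synthetic post-axotomy time course
#'
#' Builds a tip trajectory for one planted outcome. The tip starts at the
#' cut site, retracts to the bulb position with per-frame steps large
#' enough to be distinguished from bulb motility, then (depending on
#' `outcome`) initiates steady elongation, sprouts an ectopic branch,
#' disintegrates, or sits still. Frame spacing is drawn uniformly in
#' `frame_min` minutes and timestamps are stored explicitly, so no
#' downstream stage may assume uniform spacing. The planted retraction,
#' bulb time, initiation delay and elongation rate actually realised on
#' the frame grid are recorded as ground truth.
#'
#' @param outcome One of `"death"`, `"branch_loss"`, `"regeneration"`,
#'   `"ectopic"`, `"no_regeneration"`.
#' @param axotomy_um Cut distance from the axon stem (um), 250-2000.
#' @param retraction_um Planted retraction distance (um); must be smaller
#'   than `axotomy_um`.
#' @param bulb_time_hr Requested time to form the retraction bulb (hr);
#'   shortened if needed so every retraction step exceeds
#'   `min_retract_step_um` (the realised value is in the ground truth).
#' @param init_delay_hr Delay from bulb formation to regeneration
#'   initiation (hr).
#' @param elong_um_hr Elongation rate after initiation (um/hr).
#' @param gc_area_um2 Growth-cone (tip) area after initiation (um^2).
#' @param pre_area_um2 Tip area before initiation (um^2).
#' @param frame_min Frame-interval range in minutes.
#' @param total_hr Trajectory coverage (hr), at least 10.
#' @param noise_sd_um Positional measurement noise sd (um).
#' @param min_retract_step_um Smallest per-frame retraction step (um).
#' @param death_time_hr Time of the disintegration flag for `"death"`.
#' @param branch_points_um Branch-point positions (um from soma); the
#'   nearest proximal one is the target of a `"branch_loss"` trajectory.
#' @param ectopic_offset_um Distance from the bulb at which the ectopic
#'   branch appears (um, within 100).
#' @param cell_id,div,substrate Metadata labels.
#' @param seed Integer seed.
#'
#' @return A list with `tc` (an [axotomy_timecourse()]) and `truth`
#'   (planted outcome and factor values as realised on the frame grid).
#' @export
gen_axotomy_timecourse <- function(outcome,
                                   axotomy_um = 800,
                                   retraction_um = 150,
                                   bulb_time_hr = 2,
                                   init_delay_hr = 2,
                                   elong_um_hr = 30,
                                   gc_area_um2 = 40,
                                   pre_area_um2 = 15,
                                   frame_min = c(20, 30),
                                   total_hr = 13,
                                   noise_sd_um = 0,
                                   min_retract_step_um = 20,
                                   death_time_hr = 6,
                                   branch_points_um = NULL,
                                   ectopic_offset_um = 50,
                                   cell_id = "cell1", div = 16,
                                   substrate = "PDL", seed = 1) {
  outcome <- match.arg(outcome, c("death", "branch_loss", "regeneration",
                                  "ectopic", "no_regeneration"))
  assert_scalar_num(axotomy_um, "axotomy_um", lower = 250, upper = 2000)
  if (retraction_um >= axotomy_um) {
    abort("retraction cannot exceed the axotomy distance")
  }
  if (total_hr < 10) abort("`total_hr` must cover the 10 hr window")

  with_seed(seed, {
    t_hr <- c(0)
    while (tail(t_hr, 1) < total_hr) {
      t_hr <- c(t_hr, tail(t_hr, 1) + runif(1, frame_min[1], frame_min[2]) / 60)
    }
    n <- length(t_hr)
    pos <- rep(axotomy_um, n)
    area <- rep(pre_area_um2, n)
    flag <- rep(NA_character_, n)
    flag_pos <- rep(NA_real_, n)

    # retraction: linear to the bulb with per-frame steps that clear the
    # bulb-stability threshold; shorten arrival if steps would be small
    target <- if (outcome == "branch_loss") {
      if (is.null(branch_points_um)) {
        abort("branch_loss requires `branch_points_um`")
      }
      bp <- branch_points_um[branch_points_um < axotomy_um]
      if (length(bp) == 0) abort("no branch point proximal to the cut")
      max(bp)
    } else {
      axotomy_um - retraction_um
    }
    drop_um <- axotomy_um - target
    j_req <- max(1, which.min(abs(t_hr - bulb_time_hr)))
    j_max <- max(1, floor(drop_um / min_retract_step_um))
    j_arr <- min(j_req, j_max)
    ramp <- seq(axotomy_um, target, length.out = j_arr + 1)
    pos[seq_len(j_arr + 1)] <- ramp
    pos[(j_arr + 1):n] <- target
    bulb_time <- t_hr[j_arr + 1]

    init_abs <- NA_real_
    elong_real <- NA_real_
    if (outcome == "regeneration") {
      j_init <- which.min(abs(t_hr - (bulb_time + init_delay_hr)))
      j_init <- max(j_init, j_arr + 2)  # at least one stationary bulb frame
      if (t_hr[j_init] + 2 > total_hr) {
        abort("trajectory too short for 2 hr of regrowth after initiation")
      }
      init_abs <- t_hr[j_init]
      grow <- t_hr > init_abs
      pos[grow] <- target + elong_um_hr * (t_hr[grow] - init_abs)
      area[t_hr >= init_abs] <- gc_area_um2
      elong_real <- elong_um_hr
    } else if (outcome == "ectopic") {
      j_flag <- which.min(abs(t_hr - (bulb_time + init_delay_hr)))
      if (abs(ectopic_offset_um) > 100) {
        abort("ectopic branch must lie within 100 um of the bulb")
      }
      flag[j_flag] <- "new_branch"
      flag_pos[j_flag] <- target + ectopic_offset_um
    } else if (outcome == "death") {
      if (death_time_hr > 10) abort("death flag must occur within 10 hr")
      j_flag <- which.min(abs(t_hr - death_time_hr))
      flag[j_flag] <- "disintegration"
    }

    if (noise_sd_um > 0) pos <- pos + rnorm(n, 0, noise_sd_um)

    tc <- axotomy_timecourse(
      cell_id = cell_id, axotomy_um = axotomy_um,
      frames = tibble::tibble(t_hr = t_hr, tip_position_um = pos,
                              tip_area_um2 = area, flag = flag,
                              flag_position_um = flag_pos),
      div = div, substrate = substrate
    )
    list(tc = tc, truth = list(
      outcome = outcome,
      retraction_um = if (outcome %in% c("death", "branch_loss")) NA_real_
      else drop_um,
      bulb_time_hr = if (outcome %in% c("death", "branch_loss")) NA_real_
      else bulb_time,
      init_delay_hr = if (outcome == "regeneration") init_abs - bulb_time
      else NA_real_,
      init_time_abs_hr = init_abs,
      elong_um_hr = elong_real,
      gc_area_um2 = if (outcome == "regeneration") gc_area_um2 else NA_real_,
      regen_length_um = if (outcome == "regeneration") 2 * elong_um_hr
      else NA_real_
    ))
  })
}

#' Generate a cohort of axotomy time courses
#'
#' Draws planted outcomes by largest-remainder allocation of
#' `outcome_fractions`, retraction distances from a log10-normal mixture
#' (`mix_weights`, `mix_means`, `mix_sds`, in log10 um), and the
#' remaining factors uniformly from plausible ranges. Used to verify
#' outcome classification, factor recovery and the retraction mixture
#' fit by closed loop.
#'
#' @param n Number of cells.
#' @param outcome_fractions Named fractions over the five outcomes.
#' @param mix_weights,mix_means,mix_sds Log10-retraction mixture.
#' @param div,substrate Metadata labels recycled over cells.
#' @param noise_sd_um Positional noise passed to each trajectory.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [gen_axotomy_timecourse()].
#'
#' @return A list with `cells` (list of `tc` objects) and `truth` (one
#'   row per cell).
#' @export
gen_axotomy_cohort <- function(n,
                               outcome_fractions = c(death = 0.15,
                                                     branch_loss = 0.1,
                                                     regeneration = 0.3,
                                                     ectopic = 0.1,
                                                     no_regeneration = 0.35),
                               mix_weights = c(0.5, 0.5),
                               mix_means = c(1.5, 2.2),
                               mix_sds = c(0.15, 0.15),
                               div = 16, substrate = "PDL",
                               noise_sd_um = 0, seed = 1, ...) {
  n <- assert_count(n, "n", lower = 1)
  counts <- largest_remainder(n, outcome_fractions)
  outcomes <- sample_vec <- rep(names(counts), counts)
  with_seed(seed, {
    comp <- sample.int(length(mix_weights), n, replace = TRUE,
                       prob = mix_weights)
    log10_r <- rnorm(n, mix_means[comp], mix_sds[comp])
    # a retraction below the bulb-stabilization resolution (10 um) cannot
    # be resolved from bulb motility; floor the rare (<1e-3) tail draws
    retr <- pmax(10^log10_r, 12)
    axo <- pmax(pmin(runif(n, 500, 2000), 2000), retr / 0.8 + 50)
    axo <- pmin(axo, 2000)
    bulb_t <- runif(n, 1, 3)
    init_d <- runif(n, 1, 3.5)
    elong <- runif(n, 20, 60)
    gc <- runif(n, 20, 80)
    seeds <- sample.int(1e7, n)
  })
  cells <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- gen_axotomy_timecourse(
      outcome = outcomes[i], axotomy_um = axo[i],
      retraction_um = min(retr[i], 0.9 * axo[i]),
      bulb_time_hr = bulb_t[i], init_delay_hr = init_d[i],
      elong_um_hr = elong[i], gc_area_um2 = gc[i],
      noise_sd_um = noise_sd_um,
      branch_points_um = if (outcomes[i] == "branch_loss") axo[i] * 0.4,
      cell_id = sprintf("cell%03d", i), div = div, substrate = substrate,
      seed = seeds[i], ...
    )
    cells[[i]] <- sim$tc
    truth[[i]] <- tibble::tibble(
      cell_id = sim$tc$cell_id,
      outcome = sim$truth$outcome,
      retraction_um = sim$truth$retraction_um,
      log10_retraction = log10(sim$truth$retraction_um),
      bulb_time_hr = sim$truth$bulb_time_hr,
      init_delay_hr = sim$truth$init_delay_hr,
      elong_um_hr = sim$truth$elong_um_hr,
      gc_area_um2 = sim$truth$gc_area_um2,
      regen_length_um = sim$truth$regen_length_um
    )
  }
  list(cells = cells, truth = dplyr::bind_rows(truth))
}
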