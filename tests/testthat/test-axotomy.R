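# Outcome classification and the six regeneration factors.

test_that("a disintegration flag within 10 hr means death and exclusion", {
  sim <- gen_axotomy_timecourse("death", death_time_hr = 6, seed = 1)
  ir <- classify_initial_response(sim$tc)
  expect_identical(ir$initial_response, "death")
  expect_true(ir$excluded)
})

test_that("retraction to a branch point with no bulb is branch loss", {
  sim <- gen_axotomy_timecourse("branch_loss", axotomy_um = 800,
                                branch_points_um = c(300, 150), seed = 2)
  ir <- classify_initial_response(sim$tc, branch_points_um = c(300, 150))
  expect_identical(ir$initial_response, "branch_loss")
  expect_true(ir$excluded)
})

test_that("a tip stabilizing away from branch points forms a bulb", {
  sim <- gen_axotomy_timecourse("no_regeneration", axotomy_um = 800,
                                retraction_um = 150, seed = 3)
  ir <- classify_initial_response(sim$tc, branch_points_um = 300)
  expect_identical(ir$initial_response, "bulb_formation")
  expect_false(ir$excluded)
})

test_that("retraction and bulb time recover the planted values", {
  sim <- gen_axotomy_timecourse("no_regeneration", axotomy_um = 800,
                                retraction_um = 150, bulb_time_hr = 2,
                                seed = 4)
  mr <- measure_retraction(sim$tc)
  expect_true(mr$bulb_found)
  expect_equal(mr$retraction_um, 150)
  expect_equal(mr$bulb_time_hr, sim$truth$bulb_time_hr)
  # conservation: retraction + bulb position = axotomy distance
  expect_equal(mr$retraction_um + mr$bulb_position_um, 800)
})

test_that("regeneration initiation and regrowth match the plant", {
  sim <- gen_axotomy_timecourse("regeneration", axotomy_um = 800,
                                retraction_um = 150, bulb_time_hr = 2,
                                init_delay_hr = 2, elong_um_hr = 30,
                                gc_area_um2 = 40, seed = 5)
  rec <- analyze_timecourse(sim$tc)
  expect_identical(rec$outcome, "regeneration")
  expect_equal(rec$init_time_hr, sim$truth$init_delay_hr)
  expect_equal(rec$regen_length_um, 60, tolerance = 1e-8)
  expect_equal(rec$gc_area_um2, 40)
})

test_that("an ectopic branch near the bulb scores as ectopic growth", {
  sim <- gen_axotomy_timecourse("ectopic", ectopic_offset_um = 60,
                                seed = 6)
  rec <- analyze_timecourse(sim$tc)
  expect_identical(rec$outcome, "ectopic")
  rec <- categorize_record(rec)
  expect_true(rec$overall_regenerated)
})

test_that("a motile bulb that never sustains advance is no regeneration", {
  sim <- gen_axotomy_timecourse("no_regeneration", seed = 7,
                                noise_sd_um = 4)
  dr_rec <- suppressWarnings(analyze_timecourse(sim$tc,
                                                step_tolerance_um = 0))
  expect_identical(dr_rec$outcome, "none")
  expect_false(categorize_record(dr_rec)$overall_regenerated)
})

test_that("growth-cone area averages the three probe frames", {
  # frames every 20 min so the probes align exactly
  t_hr <- seq(0, 13, by = 1 / 3)
  pos <- rep(650, length(t_hr))
  pos[t_hr <= 2] <- 800 - (800 - 650) * t_hr[t_hr <= 2] / 2
  grow <- t_hr > 4
  pos[grow] <- 650 + 30 * (t_hr[grow] - 4)
  area <- rep(15, length(t_hr))
  area[abs(t_hr - (4 + 20 / 60)) < 1e-9] <- 10
  area[abs(t_hr - (4 + 40 / 60)) < 1e-9] <- 12
  area[abs(t_hr - 5) < 1e-9] <- 14
  tc <- axotomy_timecourse("c1", 800, tibble::tibble(
    t_hr = t_hr, tip_position_um = pos, tip_area_um2 = area))
  gr <- measure_regrowth(tc, init_time_abs_hr = 4)
  expect_equal(gr$regen_length_um, 60)
  expect_equal(gr$gc_area_um2, 12)
})

test_that("the 70 um short/long boundary is inclusive on the long side", {
  rec <- tibble::tibble(cell_id = c("a", "b", "c"),
                        axotomy_um = c(800, 800, 400),
                        retraction_um = c(69.9, 70, 100),
                        outcome = c("none", "regeneration", "ectopic"),
                        excluded = FALSE)
  out <- categorize_record(rec, proximal_cut_um = 500)
  expect_identical(out$retraction_class, c("short", "long", "long"))
  expect_equal(out$log10_retraction[3], 2)
  expect_identical(out$axotomy_class, c("distal", "distal", "proximal"))
  expect_identical(out$overall_regenerated, c(FALSE, TRUE, TRUE))
})

test_that("non-positive retraction is flagged and log10 left undefined", {
  rec <- tibble::tibble(cell_id = "x", axotomy_um = 800,
                        retraction_um = -3, outcome = "none",
                        excluded = FALSE)
  expect_warning(out <- categorize_record(rec), "non-positive")
  expect_true(is.na(out$log10_retraction))
})

test_that("noise-free cohort scoring is a closed loop", {
  co <- gen_axotomy_cohort(120, seed = 21)
  n_ok <- 0
  for (i in seq_along(co$cells)) {
    tr <- co$truth[i, ]
    rec <- suppressWarnings(analyze_timecourse(
      co$cells[[i]],
      branch_points_um = if (tr$outcome == "branch_loss") {
        co$cells[[i]]$axotomy_um * 0.4
      }))
    got <- if (rec$initial_response != "bulb_formation") {
      rec$initial_response
    } else {
      switch(rec$outcome, regeneration = "regeneration",
             ectopic = "ectopic", none = "no_regeneration", "excluded")
    }
    if (got == tr$outcome) n_ok <- n_ok + 1
    if (tr$outcome %in% c("regeneration", "ectopic", "no_regeneration")) {
      expect_equal(rec$retraction_um, tr$retraction_um, tolerance = 1e-9)
      expect_equal(rec$bulb_time_hr, tr$bulb_time_hr, tolerance = 1e-9)
    }
    if (tr$outcome == "regeneration") {
      expect_equal(rec$init_time_hr, tr$init_delay_hr, tolerance = 1e-9)
      expect_equal(rec$regen_length_um, tr$regen_length_um,
                   tolerance = 1e-6)
      expect_equal(rec$gc_area_um2, tr$gc_area_um2, tolerance = 1e-9)
    }
  }
  expect_equal(n_ok, length(co$cells))
})

test_that("retraction recovery degrades gracefully under 5 um noise", {
  co <- gen_axotomy_cohort(100, noise_sd_um = 5, seed = 22)
  errs <- c()
  for (i in seq_along(co$cells)) {
    tr <- co$truth[i, ]
    if (!tr$outcome %in% c("regeneration", "ectopic", "no_regeneration")) {
      next
    }
    rec <- suppressWarnings(analyze_timecourse(co$cells[[i]]))
    if (!is.na(rec$retraction_um)) {
      errs <- c(errs, abs(rec$retraction_um - tr$retraction_um))
    }
  }
  expect_gt(length(errs), 50)
  expect_lt(mean(errs), 10)
})

test_that("elongation rate is recovered by regression under noise", {
  rates <- c()
  for (s in 1:40) {
    sim <- gen_axotomy_timecourse("regeneration", elong_um_hr = 45,
                                  retraction_um = 150, init_delay_hr = 1.5,
                                  noise_sd_um = 5, seed = 400 + s)
    rec <- suppressWarnings(analyze_timecourse(sim$tc,
                                               step_tolerance_um = 5))
    if (rec$outcome != "regeneration") next
    fr <- sim$tc$frames
    t0 <- rec$bulb_time_hr + rec$init_time_hr
    sel <- fr$t_hr >= t0 + 0.5 & fr$t_hr <= t0 + 2.5
    fit <- lm(tip_position_um ~ t_hr, data = fr[sel, ])
    rates <- c(rates, unname(coef(fit)[2]))
  }
  expect_gt(length(rates), 30)
  expect_lt(abs(mean(rates) - 45) / 45, 0.1)
})

test_that("cohort summary computes the regeneration ratio over bulbs", {
  co <- gen_axotomy_cohort(10, outcome_fractions = c(
    death = 0, branch_loss = 0, regeneration = 0.6, ectopic = 0.1,
    no_regeneration = 0.3), div = 4, seed = 30)
  recs <- dplyr::bind_rows(lapply(co$cells, analyze_timecourse))
  recs <- categorize_record(recs)
  s <- summarize_cohort(recs, group_vars = "div")
  expect_equal(s$summary$n_bulb, 10L)
  expect_equal(s$summary$regeneration_ratio, 0.7)
  expect_null(s$ratio_tests)  # single group: descriptives only
})

test_that("initial-response classes partition every cell", {
  co <- gen_axotomy_cohort(60, seed = 31)
  recs <- dplyr::bind_rows(lapply(seq_along(co$cells), function(i) {
    suppressWarnings(analyze_timecourse(
      co$cells[[i]],
      branch_points_um = if (co$truth$outcome[i] == "branch_loss") {
        co$cells[[i]]$axotomy_um * 0.4
      }))
  }))
  expect_true(all(recs$initial_response %in%
                    c("death", "branch_loss", "bulb_formation")))
  bulbs <- recs[recs$initial_response == "bulb_formation", ]
  expect_true(all(bulbs$outcome %in%
                    c("regeneration", "ectopic", "none", "excluded")))
})
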