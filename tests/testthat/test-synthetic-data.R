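# Generators: determinism, planted-structure guarantees, argument checks.

test_that("generators are pure functions of their seed", {
  a <- gen_voltage_trace(3, noise_sd = 0.3, seed = 11)
  b <- gen_voltage_trace(3, noise_sd = 0.3, seed = 11)
  expect_identical(a$trace$vm_mv, b$trace$vm_mv)
  expect_identical(a$truth$spike_onset_ms, b$truth$spike_onset_ms)

  a <- gen_vesicle_tracks(25, noise_sd_um = 0.1, seed = 4)
  b <- gen_vesicle_tracks(25, noise_sd_um = 0.1, seed = 4)
  expect_identical(a$tracks, b$tracks)

  a <- gen_axotomy_timecourse("regeneration", seed = 6, noise_sd_um = 3)
  b <- gen_axotomy_timecourse("regeneration", seed = 6, noise_sd_um = 3)
  expect_identical(a$tc$frames, b$tc$frames)

  a <- gen_expression_matrix(40, 5, 5, seed = 9)
  b <- gen_expression_matrix(40, 5, 5, seed = 9)
  expect_identical(a$fpkm, b$fpkm)

  a <- gen_intensity_profiles(noise_sd = 0.05, seed = 2)
  b <- gen_intensity_profiles(noise_sd = 0.05, seed = 2)
  expect_identical(a$profiles, b$profiles)
})

test_that("voltage generator plants what it promises", {
  flat <- gen_voltage_trace(0, noise_sd = 0, resting_mv = -58, seed = 1)
  # no events planted: trace only carries the passive step response
  expect_length(flat$truth$spike_onset_ms, 0)
  base <- flat$trace$vm_mv[flat$trace$t_ms < 200]
  expect_true(all(abs(base - (-58)) < 1e-9))

  sim <- gen_voltage_trace(3, seed = 1)
  expect_length(sim$truth$spike_onset_ms, 3)
  resp <- sim$trace$protocol[which.max(sim$trace$protocol$amplitude_pa), ]
  expect_true(all(sim$truth$spike_onset_ms > resp$onset_ms &
                    sim$truth$spike_onset_ms <
                      resp$onset_ms + resp$duration_ms))
  expect_true(all(sim$truth$spike_peak_mv > 0))

  expect_error(gen_voltage_trace(3, sampling_khz = 5), "sampling")
  expect_error(gen_voltage_trace(2, spike_half_width_ms = 0.2,
                                 sampling_khz = 10), "coarse")
  expect_error(gen_voltage_trace(1, distractor_peak_mv = -5,
                                 n_distractors = 1), "-10 mV")
})

test_that("vesicle class counts follow largest-remainder allocation", {
  sim <- gen_vesicle_tracks(10, fractions = c(anterograde = 0.2,
                                              retrograde = 0.6,
                                              bidirectional = 0.1,
                                              stationary = 0.1), seed = 7)
  tab <- table(sim$truth$class)
  expect_equal(unname(tab[c("retrograde", "anterograde", "bidirectional",
                            "stationary")]), c(6L, 2L, 1L, 1L),
               ignore_attr = TRUE)
  expect_error(gen_vesicle_tracks(10, fractions = c(anterograde = 0.5,
                                                    retrograde = 0.4,
                                                    bidirectional = 0.2,
                                                    stationary = 0.1)),
               "sum to 1")
})

test_that("planted stationary tracks never exceed the 2 um rule", {
  sim <- gen_vesicle_tracks(40, fractions = c(anterograde = 0,
                                              retrograde = 0,
                                              bidirectional = 0,
                                              stationary = 1), seed = 3)
  for (d in split(sim$tracks, sim$tracks$track_id)) {
    expect_lt(diff(range(d$position_um)), 2)
  }
})

test_that("each track is 181 samples at 1 Hz inside the region", {
  sim <- gen_vesicle_tracks(30, seed = 12)
  for (d in split(sim$tracks, sim$tracks$track_id)) {
    expect_identical(d$t_s, 0:180)
    expect_true(all(d$position_um >= -1 & d$position_um <= 31))
  }
})

test_that("kymograph rendering geometry follows the pixel size", {
  still <- tibble::tibble(track_id = 1L, t_s = 0:180, position_um = 14.3,
                          compartment = "axon")
  img <- render_kymograph(still, pixel_um = 0.2, snr = Inf)
  expect_equal(dim(img), c(181L, 150L))
  # a fixed vesicle paints one constant-column bright ridge
  peaks <- apply(img, 1, which.max)
  expect_lte(diff(range(peaks)), 0)
  expect_true(all(img >= 0))
})

test_that("axotomy generator validates its parameters", {
  expect_error(gen_axotomy_timecourse("regeneration", axotomy_um = 400,
                                      retraction_um = 500),
               "retraction")
  expect_error(gen_axotomy_timecourse("regeneration", axotomy_um = 100),
               "axotomy_um")
  expect_error(gen_axotomy_timecourse("branch_loss"), "branch_points")
})

test_that("axotomy frame spacing honours the 20-30 min protocol", {
  sim <- gen_axotomy_timecourse("no_regeneration", seed = 8)
  dt_min <- diff(sim$tc$frames$t_hr) * 60
  expect_true(all(dt_min >= 20 & dt_min <= 30))
  expect_gte(max(sim$tc$frames$t_hr), 10)
})

test_that("planted log10 retraction mixture is normal per component", {
  # distributional check: each component passes Shapiro at alpha = 0.01
  # in nearly all seeds
  ok <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    co <- gen_axotomy_cohort(60, outcome_fractions = c(
      death = 0, branch_loss = 0, regeneration = 0.5, ectopic = 0,
      no_regeneration = 0.5), seed = 500 + s)
    x <- co$truth$log10_retraction
    comp1 <- x[x < 1.85]
    comp2 <- x[x >= 1.85]
    p1 <- if (length(comp1) >= 3) shapiro.test(comp1)$p.value else 1
    p2 <- if (length(comp2) >= 3) shapiro.test(comp2)$p.value else 1
    if (p1 > 0.01 && p2 > 0.01) ok <- ok + 1
  }
  expect_gte(ok / n_seeds, 0.9)
})

test_that("flat genes at mean 2 are never called trending", {
  sim <- gen_expression_matrix(30, 0, 0, seed = 5)
  # force constant means of 2: rebuild a tiny matrix directly
  fpkm <- matrix(2, 10, nrow(sim$samples),
                 dimnames = list(sprintf("g%02d", 1:10),
                                 sim$samples$sample_id))
  calls <- classify_gene_trends(fpkm, sim$samples)
  expect_true(all(calls$class == "flat"))
})

test_that("expression generator rejects inconsistent plans", {
  expect_error(gen_expression_matrix(10, 8, 8), "exceed")
  expect_error(gen_expression_matrix(10, 2, 2, fold = 2), "fold")
})

test_that("profile generator enforces region support", {
  expect_error(gen_intensity_profiles(n_dendrites = 2), "3 dendrites")
  expect_error(gen_intensity_profiles(axon_length_um = 500), "850")
  expect_error(gen_intensity_profiles(dendrite_length_um = 50), "100")
})
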