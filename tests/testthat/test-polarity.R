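# Background-corrected intensities and polarity ratios.

test_that("corrected intensity subtracts the paired background", {
  p <- tibble::tibble(arclength_um = 0:100, intensity = 50)
  expect_equal(corrected_intensity(p, c(0, 100), background = 10), 40)
  dim_p <- tibble::tibble(arclength_um = 0:100, intensity = 8)
  expect_warning(v <- corrected_intensity(dim_p, c(0, 100), 10),
                 "negative")
  expect_equal(v, -2)
  short_p <- tibble::tibble(arclength_um = 0:300, intensity = 20)
  expect_error(corrected_intensity(short_p, c(350, 450), 10), "outside")
})

test_that("adding a constant to signal and background cancels", {
  p <- tibble::tibble(arclength_um = 0:100, intensity = 50)
  p2 <- p
  p2$intensity <- p2$intensity + 17
  expect_equal(corrected_intensity(p, c(0, 100), 10),
               corrected_intensity(p2, c(0, 100), 27))
})

test_that("dendrite signal averages the brightest three, axon windows map", {
  sim <- gen_intensity_profiles(axon_dendrite_ratio = 2, noise_sd = 0,
                                n_dendrites = 5, seed = 1)
  sg <- compute_compartment_signals(sim$profiles, sim$regions,
                                    sim$cell_body)
  # planted bright trio is 0.9/1.0/1.1 x dendrite level, mean exact
  expect_equal(sg$dendrite_signal, sim$truth$dendrite_signal)
  expect_equal(sg$axon_stem_signal, sim$truth$axon_stem_signal)
  expect_equal(sg$axon_400_signal / sg$axon_stem_signal,
               sim$truth$distal_400_over_stem)
  expect_equal(sg$axon_800_signal / sg$axon_stem_signal,
               sim$truth$distal_800_over_stem)
})

test_that("explicit brightest-three example: 30/25/20/5/2 averages 25", {
  mk <- function(id, lvl) tibble::tibble(
    cell_id = "c1", neurite_id = id, kind = "dendrite",
    arclength_um = 0:100, intensity = lvl + 10)
  ax <- tibble::tibble(cell_id = "c1", neurite_id = "axon", kind = "axon",
                       arclength_um = 0:900, intensity = 50 + 10)
  profs <- dplyr::bind_rows(ax, mk("d1", 30), mk("d2", 25), mk("d3", 20),
                            mk("d4", 5), mk("d5", 2))
  regions <- tibble::tibble(
    cell_id = "c1",
    region = c("axon_stem", "axon_400", "axon_800", "cell_body",
               paste0("dendrite_d", 1:5)),
    background = 10)
  sg <- compute_compartment_signals(profs, regions)
  expect_equal(sg$dendrite_signal, 25)
  expect_equal(sg$axon_stem_signal, 50)
})

test_that("brightest-three selection breaks ties toward the lowest id", {
  mk <- function(id, lvl) tibble::tibble(
    cell_id = "c1", neurite_id = id, kind = "dendrite",
    arclength_um = 0:100, intensity = lvl)
  ax <- tibble::tibble(cell_id = "c1", neurite_id = "axon", kind = "axon",
                       arclength_um = 0:900, intensity = 60)
  profs <- dplyr::bind_rows(ax, mk("d1", 20), mk("d2", 20), mk("d3", 20),
                            mk("d4", 20))
  regions <- tibble::tibble(
    cell_id = "c1",
    region = c("axon_stem", "axon_400", "axon_800", "cell_body",
               paste0("dendrite_d", 1:4)),
    background = 0)
  sg <- compute_compartment_signals(profs, regions)
  expect_equal(sg$dendrite_signal, 20)
  # permuting the rows must not change the result
  sg2 <- compute_compartment_signals(profs[rev(seq_len(nrow(profs))), ],
                                     regions)
  expect_equal(sg2$dendrite_signal, sg$dendrite_signal)
})

test_that("cells with wrong anatomy are rejected", {
  sim <- gen_intensity_profiles(seed = 1)
  two_axons <- sim$profiles
  extra <- two_axons[two_axons$kind == "axon", ]
  extra$neurite_id <- "axon2"
  expect_error(compute_compartment_signals(
    dplyr::bind_rows(two_axons, extra), sim$regions), "exactly 1 axon")
  few_dend <- sim$profiles[sim$profiles$neurite_id %in%
                             c("axon", "dend01", "dend02"), ]
  expect_error(compute_compartment_signals(few_dend, sim$regions),
               ">= 3 dendrites")
})

test_that("noise-free planted ratios are recovered exactly", {
  sim <- gen_intensity_profiles(axon_dendrite_ratio = 2, noise_sd = 0,
                                seed = 4)
  rt <- compute_polarity_ratios(
    compute_compartment_signals(sim$profiles, sim$regions, sim$cell_body))
  expect_equal(rt$axon_dendrite_ratio, 2)
  expect_equal(rt$distal_400_over_stem, sim$truth$distal_400_over_stem)
})

test_that("ratios are invariant to a positive global intensity scale", {
  sim <- gen_intensity_profiles(axon_dendrite_ratio = 0.5, noise_sd = 0,
                                seed = 5)
  rt1 <- compute_polarity_ratios(
    compute_compartment_signals(sim$profiles, sim$regions, sim$cell_body))
  scaled <- sim$profiles
  scaled$intensity <- scaled$intensity * 3.7
  regions2 <- sim$regions
  regions2$background <- regions2$background * 3.7
  cb2 <- sim$cell_body
  cb2$intensity <- cb2$intensity * 3.7
  rt2 <- compute_polarity_ratios(
    compute_compartment_signals(scaled, regions2, cb2))
  expect_equal(rt2$axon_dendrite_ratio, rt1$axon_dendrite_ratio)
  expect_equal(rt2$axon_cell_body_ratio, rt1$axon_cell_body_ratio)
})

test_that("a zero denominator yields a flagged undefined ratio", {
  sg <- tibble::tibble(cell_id = "c1", axon_stem_signal = 0,
                       dendrite_signal = 20, cell_body_signal = 50,
                       axon_400_signal = 10, axon_800_signal = 5)
  w <- capture_warnings(rt <- compute_polarity_ratios(sg))
  expect_match(w, "undefined", all = FALSE)
  expect_true(is.na(rt$distal_400_over_stem))
  expect_equal(rt$axon_dendrite_ratio, 0)
})

test_that("a mature-like exclusion ratio is recovered under noise", {
  sim <- gen_intensity_profiles(axon_dendrite_ratio = 0.25,
                                noise_sd = 0.05, n_cells = 50, seed = 6)
  rt <- compute_polarity_ratios(
    compute_compartment_signals(sim$profiles, sim$regions, sim$cell_body))
  m <- mean(rt$axon_dendrite_ratio)
  expect_gte(m, 0.22)
  expect_lte(m, 0.28)
})
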