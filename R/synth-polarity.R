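# Synthetic neurite fluorescence profiles with a planted polarity ratio.

#' Generate neurite intensity profiles with planted polarity
#'
#' Builds one axon profile (>= 900 um) and `n_dendrites` dendrite
#' profiles for each of `n_cells` cells, sampled at 1 um arclength
#' steps, with a paired background value per measured region. The
#' corrected axon-stem signal is planted at `axon_dendrite_ratio` times
#' the corrected dendrite signal; the dendrite signal is the mean of the
#' brightest three dendrites, which are planted at 0.9 / 1.0 / 1.1 times
#' `dendrite_level` so their mean is exact. Extra dendrites are dim, so
#' brightest-three selection is exercised. Distal axon windows decay to
#' `distal_400_frac` and `distal_800_frac` of the stem signal.
#'
#' @param axon_dendrite_ratio Planted corrected axon-stem / dendrite
#'   signal ratio.
#' @param background Background intensity added to every region (a.u.).
#' @param noise_sd Pixelwise noise sd as a fraction of the local signal.
#' @param n_dendrites Dendrites per cell (>= 3).
#' @param n_cells Number of cells.
#' @param dendrite_level Corrected dendrite signal (a.u.).
#' @param cell_body_level Corrected cell-body signal (a.u.).
#' @param distal_400_frac,distal_800_frac Distal window fractions of the
#'   stem signal.
#' @param axon_length_um,dendrite_length_um Profile lengths (um); the
#'   axon must support the 750-850 um window.
#' @param seed Integer seed.
#'
#' @return A list with `profiles` (tibble: `cell_id`, `neurite_id`,
#'   `kind`, `arclength_um`, `intensity`), `regions` (tibble: `cell_id`,
#'   `region`, `background`), `cell_body` (tibble: `cell_id`,
#'   `intensity`), and `truth` (planted signals and ratios per cell).
#' @export
gen_intensity_profiles <- function(axon_dendrite_ratio = 2,
                                   background = 10,
                                   noise_sd = 0,
                                   n_dendrites = 5,
                                   n_cells = 1,
                                   dendrite_level = 30,
                                   cell_body_level = 100,
                                   distal_400_frac = 0.6,
                                   distal_800_frac = 0.3,
                                   axon_length_um = 900,
                                   dendrite_length_um = 120,
                                   seed = 1) {
  if (n_dendrites < 3) abort("need at least 3 dendrites per cell")
  if (axon_length_um < 850) {
    abort("axon must reach 850 um to support the distal windows")
  }
  if (dendrite_length_um < 100) {
    abort("dendrites must reach 100 um to support the stem window")
  }
  stem <- axon_dendrite_ratio * dendrite_level
  with_seed(seed, {
    profs <- list()
    regions <- list()
    truth <- list()
    cbod <- list()
    for (c_i in seq_len(n_cells)) {
      cid <- sprintf("cell%03d", c_i)
      x_ax <- 0:axon_length_um
      # axon: plateaus over the measured windows (0-100, 350-450, 750-850)
      # so the planted window means are exact; linear tapers in between
      lvl <- approx(c(0, 100, 350, 450, 750, 850, axon_length_um),
                    stem * c(1, 1, distal_400_frac, distal_400_frac,
                             distal_800_frac, distal_800_frac,
                             distal_800_frac),
                    xout = x_ax)$y
      add_noise <- function(v) {
        if (noise_sd > 0) v * (1 + rnorm(length(v), 0, noise_sd)) else v
      }
      profs[[length(profs) + 1]] <- tibble::tibble(
        cell_id = cid, neurite_id = "axon", kind = "axon",
        arclength_um = x_ax, intensity = add_noise(lvl + background)
      )
      bright <- dendrite_level * c(0.9, 1.0, 1.1)
      dim_lvls <- if (n_dendrites > 3) {
        dendrite_level * runif(n_dendrites - 3, 0.1, 0.5)
      } else numeric(0)
      dlv <- c(bright, dim_lvls)
      x_d <- 0:dendrite_length_um
      for (d_i in seq_len(n_dendrites)) {
        profs[[length(profs) + 1]] <- tibble::tibble(
          cell_id = cid, neurite_id = sprintf("dend%02d", d_i),
          kind = "dendrite", arclength_um = x_d,
          intensity = add_noise(rep(dlv[d_i] + background, length(x_d)))
        )
      }
      region_names <- c("axon_stem", "axon_400", "axon_800", "cell_body",
                        sprintf("dendrite_dend%02d", seq_len(n_dendrites)))
      regions[[length(regions) + 1]] <- tibble::tibble(
        cell_id = cid, region = region_names, background = background
      )
      cb_raw <- cell_body_level + background
      if (noise_sd > 0) cb_raw <- cb_raw * (1 + rnorm(1, 0, noise_sd / 10))
      cbod[[length(cbod) + 1]] <- tibble::tibble(cell_id = cid,
                                                 intensity = cb_raw)
      truth[[length(truth) + 1]] <- tibble::tibble(
        cell_id = cid,
        axon_stem_signal = stem,
        dendrite_signal = dendrite_level,
        cell_body_signal = cell_body_level,
        axon_dendrite_ratio = axon_dendrite_ratio,
        distal_400_over_stem = distal_400_frac,
        distal_800_over_stem = distal_800_frac
      )
    }
    list(profiles = dplyr::bind_rows(profs),
         regions = dplyr::bind_rows(regions),
         cell_body = dplyr::bind_rows(cbod),
         truth = dplyr::bind_rows(truth))
  })
}
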