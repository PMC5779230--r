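# Synthetic vesicle tracks and rendered kymographs with planted classes.

#' Generate vesicle tracks with planted transport classes
#'
#' Simulates vesicle positions along a neurite at one position per second
#' for 3 minutes (181 samples) inside a 30 um imaging region, with planted
#' anterograde / retrograde / bidirectional / stationary behaviour.
#' Positive positions point away from the soma. Class counts follow
#' largest-remainder rounding of `fractions`, so small cohorts are exact
#' and reproducible. Directed tracks contain at least one monotone run of
#' more than 2 um in their class direction only; bidirectional tracks run
#' more than 2 um both ways; stationary tracks never accumulate 2 um of
#' monotone displacement. A vesicle that reaches the region boundary
#' parks there (as a real vesicle would leave the focal strip).
#'
#' @param n_tracks Number of tracks.
#' @param fractions Named probabilities for classes `anterograde`,
#'   `retrograde`, `bidirectional`, `stationary`; must sum to 1.
#' @param speed_um_s Range (length-2) of per-track run speeds, um/s.
#' @param pause_prob Per-second probability that a moving vesicle pauses.
#' @param noise_sd_um Positional measurement noise sd (um), iid per sample.
#' @param region_um Length of the imaged region (um).
#' @param seed Integer seed.
#' @param compartment Compartment label stored on every track.
#' @param lanes If `TRUE`, confine each track to its own non-overlapping
#'   spatial lane (useful for testing kymograph tracing without track
#'   crossings); classes are still planted but run lengths are capped at
#'   the lane width.
#'
#' @return A list with `tracks`, a tibble (`track_id`, `t_s`,
#'   `position_um`, `compartment`), and `truth`, a tibble (`track_id`,
#'   `class`, `speed_um_s`).
#' @export
#' @examples
#' sim <- gen_vesicle_tracks(10, fractions = c(anterograde = 0.2,
#'   retrograde = 0.6, bidirectional = 0.1, stationary = 0.1), seed = 7)
#' table(sim$truth$class)
gen_vesicle_tracks <- function(n_tracks,
                               fractions = c(anterograde = 0.25,
                                             retrograde = 0.25,
                                             bidirectional = 0.25,
                                             stationary = 0.25),
                               speed_um_s = c(0.3, 1.0),
                               pause_prob = 0.3,
                               noise_sd_um = 0,
                               region_um = 30,
                               seed = 1,
                               compartment = "axon",
                               lanes = FALSE) {
  n_tracks <- assert_count(n_tracks, "n_tracks", lower = 1)
  want <- c("anterograde", "retrograde", "bidirectional", "stationary")
  if (!setequal(names(fractions), want)) {
    abort("`fractions` must be named anterograde/retrograde/bidirectional/stationary")
  }
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  if (any(speed_um_s <= 0)) abort("speeds must be positive")
  counts <- largest_remainder(n_tracks, fractions[want])
  classes <- rep(names(counts), counts)
  t_s <- 0:180

  lane_w <- region_um / n_tracks
  with_seed(seed, {
    tracks <- vector("list", n_tracks)
    speeds <- numeric(n_tracks)
    for (k in seq_len(n_tracks)) {
      cls <- classes[k]
      v <- runif(1, speed_um_s[1], speed_um_s[2])
      speeds[k] <- v
      if (lanes) {
        lo <- (k - 1) * lane_w + 0.25 * lane_w
        hi <- k * lane_w - 0.25 * lane_w
        max_run <- hi - lo
      } else {
        lo <- 0.5
        hi <- region_um - 0.5
        max_run <- Inf
      }
      pos <- switch(
        cls,
        anterograde = sim_directed(t_s, +1, v, pause_prob, lo, hi),
        retrograde = sim_directed(t_s, -1, v, pause_prob, lo, hi),
        bidirectional = sim_bidirectional(t_s, v, pause_prob, lo, hi,
                                          max_run),
        stationary = sim_stationary(t_s, lo, hi)
      )
      if (noise_sd_um > 0) pos <- pos + rnorm(length(pos), 0, noise_sd_um)
      tracks[[k]] <- tibble::tibble(
        track_id = k, t_s = t_s, position_um = pos,
        compartment = compartment
      )
    }
    list(
      tracks = dplyr::bind_rows(tracks),
      truth = tibble::tibble(track_id = seq_len(n_tracks),
                             class = classes, speed_um_s = speeds)
    )
  })
}

# Monotone mover with pauses; parks at the region/lane boundary.
sim_directed <- function(t_s, sign, v, pause_prob, lo, hi) {
  n <- length(t_s)
  start <- if (sign > 0) runif(1, lo, lo + 0.25 * (hi - lo)) else
    runif(1, hi - 0.25 * (hi - lo), hi)
  moving <- runif(n - 1) > pause_prob
  step <- ifelse(moving, sign * v, 0)
  pos <- start + c(0, cumsum(step))
  pmin(pmax(pos, lo), hi)
}

# Alternating runs of 3-6 um (capped at the lane width) in both directions.
sim_bidirectional <- function(t_s, v, pause_prob, lo, hi, max_run) {
  n <- length(t_s)
  pos <- numeric(n)
  pos[1] <- runif(1, lo + 0.35 * (hi - lo), hi - 0.35 * (hi - lo))
  dir <- sample(c(-1, 1), 1)
  run_target <- min(runif(1, 3, 6), max_run * 0.9)
  run_done <- 0
  for (i in 2:n) {
    step <- if (runif(1) > pause_prob) dir * v else 0
    nxt <- pos[i - 1] + step
    if (nxt > hi || nxt < lo || run_done + abs(step) >= run_target) {
      dir <- -dir
      run_target <- min(runif(1, 3, 6), max_run * 0.9)
      run_done <- 0
      step <- 0
      nxt <- pos[i - 1]
    }
    run_done <- run_done + abs(step)
    pos[i] <- nxt
  }
  pos
}

# Smooth sub-2 um oscillation: never accumulates a 2 um monotone run.
sim_stationary <- function(t_s, lo, hi) {
  m <- min(0.8, 0.3 * (hi - lo))
  centre <- runif(1, lo + m, hi - m)
  amp <- runif(1, 0.15, min(0.6, m))
  period <- runif(1, 40, 90)
  phase <- runif(1, 0, 2 * pi)
  centre + amp * sin(2 * pi * t_s / period + phase)
}

#' Render vesicle tracks into a kymograph image
#'
#' Produces the 2-D image a line-scan kymograph gives: one row per frame
#' (181 frames at 1 s), one column per `pixel_um` of the 30 um region.
#' Each vesicle contributes a Gaussian spot of width `psf_sigma_px` per
#' row; additive Gaussian noise with sd `amplitude / snr` models shot and
#' camera noise.
#'
#' @param tracks Track tibble from [gen_vesicle_tracks()].
#' @param pixel_um Pixel size (um); image width is `ceiling(30 / pixel_um)`.
#' @param psf_sigma_px Spot standard deviation in pixels.
#' @param snr Peak amplitude over noise sd; `Inf` for a noise-free image.
#' @param seed Integer seed for the noise.
#' @param amplitude Peak spot intensity (arbitrary units).
#' @param region_um Imaged region length (um).
#'
#' @return A `kymograph_image`: numeric matrix (frames x pixels) with
#'   attributes `pixel_um` and `frame_interval_s`.
#' @export
render_kymograph <- function(tracks, pixel_um = 0.2, psf_sigma_px = 1.5,
                             snr = 10, seed = 1, amplitude = 1,
                             region_um = 30) {
  assert_scalar_num(pixel_um, "pixel_um", lower = 1e-6)
  frames <- sort(unique(tracks$t_s))
  n_row <- length(frames)
  n_col <- ceiling(region_um / pixel_um)
  img <- matrix(0, n_row, n_col)
  cols <- seq_len(n_col)
  for (r in seq_len(n_row)) {
    rows <- tracks[tracks$t_s == frames[r], ]
    for (x in rows$position_um) {
      cc <- x / pixel_um + 0.5  # pixel j covers [(j-1), j) * pixel_um
      lo <- max(1, floor(cc - 4 * psf_sigma_px))
      hi <- min(n_col, ceiling(cc + 4 * psf_sigma_px))
      if (lo > hi) next
      j <- lo:hi
      img[r, j] <- img[r, j] +
        amplitude * exp(-(j - cc)^2 / (2 * psf_sigma_px^2))
    }
  }
  if (is.finite(snr)) {
    with_seed(seed, {
      img <- img + matrix(rnorm(length(img), 0, amplitude / snr),
                          n_row, n_col)
    })
  }
  img[img < 0] <- 0
  structure(img, pixel_um = pixel_um, frame_interval_s = 1,
            class = c("kymograph_image", "matrix", "array"))
}
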