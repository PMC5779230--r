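# Kymograph tracing, movement segmentation under the 2 um rule, and
# per-cell transport summaries.
#
# A vesicle moving only in one direction for more than 2 um is anterograde
# (away from the soma) or retrograde (towards it); one moving both ways
# over 2 um is bidirectional; anything else is reported as stationary so
# direction fractions sum to 1.

#' Trace vesicle tracks from a kymograph image
#'
#' Deliberately simple tracker for kymographs whose rows are frames and
#' columns are positions: per-row local maxima above `min_intensity` are
#' located with sub-pixel parabolic refinement, then linked frame-to-frame
#' to the nearest active track within `max_step_px`, bridging gaps of up
#' to `max_gap_frames` frames. Where two tracks compete for one peak the
#' nearer wins and the other is split rather than guessed. Tracks shorter
#' than `min_duration_s` are discarded.
#'
#' @param image A `kymograph_image` from [render_kymograph()] or
#'   [read_kymograph_tiff()].
#' @param min_intensity Detection threshold (same units as the image).
#' @param max_step_px Largest allowed frame-to-frame jump, in pixels per
#'   elapsed frame.
#' @param max_gap_frames Frames a track may go undetected before closing.
#' @param min_duration_s Minimum track duration to keep (s).
#' @param min_separation_px Peaks closer than this are merged into the
#'   strongest one (suppresses noise-split twin maxima).
#' @param compartment Compartment label attached to the traced tracks.
#'
#' @return A tibble (`track_id`, `t_s`, `position_um`, `compartment`).
#' @export
trace_tracks <- function(image, min_intensity = 0.5, max_step_px = 6,
                         max_gap_frames = 2, min_duration_s = 10,
                         min_separation_px = 3, compartment = "axon") {
  stopifnot(is.matrix(image))
  pixel_um <- attr(image, "pixel_um") %||% 1
  dt_s <- attr(image, "frame_interval_s") %||% 1
  n_row <- nrow(image)
  n_col <- ncol(image)
  empty <- tibble::tibble(track_id = integer(0), t_s = numeric(0),
                          position_um = numeric(0),
                          compartment = character(0))
  if (n_row < 1 || n_col < 3) return(empty)

  active <- list()   # each: list(cols, frames, last_col, last_frame)
  closed <- list()
  for (r in seq_len(n_row)) {
    v <- image[r, ]
    j <- 2:(n_col - 1)
    is_pk <- v[j] > v[j - 1] & v[j] >= v[j + 1] & v[j] > min_intensity
    pk <- j[is_pk]
    if (length(pk) > 1) {
      # non-maximum suppression: strongest peak wins within min_separation
      ord <- pk[order(v[pk], decreasing = TRUE)]
      keep <- numeric(0)
      for (q in ord) {
        if (all(abs(q - keep) >= min_separation_px)) keep <- c(keep, q)
      }
      pk <- sort(keep)
    }
    # parabolic sub-pixel refinement
    if (length(pk) > 0) {
      denom <- v[pk - 1] - 2 * v[pk] + v[pk + 1]
      dx <- ifelse(abs(denom) > 1e-12,
                   0.5 * (v[pk - 1] - v[pk + 1]) / denom, 0)
      dx[abs(dx) > 1] <- 0
      pk_pos <- pk + dx
    } else {
      pk_pos <- numeric(0)
    }

    taken <- rep(FALSE, length(pk_pos))
    if (length(active) > 0 && length(pk_pos) > 0) {
      # greedy nearest-neighbour assignment, closest pairs first
      cand <- expand.grid(a = seq_along(active), p = seq_along(pk_pos))
      cand$gap <- vapply(cand$a, function(a) r - active[[a]]$last_frame,
                         numeric(1))
      cand$d <- abs(vapply(cand$a, function(a) active[[a]]$last_col,
                           numeric(1)) - pk_pos[cand$p])
      cand <- cand[cand$d <= max_step_px * cand$gap, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      used_a <- rep(FALSE, length(active))
      for (i in seq_len(nrow(cand))) {
        a <- cand$a[i]; p <- cand$p[i]
        if (used_a[a] || taken[p]) next
        used_a[a] <- TRUE
        taken[p] <- TRUE
        active[[a]]$cols <- c(active[[a]]$cols, pk_pos[p])
        active[[a]]$frames <- c(active[[a]]$frames, r)
        active[[a]]$last_col <- pk_pos[p]
        active[[a]]$last_frame <- r
      }
    }
    for (p in which(!taken)) {
      active[[length(active) + 1]] <- list(cols = pk_pos[p], frames = r,
                                           last_col = pk_pos[p],
                                           last_frame = r)
    }
    stale <- vapply(active, function(a) r - a$last_frame > max_gap_frames,
                    logical(1))
    closed <- c(closed, active[stale])
    active <- active[!stale]
  }
  closed <- c(closed, active)

  keep <- Filter(function(a) {
    (max(a$frames) - min(a$frames)) * dt_s >= min_duration_s
  }, closed)
  if (length(keep) == 0) return(empty)
  dplyr::bind_rows(lapply(seq_along(keep), function(k) {
    a <- keep[[k]]
    tibble::tibble(
      track_id = k,
      t_s = (a$frames - 1) * dt_s,
      position_um = (a$cols - 0.5) * pixel_um,
      compartment = compartment
    )
  }))
}

#' Segment a track into directional movements
#'
#' Partitions one vesicle track into maximal monotone runs, ignoring
#' reversals smaller than `reversal_tolerance_um` (manual kymograph
#' reading tolerates small wiggles). Runs whose net displacement exceeds
#' the `min_displacement_um` rule become movements with a direction and a
#' speed (net displacement over run duration).
#'
#' @param track Tibble with `t_s` and `position_um` for a single track
#'   (positions increase away from the soma).
#' @param reversal_tolerance_um Reversals smaller than this do not end a
#'   run (um).
#' @param min_displacement_um The displacement rule (um).
#' @param strict If `TRUE` (default) a run must exceed the rule strictly
#'   ("more than 2 um"); if `FALSE` the boundary case counts.
#'
#' @return A tibble of movements: `start_s`, `end_s`, `direction`
#'   (anterograde/retrograde), `net_displacement_um`, `speed_um_s`.
#' @export
#' @examples
#' tr <- tibble::tibble(t_s = 0:10, position_um = seq(0, 5, by = 0.5))
#' segment_movements(tr)
segment_movements <- function(track, reversal_tolerance_um = 0.2,
                              min_displacement_um = 2, strict = TRUE) {
  p <- track$position_um
  t <- track$t_s
  n <- length(p)
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          direction = character(0),
                          net_displacement_um = numeric(0),
                          speed_um_s = numeric(0))
  if (n < 2) return(empty)
  tol <- reversal_tolerance_um

  runs <- list()
  close_run <- function(i_start, i_end) {
    net <- p[i_end] - p[i_start]
    keep <- if (strict) abs(net) > min_displacement_um else
      abs(net) >= min_displacement_um
    if (keep && t[i_end] > t[i_start]) {
      runs[[length(runs) + 1]] <<- tibble::tibble(
        start_s = t[i_start], end_s = t[i_end],
        direction = if (net > 0) "anterograde" else "retrograde",
        net_displacement_um = net,
        speed_um_s = abs(net) / (t[i_end] - t[i_start])
      )
    }
  }

  dir <- 0L
  i_min <- 1L; i_max <- 1L  # extremes since the current run started
  start <- 1L
  for (i in 2:n) {
    if (p[i] < p[i_min]) i_min <- i
    if (p[i] > p[i_max]) i_max <- i
    if (dir == 0L) {
      up <- p[i] - p[i_min] >= tol
      dn <- p[i_max] - p[i] >= tol
      if (up && dn) {
        # both already exceeded: the earlier extreme starts the first run
        dir <- if (i_min < i_max) 1L else -1L
      } else if (up) dir <- 1L else if (dn) dir <- -1L
      if (dir == 1L) {
        start <- i_min; i_max <- i
      } else if (dir == -1L) {
        start <- i_max; i_min <- i
      }
    } else if (dir == 1L) {
      if (p[i_max] - p[i] >= tol) {
        close_run(start, i_max)
        dir <- -1L
        start <- i_max
        i_min <- i
      }
    } else {
      if (p[i] - p[i_min] >= tol) {
        close_run(start, i_min)
        dir <- 1L
        start <- i_min
        i_max <- i
      }
    }
  }
  if (dir == 1L) close_run(start, i_max)
  if (dir == -1L) close_run(start, i_min)
  if (length(runs) == 0) return(empty)
  dplyr::bind_rows(runs)
}

#' Classify a track's transport direction
#'
#' Applies the displacement rule: anterograde if the track has at least
#' one anterograde movement and none retrograde; retrograde symmetric;
#' bidirectional if both; stationary if no movement exceeds the rule.
#'
#' @inheritParams segment_movements
#' @return One of `"anterograde"`, `"retrograde"`, `"bidirectional"`,
#'   `"stationary"`.
#' @export
classify_track <- function(track, reversal_tolerance_um = 0.2,
                           min_displacement_um = 2, strict = TRUE) {
  mv <- segment_movements(track, reversal_tolerance_um,
                          min_displacement_um, strict)
  has_a <- any(mv$direction == "anterograde")
  has_r <- any(mv$direction == "retrograde")
  if (has_a && has_r) "bidirectional"
  else if (has_a) "anterograde"
  else if (has_r) "retrograde"
  else "stationary"
}

#' Summarize a cell's vesicle transport
#'
#' Direction fractions over tracks, plus the cell's anterograde and
#' retrograde vesicle velocities: the speed of every movement of that
#' direction during the imaging period is collected across the cell's
#' tracks and averaged. A velocity is `NA` when the cell has no movement
#' in that direction.
#'
#' @param tracks Tibble with `track_id`, `t_s`, `position_um` (one or more
#'   tracks).
#' @inheritParams segment_movements
#' @return A one-row tibble: `n_tracks`, the four class fractions, and
#'   `velocity_anterograde_um_s` / `velocity_retrograde_um_s`.
#' @export
summarize_transport <- function(tracks, reversal_tolerance_um = 0.2,
                                min_displacement_um = 2, strict = TRUE) {
  if (nrow(tracks) == 0) abort("no tracks supplied")
  split_tracks <- split(tracks, tracks$track_id)
  mv <- dplyr::bind_rows(lapply(split_tracks, segment_movements,
                                reversal_tolerance_um = reversal_tolerance_um,
                                min_displacement_um = min_displacement_um,
                                strict = strict))
  cls <- vapply(split_tracks, classify_track, character(1),
                reversal_tolerance_um = reversal_tolerance_um,
                min_displacement_um = min_displacement_um, strict = strict)
  n <- length(split_tracks)
  frac <- function(x) sum(cls == x) / n
  vel <- function(d) {
    s <- mv$speed_um_s[mv$direction == d]
    if (length(s) == 0) NA_real_ else mean(s)
  }
  tibble::tibble(
    n_tracks = n,
    frac_anterograde = frac("anterograde"),
    frac_retrograde = frac("retrograde"),
    frac_bidirectional = frac("bidirectional"),
    frac_stationary = frac("stationary"),
    velocity_anterograde_um_s = vel("anterograde"),
    velocity_retrograde_um_s = vel("retrograde")
  )
}

#' Match traced tracks against planted ground truth
#'
#' Validation harness for the tracer. Each recovered track is assigned to
#' the planted track it matches best (smallest mean absolute position
#' error over common frames, required to be under `match_tol_um`); a
#' tracker hand-off that splits one vesicle into two clean fragments
#' therefore still scores as a recovery. A planted track counts as
#' recovered when its assigned fragments jointly cover at least
#' `min_overlap` of its frames.
#'
#' @param recovered Tibble from [trace_tracks()].
#' @param truth_tracks Tibble of planted tracks (`track_id`, `t_s`,
#'   `position_um`).
#' @param pixel_um Pixel size used to express the error in pixels.
#' @param min_overlap Minimum jointly covered fraction of planted frames.
#' @param match_tol_um Largest mean error (um) for a fragment to be
#'   assigned to a planted track.
#'
#' @return A tibble per planted track: `track_id`, `recovered`,
#'   `overlap_frac`, `mean_abs_error_um`, `mean_abs_error_px`.
#' @export
track_recovery <- function(recovered, truth_tracks, pixel_um = 0.2,
                           min_overlap = 0.8, match_tol_um = 1) {
  truth_split <- split(truth_tracks, truth_tracks$track_id)
  rec_split <- if (nrow(recovered) > 0) split(recovered, recovered$track_id)
  else list()

  # assign each recovered fragment to its best planted track
  assign_tbl <- lapply(rec_split, function(rr) {
    best <- list(id = NA, err = Inf, m = NULL)
    for (tt in truth_split) {
      m <- merge(tt[, c("t_s", "position_um")],
                 rr[, c("t_s", "position_um")], by = "t_s")
      if (nrow(m) < 2) next
      err <- mean(abs(m$position_um.x - m$position_um.y))
      if (err < best$err) best <- list(id = tt$track_id[1], err = err, m = m)
    }
    if (is.finite(best$err) && best$err <= match_tol_um) best else NULL
  })
  assign_tbl <- Filter(Negate(is.null), assign_tbl)

  rows <- lapply(truth_split, function(tt) {
    mine <- Filter(function(a) a$id == tt$track_id[1], assign_tbl)
    if (length(mine) == 0) {
      return(tibble::tibble(track_id = tt$track_id[1], recovered = FALSE,
                            overlap_frac = 0, mean_abs_error_um = NA_real_,
                            mean_abs_error_px = NA_real_))
    }
    frames <- unique(unlist(lapply(mine, function(a) a$m$t_s)))
    errs <- unlist(lapply(mine, function(a)
      abs(a$m$position_um.x - a$m$position_um.y)))
    ov <- length(frames) / nrow(tt)
    tibble::tibble(
      track_id = tt$track_id[1],
      recovered = ov >= min_overlap,
      overlap_frac = ov,
      mean_abs_error_um = mean(errs),
      mean_abs_error_px = mean(errs) / pixel_um
    )
  })
  dplyr::bind_rows(rows)
}
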