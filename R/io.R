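# Readers and writers for the package's plain-text interchange formats.
# Units are embedded in column names (t_ms, position_um, tip_position_um)
# to prevent silent unit errors. Readers validate the schema and report
# all row-level problems together.

validate_table <- function(df, numeric_cols, required_cols, key_cols = NULL,
                           what = "table") {
  problems <- character(0)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    problems <- c(problems, sprintf("%s: missing column(s) %s", what,
                                    paste(missing, collapse = ", ")))
  }
  for (cl in intersect(numeric_cols, names(df))) {
    bad <- which(!is.na(df[[cl]]) & !is.finite(suppressWarnings(
      as.numeric(df[[cl]]))))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "%s: non-numeric '%s' at row(s) %s", what, cl,
        paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (!is.null(key_cols) && all(key_cols %in% names(df))) {
    dup <- duplicated(df[key_cols])
    if (any(dup)) {
      problems <- c(problems, sprintf(
        "%s: duplicated (%s) at row(s) %s", what,
        paste(key_cols, collapse = ", "),
        paste(head(which(dup), 5), collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    abort(paste(problems, collapse = "\n"))
  }
  invisible(df)
}

read_csv_quiet <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read voltage traces and their protocols from tidy CSV
#'
#' @param traces_path CSV with `trace_id`, `t_ms`, `vm_mv`.
#' @param protocol_path CSV with `trace_id`, `onset_ms`, `duration_ms`,
#'   `amplitude_pa`, or `NULL` for spontaneous recordings.
#'
#' @return A named list of [voltage_trace()] objects.
#' @export
read_traces_csv <- function(traces_path, protocol_path = NULL) {
  tr <- read_csv_quiet(traces_path)
  validate_table(tr, c("t_ms", "vm_mv"), c("trace_id", "t_ms", "vm_mv"),
                 key_cols = c("trace_id", "t_ms"), what = traces_path)
  proto <- NULL
  if (!is.null(protocol_path)) {
    proto <- read_csv_quiet(protocol_path)
    validate_table(proto, c("onset_ms", "duration_ms", "amplitude_pa"),
                   c("trace_id", "onset_ms", "duration_ms", "amplitude_pa"),
                   what = protocol_path)
  }
  out <- lapply(split(tr, tr$trace_id), function(d) {
    d <- d[order(d$t_ms), ]
    dt <- median(diff(d$t_ms))
    p <- NULL
    if (!is.null(proto)) {
      p <- proto[proto$trace_id == d$trace_id[1], ]
      if (nrow(p) == 0) p <- NULL else p$step <- seq_len(nrow(p))
    }
    voltage_trace(d$t_ms, d$vm_mv, sampling_khz = 1 / dt, protocol = p)
  })
  out
}

#' Write voltage traces to tidy CSV
#'
#' @param traces Named list of [voltage_trace()] objects.
#' @param traces_path,protocol_path Output CSV paths.
#' @export
write_traces_csv <- function(traces, traces_path, protocol_path = NULL) {
  ids <- names(traces) %||% as.character(seq_along(traces))
  tr <- dplyr::bind_rows(lapply(seq_along(traces), function(i) {
    tibble::tibble(trace_id = ids[i], t_ms = traces[[i]]$t_ms,
                   vm_mv = traces[[i]]$vm_mv)
  }))
  readr::write_csv(tr, traces_path)
  if (!is.null(protocol_path)) {
    pr <- dplyr::bind_rows(lapply(seq_along(traces), function(i) {
      p <- traces[[i]]$protocol
      if (is.null(p)) return(NULL)
      tibble::tibble(trace_id = ids[i], onset_ms = p$onset_ms,
                     duration_ms = p$duration_ms,
                     amplitude_pa = p$amplitude_pa)
    }))
    readr::write_csv(pr, protocol_path)
  }
  invisible(traces_path)
}

#' Read vesicle tracks from CSV
#'
#' @param path CSV with `track_id`, `t_s`, `position_um` and optionally
#'   `compartment`.
#' @return A validated tibble.
#' @export
read_tracks_csv <- function(path) {
  d <- read_csv_quiet(path)
  validate_table(d, c("t_s", "position_um"),
                 c("track_id", "t_s", "position_um"),
                 key_cols = c("track_id", "t_s"), what = path)
  if (!"compartment" %in% names(d)) d$compartment <- "axon"
  d
}

#' Write a kymograph image as a single-page grayscale TIFF
#'
#' Intensities are scaled to the unit interval by the image maximum
#' before writing (32-bit float samples); [read_kymograph_tiff()]
#' restores metadata from its arguments.
#'
#' @param image A `kymograph_image`.
#' @param path Output TIFF path.
#' @export
write_kymograph_tiff <- function(image, path) {
  m <- unclass(image)
  attributes(m) <- list(dim = dim(image))
  mx <- max(m)
  if (mx > 0) m <- m / mx
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a kymograph TIFF
#'
#' @param path TIFF path (rows = frames, columns = positions).
#' @param pixel_um Pixel size (um).
#' @param frame_interval_s Frame interval (s).
#' @return A `kymograph_image`.
#' @export
read_kymograph_tiff <- function(path, pixel_um, frame_interval_s = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  structure(m, pixel_um = pixel_um, frame_interval_s = frame_interval_s,
            class = c("kymograph_image", "matrix", "array"))
}

#' Read an axotomy cohort from frames + metadata CSV
#'
#' @param frames_path CSV with `cell_id`, `t_hr`, `tip_position_um` and
#'   optionally `tip_area_um2`, `flag`, `flag_position_um`.
#' @param meta_path CSV with `cell_id`, `axotomy_um` and optionally
#'   `div`, `substrate`, `branch_points_um` (semicolon-separated).
#'
#' @return A list with `cells` (named list of [axotomy_timecourse()])
#'   and `branch_points` (named list of numeric vectors).
#' @export
read_axotomy_csv <- function(frames_path, meta_path) {
  fr <- read_csv_quiet(frames_path)
  validate_table(fr, c("t_hr", "tip_position_um"),
                 c("cell_id", "t_hr", "tip_position_um"),
                 key_cols = c("cell_id", "t_hr"), what = frames_path)
  meta <- read_csv_quiet(meta_path)
  validate_table(meta, "axotomy_um", c("cell_id", "axotomy_um"),
                 key_cols = "cell_id", what = meta_path)
  cells <- list()
  bps <- list()
  for (cid in meta$cell_id) {
    d <- fr[fr$cell_id == cid, ]
    if (nrow(d) == 0) abort(sprintf("no frames for cell %s", cid))
    mrow <- meta[meta$cell_id == cid, ]
    cells[[cid]] <- axotomy_timecourse(
      cell_id = cid, axotomy_um = mrow$axotomy_um,
      frames = d[order(d$t_hr), setdiff(names(d), "cell_id")],
      div = if ("div" %in% names(mrow)) mrow$div else NA,
      substrate = if ("substrate" %in% names(mrow)) mrow$substrate else NA
    )
    bps[[cid]] <- if ("branch_points_um" %in% names(mrow) &&
                      !is.na(mrow$branch_points_um)) {
      as.numeric(strsplit(as.character(mrow$branch_points_um), ";")[[1]])
    } else numeric(0)
  }
  list(cells = cells, branch_points = bps)
}

#' Write an axotomy cohort to frames + metadata CSV
#'
#' @param cells List of [axotomy_timecourse()] objects.
#' @param frames_path,meta_path Output CSV paths.
#' @param branch_points Optional named list of branch-point vectors.
#' @export
write_axotomy_csv <- function(cells, frames_path, meta_path,
                              branch_points = NULL) {
  fr <- dplyr::bind_rows(lapply(cells, function(tc) {
    dplyr::bind_cols(tibble::tibble(cell_id = tc$cell_id), tc$frames)
  }))
  readr::write_csv(fr, frames_path)
  meta <- dplyr::bind_rows(lapply(cells, function(tc) {
    bp <- branch_points[[tc$cell_id]]
    tibble::tibble(cell_id = tc$cell_id, axotomy_um = tc$axotomy_um,
                   div = tc$div, substrate = tc$substrate,
                   branch_points_um = if (length(bp) > 0) {
                     paste(bp, collapse = ";")
                   } else NA_character_)
  }))
  readr::write_csv(meta, meta_path)
  invisible(frames_path)
}

#' Read an FPKM matrix and its sample map
#'
#' @param fpkm_path CSV whose first column is `gene`, remaining columns
#'   one per sample.
#' @param samples_path CSV with `sample_id`, `div`, `replicate`.
#' @return A list with `fpkm` (matrix) and `samples` (tibble).
#' @export
read_fpkm_csv <- function(fpkm_path, samples_path) {
  d <- read_csv_quiet(fpkm_path)
  if (names(d)[1] != "gene") abort("first FPKM column must be `gene`")
  samples <- read_csv_quiet(samples_path)
  validate_table(samples, c("div", "replicate"),
                 c("sample_id", "div", "replicate"),
                 key_cols = "sample_id", what = samples_path)
  m <- as.matrix(d[, -1])
  rownames(m) <- d$gene
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("FPKM values must be finite and nonnegative")
  }
  list(fpkm = m, samples = samples)
}

#' Write an FPKM matrix and sample map
#'
#' @param fpkm Matrix genes x samples.
#' @param samples Sample-map tibble.
#' @param fpkm_path,samples_path Output CSV paths.
#' @export
write_fpkm_csv <- function(fpkm, samples, fpkm_path, samples_path) {
  d <- tibble::as_tibble(fpkm, rownames = "gene")
  readr::write_csv(d, fpkm_path)
  readr::write_csv(samples, samples_path)
  invisible(fpkm_path)
}

#' Read neurite intensity profiles and region backgrounds
#'
#' @param profiles_path CSV with `cell_id`, `neurite_id`, `kind`,
#'   `arclength_um`, `intensity`.
#' @param regions_path CSV with `cell_id`, `region`, `background`.
#' @return A list with `profiles` and `regions` tibbles.
#' @export
read_profiles_csv <- function(profiles_path, regions_path) {
  p <- read_csv_quiet(profiles_path)
  validate_table(p, c("arclength_um", "intensity"),
                 c("cell_id", "neurite_id", "kind", "arclength_um",
                   "intensity"),
                 key_cols = c("cell_id", "neurite_id", "arclength_um"),
                 what = profiles_path)
  r <- read_csv_quiet(regions_path)
  validate_table(r, "background", c("cell_id", "region", "background"),
                 key_cols = c("cell_id", "region"), what = regions_path)
  list(profiles = p, regions = r)
}
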