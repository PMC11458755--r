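#' Construct a fluorescence movie
#'
#' A `gevi_movie` wraps a T x H x W stack of non-negative fluorescence
#' intensities (camera counts) with its frame interval and slice metadata.
#' Raw GEVI signals recorded through the green emission channel are
#' negative-going with depolarization; movies store the raw polarity and
#' inversion happens in [compute_dff()].
#'
#' @param frames Numeric array with `dim = c(T, H, W)`, `T >= 2`, all values
#'   finite and `>= 0`.
#' @param frame_interval_ms Positive frame interval in ms (default 1.020,
#'   i.e. ~1 kHz full-frame rate).
#' @param meta Named list of metadata (slice_id, animal_id, group in
#'   AD/CTRL, sex in F/M, trial index, pixel_size_um, ...). Free-form.
#'
#' @return An object of class `gevi_movie`.
#' @export
gevi_movie <- function(frames, frame_interval_ms = 1.020, meta = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("movie must be 3-dimensional (frames x rows x cols)", call. = FALSE)
  }
  d <- dim(frames)
  if (d[1] < 2L || d[2] < 1L || d[3] < 1L) {
    stop("movie needs T >= 2 frames and H, W >= 1", call. = FALSE)
  }
  if (!all(is.finite(frames)) || any(frames < 0)) {
    stop("movie intensities must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(frame_interval_ms) || length(frame_interval_ms) != 1L ||
      !is.finite(frame_interval_ms) || frame_interval_ms <= 0) {
    stop("frame_interval_ms must be a positive number", call. = FALSE)
  }
  structure(
    list(
      frames = frames,
      frame_interval_ms = as.numeric(frame_interval_ms),
      meta = meta
    ),
    class = "gevi_movie"
  )
}

#' @export
print.gevi_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<gevi_movie> %d frames of %dx%d @ %.3f ms\n",
    d[1], d[2], d[3], x$frame_interval_ms
  ))
  if (length(x$meta)) {
    keys <- vapply(x$meta, function(v) paste(format(v), collapse = ","), "")
    cat("  meta:", paste(names(keys), keys, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.gevi_movie <- function(x) dim(x$frames)

#' Write a movie to a multi-page TIFF with a YAML sidecar
#'
#' Frames are written as 16-bit grayscale pages (intensities must lie in
#' 0..65535; integer inputs round-trip bit-exactly). The frame interval and
#' metadata, which TIFF does not carry, go to `<path>.yaml`.
#'
#' @param movie A [gevi_movie()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "gevi_movie"))
  if (max(movie$frames) > 65535) {
    stop("TIFF export supports intensities in 0..65535", call. = FALSE)
  }
  d <- dim(movie$frames)
  pages <- lapply(seq_len(d[1]), function(i) {
    matrix(movie$frames[i, , ], d[2], d[3]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    frame_interval_ms = movie$frame_interval_ms,
    max_value = 65535,
    meta = movie$meta
  )
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a movie from a multi-page TIFF
#'
#' The frame interval is taken from the `<path>.yaml` sidecar written by
#' [write_movie()], or from `frame_interval_ms` when no sidecar exists.
#'
#' @param path TIFF path.
#' @param frame_interval_ms Frame interval override/fallback in ms.
#' @return A [gevi_movie()].
#' @export
read_movie <- function(path, frame_interval_ms = NULL) {
  if (!file.exists(path)) {
    stop("movie file not found: ", path, call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, TRUE))) {
    stop("movie must be 3-dimensional (grayscale pages)", call. = FALSE)
  }
  sidecar_path <- paste0(path, ".yaml")
  meta <- list()
  scale <- 65535
  if (file.exists(sidecar_path)) {
    sc <- yaml::read_yaml(sidecar_path)
    if (is.null(frame_interval_ms)) frame_interval_ms <- sc$frame_interval_ms
    if (!is.null(sc$max_value)) scale <- sc$max_value
    if (!is.null(sc$meta)) meta <- sc$meta
  }
  if (is.null(frame_interval_ms)) {
    stop("frame_interval_ms missing: supply it or provide a sidecar",
         call. = FALSE)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), h, w))
  for (i in seq_along(pages)) frames[i, , ] <- round(pages[[i]] * scale)
  gevi_movie(frames, frame_interval_ms, meta)
}

#' Per-pixel dF/F transform of a movie
#'
#' Computes `(F_t - Fbase) / Fbase` pixelwise against the mean over
#' `baseline_frames`, optionally inverting so that depolarization (which
#' dims emission in the raw records) becomes positive.
#'
#' @param movie A [gevi_movie()].
#' @param baseline_frames Integer vector of frame indices preceding the
#'   first stimulus.
#' @param invert Multiply by -1 (default TRUE, depolarization-positive).
#' @return A `gevi_movie` whose frames hold dF/F values (offset so the
#'   array stays non-negative is NOT applied; dF/F movies are flagged in
#'   `meta$signal = "dff"` and skip the non-negativity check).
#' @export
dff_movie <- function(movie, baseline_frames, invert = TRUE) {
  stopifnot(inherits(movie, "gevi_movie"))
  baseline_frames <- as.integer(baseline_frames)
  if (length(baseline_frames) < 1L ||
      any(baseline_frames < 1L | baseline_frames > dim(movie$frames)[1])) {
    stop("baseline_frames must be a non-empty in-range index vector",
         call. = FALSE)
  }
  base <- apply(movie$frames[baseline_frames, , , drop = FALSE], c(2, 3), mean)
  if (any(base <= 0)) {
    stop("baseline mean must be positive for every pixel", call. = FALSE)
  }
  d <- dim(movie$frames)
  out <- sweep(movie$frames, c(2, 3), base, "-")
  out <- sweep(out, c(2, 3), base, "/")
  if (invert) out <- -out
  res <- movie
  res$frames <- out
  res$meta$signal <- "dff"
  res
}
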