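#' Simulate a multi-group experimental cohort
#'
#' Draws per-slice variability (lognormal scatter on response amplitude
#' and on the synaptic space constant) around group-level parameters and
#' lays out the full recording design: every slice is tested at every
#' requested train frequency under the standard paradigm (one conditioning
#' pulse then a 10-pulse train). The AD condition gets a shorter synaptic
#' space constant than CTRL by default — weaker horizontal propagation —
#' while the vertical pathway and summation parameters are group-equal.
#'
#' Movies are not materialized here (a full cohort would not fit in
#' memory); each row carries a `sim_seed` so [render_slice()] regenerates
#' its sweeps deterministically on demand.
#'
#' @param n_slices Named integer vector of slices per group; names in
#'   `AD_F`, `AD_M`, `CTRL_F`, `CTRL_M` (defaults give a realistic unbalanced design,
#'   42/41/18/26 slices).
#' @param frequencies Train frequencies in Hz (default 20, 40, 83).
#' @param config Base [sim_config()] shared by all slices.
#' @param lambda_epsp_um Named vector `c(AD = ..., CTRL = ...)` of group
#'   HORIZONTAL (trans-columnar) synaptic space constants, um; the
#'   vertical constant stays at the base config's value for both groups
#'   (the vertical pathway is group-equal). Set both equal for a null
#'   cohort.
#' @param slice_cv Named vector: lognormal coefficients of variation of
#'   per-slice `amplitude` and `lambda` scatter.
#' @param n_pulses Train length (default 10).
#' @param truth_branches Analysis branches for which ground-truth metric
#'   columns are computed (default both).
#' @param seed Optional integer seed; all randomness (slice draws and the
#'   per-slice movie seeds) flows from it.
#' @return A tibble with one row per slice x frequency: identifiers,
#'   `sim_seed`, list-columns `config` and `protocol`, and the
#'   ground-truth metrics (`true_` columns) from [simulation_truth()].
#' @export
simulate_cohort <- function(n_slices = c(AD_F = 42, AD_M = 41,
                                         CTRL_F = 18, CTRL_M = 26),
                            frequencies = c(20, 40, 83),
                            config = sim_config(),
                            lambda_epsp_um = c(AD = 340, CTRL = 600),
                            slice_cv = c(amplitude = 0.2, lambda = 0.08),
                            n_pulses = 10,
                            truth_branches = c("summation", "propagation"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(n_slices < 1)) stop("zero slices requested for a group", call. = FALSE)
  known <- c("AD_F", "AD_M", "CTRL_F", "CTRL_M")
  if (is.null(names(n_slices)) || !all(names(n_slices) %in% known)) {
    stop("group labels must be among: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  protocols <- lapply(frequencies, function(f) {
    train_paradigm(f, n_pulses, config$frame_interval_ms %||% 1.020)
  })
  names(protocols) <- as.character(frequencies)

  rows <- list()
  for (gs in names(n_slices)) {
    parts <- strsplit(gs, "_", fixed = TRUE)[[1]]
    grp <- parts[1]; sex <- parts[2]
    lam <- lambda_epsp_um[[grp]]
    for (i in seq_len(n_slices[[gs]])) {
      amp_scale <- stats::rlnorm(1, 0, slice_cv[["amplitude"]])
      lam_scale <- stats::rlnorm(1, 0, slice_cv[["lambda"]])
      cfg <- config
      cfg$peak_dff <- config$peak_dff * amp_scale
      cfg$lambda_epsp_um <- c(
        vertical = unname(config$lambda_epsp_um[["vertical"]]) * lam_scale,
        horizontal = lam * lam_scale
      )
      slice_id <- sprintf("%s_%02d", gs, i)
      animal_id <- sprintf("%s_m%02d", gs, ceiling(i / 3))
      for (f in as.character(frequencies)) {
        sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        # truth per analysis branch: the branch filters are part of the
        # measurement definition, so true metrics are extracted from
        # noiseless traces passed through the same chain
        parts <- list()
        if ("summation" %in% truth_branches) {
          tr_s <- simulation_truth(cfg, protocols[[f]], branch = "summation")$table
          parts <- c(parts, list(
            dplyr::select(tr_s, dplyr::starts_with("p2_over_p1"),
                          dplyr::starts_with("max_peak"))))
        }
        if ("propagation" %in% truth_branches) {
          tr_p <- simulation_truth(cfg, protocols[[f]], branch = "propagation")$table
          parts <- c(parts, list(
            dplyr::select(tr_p, dplyr::starts_with("p1_"),
                          "roi2_over_roi1", "roi3_over_roi2", "roi3_over_roi1")))
        }
        truth_cols <- dplyr::bind_cols(parts)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(
            slice_id = slice_id, animal_id = animal_id,
            group = grp, sex = sex,
            frequency_hz = as.numeric(f),
            sim_seed = sim_seed,
            config = list(cfg), protocol = list(protocols[[f]])
          ),
          dplyr::rename_with(truth_cols, ~ paste0("true_", .x))
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize the movies of one cohort row
#'
#' Regenerates the raw sweep movies of a single slice x frequency record
#' from its stored config, protocol and seed.
#'
#' @param row One row of a [simulate_cohort()] tibble.
#' @return As [simulate_movie()]: list with `sweeps`, `truth`, `protocol`.
#' @export
render_slice <- function(row) {
  stopifnot(nrow(row) == 1L)
  simulate_movie(row$config[[1]], row$protocol[[1]], seed = row$sim_seed)
}

#' Extract every ROI's preprocessed trace from one slice
#'
#' Same stage chain as [preprocess_branch()] but computes the per-pixel
#' dF/F once per sweep and reuses it for all ROI labels.
#'
#' @param sweeps List of raw [gevi_movie()] sweeps.
#' @param rois A [roi_set()].
#' @param protocol A [stim_protocol()].
#' @param branch `"summation"` or `"propagation"`.
#' @return Named list of [gevi_trace()], one per ROI label.
#' @export
preprocess_all_rois <- function(sweeps, rois, protocol,
                                branch = c("summation", "propagation")) {
  branch <- match.arg(branch)
  dt <- sweeps[[1]]$frame_interval_ms
  first_stim <- protocol_first_event_ms(protocol)
  base_frames <- seq_len(max(2L, floor((first_stim - 5) / dt)))
  dms <- lapply(sweeps, dff_movie, baseline_frames = base_frames,
                invert = TRUE)
  protect <- list(c(first_stim - 5, max(protocol$pulse_times_ms) + 300))
  labels <- as.integer(names(rois$pixel_counts))
  out <- list()
  for (lab in labels) {
    per_sweep <- lapply(dms, function(dm) {
      tr <- spatial_average(dm, rois, lab)
      gevi_trace(tr$samples, tr$sampling_interval_ms,
                 c("dff(invert)", tr$provenance))
    })
    avg <- average_sweeps(per_sweep)
    tr <- correct_bleach(avg, protect)$trace
    tr <- if (branch == "summation") {
      gaussian_lowpass(tr, 33)
    } else {
      rc_highpass(gaussian_lowpass(tr, 77), 0.1)
    }
    out[[as.character(lab)]] <- tr
  }
  out
}

#' Run the analysis pipeline over a simulated cohort
#'
#' For every slice x frequency record: renders the sweeps, extracts the
#' three ROI traces through the requested branch's preprocessing chain,
#' detects the per-pulse train peaks and assembles the efficacy table —
#' P1, P2, P2/P1 and Max Peak per ROI plus the inter-ROI P1 amplitude
#' ratios per slice. ROI apertures are 57 pixels for the summation branch
#' and 37 for the propagation branch.
#'
#' @param cohort A [simulate_cohort()] tibble (or subset of rows).
#' @param branch `"summation"` or `"propagation"`.
#' @param roi_pixels Aperture override; default by branch.
#' @param with_truth Append the realized-trial ground-truth metrics
#'   ([realized_truth()]) as `truth_` columns, for parameter-recovery
#'   studies.
#' @param progress Print a line per slice processed.
#' @return An efficacy table: one row per slice x frequency x ROI with
#'   columns `slice_id`, `group`, `sex`, `frequency_hz`, `roi`, `p1`,
#'   `p2`, `p2_over_p1`, `max_peak`, `roi2_over_roi1`, `roi3_over_roi2`,
#'   `roi3_over_roi1` (ratio columns repeated across the slice's ROI
#'   rows; `NA` marks measurements below the validity threshold).
#' @export
process_cohort <- function(cohort, branch = c("summation", "propagation"),
                           roi_pixels = NULL, with_truth = FALSE,
                           progress = FALSE) {
  branch <- match.arg(branch)
  if (is.null(roi_pixels)) roi_pixels <- if (branch == "summation") 57 else 37
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    sim <- render_slice(row)
    cfg <- row$config[[1]]
    rois <- default_rois(cfg, roi_pixels)
    traces <- preprocess_all_rois(sim$sweeps, rois, sim$protocol, branch)
    resp <- lapply(traces, detect_train_peaks, protocol = sim$protocol,
                   epsp_decay_ms = cfg$epsp_decay_ms)
    r21 <- propagation_efficacy(resp[["2"]], resp[["1"]])
    r32 <- propagation_efficacy(resp[["3"]], resp[["2"]])
    r31 <- propagation_efficacy(resp[["3"]], resp[["1"]])
    truth_cols <- NULL
    if (with_truth) {
      rt <- realized_truth(cfg, sim$protocol, sim$truth$jitters_ms,
                           sim$truth$epsp_successes,
                           roi_pixels = roi_pixels, branch = branch)$table
      truth_cols <- dplyr::rename_with(
        dplyr::select(rt, -"frequency_hz"), ~ paste0("truth_", .x))
    }
    out[[i]] <- purrr::map_dfr(names(resp), function(lab) {
      r <- resp[[lab]]
      base <- tibble::tibble(
        slice_id = row$slice_id, group = row$group, sex = row$sex,
        frequency_hz = row$frequency_hz, roi = as.integer(lab),
        p1 = r$peak_amplitudes[1],
        p2 = if (length(r$peak_amplitudes) >= 2) r$peak_amplitudes[2] else NA_real_,
        p2_over_p1 = suppressMessages(summation_efficacy(r)),
        max_peak = r$max_peak,
        roi2_over_roi1 = r21, roi3_over_roi2 = r32, roi3_over_roi1 = r31
      )
      if (!is.null(truth_cols)) base <- dplyr::bind_cols(base, truth_cols)
      base
    })
    if (progress && row$frequency_hz == cohort$frequency_hz[1]) {
      message(sprintf("processed %s", row$slice_id))
    }
  }
  dplyr::bind_rows(out)
}

#' Write an analysis table to CSV
#'
#' Comma-separated, UTF-8, `.` decimal, mandatory header; numeric fields
#' keep full precision so tables round-trip losslessly.
#'
#' @param table A data frame (efficacy table, group summaries, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  is_list <- vapply(table, is.list, TRUE)
  if (any(is_list)) table <- table[, !is_list, drop = FALSE]
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Read an analysis table written by [write_table()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
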