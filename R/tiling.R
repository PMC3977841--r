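# Tiling array-CGH validation track: moving-average smoothing of
# log2(test/reference) ratios and two-class copy-number classification
# against a reference panel envelope. "Unchanged copy number" means the
# ratio stays within the normal panel's band; "copy number loss" means
# the downward deviation exceeds 1 SD below the per-probe median. Gains
# are outside the two-class scheme (none were observed in the study
# populations this mirrors).

# centered truncated moving average of one vector, NA-aware
ma_vector <- function(v, window) {
  n <- length(v)
  half <- (window - 1) / 2
  vals <- ifelse(is.na(v), 0, v)
  cs <- c(0, cumsum(vals))
  cn <- c(0, cumsum(!is.na(v)))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  total <- cs[hi + 1] - cs[lo]
  count <- cn[hi + 1] - cn[lo]
  out <- total / count
  out[count == 0] <- NA_real_
  out
}

#' Moving-average smoothing of log2-ratio tracks
#'
#' Replaces each probe's value by the mean of the non-missing values in a
#' centered window of `window` probes, truncated at track ends (and at
#' chromosome boundaries when a manifest is supplied). Probes whose whole
#' window is missing stay missing. `window = 1` is the identity.
#'
#' @param tracks Wide tibble (`probe_id` + one log2-ratio column per
#'   subject).
#' @param window Odd positive probe count.
#' @param manifest Optional manifest; when given, windows never span
#'   chromosomes.
#' @return Wide tibble of the same shape.
#' @export
moving_average <- function(tracks, window = 11, manifest = NULL) {
  if (window < 1 || window %% 2 == 0) {
    abort("window must be an odd positive probe count")
  }
  m <- as_probe_matrix(tracks, manifest)
  if (is.null(manifest)) {
    blocks <- list(seq_len(nrow(m)))
  } else {
    blocks <- split(seq_len(nrow(m)), manifest$chrom)
  }
  out <- m
  for (idx in blocks) {
    out[idx, ] <- apply(m[idx, , drop = FALSE], 2, ma_vector,
                        window = window)
  }
  as_probe_tibble(out)
}

#' Build the normal-population reference envelope
#'
#' Per-probe center and scale of the log2 ratio over a panel of
#' copy-neutral individuals: center is the per-probe median (a mean
#' option exists), scale is the per-probe standard deviation floored at
#' `sd_floor` so identical panels never give a zero-width band. A pooled
#' scale (root mean per-probe variance, one value for all probes) is
#' available for homogeneous platforms.
#'
#' @param panel Wide tibble of the panel's unsmoothed log2-ratio tracks;
#'   at least 3 tracks.
#' @param sd_floor Minimum scale (log2 units).
#' @param center `"median"` (robust default) or `"mean"`.
#' @param scale `"per_probe"` (default) or `"pooled"`.
#' @return Tibble `probe_id`, `center`, `scale`, with attribute
#'   `panel_size`.
#' @export
build_reference_envelope <- function(panel, sd_floor = 0.05,
                                     center = c("median", "mean"),
                                     scale = c("per_probe", "pooled")) {
  center <- match.arg(center)
  scale <- match.arg(scale)
  m <- as_probe_matrix(panel)
  if (ncol(m) < 3) abort("reference envelope needs a panel of >= 3 tracks")
  ctr <- apply(m, 1, if (center == "median") median else mean, na.rm = TRUE)
  sds <- apply(m, 1, sd, na.rm = TRUE)
  if (scale == "pooled") {
    sds <- rep(sqrt(mean(sds^2, na.rm = TRUE)), length(sds))
  }
  out <- tibble::tibble(probe_id = rownames(m), center = unname(ctr),
                        scale = pmax(unname(sds), sd_floor))
  attr(out, "panel_size") <- ncol(m)
  out
}

#' Classify probes as unchanged copy number or copy number loss
#'
#' A probe is labelled `"loss"` when its (smoothed) log2 ratio falls
#' strictly below `center - 1 * scale`; exact-threshold values and all
#' upward deviations are `"unchanged"` (the two-class scheme has no gain
#' label). Missing values stay `"missing"`.
#'
#' @param smoothed Wide tibble of log2-ratio tracks, usually from
#'   [moving_average()].
#' @param envelope Envelope tibble from [build_reference_envelope()],
#'   aligned by probe.
#' @param n_sd Multiplier on the scale (default 1 SD).
#' @return Wide tibble of class labels per probe and subject.
#' @export
classify_copy_number <- function(smoothed, envelope, n_sd = 1) {
  m <- as_probe_matrix(smoothed)
  if (!identical(rownames(m), envelope$probe_id)) {
    abort("smoothed tracks and envelope are not probe-aligned")
  }
  thr <- envelope$center - n_sd * envelope$scale
  lab <- ifelse(m < thr, "loss", "unchanged")
  lab[is.na(m)] <- "missing"
  as_probe_tibble(lab)
}

#' Extract copy-number-loss segments from a classified track
#'
#' Maximal runs of at least `min_probes` consecutive `"loss"` labels
#' become segments spanning first to last probe of the run; runs broken
#' by missing labels (coverage gaps) are never merged.
#'
#' @param classes Wide label tibble from [classify_copy_number()].
#' @param manifest Tiling probe manifest, probe-aligned.
#' @param min_probes Minimum run length (default 2).
#' @return Call tibble: `subject_id`, `chrom`, `start`, `end`, `state`
#'   (always "loss"), `n_probes`, `first_probe`, `last_probe`.
#' @export
extract_loss_segments <- function(classes, manifest, min_probes = 2) {
  validate_manifest(manifest)
  if (min_probes < 2) abort("min_probes must be >= 2")
  m <- as_probe_matrix(classes, manifest)
  state_num <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  state_num[m == "loss"] <- 1L
  state_num[m == "unchanged"] <- 2L
  calls <- purrr::map(colnames(state_num), function(s) {
    seg <- segment_runs(state_num[, s], manifest, min_probes)
    seg <- seg[seg$state == "loss", , drop = FALSE]
    if (nrow(seg) > 0) seg$subject_id <- s
    seg
  })
  out <- dplyr::bind_rows(calls)
  if (nrow(out) == 0) out$subject_id <- character()
  dplyr::relocate(out, "subject_id")
}

#' Run the tiling-aCGH segmenter
#'
#' Builds the reference envelope from the unsmoothed panel tracks,
#' smooths every track with a centered moving average, classifies against
#' the envelope, extracts loss segments, and dichotomizes regions. A
#' switch applies the envelope rule to raw instead of smoothed ratios.
#'
#' @param tracks Wide tibble of all subjects' log2-ratio tracks.
#' @param manifest Tiling probe manifest.
#' @param panel_subjects Character vector of column names used as the
#'   normal reference panel.
#' @param regions Region tibble.
#' @param window Moving-average window (odd probe count).
#' @param min_probes Consecutive-loss threshold for segments and region
#'   overlap.
#' @param sd_floor,center,scale Envelope options, see
#'   [build_reference_envelope()].
#' @param classify_smoothed Apply the 1-SD rule to smoothed (default) or
#'   raw ratios.
#' @return An `acgh_calls` list: `status`, `calls`, `classes`,
#'   `envelope`, `smoothed`, parameters.
#' @export
call_acgh <- function(tracks, manifest, panel_subjects,
                      regions = builtin_regions(), window = 11,
                      min_probes = 2, sd_floor = 0.05,
                      center = "median", scale = "per_probe",
                      classify_smoothed = TRUE) {
  validate_manifest(manifest)
  missing_panel <- setdiff(panel_subjects, names(tracks))
  if (length(missing_panel) > 0) {
    abort(paste0("panel subject(s) absent from tracks: ",
                 paste(head(missing_panel, 3), collapse = ", ")))
  }
  envelope <- build_reference_envelope(
    tracks[, c("probe_id", panel_subjects)],
    sd_floor = sd_floor, center = center, scale = scale)
  smoothed <- moving_average(tracks, window = window, manifest = manifest)
  classes <- classify_copy_number(
    if (classify_smoothed) smoothed else tracks, envelope)
  calls <- extract_loss_segments(classes, manifest, min_probes = min_probes)
  subjects <- setdiff(names(tracks), "probe_id")
  status <- region_status_from_calls(calls, regions, manifest,
                                     subjects = subjects,
                                     min_overlap_probes = min_probes)
  structure(list(status = status, calls = calls, classes = classes,
                 envelope = envelope, smoothed = smoothed,
                 params = list(window = window, min_probes = min_probes,
                               sd_floor = sd_floor,
                               classify_smoothed = classify_smoothed)),
            class = "acgh_calls")
}

#' @export
print.acgh_calls <- function(x, ...) {
  cat("Tiling-aCGH CNV calls:",
      length(unique(x$status$subject_id)), "subjects,",
      nrow(x$calls), "loss segment(s)\n")
  print(dplyr::count(x$status, .data$region, .data$status))
  invisible(x)
}

#' Cross-platform confirmation rate
#'
#' Among subjects the primary (bead-array) screen called loss in a
#' region, the fraction whose validation (aCGH) status is also loss —
#' per region and overall. Mirrors confirmatory re-testing of
#' screen-positive subjects on the second platform.
#'
#' @param primary,validation Long status tibbles (`subject_id`, `region`,
#'   `status`). Only subjects present in both are compared.
#' @return Tibble `region`, `n_primary_loss`, `n_confirmed`,
#'   `concordance`, with an `"overall"` row; concordance is `NA` where no
#'   primary losses exist among shared subjects.
#' @export
concordance <- function(primary, validation) {
  shared <- dplyr::inner_join(
    primary, validation,
    by = c("subject_id", "region"), suffix = c("_primary", "_validation"))
  losses <- shared[shared$status_primary == "loss", ]
  per_region <- dplyr::summarise(
    dplyr::group_by(losses, .data$region),
    n_primary_loss = dplyr::n(),
    n_confirmed = sum(.data$status_validation == "loss"),
    .groups = "drop")
  all_regions <- tibble::tibble(region = unique(primary$region))
  per_region <- dplyr::left_join(all_regions, per_region, by = "region")
  per_region$n_primary_loss[is.na(per_region$n_primary_loss)] <- 0L
  per_region$n_confirmed[is.na(per_region$n_confirmed)] <- 0L
  overall <- tibble::tibble(
    region = "overall",
    n_primary_loss = sum(per_region$n_primary_loss),
    n_confirmed = sum(per_region$n_confirmed))
  out <- dplyr::bind_rows(per_region, overall)
  out$concordance <- ifelse(out$n_primary_loss > 0,
                            out$n_confirmed / out$n_primary_loss, NA_real_)
  out
}
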