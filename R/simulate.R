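# Synthetic cohorts and array signals. The generator emulates the study
# design the callers assume: 100 early-onset T2DM cases and 100 elderly
# non-diabetic controls, heterozygous (single-copy) subtelomeric deletions
# with an expected log2-ratio shift of log2(1/2) = -1, Gaussian probe
# noise, a smooth GC intensity bias, additive per-batch offsets, and
# low-coverage gap intervals emitted as missing values. Gains are left as
# a parameter hook only: the study populations showed no detectable gain.

#' Cohort simulation settings
#'
#' Bundles the case/control sizes, per-region loss prevalences and
#' deletion-extent range used by [simulate_cohort()]. Default prevalences
#' follow the observed per-region loss counts (cases 15%, 22% for
#' 16q24.2-3 and 22q13.31-33; controls 3%, 6%); the 4p16.3 prevalences
#' were not reported at this granularity and default to plausible values.
#'
#' @param n_cases,n_controls Group sizes.
#' @param case_prevalence,control_prevalence Named vectors, region label ->
#'   loss probability in \[0, 1\]. Regions are drawn independently.
#' @param deletion_span_frac Length-2 vector: deletion extents are drawn
#'   uniformly between these fractions of the region length.
#' @param n_batches Number of processing batches subjects are spread over.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 100, n_controls = 100,
                        case_prevalence = c("4p16.3" = 0.16,
                                            "16q24.2-3" = 0.15,
                                            "22q13.31-33" = 0.22),
                        control_prevalence = c("4p16.3" = 0.02,
                                               "16q24.2-3" = 0.03,
                                               "22q13.31-33" = 0.06),
                        deletion_span_frac = c(0.5, 0.9),
                        n_batches = 4) {
  stopifnot(n_cases >= 0, n_controls >= 0,
            all(case_prevalence >= 0), all(case_prevalence <= 1),
            all(control_prevalence >= 0), all(control_prevalence <= 1),
            length(deletion_span_frac) == 2,
            deletion_span_frac[1] > 0,
            deletion_span_frac[2] <= 1,
            deletion_span_frac[1] <= deletion_span_frac[2],
            n_batches >= 1)
  if (!identical(sort(names(case_prevalence)),
                 sort(names(control_prevalence)))) {
    abort("case and control prevalence maps must name the same regions")
  }
  structure(
    list(n_cases = n_cases, n_controls = n_controls,
         case_prevalence = case_prevalence,
         control_prevalence = control_prevalence,
         deletion_span_frac = deletion_span_frac,
         n_batches = n_batches),
    class = "cohort_spec"
  )
}

#' Noise and bias settings for simulated arrays
#'
#' @param probe_sd Per-probe Gaussian noise standard deviation on the log2
#'   scale.
#' @param gc_coefficients Length-2 vector `(c1, c2)`: raw bead intensity is
#'   scaled by `1 + c1 * gc + c2 * gc^2`.
#' @param batch_effect_sd Standard deviation of per-batch log2 offsets
#'   shared by all probes of a batch.
#' @param loss_shift Expected log2 ratio inside a single-copy deletion;
#'   log2(1/2) = -1 for a heterozygous loss against a two-copy reference.
#' @return A `noise_model` list.
#' @export
noise_model <- function(probe_sd = 0.2, gc_coefficients = c(0.4, -0.4),
                        batch_effect_sd = 0.05, loss_shift = -1) {
  stopifnot(probe_sd >= 0, length(gc_coefficients) == 2,
            batch_effect_sd >= 0, loss_shift < 0)
  structure(
    list(probe_sd = probe_sd, gc_coefficients = gc_coefficients,
         batch_effect_sd = batch_effect_sd, loss_shift = loss_shift),
    class = "noise_model"
  )
}

#' Simulate per-subject deletion truth for a cohort
#'
#' Draws, for every subject and region, a Bernoulli loss flag at the
#' group's prevalence and, for carriers, a deletion interval with extent
#' uniform within `deletion_span_frac` of the region length and start
#' uniform within the region. Subjects are assigned to processing batches
#' round-robin so batches mix cases and controls.
#'
#' @param spec A [cohort_spec()].
#' @param regions Region tibble as from [builtin_regions()]; every
#'   prevalence-map region must be present.
#' @param seed Integer seed; fixes every draw.
#' @return A tibble with one row per subject x region: `subject_id`,
#'   `group` ("case"/"control"), `batch`, `region`, `loss` (logical),
#'   `del_start`, `del_end` (NA when no loss).
#' @export
simulate_cohort <- function(spec, regions = builtin_regions(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_regions(regions)
  region_labels <- names(spec$case_prevalence)
  missing_regions <- setdiff(region_labels, regions$region)
  if (length(missing_regions) > 0) {
    abort(paste0("prevalence map names region(s) absent from the region ",
                 "set: ", paste(missing_regions, collapse = ", ")))
  }
  subjects <- tibble::tibble(
    subject_id = c(sprintf("case_%03d", seq_len(spec$n_cases)),
                   sprintf("ctrl_%03d", seq_len(spec$n_controls))),
    group = rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  )
  subjects$batch <- ((seq_len(nrow(subjects)) - 1L) %% spec$n_batches) + 1L

  withr::with_seed(seed, {
    rows <- purrr::map(region_labels, function(rl) {
      r <- regions[regions$region == rl, ]
      len <- interval_length(r$start, r$end)
      prev <- ifelse(subjects$group == "case",
                     spec$case_prevalence[[rl]],
                     spec$control_prevalence[[rl]])
      loss <- rbinom(nrow(subjects), 1L, prev) == 1L
      span <- round(runif(nrow(subjects),
                          spec$deletion_span_frac[1] * len,
                          spec$deletion_span_frac[2] * len))
      del_start <- round(runif(nrow(subjects), r$start, r$end - span + 1))
      tibble::tibble(
        subject_id = subjects$subject_id, group = subjects$group,
        batch = subjects$batch, region = rl, loss = loss,
        del_start = ifelse(loss, del_start, NA_real_),
        del_end = ifelse(loss, del_start + span - 1, NA_real_)
      )
    })
    dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id, .data$region)
  })
}

#' True region status implied by a simulated cohort
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @return Long status tibble (`subject_id`, `group`, `region`, `status`)
#'   with status "loss" or "unchanged" — the ground truth downstream calls
#'   are scored against.
#' @export
truth_region_status <- function(truth) {
  dplyr::transmute(truth,
    subject_id = .data$subject_id, group = .data$group,
    region = .data$region,
    status = ifelse(.data$loss, "loss", "unchanged"))
}

# logical probes x subjects matrix: probe inside subject's deletion
deletion_mask <- function(truth, manifest, regions) {
  subjects <- unique(truth$subject_id)
  mid <- (manifest$start + manifest$end) / 2
  mask <- matrix(FALSE, nrow(manifest), length(subjects),
                 dimnames = list(manifest$probe_id, subjects))
  del <- truth[truth$loss, ]
  if (nrow(del) == 0) return(mask)
  chrom_of <- setNames(regions$chrom, regions$region)
  for (i in seq_len(nrow(del))) {
    hit <- manifest$chrom == chrom_of[[del$region[i]]] &
      mid >= del$del_start[i] & mid <= del$del_end[i]
    mask[hit, del$subject_id[i]] <- TRUE
  }
  mask
}

#' Simulate tiling-aCGH log2-ratio tracks
#'
#' Emits one log2(test/reference) track per subject on the tiling manifest:
#' mean `loss_shift` at probes inside a true deletion, mean 0 elsewhere,
#' independent Gaussian noise of sd `probe_sd`, and `NA` at probes falling
#' in low-coverage gap intervals.
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param manifest Tiling probe manifest.
#' @param noise A [noise_model()].
#' @param regions Region tibble (maps region labels to chromosomes).
#' @param gaps Optional gap interval tibble (`chrom`, `start`, `end`).
#' @param seed Integer seed.
#' @return Wide tibble: `probe_id` plus one log2-ratio column per subject.
#' @export
simulate_log2_tracks <- function(truth, manifest, noise = noise_model(),
                                 regions = builtin_regions(), gaps = NULL,
                                 seed = 1) {
  validate_manifest(manifest)
  validate_gaps(gaps, regions)
  mask <- deletion_mask(truth, manifest, regions)
  withr::with_seed(seed, {
    vals <- ifelse(mask, noise$loss_shift, 0) +
      matrix(rnorm(length(mask), 0, noise$probe_sd),
             nrow(mask), ncol(mask))
  })
  if (!is.null(gaps)) {
    vals[probes_in_intervals(manifest, gaps), ] <- NA_real_
  }
  dplyr::bind_cols(tibble::tibble(probe_id = manifest$probe_id),
                   tibble::as_tibble(vals))
}

#' Simulate two-channel bead-array intensities
#'
#' Raw expected intensity scales with copy number (2 copies = baseline,
#' 1 copy = half), is multiplied by the quadratic GC-bias factor
#' `1 + c1*gc + c2*gc^2`, and carries a per-batch offset plus Gaussian
#' probe noise on the log2 scale (so intensities stay strictly positive).
#' The signal is split evenly over the two colour channels.
#'
#' @inheritParams simulate_log2_tracks
#' @param manifest Beadchip probe manifest.
#' @param baseline Two-copy raw intensity level.
#' @return List with wide tibbles `channel_a` and `channel_b` (`probe_id`
#'   plus one column per subject) and the `batch` assignment tibble.
#' @export
simulate_bead_intensities <- function(truth, manifest, noise = noise_model(),
                                      regions = builtin_regions(),
                                      baseline = 1000, seed = 1) {
  validate_manifest(manifest)
  mask <- deletion_mask(truth, manifest, regions)
  subjects <- colnames(mask)
  batch_of <- dplyr::distinct(truth, .data$subject_id, .data$batch)
  batch_of <- setNames(batch_of$batch, batch_of$subject_id)[subjects]
  gc_factor <- 1 + noise$gc_coefficients[1] * manifest$gc_fraction +
    noise$gc_coefficients[2] * manifest$gc_fraction^2
  if (any(gc_factor <= 0)) abort("gc_coefficients give non-positive bias")
  cn <- ifelse(mask, 1, 2)
  withr::with_seed(seed, {
    batch_offsets <- rnorm(max(batch_of), 0, noise$batch_effect_sd)
    log2_noise <- matrix(rnorm(length(mask), 0, noise$probe_sd),
                         nrow(mask), ncol(mask))
  })
  total <- baseline * (cn / 2) * gc_factor *
    2^(sweep(log2_noise, 2, batch_offsets[batch_of], `+`))
  half <- total / 2
  out <- function(m) dplyr::bind_cols(
    tibble::tibble(probe_id = manifest$probe_id), tibble::as_tibble(m))
  list(channel_a = out(half), channel_b = out(half),
       batches = tibble::tibble(subject_id = subjects,
                                batch = unname(batch_of)))
}
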