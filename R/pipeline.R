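# End-to-end orchestration: simulate a cohort, screen it with the
# bead-array caller, validate screen-positive subjects on the tiling-aCGH
# track, measure cross-platform concordance, and run the case-control
# association. One master seed deterministically spawns per-stage seeds,
# so stages can be re-run standalone and a fixed config + seed gives a
# byte-identical result.

#' Pipeline configuration
#'
#' Bundles every tunable of the simulate -> call -> validate -> associate
#' chain. Defaults are the study-profile conditions: 100 + 100 subjects,
#' region loss prevalences matching the observed per-region counts, a
#' -1 log2 loss shift with 0.2 probe noise.
#'
#' @param spec A [cohort_spec()].
#' @param noise A [noise_model()].
#' @param regions Region tibble.
#' @param gaps Optional low-coverage gap tibble (tiling platform).
#' @param n_probes_beadchip,n_probes_tiling Probes per region on each
#'   simulated platform.
#' @param n_probes_background Copy-neutral background probes added to the
#'   beadchip manifest, standing in for the genome-wide probe content
#'   that anchors median normalization (see [make_probe_manifest()]).
#' @param k_pcs Principal components removed in the bead-array caller;
#'   0 by default because on a region-targeted manifest the leading
#'   components carry the deletion signal itself (see
#'   [call_beadchip()]).
#' @param window Moving-average window for the aCGH track.
#' @param min_probes Consecutive-marker threshold (both platforms).
#' @param sd_floor Envelope scale floor.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = cohort_spec(), noise = noise_model(),
                            regions = builtin_regions(), gaps = NULL,
                            n_probes_beadchip = 40, n_probes_tiling = 150,
                            n_probes_background = 150,
                            k_pcs = 0, window = 11, min_probes = 2,
                            sd_floor = 0.05, seed = 1) {
  structure(list(spec = spec, noise = noise, regions = regions,
                 gaps = gaps, n_probes_beadchip = n_probes_beadchip,
                 n_probes_tiling = n_probes_tiling,
                 n_probes_background = n_probes_background, k_pcs = k_pcs,
                 window = window, min_probes = min_probes,
                 sd_floor = sd_floor, seed = as.integer(seed)),
            class = "pipeline_config")
}

# spawn reproducible per-stage seeds below 2^31 from the master seed
stage_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 7919) %% 2147483647
}

#' Score called region status against simulation truth
#'
#' @param status Long called-status tibble (`subject_id`, `region`,
#'   `status`).
#' @param truth_status Long truth tibble from [truth_region_status()].
#' @return Tibble per region plus an `"overall"` row: `n_loss_true`,
#'   `n_detected`, `n_unchanged_true`, `n_false_pos`, `sensitivity`,
#'   `false_positive_rate`.
#' @export
call_performance <- function(status, truth_status) {
  joined <- dplyr::inner_join(
    status, truth_status, by = c("subject_id", "region"),
    suffix = c("_called", "_true"))
  score <- function(df, label) {
    tl <- df$status_true == "loss"
    tibble::tibble(
      region = label,
      n_loss_true = sum(tl),
      n_detected = sum(tl & df$status_called == "loss"),
      n_unchanged_true = sum(!tl),
      n_false_pos = sum(!tl & df$status_called == "loss"))
  }
  out <- dplyr::bind_rows(
    purrr::map_dfr(unique(joined$region),
                   function(rl) score(joined[joined$region == rl, ], rl)),
    score(joined, "overall"))
  out$sensitivity <- ifelse(out$n_loss_true > 0,
                            out$n_detected / out$n_loss_true, NA_real_)
  out$false_positive_rate <- ifelse(out$n_unchanged_true > 0,
                                    out$n_false_pos / out$n_unchanged_true,
                                    NA_real_)
  out
}

write_stage_tsv <- function(df, path, config_hash, seed) {
  writeLines(sprintf("# subtelcnv config_hash=%s seed=%d",
                     config_hash, seed), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the whole pipeline on a simulated cohort
#'
#' Executes simulate -> bead-array calling -> tiling-aCGH validation ->
#' cross-platform concordance -> case-control association, plus truth
#' scoring of both platforms. The aCGH reference panel is the control
#' group; validation statuses are computed for all subjects, and
#' concordance is measured on the subjects the bead screen called loss.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, status matrices, calls,
#'   concordance, performance and the association summary are written as
#'   TSVs, each headed by a comment carrying the config hash and seed.
#' @return A `cnv_pipeline_result` list: `truth`, `status_beadchip`,
#'   `status_acgh`, `calls_beadchip`, `calls_acgh`, `concordance`,
#'   `performance` (both platforms), `association`
#'   (a [association_report()] object), `config`.
#' @export
run_cnv_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  regions <- config$regions
  truth <- stage("simulate", simulate_cohort(
    config$spec, regions, seed = stage_seed(config$seed, 1)))
  groups <- dplyr::distinct(truth, .data$subject_id, .data$group)

  manifest_bead <- make_probe_manifest(
    regions, n_probes = config$n_probes_beadchip, platform = "beadchip",
    background_probes = config$n_probes_background)
  intens <- stage("simulate", simulate_bead_intensities(
    truth, manifest_bead, config$noise, regions,
    seed = stage_seed(config$seed, 2)))
  bead <- stage("beadchip_calling", call_beadchip(
    intens$channel_a, intens$channel_b, manifest_bead,
    regions, k_pcs = config$k_pcs, min_probes = config$min_probes))
  status_bead <- dplyr::inner_join(bead$status, groups, by = "subject_id")

  manifest_tiling <- make_probe_manifest(
    regions, n_probes = config$n_probes_tiling, platform = "tiling")
  tracks <- stage("simulate", simulate_log2_tracks(
    truth, manifest_tiling, config$noise, regions, gaps = config$gaps,
    seed = stage_seed(config$seed, 3)))
  panel <- groups$subject_id[groups$group == "control"]
  acgh <- stage("acgh_validation", call_acgh(
    tracks, manifest_tiling, panel_subjects = panel,
    regions = regions, window = config$window,
    min_probes = config$min_probes, sd_floor = config$sd_floor))
  status_acgh <- dplyr::inner_join(acgh$status, groups, by = "subject_id")

  conc <- stage("concordance", concordance(bead$status, acgh$status))
  truth_status <- truth_region_status(truth)
  performance <- dplyr::bind_rows(
    dplyr::mutate(call_performance(bead$status, truth_status),
                  platform = "beadchip"),
    dplyr::mutate(call_performance(acgh$status, truth_status),
                  platform = "acgh"))
  report <- stage("association",
                  association_report(status_bead, regions = regions$region))

  result <- structure(
    list(truth = truth, status_beadchip = status_bead,
         status_acgh = status_acgh, calls_beadchip = bead$calls,
         calls_acgh = acgh$calls, concordance = conc,
         performance = performance, association = report,
         config = config),
    class = "cnv_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- rlang::hash(config)
    w <- function(df, name) write_stage_tsv(
      df, file.path(out_dir, name), h, config$seed)
    w(truth, "truth.tsv")
    w(status_bead, "status_beadchip.tsv")
    w(status_acgh, "status_acgh.tsv")
    w(bead$calls, "calls_beadchip.tsv")
    w(acgh$calls, "calls_acgh.tsv")
    w(conc, "concordance.tsv")
    w(performance, "performance.tsv")
    w(report$per_region, "association_per_region.tsv")
    w(report$combined$by_count, "association_combined.tsv")
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(config_hash = h, seed = config$seed,
             per_region = report$per_region,
             combined_by_count = report$combined$by_count,
             p_all_regions = report$combined$p_all_regions,
             p_exactly_two = report$combined$p_exactly_two),
        file.path(out_dir, "association.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }
  result
}

#' @export
print.cnv_pipeline_result <- function(x, ...) {
  cat("subtelcnv pipeline result (seed", x$config$seed, ")\n\n")
  perf <- x$performance[x$performance$region == "overall", ]
  for (i in seq_len(nrow(perf))) {
    cat(sprintf("  %-9s sensitivity %.3f  false-positive rate %.4f\n",
                perf$platform[i], perf$sensitivity[i],
                perf$false_positive_rate[i]))
  }
  ov <- x$concordance[x$concordance$region == "overall", ]
  cat(sprintf("  concordance (bead loss confirmed by aCGH): %d/%d\n\n",
              ov$n_confirmed, ov$n_primary_loss))
  print(x$association)
  invisible(x)
}
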