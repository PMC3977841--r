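# Stages of the bead-array caller: normalization/GC correction, batch
# component removal, per-probe mixture calling, consecutive-marker
# segmentation, region dichotomization.

test_that("normalization is a fixed point on median-aligned, GC-free input", {
  manifest <- flat_manifest(40)
  gc <- manifest$gc_fraction
  set.seed(21)
  x <- sapply(1:5, function(i) {
    l <- residuals(lm(rnorm(40, 0, 0.3) ~ gc + I(gc^2)))
    v <- 2^l
    v / median(v)
  })
  colnames(x) <- sprintf("s%02d", 1:5)
  input <- tracks_from_matrix(x, manifest$probe_id)
  out <- normalize_and_gc_correct(input, manifest)
  expect_equal(as.matrix(out[-1]), x, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("normalization is invariant to a global per-subject scale", {
  manifest <- flat_manifest(30)
  set.seed(22)
  v <- 2^rnorm(30, 0, 0.2)
  x <- cbind(s1 = v, s2 = 2 * v)
  out <- normalize_and_gc_correct(tracks_from_matrix(x, manifest$probe_id),
                                  manifest)
  expect_equal(out$s1, out$s2, tolerance = 1e-12)
})

test_that("an injected quadratic GC trend is removed", {
  regions <- tiny_regions()
  spec <- tiny_cohort(case_prev = c(regA = 0, regB = 0),
                      ctrl_prev = c(regA = 0, regB = 0), n = 10)
  truth <- simulate_cohort(spec, regions, seed = 23)
  manifest <- tiny_manifest(n = 100, platform = "beadchip")
  nm <- noise_model(probe_sd = 0.1, gc_coefficients = c(0.6, -0.5),
                    batch_effect_sd = 0)
  ints <- simulate_bead_intensities(truth, manifest, nm, regions, seed = 24)
  raw_total <- as.matrix(ints$channel_a[-1]) + as.matrix(ints$channel_b[-1])
  rho_before <- cor(manifest$gc_fraction, rowMeans(raw_total),
                    method = "spearman")
  out <- normalize_and_gc_correct(ints$channel_a, manifest, ints$channel_b)
  rho_after <- cor(manifest$gc_fraction, rowMeans(as.matrix(out[-1])),
                   method = "spearman")
  expect_gt(abs(rho_before), 0.4)
  expect_lt(abs(rho_after), 0.05)
  expect_equal(attr(out, "channel_policy"), "sum")
})

test_that("non-positive intensities are rejected", {
  manifest <- flat_manifest(5)
  x <- tracks_from_matrix(matrix(c(1, 1, 0, 1, 1), 5, 1),
                          manifest$probe_id)
  expect_error(normalize_and_gc_correct(x, manifest), "strictly positive")
})

test_that("removing 0 batch components is the identity", {
  manifest <- flat_manifest(20)
  set.seed(25)
  x <- tracks_from_matrix(matrix(2^rnorm(20 * 6, 0, 0.2), 20, 6),
                          manifest$probe_id)
  out <- remove_batch_components(x, k = 0)
  expect_equal(as.matrix(out[-1]), as.matrix(x[-1]), ignore_attr = TRUE)
  expect_error(remove_batch_components(x, k = 6), "number of subjects")
})

test_that("residuals are orthogonal to every removed component", {
  manifest <- flat_manifest(25)
  set.seed(26)
  x <- tracks_from_matrix(matrix(2^rnorm(25 * 12, 0, 0.3), 25, 12),
                          manifest$probe_id)
  out <- remove_batch_components(x, k = 2)
  scores <- attr(out, "removed_scores")
  resid <- log2(as.matrix(out[-1]))
  resid <- resid - rowMeans(resid)
  cross <- resid %*% scores
  expect_lt(max(abs(cross)), 1e-8)
})

test_that("one strong batch axis is suppressed by removing one component", {
  regions <- tiny_regions()
  spec <- tiny_cohort(case_prev = c(regA = 0, regB = 0),
                      ctrl_prev = c(regA = 0, regB = 0), n = 20)
  truth <- simulate_cohort(spec, regions, seed = 27)
  manifest <- tiny_manifest(n = 50, platform = "beadchip")
  nm <- noise_model(probe_sd = 0.05, gc_coefficients = c(0, 0),
                    batch_effect_sd = 0.5)
  ints <- simulate_bead_intensities(truth, manifest, nm, regions, seed = 28)
  batch <- ints$batches$batch
  between_batch_var <- function(wide) {
    m <- colMeans(log2(as.matrix(wide[-1])))
    stats::var(tapply(m, batch, mean))
  }
  norm <- normalize_and_gc_correct(ints$channel_a, manifest,
                                   ints$channel_b)
  cleaned <- remove_batch_components(norm, k = 1)
  # median rescaling already removes a global batch shift, so measure the
  # batch axis on the raw combined input vs the fully processed output
  raw <- ints$channel_a
  raw[-1] <- tibble::as_tibble(as.matrix(ints$channel_a[-1]) +
                                 as.matrix(ints$channel_b[-1]))
  expect_lt(between_batch_var(cleaned), 0.1 * between_batch_var(raw))
})

test_that("a degenerate constant probe yields one component, all normal", {
  fit <- fit_probe_mixture(rep(0.3, 50))
  expect_equal(fit$n_components, 1L)
  expect_true(all(fit$states == 2L))
})

test_that("well-separated loss and normal clusters are called without error", {
  withr::with_seed(29, {
    x <- c(rnorm(85, 0, 0.05), rnorm(15, -1, 0.05))
  })
  fit <- fit_probe_mixture(x)
  expect_equal(fit$n_components, 2L)
  expect_equal(sum(fit$states == 1L), 15)
  expect_true(all(fit$states[86:100] == 1L))
  expect_true(all(fit$states[1:85] == 2L))
  # largest-weight component anchors the normal state
  expect_equal(which.max(fit$weights), 2L)
  td <- tidy(fit)
  expect_equal(td$mean, fit$means)
  expect_equal(sum(td$weight), 1, tolerance = 1e-8)
})

test_that("mixture means are recovered across replicates", {
  devs <- t(sapply(1:20, function(i) {
    withr::with_seed(1000 + i, {
      x <- c(rnorm(160, 0, 0.2), rnorm(40, -1, 0.2))
    })
    fit <- fit_probe_mixture(x)
    if (fit$n_components != 2) return(c(NA, NA))
    abs(fit$means - c(-1, 0))
  }))
  expect_true(all(!is.na(devs)))
  # 3 standard errors of each component mean
  expect_gt(mean(devs[, 1] <= 3 * 0.2 / sqrt(40) &
                   devs[, 2] <= 3 * 0.2 / sqrt(160)), 0.9)
})

test_that("the in-package mixture agrees with an independent EM fit", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::with_seed(30, {
    x <- c(rnorm(150, 0, 0.15), rnorm(50, -1, 0.15))
  })
  ours <- fit_probe_mixture(x)
  ref <- mclust::Mclust(x, G = 1:3, modelNames = "V", verbose = FALSE)
  expect_equal(ours$n_components, ref$G)
  expect_equal(sort(ours$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
})

test_that("the consecutive-marker rule drops isolated aberrant probes", {
  manifest <- flat_manifest(7)
  # isolated loss probe: no call
  expect_equal(nrow(call_segments(c(2, 2, 1, 2, 2, 2, 2), manifest)), 0)
  # strict alternation: no call
  expect_equal(nrow(call_segments(c(1, 2, 1, 2, 1, 2, 1), manifest)), 0)
  # two adjacent loss probes: exactly one call supported by both
  calls <- call_segments(c(2, 1, 1, 2, 2, 2, 2), manifest)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_probes, 2L)
  expect_equal(calls$state, "loss")
  expect_equal(calls$start, manifest$start[2])
  expect_equal(calls$end, manifest$end[3])
})

test_that("runs never merge across missing probes or chromosomes", {
  manifest <- flat_manifest(6)
  calls <- call_segments(c(1, 1, NA, 1, 1, 2), manifest)
  expect_equal(nrow(calls), 2)
  expect_true(all(calls$n_probes == 2))

  two_chrom <- manifest
  two_chrom$chrom <- rep(c("chr1", "chr2"), each = 3)
  calls2 <- call_segments(rep(1, 6), two_chrom)
  expect_equal(nrow(calls2), 2)
  expect_equal(sort(calls2$chrom), c("chr1", "chr2"))
})

test_that("gain runs are typed separately from losses", {
  manifest <- flat_manifest(8)
  calls <- call_segments(c(3, 3, 2, 1, 1, 1, 2, 2), manifest)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$state[order(calls$start)], c("gain", "loss"))
  expect_equal(sort(calls$n_probes), c(2L, 3L))
})

test_that("region status requires a two-probe overlap", {
  manifest <- flat_manifest(10, spacing = 1000)
  # region covers probes 1..5 (midpoints up to 4031)
  regions <- tibble::tibble(region = "r1", chrom = "chr1",
                            start = 1, end = manifest$end[5])
  # loss run on probes 5..8: only probe 5 inside the region
  calls <- call_segments(c(2, 2, 2, 2, 1, 1, 1, 1, 2, 2), manifest)
  status <- region_status_from_calls(calls, regions, manifest,
                                     subjects = "subject")
  expect_equal(status$status, "unchanged")
  # loss run on probes 4..8: two probes inside -> loss
  calls2 <- call_segments(c(2, 2, 2, 1, 1, 1, 1, 1, 2, 2), manifest)
  status2 <- region_status_from_calls(calls2, regions, manifest,
                                      subjects = "subject")
  expect_equal(status2$status, "loss")
  # no calls at all -> unchanged
  none <- call_segments(rep(2, 10), manifest)
  expect_equal(region_status_from_calls(none, regions, manifest,
                                        subjects = "subject")$status,
               "unchanged")
})

test_that("the caller is invariant to subject column order", {
  regions <- tiny_regions()
  spec <- tiny_cohort(n = 12)
  truth <- simulate_cohort(spec, regions, seed = 31)
  manifest <- tiny_manifest(n = 30, platform = "beadchip")
  ints <- simulate_bead_intensities(truth, manifest, noise_model(),
                                    regions, seed = 32)
  res1 <- call_beadchip(ints$channel_a, ints$channel_b, manifest, regions)
  perm <- c(1, sample(2:ncol(ints$channel_a)))
  res2 <- call_beadchip(ints$channel_a[perm], ints$channel_b[perm],
                        manifest, regions)
  s1 <- dplyr::arrange(res1$status, subject_id, region)
  s2 <- dplyr::arrange(res2$status, subject_id, region)
  expect_equal(s1, s2)
})

test_that("segment calls are maximal: no two calls touch", {
  manifest <- flat_manifest(12)
  withr::with_seed(33, {
    for (i in 1:30) {
      states <- sample(c(1L, 2L), 12, replace = TRUE)
      calls <- call_segments(states, manifest)
      if (nrow(calls) >= 2) {
        calls <- dplyr::arrange(calls, first_probe)
        gaps <- calls$first_probe[-1] - calls$last_probe[-nrow(calls)]
        expect_true(all(gaps >= 2))
      }
    }
  })
})

test_that("the bead caller recovers implanted losses on a small cohort", {
  regions <- tiny_regions()
  spec <- tiny_cohort(n = 25)
  truth <- simulate_cohort(spec, regions, seed = 34)
  # background probes anchor median normalization as on a genome-wide chip
  manifest <- make_probe_manifest(regions, n_probes = 30,
                                  platform = "beadchip",
                                  background_probes = 40)
  ints <- simulate_bead_intensities(truth, manifest, noise_model(),
                                    regions, seed = 35)
  res <- call_beadchip(ints$channel_a, ints$channel_b, manifest, regions)
  perf <- call_performance(res$status, truth_region_status(truth))
  overall <- perf[perf$region == "overall", ]
  expect_gte(overall$sensitivity, 0.9)
  expect_lte(overall$false_positive_rate, 0.05)
})
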