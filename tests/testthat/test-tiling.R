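# The aCGH validation segmenter: moving average, reference envelope,
# two-class thresholding, loss-segment extraction, concordance.

test_that("moving average reproduces hand-computed window means", {
  v <- c(0, 0, -1, -1, -1, 0, 0)
  tr <- tracks_from_matrix(matrix(v, ncol = 1))
  out <- moving_average(tr, window = 3)[[2]]
  expect_equal(out, c(0, -1 / 3, -2 / 3, -1, -2 / 3, -1 / 3, 0))
  # constant track stays constant under any window
  const <- tracks_from_matrix(matrix(0.37, 9, 1))
  expect_equal(moving_average(const, window = 5)[[2]], rep(0.37, 9))
  # window 1 is the identity
  expect_equal(moving_average(tr, window = 1)[[2]], v)
})

test_that("moving average handles missing values and window validation", {
  v <- c(1, NA, 1, NA, NA, NA, 2)
  tr <- tracks_from_matrix(matrix(v, ncol = 1))
  out <- moving_average(tr, window = 3)[[2]]
  expect_equal(out[1], 1)       # truncated window, NA ignored
  expect_equal(out[2], 1)       # mean of the two non-missing neighbours
  expect_true(is.na(out[5]))    # window entirely missing stays missing
  expect_equal(out[7], 2)
  expect_error(moving_average(tr, window = 4), "odd")
  expect_error(moving_average(tr, window = 0), "odd")
})

test_that("windows do not cross chromosome boundaries", {
  manifest <- flat_manifest(6)
  manifest$chrom <- rep(c("chr1", "chr2"), each = 3)
  m <- matrix(c(rep(-1, 3), rep(1, 3)), ncol = 1)
  tr <- tracks_from_matrix(m, manifest$probe_id)
  out <- moving_average(tr, window = 3, manifest = manifest)[[2]]
  expect_equal(out, c(-1, -1, -1, 1, 1, 1))
})

test_that("an identical-track panel gives the track as center, floored scale", {
  v <- seq(-0.2, 0.2, length.out = 10)
  panel <- tracks_from_matrix(matrix(rep(v, 4), ncol = 4))
  env <- build_reference_envelope(panel, sd_floor = 0.05)
  expect_equal(env$center, v)
  expect_equal(env$scale, rep(0.05, 10))
  expect_equal(attr(env, "panel_size"), 4)
  expect_error(build_reference_envelope(panel[, 1:3]), ">= 3")
})

test_that("per-probe scale estimates track the generating noise sd", {
  withr::with_seed(41, {
    m <- matrix(rnorm(200 * 50, 0, 0.2), 200, 50)
  })
  env <- build_reference_envelope(tracks_from_matrix(m), sd_floor = 0.01)
  # sampling distribution of the SD at n = 50: ~95% within [0.15, 0.25]
  expect_gte(mean(env$scale >= 0.15 & env$scale <= 0.25), 0.95)
})

test_that("the median center resists a grossly shifted outlier track", {
  withr::with_seed(42, {
    m <- matrix(rnorm(30 * 5, 0, 0.1), 30, 5)
  })
  env_clean <- build_reference_envelope(tracks_from_matrix(m))
  m_out <- m
  m_out[, 5] <- m_out[, 5] - 5
  env_out <- build_reference_envelope(tracks_from_matrix(m_out))
  expect_lt(max(abs(env_out$center - env_clean$center)), 0.2)
  # a mean center would have moved by about 1 unit
  env_mean <- build_reference_envelope(tracks_from_matrix(m_out),
                                       center = "mean")
  expect_gt(max(abs(env_mean$center - env_clean$center)), 0.8)
})

test_that("classification uses strict exceedance below center - 1 SD", {
  env <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        center = 0, scale = 0.2)
  vals <- matrix(c(-0.3, 0, -0.2), ncol = 1)
  tr <- tracks_from_matrix(vals, env$probe_id)
  cls <- classify_copy_number(tr, env)[[2]]
  expect_equal(cls, c("loss", "unchanged", "unchanged"))
  # upward deviations are unchanged; missing stays missing
  tr2 <- tracks_from_matrix(matrix(c(5, NA, -5), ncol = 1), env$probe_id)
  expect_equal(classify_copy_number(tr2, env)[[2]],
               c("unchanged", "missing", "loss"))
})

test_that("loss segments respect the minimum run and gap rules", {
  manifest <- flat_manifest(10)
  lab <- function(x) tracks_from_matrix(matrix(x, ncol = 1),
                                        manifest$probe_id)
  # all unchanged -> empty
  expect_equal(nrow(extract_loss_segments(lab(rep("unchanged", 10)),
                                          manifest)), 0)
  # a run of exactly min_probes - 1 -> empty
  r2 <- rep("unchanged", 10); r2[4:5] <- "loss"
  expect_equal(nrow(extract_loss_segments(lab(r2), manifest,
                                          min_probes = 3)), 0)
  # one long run -> one segment spanning first to last probe
  r3 <- rep("unchanged", 10); r3[3:9] <- "loss"
  seg <- extract_loss_segments(lab(r3), manifest)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_probes, 7L)
  expect_equal(seg$start, manifest$start[3])
  expect_equal(seg$end, manifest$end[9])
  # a missing label splits the run
  r4 <- rep("loss", 10); r4[5] <- "missing"
  seg4 <- extract_loss_segments(lab(r4), manifest)
  expect_equal(nrow(seg4), 2)
  # segments are disjoint and ordered
  expect_true(all(diff(seg4$start) > 0))
  expect_true(seg4$end[1] < seg4$start[2])
})

test_that("null exceedance is ~15.9% raw and collapses after smoothing", {
  manifest <- flat_manifest(2000)
  env <- tibble::tibble(probe_id = manifest$probe_id, center = 0,
                        scale = 0.2)
  withr::with_seed(43, {
    m <- matrix(rnorm(2000, 0, 0.2), ncol = 1)
  })
  tr <- tracks_from_matrix(m, manifest$probe_id)
  raw_rate <- mean(classify_copy_number(tr, env)[[2]] == "loss")
  expect_lt(abs(raw_rate - pnorm(-1)), 0.03)
  sm <- moving_average(tr, window = 11, manifest = manifest)
  sm_rate <- mean(classify_copy_number(sm, env)[[2]] == "loss")
  expect_lt(sm_rate, raw_rate / 3)
})

test_that("breakpoints are recovered within a window of truth on noiseless tracks", {
  regions <- tiny_regions()
  spec <- tiny_cohort(case_prev = c(regA = 1, regB = 0),
                      ctrl_prev = c(regA = 0, regB = 0), n = 4)
  truth <- simulate_cohort(spec, regions, seed = 44)
  manifest <- tiny_manifest(n = 120)
  clean <- noise_model(probe_sd = 0, gc_coefficients = c(0, 0),
                       batch_effect_sd = 0)
  tracks <- simulate_log2_tracks(truth, manifest, clean, regions, seed = 45)
  window <- 11
  res <- call_acgh(tracks, manifest,
                   panel_subjects = sprintf("ctrl_%03d", 1:4),
                   regions = regions, window = window)
  spacing <- median(diff(manifest$start[manifest$chrom == "chrA"]))
  for (s in sprintf("case_%03d", 1:4)) {
    d <- truth[truth$subject_id == s & truth$region == "regA", ]
    seg <- res$calls[res$calls$subject_id == s, ]
    expect_equal(nrow(seg), 1)
    expect_lt(abs(seg$start - d$del_start), window * spacing)
    expect_lt(abs(seg$end - d$del_end), window * spacing)
  }
})

test_that("concordance is 1 on identical matrices and 0 on disjoint loss sets", {
  status <- tibble::tibble(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    region = rep(c("regA", "regB"), 3),
    status = c("loss", "unchanged", "unchanged", "loss", "loss", "loss"))
  same <- concordance(status, status)
  expect_true(all(same$concordance[same$n_primary_loss > 0] == 1))
  flipped <- status
  flipped$status <- ifelse(status$status == "loss", "unchanged", "loss")
  none <- concordance(status, flipped)
  expect_true(all(none$concordance[none$n_primary_loss > 0] == 0))
  # empty intersection of loss carriers -> NA, not an error
  no_loss <- status; no_loss$status <- "unchanged"
  expect_true(all(is.na(concordance(no_loss, status)$concordance)))
})

test_that("aCGH recovers implanted losses on a small dual-platform cohort", {
  regions <- tiny_regions()
  spec <- tiny_cohort(n = 20)
  truth <- simulate_cohort(spec, regions, seed = 46)
  manifest <- tiny_manifest(n = 80)
  tracks <- simulate_log2_tracks(truth, manifest, noise_model(),
                                 regions, seed = 47)
  res <- call_acgh(tracks, manifest,
                   panel_subjects = sprintf("ctrl_%03d", 1:20),
                   regions = regions)
  perf <- call_performance(res$status, truth_region_status(truth))
  overall <- perf[perf$region == "overall", ]
  expect_gte(overall$sensitivity, 0.9)
  expect_lte(overall$false_positive_rate, 0.05)
})
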