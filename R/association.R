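# Case-control association statistics for region-level loss status:
# exact two-sided Fisher tests by hypergeometric enumeration, odds ratios
# with Woolf (log-OR normal) confidence intervals, chi-square comparisons
# of cohort characteristics, and combined multi-region loss counts.

# accepts a 2x2 matrix [[a,b],[c,d]] (rows = groups, cols =
# exposed/unexposed) or four counts
as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!identical(dim(a), c(2L, 2L))) abort("expected a 2x2 matrix")
    counts <- c(a[1, 1], a[1, 2], a[2, 1], a[2, 2])
  } else {
    counts <- c(a, b, c, d)
  }
  if (anyNA(counts) || min(counts) < 0 ||
      any(counts != floor(counts))) {
    abort("2x2 cells must be non-negative integers")
  }
  counts
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact P by hypergeometric enumeration over all tables with the
#' observed margins, summing the probabilities of every table no more
#' probable than the observed one (the minimum-likelihood two-sided
#' convention), clamped to 1.
#'
#' @param a,b,c,d Cell counts: `a` case-exposed, `b` case-unexposed, `c`
#'   control-exposed, `d` control-unexposed. `a` may instead be a 2x2
#'   matrix `rbind(c(a, b), c(c, d))`.
#' @return The two-sided P value.
#' @examples
#' fisher_exact_two_sided(15, 85, 3, 97) # 5.19e-3
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  cell <- as_2x2(a, b, c, d)
  if (sum(cell) == 0) abort("all-zero table: Fisher P undefined")
  r1 <- cell[1] + cell[2]
  r2 <- cell[3] + cell[4]
  k <- cell[1] + cell[3]
  if (r1 == 0 || r2 == 0) abort("a zero row margin makes the test undefined")
  support <- max(0, k - r2):min(k, r1)
  probs <- dhyper(support, r1, r2, k)
  p_obs <- probs[support == cell[1]]
  # relative tolerance guards ties at floating-point resolution
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = (a d) / (b c); the confidence interval is the log-OR normal
#' approximation `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any
#' zero cell triggers the Haldane-Anscombe correction (+0.5 to every
#' cell), recorded in the `haldane_correction` flag — never applied
#' silently.
#'
#' @inheritParams fisher_exact_two_sided
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `odds_ratio`, `conf_low`, `conf_high`,
#'   `conf_level`, `haldane_correction`.
#' @examples
#' odds_ratio_ci(15, 85, 3, 97) # OR 5.7, CI 1.6-20.4
#' @export
odds_ratio_ci <- function(a, b = NULL, c = NULL, d = NULL,
                          conf_level = 0.95) {
  cell <- as_2x2(a, b, c, d)
  haldane <- any(cell == 0)
  if (haldane) cell <- cell + 0.5
  or <- (cell[1] * cell[4]) / (cell[2] * cell[3])
  se <- sqrt(sum(1 / cell))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    odds_ratio = or,
    conf_low = exp(log(or) - z * se),
    conf_high = exp(log(or) + z * se),
    conf_level = conf_level,
    haldane_correction = haldane
  )
}

#' Pearson chi-square test
#'
#' Wraps [stats::chisq.test()]: Yates continuity correction on for 2x2
#' tables by default (switchable), off for larger tables.
#'
#' @param counts A contingency matrix, or the first of four 2x2 cell
#'   counts as in [fisher_exact_two_sided()].
#' @param b,c,d Remaining cells when `counts` is a single count.
#' @param correct Apply the continuity correction (2x2 only).
#' @return The P value.
#' @export
chi_square_test <- function(counts, b = NULL, c = NULL, d = NULL,
                            correct = TRUE) {
  if (!is.matrix(counts)) {
    counts <- matrix(as_2x2(counts, b, c, d), 2, 2, byrow = TRUE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero margin: chi-square test undefined")
  }
  suppressWarnings(chisq.test(counts, correct = correct)$p.value)
}

#' Convert HbA1c from the JDS to the NGSP scale
#'
#' NGSP-equivalent HbA1c (%) = JDS value (%) + 0.4, the conversion used
#' for Japanese cohorts measured against the former JDS standard.
#'
#' @param hba1c_jds HbA1c percentage on the JDS scale; must be
#'   non-negative.
#' @return HbA1c percentage on the NGSP scale.
#' @examples
#' ngsp_from_jds(5.1) # 5.5
#' @export
ngsp_from_jds <- function(hba1c_jds) {
  if (any(hba1c_jds < 0, na.rm = TRUE)) {
    abort("HbA1c cannot be negative")
  }
  hba1c_jds + 0.4
}

#' Combined multi-region loss status per subject
#'
#' Counts, for each subject, how many of the named regions carry a
#' copy-number loss, and flags subjects with loss in every one of them.
#' Missing statuses never count as loss.
#'
#' @param status Long status tibble (`subject_id`, `region`, `status`,
#'   optionally `group`).
#' @param region_subset Region labels to combine; defaults to all regions
#'   present.
#' @return Per-subject tibble: `subject_id` (and `group` if present),
#'   `n_loss`, `all_loss`.
#' @export
combined_loss_status <- function(status, region_subset = NULL) {
  region_subset <- region_subset %||% unique(status$region)
  unknown <- setdiff(region_subset, unique(status$region))
  if (length(unknown) > 0) {
    abort(paste0("unknown region label(s): ",
                 paste(unknown, collapse = ", ")))
  }
  sub <- status[status$region %in% region_subset, ]
  keys <- intersect(c("subject_id", "group"), names(sub))
  out <- dplyr::summarise(
    dplyr::group_by(sub, dplyr::across(dplyr::all_of(keys))),
    n_loss = sum(.data$status == "loss", na.rm = TRUE),
    .groups = "drop")
  out$all_loss <- out$n_loss == length(region_subset)
  out
}

# 2x2 for one region: rows case/control, cols loss/other
region_table <- function(status, region) {
  sub <- status[status$region == region, ]
  if (!all(c("case", "control") %in% sub$group)) {
    abort("both case and control groups are required for association")
  }
  a <- sum(sub$group == "case" & sub$status == "loss")
  b <- sum(sub$group == "case" & sub$status != "loss")
  c_ <- sum(sub$group == "control" & sub$status == "loss")
  d <- sum(sub$group == "control" & sub$status != "loss")
  matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("loss", "other")))
}

#' Per-region case-control association
#'
#' For every region, builds the case/control x loss/other 2x2 table and
#' computes the exact two-sided Fisher P and the odds ratio with its
#' Woolf confidence interval.
#'
#' @param status Long status tibble with a `group` column
#'   ("case"/"control").
#' @param regions Region labels to test; defaults to all present.
#' @param conf_level Confidence level for the OR interval.
#' @return Tibble, one row per region: cell counts `a`-`d`, `p_fisher`,
#'   `odds_ratio`, `conf_low`, `conf_high`, `haldane_correction`.
#' @export
region_association <- function(status, regions = NULL, conf_level = 0.95) {
  regions <- regions %||% unique(status$region)
  purrr::map_dfr(regions, function(rl) {
    tab <- region_table(status, rl)
    orci <- odds_ratio_ci(tab, conf_level = conf_level)
    tibble::tibble(
      region = rl,
      a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
      p_fisher = fisher_exact_two_sided(tab),
      odds_ratio = orci$odds_ratio,
      conf_low = orci$conf_low, conf_high = orci$conf_high,
      haldane_correction = orci$haldane_correction
    )
  })
}

# compare one clinical variable between two subject groups
compare_clinical_variable <- function(v, in_a) {
  v_a <- v[in_a]
  v_b <- v[!in_a]
  if (is.numeric(v)) {
    p <- tryCatch(t.test(v_a, v_b)$p.value, error = function(e) NA_real_)
    tibble::tibble(
      summary_group1 = sprintf("%.1f±%.1f", mean(v_a, na.rm = TRUE),
                               sd(v_a, na.rm = TRUE)),
      summary_group2 = sprintf("%.1f±%.1f", mean(v_b, na.rm = TRUE),
                               sd(v_b, na.rm = TRUE)),
      test = "welch_t", p_value = p)
  } else {
    tab <- table(factor(in_a, c(TRUE, FALSE)), as.character(v))
    p <- if (any(dim(tab) < 2)) NA_real_ else
      suppressWarnings(chisq.test(tab)$p.value)
    lvl <- utils::tail(sort(unique(as.character(v))), 1)
    tibble::tibble(
      summary_group1 = sprintf("%d/%d", sum(v_a == lvl, na.rm = TRUE),
                               sum(!is.na(v_a))),
      summary_group2 = sprintf("%d/%d", sum(v_b == lvl, na.rm = TRUE),
                               sum(!is.na(v_b))),
      test = "chi_square", p_value = p)
  }
}

#' Full association report
#'
#' The complete statistical read-out for a status matrix: per-region 2x2
#' association (Fisher P, OR, CI), the combined-loss cross-tabulation
#' (how many subjects of each group carry losses in exactly 0, 1, ...,
#' all of the regions, with Fisher tests for the all-regions and
#' exactly-two-regions contrasts), and — when clinical records are given
#' — a comparison of clinical characteristics between all-region-loss
#' cases and the remaining cases (Welch t for continuous variables,
#' chi-square for proportions).
#'
#' @param status Long status tibble with `group`.
#' @param clinical Optional clinical tibble with `subject_id` plus
#'   characteristic columns (numeric or categorical).
#' @param regions Region labels; defaults to all present.
#' @param conf_level Confidence level for OR intervals.
#' @return A `cnv_association_report` list: `per_region`, `combined`
#'   (`by_count` tibble + `p_all_regions` + `p_exactly_two`), `clinical`
#'   (tibble or NULL), `n_cases`, `n_controls`.
#' @export
association_report <- function(status, clinical = NULL, regions = NULL,
                               conf_level = 0.95) {
  if (nrow(status) == 0) abort("empty status matrix")
  regions <- regions %||% unique(status$region)
  per_region <- region_association(status, regions, conf_level)

  combined <- combined_loss_status(status, regions)
  by_count <- dplyr::count(combined, .data$group, .data$n_loss,
                           name = "n_subjects")
  by_count <- tidyr::complete(
    by_count, group = c("case", "control"),
    n_loss = 0:length(regions), fill = list(n_subjects = 0L))
  n_cases <- sum(combined$group == "case")
  n_controls <- sum(combined$group == "control")
  count_of <- function(grp, cond) sum(combined$n_loss[combined$group == grp]
                                      %in% cond)
  k <- length(regions)
  p_all <- fisher_exact_two_sided(
    count_of("case", k), n_cases - count_of("case", k),
    count_of("control", k), n_controls - count_of("control", k))
  p_two <- if (k >= 2) fisher_exact_two_sided(
    count_of("case", k - 1), n_cases - count_of("case", k - 1),
    count_of("control", k - 1), n_controls - count_of("control", k - 1))
  else NA_real_

  clin_tbl <- NULL
  if (!is.null(clinical)) {
    cases <- combined[combined$group == "case", ]
    clin <- dplyr::inner_join(clinical, cases, by = "subject_id")
    vars <- setdiff(names(clinical), "subject_id")
    clin_tbl <- purrr::map_dfr(vars, function(v) {
      dplyr::bind_cols(tibble::tibble(variable = v),
                       compare_clinical_variable(clin[[v]], clin$all_loss))
    })
  }

  structure(list(per_region = per_region,
                 combined = list(by_count = by_count,
                                 p_all_regions = p_all,
                                 p_exactly_two = p_two),
                 clinical = clin_tbl,
                 n_cases = n_cases, n_controls = n_controls,
                 regions = regions),
            class = "cnv_association_report")
}

#' @export
print.cnv_association_report <- function(x, digits = 3, ...) {
  cat("Case-control CNV association:", x$n_cases, "cases,",
      x$n_controls, "controls\n\nPer-region:\n")
  pr <- x$per_region
  for (i in seq_len(nrow(pr))) {
    cat(sprintf(
      "  %-12s loss %d/%d vs %d/%d  P = %.3g  OR = %.1f (%.1f-%.1f)%s\n",
      pr$region[i], pr$a[i], pr$a[i] + pr$b[i], pr$c[i],
      pr$c[i] + pr$d[i], pr$p_fisher[i], pr$odds_ratio[i],
      pr$conf_low[i], pr$conf_high[i],
      ifelse(pr$haldane_correction[i], " [Haldane-corrected]", "")))
  }
  cat(sprintf("\nLoss in all %d regions: P = %.3g (Fisher, two-sided)\n",
              length(x$regions), x$combined$p_all_regions))
  if (!is.na(x$combined$p_exactly_two)) {
    cat(sprintf("Loss in exactly %d regions: P = %.3g\n",
                length(x$regions) - 1, x$combined$p_exactly_two))
  }
  if (!is.null(x$clinical)) {
    cat("\nClinical characteristics (all-region-loss vs other cases):\n")
    print(as.data.frame(x$clinical), row.names = FALSE)
  }
  invisible(x)
}

#' @rdname association_report
#' @param x A `cnv_association_report`.
#' @param ... Unused.
#' @export
tidy.cnv_association_report <- function(x, ...) {
  x$per_region
}

#' @rdname association_report
#' @export
glance.cnv_association_report <- function(x, ...) {
  tibble::tibble(
    n_cases = x$n_cases, n_controls = x$n_controls,
    n_regions = length(x$regions),
    p_all_regions = x$combined$p_all_regions,
    p_exactly_two = x$combined$p_exactly_two,
    min_p_region = min(x$per_region$p_fisher)
  )
}

#' Build a status matrix from per-region loss counts
#'
#' Constructs a long status tibble in which the first `case_counts[r]`
#' cases and first `control_counts[r]` controls carry a loss in region
#' `r`. Marginal per-region counts are exact; the joint (multi-region)
#' structure is the nested one implied by "first k subjects", so only
#' marginal statistics should be read off such a matrix.
#'
#' @param case_counts,control_counts Named integer vectors, region ->
#'   loss count.
#' @param n_cases,n_controls Group sizes.
#' @return Long status tibble (`subject_id`, `group`, `region`,
#'   `status`).
#' @export
status_from_counts <- function(case_counts, control_counts,
                               n_cases = 100, n_controls = 100) {
  stopifnot(identical(sort(names(case_counts)),
                      sort(names(control_counts))),
            all(case_counts <= n_cases), all(control_counts <= n_controls))
  subjects <- tibble::tibble(
    subject_id = c(sprintf("case_%03d", seq_len(n_cases)),
                   sprintf("ctrl_%03d", seq_len(n_controls))),
    group = rep(c("case", "control"), c(n_cases, n_controls)))
  purrr::map_dfr(names(case_counts), function(rl) {
    loss <- c(seq_len(n_cases) <= case_counts[[rl]],
              seq_len(n_controls) <= control_counts[[rl]])
    dplyr::mutate(subjects, region = rl,
                  status = ifelse(loss, "loss", "unchanged"))
  })
}
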