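# The four-stage bead-array loss/gain caller: (1) intensity normalization
# and GC correction, (2) batch-effect removal by principal components,
# (3) per-probe Gaussian-mixture cluster calling across subjects, and
# (4) copy-state typing with a consecutive-marker stretch rule. The
# vendor's normalization equation is unpublished; stage (1) here is
# median rescaling plus per-subject quadratic GC residualization.

# wide tibble (probe_id + subject columns) -> matrix with dimnames
as_probe_matrix <- function(wide, manifest = NULL) {
  if (!"probe_id" %in% names(wide)) abort("expected a probe_id column")
  m <- as.matrix(wide[, setdiff(names(wide), "probe_id"), drop = FALSE])
  rownames(m) <- wide$probe_id
  if (!is.null(manifest)) {
    if (!identical(wide$probe_id, manifest$probe_id)) {
      abort("probe_id order does not match the manifest")
    }
  }
  m
}

as_probe_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' Normalize bead intensities and remove GC bias
#'
#' Stage 1 of the bead-array caller. The two colour channels are combined
#' by summation, every subject is rescaled so its median intensity equals
#' the cohort's common median, and the GC trend is removed per subject by
#' regressing log2 intensity on a quadratic in probe GC fraction and
#' keeping residuals plus the subject's grand mean. Output stays on the
#' raw intensity scale.
#'
#' @param intensities Wide tibble (`probe_id` + one column per subject):
#'   channel A, or already-combined intensities.
#' @param manifest Beadchip probe manifest (supplies `gc_fraction`).
#' @param channel_b Optional second-channel wide tibble, summed into the
#'   first.
#' @return Wide tibble of normalized intensities with attribute
#'   `channel_policy` ("sum" or "single").
#' @export
normalize_and_gc_correct <- function(intensities, manifest,
                                     channel_b = NULL) {
  validate_manifest(manifest)
  x <- as_probe_matrix(intensities, manifest)
  policy <- "single"
  if (!is.null(channel_b)) {
    x <- x + as_probe_matrix(channel_b, manifest)
    policy <- "sum"
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("raw intensities must be strictly positive and finite")
  }
  med <- apply(x, 2, median)
  target <- median(med)
  x <- sweep(x, 2, med, `/`) * target

  l <- log2(x)
  gc <- manifest$gc_fraction
  gc2 <- gc^2
  corrected <- apply(l, 2, function(col) {
    fit <- lm(col ~ gc + gc2)
    residuals(fit) + mean(col)
  })
  rownames(corrected) <- rownames(x)
  out <- as_probe_tibble(2^corrected)
  attr(out, "channel_policy") <- policy
  out
}

#' Remove leading principal components (batch effects)
#'
#' Stage 2 of the bead-array caller. On the probe-centered log2 matrix,
#' the top `k` principal components across subjects are projected out;
#' systematic batch axes load on these leading components while the
#' localized copy-number signal does not. `k = 0` is the identity.
#'
#' @param normalized Wide tibble from [normalize_and_gc_correct()].
#' @param k Number of components to remove; must be < number of subjects.
#' @return Wide tibble on the same scale, with attribute `removed_scores`
#'   (subjects x k matrix of the removed component scores).
#' @export
remove_batch_components <- function(normalized, k = 2) {
  x <- as_probe_matrix(normalized)
  n_subj <- ncol(x)
  if (k < 0 || k >= n_subj) {
    abort("k must satisfy 0 <= k < number of subjects")
  }
  if (k == 0) {
    out <- as_probe_tibble(x)
    attr(out, "removed_scores") <- matrix(0, n_subj, 0)
    return(out)
  }
  l <- log2(x)
  rm_mean <- rowMeans(l)
  lc <- l - rm_mean
  sv <- svd(lc, nu = k, nv = k)
  removed <- sv$u %*% diag(sv$d[seq_len(k)], k, k) %*% t(sv$v)
  out <- as_probe_tibble(2^(lc - removed + rm_mean))
  scores <- sv$v
  rownames(scores) <- colnames(x)
  attr(out, "removed_scores") <- scores
  out
}

#' Call per-probe copy states across subjects
#'
#' Stage 3: fits a per-probe Gaussian mixture ([fit_probe_mixture()]) to
#' log2 normalized intensities and returns the copy-state assignment.
#'
#' @param normalized Wide tibble of normalized (batch-corrected)
#'   intensities.
#' @param manifest Beadchip probe manifest in the same probe order.
#' @param max_components Largest mixture order tried per probe.
#' @return List: `states`, a wide tibble (`probe_id` + per-subject integer
#'   state 1 = loss, 2 = normal, 3 = gain, NA = missing), and `mixtures`,
#'   a per-probe tibble of the selected order and component means.
#' @export
call_probe_states <- function(normalized, manifest, max_components = 3) {
  x <- log2(as_probe_matrix(normalized, manifest))
  fits <- apply(x, 1, fit_probe_mixture, max_components = max_components,
                simplify = FALSE)
  states <- do.call(rbind, lapply(fits, `[[`, "states"))
  dimnames(states) <- dimnames(x)
  mixtures <- tibble::tibble(
    probe_id = rownames(x),
    n_components = vapply(fits, `[[`, integer(1), "n_components"),
    means = lapply(fits, `[[`, "means"),
    weights = lapply(fits, `[[`, "weights")
  )
  list(states = as_probe_tibble(states), mixtures = mixtures)
}

# Maximal runs of >= min_probes consecutive probes sharing an aberrant
# state, never crossing a chromosome boundary or a missing-value probe.
segment_runs <- function(state_vec, manifest, min_probes = 2) {
  state_vec <- unname(state_vec)
  out <- list()
  for (ch in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == ch)
    s <- state_vec[idx]
    key <- ifelse(is.na(s), "NA", as.character(s))
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values %in% c("1", "3") & r$lengths >= min_probes
    for (j in which(keep)) {
      first <- idx[starts[j]]
      last <- idx[ends[j]]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch,
        start = manifest$start[first],
        end = manifest$end[last],
        state = if (r$values[j] == "1") "loss" else "gain",
        n_probes = r$lengths[j],
        first_probe = first, last_probe = last
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), state = character(),
                          n_probes = integer(), first_probe = integer(),
                          last_probe = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Extract CNV segment calls with the consecutive-marker rule
#'
#' Stage 4: a stretch of two or more consecutive probes sharing an
#' aberrant copy state becomes one maximal segment call; an isolated
#' aberrant probe is treated as noise and produces no call. Runs never
#' extend across missing-value probes or chromosome boundaries. The call
#' interval spans the first to the last supporting probe.
#'
#' @param states Wide tibble of per-probe states (from
#'   [call_probe_states()]) or a single subject's integer vector.
#' @param manifest Probe manifest aligned to the states.
#' @param min_probes Minimum run length (default 2: "more than one
#'   marker").
#' @return Tibble of calls: `subject_id`, `chrom`, `start`, `end`,
#'   `state`, `n_probes`, `first_probe`, `last_probe`.
#' @export
call_segments <- function(states, manifest, min_probes = 2) {
  validate_manifest(manifest)
  if (min_probes < 2) abort("min_probes must be >= 2 (stretch rule)")
  if (is.data.frame(states)) {
    m <- as_probe_matrix(states, manifest)
    calls <- purrr::map(colnames(m), function(s) {
      seg <- segment_runs(m[, s], manifest, min_probes)
      if (nrow(seg) > 0) seg$subject_id <- s
      seg
    })
    out <- dplyr::bind_rows(calls)
  } else {
    if (length(states) != nrow(manifest)) {
      abort("states length does not match the manifest")
    }
    out <- segment_runs(states, manifest, min_probes)
    if (nrow(out) > 0) out$subject_id <- "subject"
  }
  if (nrow(out) == 0) {
    out$subject_id <- character()
  }
  dplyr::relocate(out, "subject_id")
}

#' Dichotomize regions from segment calls
#'
#' A region is labelled `"loss"` for a subject when at least one loss call
#' overlaps it by `min_overlap_probes` (default 2) of its supporting
#' probes; a single-probe overlap is treated as noise. Gains are tracked
#' the same way; loss takes precedence if both occur. Everything else is
#' `"unchanged"`.
#'
#' @param calls Call tibble from [call_segments()] (or
#'   [extract_loss_segments()]).
#' @param regions Region tibble.
#' @param manifest Probe manifest the calls were made on.
#' @param subjects Subject ids to report (so no-call subjects still get
#'   "unchanged" rows); defaults to the subjects present in `calls`.
#' @param min_overlap_probes Minimum supporting probes inside the region.
#' @return Long status tibble: `subject_id`, `region`, `status`.
#' @export
region_status_from_calls <- function(calls, regions, manifest,
                                     subjects = NULL,
                                     min_overlap_probes = 2) {
  validate_regions(regions)
  subjects <- subjects %||% unique(calls$subject_id)
  mid <- (manifest$start + manifest$end) / 2
  grid <- tidyr::expand_grid(subject_id = subjects,
                             region = regions$region)
  grid$status <- "unchanged"
  if (nrow(calls) > 0) {
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      for (j in seq_len(nrow(calls))) {
        probes <- seq(calls$first_probe[j], calls$last_probe[j])
        n_in <- sum(manifest$chrom[probes] == r$chrom &
                      mid[probes] >= r$start & mid[probes] <= r$end)
        if (n_in >= min_overlap_probes) {
          row <- grid$subject_id == calls$subject_id[j] &
            grid$region == r$region
          cur <- grid$status[row]
          new <- calls$state[j]
          grid$status[row] <- ifelse(cur == "loss", "loss", new)
        }
      }
    }
  }
  grid
}

#' Run the full bead-array caller
#'
#' Chains the four stages: normalization + GC correction, principal
#' component batch removal, per-probe mixture calling, and segment/region
#' typing with the consecutive-marker rule.
#'
#' @param channel_a,channel_b Wide intensity tibbles (one per colour
#'   channel; `channel_b` may be `NULL` for pre-combined input).
#' @param manifest Beadchip probe manifest.
#' @param regions Region tibble for dichotomization.
#' @param k_pcs Principal components removed as batch effects. The
#'   default 0 suits region-targeted manifests, where common deletions —
#'   not batches — dominate the leading components; raise it only for
#'   genome-scale manifests in which CNV probes are a negligible
#'   fraction.
#' @param min_probes Consecutive-marker threshold.
#' @param max_components Largest per-probe mixture order.
#' @return A `beadchip_calls` list: `status` (subject x region long
#'   tibble), `calls`, `states`, `mixtures`, and the parameters used.
#' @export
call_beadchip <- function(channel_a, channel_b = NULL, manifest,
                          regions = builtin_regions(), k_pcs = 0,
                          min_probes = 2, max_components = 3) {
  normalized <- normalize_and_gc_correct(channel_a, manifest, channel_b)
  corrected <- remove_batch_components(normalized, k = k_pcs)
  st <- call_probe_states(corrected, manifest,
                          max_components = max_components)
  subjects <- setdiff(names(st$states), "probe_id")
  calls <- call_segments(st$states, manifest, min_probes = min_probes)
  status <- region_status_from_calls(calls, regions, manifest,
                                     subjects = subjects,
                                     min_overlap_probes = min_probes)
  structure(list(status = status, calls = calls, states = st$states,
                 mixtures = st$mixtures,
                 params = list(k_pcs = k_pcs, min_probes = min_probes,
                               max_components = max_components)),
            class = "beadchip_calls")
}

#' @export
print.beadchip_calls <- function(x, ...) {
  cat("Bead-array CNV calls:",
      length(unique(x$status$subject_id)), "subjects,",
      nrow(x$calls), "segment call(s)\n")
  print(dplyr::count(x$status, .data$region, .data$status))
  invisible(x)
}
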