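# Small in-code fixtures shared across the suite. Everything is built
# programmatically; nothing is read from disk except round-trip tests
# that write into tempdir().

# two tiny regions on separate chromosomes, 100 kb each
tiny_regions <- function() {
  tibble::tibble(
    region = c("regA", "regB"),
    chrom = c("chrA", "chrB"),
    start = c(1e5, 5e5),
    end = c(2e5 - 1, 6e5 - 1),
    assembly = "synthetic"
  )
}

# manifest of n probes per tiny region
tiny_manifest <- function(n = 50, platform = "tiling") {
  make_probe_manifest(tiny_regions(), n_probes = n, platform = platform)
}

# a cohort spec sized for fast unit tests
tiny_cohort <- function(case_prev = c(regA = 0.3, regB = 0.2),
                        ctrl_prev = c(regA = 0.05, regB = 0.05),
                        n = 30) {
  cohort_spec(n_cases = n, n_controls = n,
              case_prevalence = case_prev, control_prevalence = ctrl_prev,
              deletion_span_frac = c(0.5, 0.9), n_batches = 2)
}

# wide track tibble from a plain matrix
tracks_from_matrix <- function(m, probe_ids = NULL) {
  probe_ids <- probe_ids %||% sprintf("p%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(probe_id = probe_ids),
                   tibble::as_tibble(m))
}

# single-chromosome manifest of n probes for sequence-rule tests;
# gc varies smoothly so GC regression designs are non-degenerate
flat_manifest <- function(n, spacing = 1000, width = 60) {
  tibble::tibble(
    chrom = "chr1",
    start = seq(1, by = spacing, length.out = n),
    end = seq(1, by = spacing, length.out = n) + width - 1,
    probe_id = sprintf("p%03d", seq_len(n)),
    gc_fraction = seq(0.35, 0.65, length.out = n)
  )
}

`%||%` <- rlang::`%||%`
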