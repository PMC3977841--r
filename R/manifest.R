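# Probe manifests: the ordered coordinate backbone shared by both array
# platforms. A manifest is a tibble with columns chrom, start, end,
# probe_id, gc_fraction, sorted by (chrom, start), plus a "platform"
# attribute ("beadchip" or "tiling").

manifest_cols <- c("chrom", "start", "end", "probe_id", "gc_fraction")

#' Validate a probe manifest
#'
#' Checks the manifest contract: required columns, numeric coordinates with
#' `end >= start >= 1`, unique probe ids, GC fractions in \[0, 1\], rows
#' sorted by chromosome then start.
#'
#' @param manifest Manifest tibble.
#' @return The manifest, invisibly; errors describe the first violation.
#' @export
validate_manifest <- function(manifest) {
  missing_cols <- setdiff(manifest_cols, names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(manifest$start) | !is.finite(manifest$end) |
                 manifest$start < 1 | manifest$end < manifest$start)
  if (length(bad) > 0) {
    abort(paste0("invalid probe coordinates at row ", bad[1]))
  }
  bad_gc <- which(!is.finite(manifest$gc_fraction) |
                    manifest$gc_fraction < 0 | manifest$gc_fraction > 1)
  if (length(bad_gc) > 0) {
    abort(paste0("gc_fraction outside [0,1] at row ", bad_gc[1]))
  }
  if (anyDuplicated(manifest$probe_id)) {
    dup <- manifest$probe_id[duplicated(manifest$probe_id)][1]
    abort(paste0("duplicate probe_id: ", dup))
  }
  ord <- order(manifest$chrom, manifest$start)
  if (!identical(ord, seq_len(nrow(manifest)))) {
    abort("manifest rows not sorted by (chrom, start)")
  }
  invisible(manifest)
}

#' Read a probe manifest from TSV
#'
#' Expects tab-separated columns `chrom`, `start`, `end`, `probe_id`,
#' `gc_fraction`; a header line is optional (detected by a non-numeric
#' second field on line 1). Rows out of coordinate order are sorted, not
#' rejected. Malformed rows (non-numeric coordinate, GC outside \[0,1\])
#' raise an error naming the offending line; duplicate probe ids raise a
#' validation error.
#'
#' @param path Path to the TSV file.
#' @param platform `"beadchip"` or `"tiling"`, recorded as an attribute.
#' @return Manifest tibble sorted by (chrom, start).
#' @export
read_probe_manifest <- function(path, platform = c("beadchip", "tiling")) {
  platform <- match.arg(platform)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty manifest file")
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  # a header has non-numeric start AND gc fields; a merely malformed data
  # row is parsed (and rejected) as data
  has_header <- length(first) >= 5 &&
    is.na(suppressWarnings(as.numeric(first[2]))) &&
    is.na(suppressWarnings(as.numeric(first[5])))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  if (length(body) == 0) abort("manifest file has no data rows")
  rows <- strsplit(body, "\t", fixed = TRUE)
  parsed <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    line_no <- i + offset
    if (length(f) < 5) {
      abort(paste0("line ", line_no, ": expected 5 tab-separated fields"))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    gc <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end)) {
      abort(paste0("line ", line_no, ": non-numeric coordinate"))
    }
    if (is.na(gc) || gc < 0 || gc > 1) {
      abort(paste0("line ", line_no, ": gc_fraction outside [0,1]"))
    }
    if (start < 1 || end < start) {
      abort(paste0("line ", line_no, ": invalid interval ", start, "-", end))
    }
    parsed[[i]] <- tibble::tibble(
      chrom = f[1], start = start, end = end,
      probe_id = f[4], gc_fraction = gc
    )
  }
  manifest <- dplyr::arrange(dplyr::bind_rows(parsed), .data$chrom, .data$start)
  validate_manifest(manifest)
  attr(manifest, "platform") <- platform
  manifest
}

#' Write a probe manifest
#'
#' `write_probe_manifest()` writes the native TSV (1-based inclusive, with
#' header). `write_probe_bed()` exports BED5 in the standard 0-based
#' half-open dialect, with `gc_fraction` in the score column.
#'
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_probe_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest[, manifest_cols], path)
  invisible(path)
}

#' @rdname write_probe_manifest
#' @export
write_probe_bed <- function(manifest, path) {
  validate_manifest(manifest)
  bed <- tibble::tibble(
    chrom = manifest$chrom,
    start = manifest$start - 1,   # 0-based
    end = manifest$end,           # half-open: inclusive end + 1 - 1
    name = manifest$probe_id,
    score = manifest$gc_fraction
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Generate an evenly spaced probe manifest over a region set
#'
#' Lays `n_probes` probes per region at even spacing, with a smooth
#' sinusoidal GC profile (mean 0.45, amplitude 0.15) standing in for local
#' GC content. Used to build test and simulation backbones; real manifests
#' come in via [read_probe_manifest()].
#'
#' @param regions Region tibble as from [builtin_regions()].
#' @param n_probes Probes per region (recycled across regions).
#' @param probe_width Probe footprint in bp (60 = oligo tiling probes).
#' @param platform `"beadchip"` or `"tiling"`.
#' @param background_probes Number of copy-neutral probes added on a
#'   separate background chromosome (`chrBG`). A genome-wide bead chip is
#'   copy-neutral at almost all of its probes for any one subject, which
#'   is what anchors per-subject median normalization; a manifest
#'   truncated to the target regions loses that anchor for subjects whose
#'   deletions span most probes, so beadchip simulations should carry a
#'   background.
#' @return Manifest tibble.
#' @export
make_probe_manifest <- function(regions, n_probes = 100, probe_width = 60,
                                platform = c("beadchip", "tiling"),
                                background_probes = 0) {
  platform <- match.arg(platform)
  validate_regions(regions)
  if (background_probes > 0) {
    regions <- dplyr::bind_rows(
      regions[, c("region", "chrom", "start", "end")],
      tibble::tibble(region = "background", chrom = "chrBG", start = 1,
                     end = background_probes * 5000))
    n_probes <- c(rep_len(n_probes, nrow(regions) - 1), background_probes)
  }
  n_probes <- rep_len(n_probes, nrow(regions))
  pieces <- purrr::map(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    pos <- round(seq(r$start, r$end - probe_width + 1,
                     length.out = n_probes[i]))
    tibble::tibble(
      chrom = r$chrom,
      start = pos,
      end = pos + probe_width - 1,
      probe_id = sprintf("%s_p%04d", gsub("[^A-Za-z0-9]", "", r$region),
                         seq_len(n_probes[i])),
      gc_fraction = 0.45 + 0.15 * sin(seq(0, 6 * pi, length.out = n_probes[i]))
    )
  })
  manifest <- dplyr::arrange(dplyr::bind_rows(pieces), .data$chrom, .data$start)
  validate_manifest(manifest)
  attr(manifest, "platform") <- platform
  manifest
}

# Index of manifest probes whose footprint lies inside an interval set.
# Returns a logical vector over manifest rows; a probe counts as inside
# when its midpoint falls within any interval of the set.
probes_in_intervals <- function(manifest, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, nrow(manifest)))
  }
  mid <- (manifest$start + manifest$end) / 2
  hit <- rep(FALSE, nrow(manifest))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (manifest$chrom == intervals$chrom[i] &
                    mid >= intervals$start[i] & mid <= intervals$end[i])
  }
  hit
}
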