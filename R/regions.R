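# Genomic coordinates are 1-based and inclusive on both ends (NCBI-style),
# matching Build 36 positions throughout. The only place the half-open,
# 0-based dialect appears is BED export.

#' The three subtelomeric target regions
#'
#' Returns the subtelomeric regions screened for copy-number loss in
#' early-onset type 2 diabetes: 16q24.2-3 (chr16:86,950,000-88,700,000,
#' 1.75 Mb) and 22q13.31-33 (chr22:44,750,000-49,550,000, 4.8 Mb) on
#' NCBI Build 36 (hg18), plus the 1.3-Mb 4p16.3 region from the preceding
#' study. The 4p16.3 bounds were never published at base-pair resolution,
#' so a placeholder interval of the right span is used by default and can
#' be overridden.
#'
#' @param region_4p Length-3 list or vector `(chrom, start, end)` overriding
#'   the 4p16.3 placeholder coordinates.
#' @return A tibble with columns `region`, `chrom`, `start`, `end`,
#'   `assembly`; one row per region, coordinates 1-based inclusive.
#' @examples
#' builtin_regions()
#' @export
builtin_regions <- function(region_4p = list("chr4", 1L, 1300000L)) {
  stopifnot(length(region_4p) == 3)
  tbl <- tibble::tibble(
    region = c("4p16.3", "16q24.2-3", "22q13.31-33"),
    chrom = c(as.character(region_4p[[1]]), "chr16", "chr22"),
    start = c(as.numeric(region_4p[[2]]), 86950000, 44750000),
    end   = c(as.numeric(region_4p[[3]]), 88700000, 49550000),
    assembly = "NCBI36/hg18"
  )
  validate_regions(tbl)
  tbl
}

validate_regions <- function(regions) {
  req <- c("region", "chrom", "start", "end")
  missing_cols <- setdiff(req, names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("region table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(regions$region)) abort("region labels must be unique")
  if (any(regions$start < 1)) abort("region start must be >= 1")
  if (any(regions$end < regions$start)) abort("region end must be >= start")
  invisible(regions)
}

#' Interval length in base pairs
#'
#' Length of a 1-based inclusive interval: `end - start + 1`.
#'
#' @param start,end Interval bounds (vectors recycle).
#' @return Numeric vector of lengths.
#' @export
interval_length <- function(start, end) {
  end - start + 1
}

#' Overlap between two genomic intervals
#'
#' Base pairs shared by two 1-based inclusive intervals; 0 when the
#' chromosomes differ or the intervals are disjoint. Vectorised.
#'
#' @param chrom_a,start_a,end_a First interval.
#' @param chrom_b,start_b,end_b Second interval.
#' @return Non-negative base-pair counts.
#' @examples
#' overlap_length("chr16", 100, 200, "chr16", 150, 250) # 51
#' @export
overlap_length <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  same <- as.character(chrom_a) == as.character(chrom_b)
  ov <- pmin(end_a, end_b) - pmax(start_a, start_b) + 1
  ifelse(same, pmax(0, ov), 0)
}

#' Read or write a region set
#'
#' Region sets are TSV files with columns `region`, `chrom`, `start`, `end`
#' (1-based inclusive). Low-coverage gap intervals use the same shape and
#' are carried as a separate table.
#'
#' @param path File path.
#' @return `read_region_set()` returns a validated tibble.
#' @export
read_region_set <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double()
  ))
  validate_regions(tbl)
  tbl
}

#' @rdname read_region_set
#' @param regions Region tibble to write.
#' @export
write_region_set <- function(regions, path) {
  validate_regions(regions)
  readr::write_tsv(regions[, c("region", "chrom", "start", "end")], path)
  invisible(path)
}

#' Validate coverage-gap intervals against a region set
#'
#' Gaps mark stretches where copy-number status cannot be inferred (poor
#' probe coverage / low-copy repeats); every gap must fall inside one of
#' the named regions.
#'
#' @param gaps Tibble with `chrom`, `start`, `end` (a `region` column is
#'   allowed and ignored); may be `NULL` or empty.
#' @param regions Region tibble as from [builtin_regions()].
#' @return The gaps tibble, invisibly; errors if a gap lies outside all
#'   regions.
#' @export
validate_gaps <- function(gaps, regions) {
  if (is.null(gaps) || nrow(gaps) == 0) return(invisible(gaps))
  inside <- vapply(seq_len(nrow(gaps)), function(i) {
    any(regions$chrom == gaps$chrom[i] &
          regions$start <= gaps$start[i] &
          regions$end >= gaps$end[i])
  }, logical(1))
  if (!all(inside)) {
    abort(paste0("gap interval(s) outside every region: row ",
                 paste(which(!inside), collapse = ", ")))
  }
  invisible(gaps)
}
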