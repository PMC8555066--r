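# Internal helpers shared across modules.

# Variant identifier used throughout: chrom:pos:ref:alt (1-based VCF position).
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Stable, locale-independent string ordering (C collation).
c_order <- function(x) order(x, method = "radix")

c_sort <- function(x) x[c_order(x)]

# Deterministic serialization of a sample set (used for cluster ids and
# tie-breaking).
set_key <- function(samples) paste(c_sort(samples), collapse = ",")

is_subset <- function(a, b) all(a %in% b)

#' Read a 3-column BED file as a region mask
#'
#' Masks are stored as 0-based half-open intervals, matching BED. Overlapping
#' intervals are merged so that membership tests are well defined.
#'
#' @param path Path to a 3-column tab-delimited BED file (chrom, start, end).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   normalized to non-overlapping intervals.
#' @export
read_region_mask <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", comment = "#", progress = FALSE)
  normalize_mask(bed)
}

# Merge overlapping/adjacent intervals; validate start < end.
normalize_mask <- function(mask) {
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
  if (any(mask$start >= mask$end)) {
    abort("region mask contains intervals with start >= end")
  }
  gr <- GenomicRanges::reduce(mask_to_granges(mask))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# BED half-open 0-based -> GRanges (1-based closed).
mask_to_granges <- function(mask) {
  GenomicRanges::GRanges(
    seqnames = mask$chrom,
    ranges = IRanges::IRanges(start = mask$start + 1L, end = mask$end)
  )
}

# TRUE where the 1-based position falls inside the mask.
pos_in_mask <- function(chrom, pos, mask) {
  if (is.null(mask) || nrow(mask) == 0) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, mask_to_granges(mask))
}
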