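# Coordinate mapping between SNVs, HERV elements, region classes and tracks.
# Backed by IRanges/GenomicRanges overlap machinery; all coordinates are
# 0-based half-open internally, converted to 1-based closed GRanges at the
# boundary.  Strand is ignored throughout: mapping is purely positional.

# 0-based half-open interval table -> GRanges (1-based closed)
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(df$chrom),
    ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                              end = as.integer(df$end))
  )
}

# SNV table (1-based pos) -> width-1 GRanges
snvs_to_gr <- function(snvs) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(snvs$chrom),
    ranges = IRanges::IRanges(start = as.integer(snvs$pos), width = 1L)
  )
}

#' Build a searchable interval index
#'
#' Wraps a set of 0-based half-open intervals in a per-chromosome searchable
#' structure supporting point and range queries.  Query results are identical
#' to a linear scan and are ordered by (interval start, input order).
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return an object of class `interval_index`.
#' @export
build_index <- function(intervals) {
  validate_intervals(intervals, "index input")
  structure(
    list(gr = intervals_to_gr(intervals),
         start = as.numeric(intervals$start),
         n = nrow(intervals)),
    class = "interval_index"
  )
}

#' Query an interval index at a single point
#'
#' @param index an [build_index()] result.
#' @param chrom chromosome name.
#' @param pos0 0-based position; an interval `[s, e)` is hit iff `s <= pos0 < e`.
#' @return integer vector of interval row indices, ordered by (start, input
#'   order).
#' @export
query_point <- function(index, chrom, pos0) {
  query_range(index, chrom, pos0, pos0 + 1)
}

#' Query an interval index with a range
#'
#' @param index an [build_index()] result.
#' @param chrom chromosome name.
#' @param start0,end0 0-based half-open query span.
#' @return integer vector of row indices of intervals overlapping the query.
#' @export
query_range <- function(index, chrom, start0, end0) {
  if (end0 <= start0) invalid_argument("query range must satisfy end0 > start0")
  if (index$n == 0L) return(integer())
  q <- GenomicRanges::GRanges(norm_chrom(chrom),
                              IRanges::IRanges(start0 + 1, end0))
  hits <- S4Vectors::subjectHits(
    suppressWarnings(GenomicRanges::findOverlaps(q, index$gr)))
  hits[order(index$start[hits], hits)]
}

#' Map SNVs onto HERV elements by genomic coordinate
#'
#' An SNV at 1-based position `p` hits an element `[s, e)` iff
#' `s <= p - 1 < e`.  One SNV may hit several overlapping elements and then
#' contributes to each of their observed counts, so element totals may exceed
#' the number of SNVs.  Chromosomes present in the SNVs but absent from the
#' element table simply yield no hits.
#'
#' @param snvs an [snv_records] table.
#' @param elements a [herv_elements] table.
#' @return list with `counts` (integer vector of per-element observed counts,
#'   named by `element_id`, in element order) and `hits` (data.frame with one
#'   row per (SNV, element) pair: `snv` row index and `element_id`).
#' @export
assign_snvs_to_elements <- function(snvs, elements) {
  counts <- integer(nrow(elements))
  names(counts) <- elements$element_id
  if (nrow(snvs) == 0L || nrow(elements) == 0L) {
    return(list(counts = counts,
                hits = data.frame(snv = integer(), element_id = character(),
                                  stringsAsFactors = FALSE)))
  }
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(snvs_to_gr(snvs), intervals_to_gr(elements)))
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  tab <- tabulate(s, nbins = nrow(elements))
  counts[] <- tab
  o <- order(q, s)
  list(counts = counts,
       hits = data.frame(snv = q[o], element_id = elements$element_id[s[o]],
                         stringsAsFactors = FALSE))
}

#' Classify SNVs as coding or non-coding
#'
#' Sets `region_class` to `"coding"` for SNVs whose position falls inside any
#' supplied coding interval (exon/CDS spans), `"noncoding"` otherwise.
#' Retroviral ORFs (gag/pro/pol/env) are deliberately not treated as human
#' protein-coding: only intervals present in `coding_intervals` count.
#'
#' @param snvs an [snv_records] table.
#' @param coding_intervals data.frame of 0-based half-open exon/CDS spans.
#' @return `snvs` with `region_class` filled in.
#' @export
classify_region <- function(snvs, coding_intervals) {
  if (nrow(snvs) == 0L) {
    snvs$region_class <- character(0)
    return(snvs)
  }
  if (is.null(coding_intervals) || nrow(coding_intervals) == 0L) {
    snvs$region_class <- "noncoding"
    return(snvs)
  }
  validate_intervals(coding_intervals, "coding")
  inside <- suppressWarnings(IRanges::overlapsAny(
    snvs_to_gr(snvs), intervals_to_gr(coding_intervals)))
  snvs$region_class <- ifelse(inside, "coding", "noncoding")
  snvs
}

#' Total bases covered by a set of intervals
#'
#' With `merge_overlaps = TRUE` overlapping spans are unioned before summing
#' (the correct way to obtain a region length `L` for the background model);
#' otherwise lengths are summed as-is.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param merge_overlaps union overlapping spans before summing.
#' @return total base count (numeric).
#' @export
region_total_bases <- function(intervals, merge_overlaps = TRUE) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  validate_intervals(intervals, "region")
  if (!merge_overlaps) return(sum(interval_length(intervals)))
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(intervals_to_gr(intervals)))))
}

#' Non-coding region length for the background model
#'
#' The genome is partitioned into exactly two classes: the merged union of
#' coding intervals, and everything else.  An optional exclusion set (assembly
#' gaps, centromeric N-runs) is removed from the non-coding total as well.
#'
#' @param genome_length total genome length in bases.
#' @param coding_intervals exon/CDS spans (may be `NULL`).
#' @param exclude optional intervals to exclude from the non-coding total.
#' @return non-coding base count.
#' @export
noncoding_total_bases <- function(genome_length, coding_intervals,
                                  exclude = NULL) {
  if (genome_length <= 0) invalid_argument("genome_length must be positive")
  both <- rbind(
    if (!is.null(coding_intervals) && nrow(coding_intervals))
      coding_intervals[, c("chrom", "start", "end")],
    if (!is.null(exclude) && nrow(exclude))
      exclude[, c("chrom", "start", "end")]
  )
  covered <- if (is.null(both)) 0 else region_total_bases(both, TRUE)
  if (covered >= genome_length) {
    invalid_argument("coding/excluded intervals cover the whole genome")
  }
  genome_length - covered
}
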