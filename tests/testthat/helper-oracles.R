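# Independent brute-force oracles and random fixture builders.  These are
# deliberately naive O(n*m) / enumeration implementations, kept free of any
# package internals so they can arbitrate the optimized paths.

# point 0-based pos0 hits interval [s, e) iff s <= pos0 < e (linear scan)
bf_point_hits <- function(intervals, chrom, pos0) {
  which(sub("^[Cc][Hh][Rr]", "", intervals$chrom) ==
          sub("^[Cc][Hh][Rr]", "", chrom) &
        intervals$start <= pos0 & pos0 < intervals$end)
}

# per-element SNV counts by double loop
bf_assign_counts <- function(snvs, elements) {
  counts <- integer(nrow(elements))
  for (i in seq_len(nrow(snvs))) {
    counts <- counts + as.integer(
      seq_len(nrow(elements)) %in%
        bf_point_hits(elements, snvs$chrom[i], snvs$pos[i] - 1))
  }
  stats::setNames(counts, elements$element_id)
}

# membership test per SNV against a set of intervals
bf_member <- function(snvs, intervals) {
  vapply(seq_len(nrow(snvs)), function(i) {
    length(bf_point_hits(intervals, snvs$chrom[i], snvs$pos[i] - 1)) > 0
  }, logical(1))
}

# union length via a boolean base mask (small genomes only)
bf_union_length <- function(intervals, chrom_len) {
  total <- 0
  for (c in unique(intervals$chrom)) {
    mask <- logical(chrom_len)
    iv <- intervals[intervals$chrom == c, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      mask[(iv$start[i] + 1):iv$end[i]] <- TRUE
    }
    total <- total + sum(mask)
  }
  total
}

# binomial upper tail by direct pmf summation
bf_binom_upper <- function(n_O, N, p) sum(stats::dbinom(n_O:N, N, p))
bf_binom_lower <- function(n_O, N, p) sum(stats::dbinom(0:n_O, N, p))

# random interval table on a toy genome
rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                           max_len = 300) {
  start <- floor(runif(n, 0, max_pos - max_len))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + floor(runif(n, 1, max_len + 1)),
             stringsAsFactors = FALSE)
}

rand_snvs <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                      labels = NULL) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- c("C", "G", "T", "A")[match(ref, c("A", "C", "G", "T"))]
  snv_records(chrom = sample(chroms, n, replace = TRUE),
              pos = sample.int(max_pos, n, replace = TRUE),
              ref = ref, alt = alt,
              cancer_label = if (is.null(labels)) NA_character_
                             else sample(labels, n, replace = TRUE))
}

rand_elements <- function(n, ...) {
  iv <- rand_intervals(n, ...)
  herv_elements(element_id = sprintf("R%04d", seq_len(n)),
                chrom = iv$chrom, start = iv$start, end = iv$end,
                group = sample(c("HERV-H/LTR7", "MST/MaLR"), n, replace = TRUE),
                supergroup = sample(c("GE", "S"), n, replace = TRUE),
                canonical = runif(n) < 0.5)
}

# unique scratch file path in the session tempdir (cleaned up by R on exit)
withr_local_file <- function(name) {
  ext <- tools::file_ext(name)
  tempfile(pattern = paste0(sub("\\..*$", "", name), "_"),
           fileext = if (nzchar(ext)) paste0(".", ext) else "")
}
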