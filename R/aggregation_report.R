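# Taxonomy and cancer-type cross-tabulation, functional-element overlap, and
# the protein functional-site annotation join.

#' Percentage with controlled rounding
#'
#' @param num numerator (or a proportion if `den` is 1).
#' @param den denominator.
#' @param digits decimal places (default 1; use 0 to mirror integer-percent
#'   reporting styles).
#' @return numeric percentage.
#' @examples
#' pct(28, 32)      # 87.5
#' pct(788, 1820, 0)  # 43
#' @export
pct <- function(num, den = 1, digits = 1) {
  round(100 * num / den, digits)
}

#' Summarize records by grouping keys
#'
#' Counts and proportions per combination of grouping keys (canonical flag,
#' supergroup, group, cancer label, direction, functional category, ...).
#' Proportions are relative to the whole input, so within one grouping
#' universe they sum to 1.  Ordering is deterministic: descending count, then
#' key values.
#'
#' @param x data.frame carrying the requested key columns.
#' @param keys character vector of column names to group by.
#' @return data.frame of class `group_summary` with the key columns plus
#'   `snv_count` and `proportion`.
#' @export
summarize_by_group <- function(x, keys) {
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    invalid_argument(sprintf("unknown grouping key(s): %s",
                             paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0L) {
    out <- x[0, keys, drop = FALSE]
    out$snv_count <- integer(0)
    out$proportion <- numeric(0)
  } else {
    dt <- data.table::as.data.table(x)
    agg <- dt[, list(snv_count = .N), by = keys]
    agg[, "proportion" := agg$snv_count / sum(agg$snv_count)]
    out <- as.data.frame(agg)
    out <- out[do.call(order, c(list(-out$snv_count), out[keys])), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Element-by-cancer-type contingency table
#'
#' Counts of SNV assignments per (element or group) and cancer label.
#' Records without a label aggregate under `"unlabeled"`.  Row and column
#' marginals equal the respective totals by construction.
#'
#' @param assignments data.frame with one row per (SNV, element) assignment,
#'   carrying the key column and `cancer_label`.
#' @param key column to use for rows (default `"element_id"`).
#' @return integer matrix (rows = key values, columns = cancer labels).
#' @export
cancer_crosstab <- function(assignments, key = "element_id") {
  if (!key %in% names(assignments)) {
    invalid_argument(sprintf("unknown key column '%s'", key))
  }
  lab <- assignments$cancer_label
  lab[is.na(lab) | !nzchar(lab)] <- "unlabeled"
  if (nrow(assignments) == 0L) {
    return(matrix(integer(), 0, 0))
  }
  tab <- table(assignments[[key]], lab)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c(key, "cancer_label")
  m
}

#' Tidy (long) form of a crosstab for plotting pipelines
#' @param tab a [cancer_crosstab()] matrix.
#' @return data.frame with key, cancer_label, count.
#' @export
tidy_crosstab <- function(tab) {
  df <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
  names(df)[3] <- "count"
  df$count <- as.integer(df$count)
  df
}

#' Overlap SNVs with DNA functional-element tracks
#'
#' Two counting modes.  `multi`: an SNV increments every track it overlaps
#' (category counts can exceed the SNV total).  `exclusive`: each SNV is
#' assigned to the single highest-precedence track it overlaps; the default
#' precedence `lncRNA > intron > TFBS > AS > PE > CpG` follows descending
#' genome-wide share.  SNVs overlapping no track are reported in a separate
#' `"none"` bucket in both modes.
#'
#' @param snvs an [snv_records] table.
#' @param tracks named list of [functional_track]s.
#' @param mode `"exclusive"` or `"multi"`.
#' @param precedence total order over track names (exclusive mode only;
#'   defaults to the order of `tracks` and must cover every track name).
#' @return list of class `functional_overlap`: `mode`, `counts` (named, per
#'   track), `none` (SNVs overlapping no track), `proportions` (counts over
#'   SNVs overlapping at least one track), and `per_snv` (exclusive mode: the
#'   assigned category per SNV; multi mode: list of overlapped categories).
#' @export
functional_overlap <- function(snvs, tracks,
                               mode = c("exclusive", "multi"),
                               precedence = names(tracks)) {
  mode <- match.arg(mode)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    invalid_argument("tracks must be a named list")
  }
  if (mode == "exclusive") {
    missing <- setdiff(names(tracks), precedence)
    if (length(missing)) {
      invalid_argument(sprintf("precedence is missing track name(s): %s",
                               paste(missing, collapse = ", ")))
    }
    tracks <- tracks[precedence[precedence %in% names(tracks)]]
  }
  n <- nrow(snvs)
  hit <- matrix(FALSE, n, length(tracks),
                dimnames = list(NULL, names(tracks)))
  if (n > 0) {
    gr <- snvs_to_gr(snvs)
    for (nm in names(tracks)) {
      tr <- tracks[[nm]]
      if (nrow(tr)) {
        hit[, nm] <- suppressWarnings(
          IRanges::overlapsAny(gr, intervals_to_gr(tr)))
      }
    }
  }
  any_hit <- rowSums(hit) > 0
  if (mode == "multi") {
    counts <- colSums(hit)
    per_snv <- apply(hit, 1, function(r) names(tracks)[r], simplify = FALSE)
  } else {
    assigned <- rep("none", n)
    for (nm in rev(names(tracks))) assigned[hit[, nm]] <- nm
    counts <- vapply(names(tracks), function(nm) sum(assigned == nm), 0)
    per_snv <- assigned
  }
  denom <- sum(any_hit)
  structure(list(
    mode = mode,
    counts = counts,
    none = n - denom,
    proportions = if (denom > 0) counts / denom else counts * NA_real_,
    per_snv = per_snv
  ), class = "functional_overlap")
}

#' @export
print.functional_overlap <- function(x, ...) {
  cat(sprintf("<functional_overlap mode=%s> %s; none=%d\n", x$mode,
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", "), x$none))
  invisible(x)
}

#' Functional-category counts by HERV class
#'
#' The report layer behind per-(track, canonical flag, supergroup) bar
#' structures: joins each SNV's functional category (exclusive mode) and its
#' element's taxonomy, then counts.
#'
#' @param snvs an [snv_records] table.
#' @param elements a [herv_elements] table.
#' @param tracks named list of [functional_track]s.
#' @param precedence precedence for the exclusive assignment.
#' @return data.frame with `category`, `canonical`, `supergroup`, `snv_count`.
#' @export
functional_overlap_by_class <- function(snvs, elements, tracks,
                                        precedence = names(tracks)) {
  fo <- functional_overlap(snvs, tracks, "exclusive", precedence)
  asg <- assign_snvs_to_elements(snvs, elements)$hits
  if (nrow(asg) == 0L) {
    return(data.frame(category = character(), canonical = logical(),
                      supergroup = character(), snv_count = integer(),
                      stringsAsFactors = FALSE))
  }
  meta <- elements[match(asg$element_id, elements$element_id),
                   c("canonical", "supergroup")]
  joined <- data.frame(category = fo$per_snv[asg$snv],
                       canonical = meta$canonical,
                       supergroup = meta$supergroup,
                       stringsAsFactors = FALSE)
  joined <- joined[joined$category != "none", , drop = FALSE]
  out <- summarize_by_group(joined, c("category", "canonical", "supergroup"))
  out$proportion <- NULL
  as.data.frame(out)
}

#' Annotate nsSNVs with protein functional-site effects
#'
#' Joins amino-acid-level SNV records against a user-supplied functional-site
#' table (phosphorylation/glycosylation gains and losses, binding sites, ...)
#' on (gene, amino-acid position).  Unmatched records get an empty flag;
#' duplicate site rows are deduplicated and joined with `";"`.
#'
#' @param snv_sites data.frame with columns `gene` and `aa_pos` (1-based
#'   amino-acid position).
#' @param site_table data.frame with columns `gene`, `aa_pos`, `effect`.
#' @return `snv_sites` with an `effect` column added.
#' @export
annotate_sites <- function(snv_sites, site_table) {
  for (col in c("gene", "aa_pos")) {
    if (!col %in% names(snv_sites)) {
      invalid_argument(sprintf("snv_sites is missing column '%s'", col))
    }
  }
  if (is.null(site_table) || nrow(site_table) == 0L) {
    snv_sites$effect <- rep("", nrow(snv_sites))
    return(snv_sites)
  }
  if (any(site_table$aa_pos < 1)) {
    invalid_argument("site_table aa_pos must be >= 1")
  }
  key <- paste(site_table$gene, site_table$aa_pos)
  effects <- lapply(split(site_table$effect, key),
                    function(e) paste(sort(unique(e)), collapse = ";"))
  qkey <- paste(snv_sites$gene, snv_sites$aa_pos)
  flag <- unlist(effects[qkey], use.names = FALSE)
  out <- character(nrow(snv_sites))
  out[qkey %in% names(effects)] <- flag
  snv_sites$effect <- out
  snv_sites
}
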