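# Domain types shared by every stage: genomic intervals (0-based half-open
# internally, BED-style), HERV elements with taxonomy, SNV records (1-based
# positions, as in VCF), and the uniform-genome background model.

#' Recognised HERV supergroup codes
#'
#' Five-way classification of HERV elements: Gamma-/Epsilon-retrovirus-related
#' (`GE`, formerly Class I), Alpha-/Beta-retrovirus-related (`AB`, Class II),
#' Spumavirus-related (`S`, Class III), uncertain Errantivirus-like, and
#' unclassified.
#' @export
HERV_SUPERGROUPS <- c("GE", "AB", "S", "UncertainErrantivirus", "Unclassified")

#' Valid SNV region classes
#' @export
REGION_CLASSES <- c("coding", "noncoding", "unassigned")

NUCLEOTIDES <- c("A", "C", "G", "T")

## ---- condition helpers ------------------------------------------------------

herv_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "herv_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

invalid_argument <- function(msg) herv_error(msg, "herv_invalid_argument")
format_error     <- function(msg) herv_error(msg, "herv_format_error")
io_error         <- function(msg) herv_error(msg, "herv_io_error")
usage_error      <- function(msg) herv_error(msg, "herv_usage_error")

## ---- supergroup / chromosome normalization ---------------------------------

#' Normalize HERV supergroup labels
#'
#' Accepts the short codes (`"GE"`, `"AB"`, `"S"`) as well as the long forms
#' used in supplementary annotation tables
#' (`"Gamma-retrovirus/Epsilon-retrovirus-related"`, etc.), case-insensitively.
#' Anything unrecognised maps to `"Unclassified"` with a warning.
#'
#' @param x character vector of supergroup labels.
#' @param warn warn when an unknown label is coerced to `"Unclassified"`.
#' @return character vector drawn from [HERV_SUPERGROUPS].
#' @export
normalize_supergroup <- function(x, warn = TRUE) {
  key <- tolower(gsub("[^a-z]", "", tolower(as.character(x))))
  out <- rep("Unclassified", length(x))
  out[key %in% c("ge", "gammaretrovirusepsilonretrovirusrelated",
                 "gammaepsilonretrovirusrelated")] <- "GE"
  out[key %in% c("ab", "alpharetrovirusbetaretrovirusrelated",
                 "alphabetaretrovirusrelated")] <- "AB"
  out[key %in% c("s", "spumavirusrelated")] <- "S"
  out[grepl("errantivirus", key)] <- "UncertainErrantivirus"
  unknown <- out == "Unclassified" &
    !(key %in% c("unclassified", "", "na")) & !is.na(x)
  if (warn && any(unknown)) {
    warning(sprintf("%d unknown supergroup label(s) mapped to 'Unclassified': %s",
                    sum(unknown), paste(unique(x[unknown]), collapse = ", ")),
            call. = FALSE)
  }
  out[is.na(x)] <- "Unclassified"
  out
}

#' Normalize chromosome names
#'
#' Unifies UCSC-style (`"chr1"`) and Ensembl/ICGC-style (`"1"`) names by
#' stripping a leading `chr`/`Chr` prefix, so mixed sources overlap correctly.
#'
#' @param x character vector of chromosome names.
#' @export
norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

## ---- interval validation ----------------------------------------------------

# shared invariant check for any 0-based half-open interval table
validate_intervals <- function(df, what = "interval") {
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(df)) {
      format_error(sprintf("%s table is missing required column '%s'", what, col))
    }
  }
  bad <- which(!(df$end > df$start & df$start >= 0))
  if (length(bad)) {
    invalid_argument(sprintf(
      "%s record %d violates end > start >= 0 (start=%s, end=%s)",
      what, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

interval_length <- function(df) as.numeric(df$end) - as.numeric(df$start)

## ---- HERV elements ----------------------------------------------------------

#' Construct a HERV element table
#'
#' The central annotation container: one row per element, with 0-based
#' half-open coordinates and the taxonomy used for aggregation.  Elements may
#' overlap each other; each is tested independently, and an SNV inside two
#' overlapping elements counts towards both.
#'
#' @param element_id stable element identifier (e.g. `"4673"`).
#' @param chrom chromosome name.
#' @param start,end 0-based half-open span; `end > start >= 0`.
#' @param group HERV group name (e.g. `"HERV-W/LTR17/HERV17"`); non-empty.
#' @param supergroup supergroup label, normalized via [normalize_supergroup()].
#' @param canonical logical; `TRUE` for elements composed of a single HERV
#'   group, `FALSE` for mosaics of two or more groups.
#' @param strand optional strand (`"+"`, `"-"`, or `NA` for unknown).
#' @return a `data.frame` of class `herv_elements`.
#' @export
herv_elements <- function(element_id, chrom, start, end, group,
                          supergroup = "Unclassified", canonical = NA,
                          strand = NA_character_) {
  df <- data.frame(
    element_id = as.character(element_id),
    chrom      = as.character(chrom),
    start      = as.numeric(start),
    end        = as.numeric(end),
    strand     = as.character(strand),
    group      = as.character(group),
    supergroup = normalize_supergroup(supergroup),
    canonical  = as.logical(canonical),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, "HERV element")
  if (any(!nzchar(df$group) | is.na(df$group))) {
    invalid_argument("HERV element 'group' must be non-empty")
  }
  if (anyDuplicated(df$element_id)) {
    invalid_argument("duplicate element_id values in HERV element table")
  }
  class(df) <- c("herv_elements", "data.frame")
  df
}

#' @export
print.herv_elements <- function(x, ...) {
  cat(sprintf("<herv_elements> %d element(s) on %d chromosome(s)\n",
              nrow(x), length(unique(norm_chrom(x$chrom)))))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

## ---- SNV records ------------------------------------------------------------

#' Construct an SNV record table
#'
#' Somatic single-nucleotide variants with 1-based positions (the VCF
#' convention; converted to 0-based internally at query time).  Both alleles
#' must be single nucleotides and distinct.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param ref,alt reference / alternate alleles, single characters in ACGT.
#' @param cancer_label optional free-text or DOID cancer-type label.
#' @param region_class one of `r paste(REGION_CLASSES, collapse=", ")`.
#' @param sample_id optional sample identifier.
#' @return a `data.frame` of class `snv_records`.
#' @export
snv_records <- function(chrom, pos, ref, alt, cancer_label = NA_character_,
                        region_class = "unassigned", sample_id = NA_character_) {
  n <- length(pos)
  df <- data.frame(
    chrom        = as.character(chrom),
    pos          = as.numeric(pos),
    ref          = toupper(as.character(ref)),
    alt          = toupper(as.character(alt)),
    cancer_label = rep_len(as.character(cancer_label), n),
    region_class = rep_len(as.character(region_class), n),
    sample_id    = rep_len(as.character(sample_id), n),
    stringsAsFactors = FALSE
  )
  if (n && any(df$pos < 1 | df$pos != floor(df$pos))) {
    invalid_argument("SNV positions must be 1-based positive integers")
  }
  bad <- !(df$ref %in% NUCLEOTIDES) | !(df$alt %in% NUCLEOTIDES)
  if (any(bad)) {
    invalid_argument(sprintf("SNV record %d has non-ACGT allele(s): %s>%s",
                             which(bad)[1], df$ref[which(bad)[1]],
                             df$alt[which(bad)[1]]))
  }
  if (any(df$ref == df$alt)) {
    invalid_argument("SNV ref and alt alleles must differ")
  }
  if (any(!df$region_class %in% REGION_CLASSES)) {
    invalid_argument(sprintf("region_class must be one of: %s",
                             paste(REGION_CLASSES, collapse = ", ")))
  }
  class(df) <- c("snv_records", "data.frame")
  df
}

# empty snv table with the right columns
empty_snvs <- function() {
  snv_records(character(), numeric(), character(), character())
}

#' Collapse SNV records to unique genomic sites
#'
#' Recurrent mutations at one (chromosome, position) collapse to a single
#' record, matching site-based counting of mutational burden; event-based
#' counting keeps every record.
#'
#' @param snvs an [snv_records] table.
#' @return `snvs` with duplicate sites removed (first record kept).
#' @export
collapse_sites <- function(snvs) {
  key <- paste(norm_chrom(snvs$chrom), snvs$pos)
  out <- snvs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- functional tracks ------------------------------------------------------

#' Construct a DNA functional-element track
#'
#' A named set of 0-based half-open intervals (lncRNA, intron, TFBS,
#' alternative splice site, pseudo exon, CpG island, ...).  Intervals are
#' sorted per chromosome; overlapping intervals are kept as-is (not merged).
#'
#' @param name track name.
#' @param chrom,start,end interval columns (0-based half-open).
#' @return a `data.frame` of class `functional_track` with a `"track_name"`
#'   attribute.
#' @export
functional_track <- function(name, chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  validate_intervals(df, sprintf("track '%s'", name))
  df <- df[order(norm_chrom(df$chrom), df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "track_name") <- as.character(name)
  class(df) <- c("functional_track", "data.frame")
  df
}

#' @export
print.functional_track <- function(x, ...) {
  cat(sprintf("<functional_track '%s'> %d interval(s)\n",
              attr(x, "track_name"), nrow(x)))
  invisible(x)
}

## ---- background model -------------------------------------------------------

#' Build a uniform-genome background model
#'
#' The null model against which every element is tested: within a region class
#' (protein-coding or non-coding), all `L` bases are equally likely to carry
#' one of the `N` observed SNV sites, so the per-base density is `N / L` and an
#' element of length `n_F` expects `N * n_F / L` SNVs.
#'
#' @param region_class `"coding"` or `"noncoding"`.
#' @param total_bases_L total bases in the region class (must be > 0).
#' @param total_snvs_N total SNV sites observed in the region class (>= 0).
#' @return an object of class `background_model` with fields `region_class`,
#'   `total_bases_L`, `total_snvs_N`, `density`.
#' @examples
#' bg <- make_background("coding", total_bases_L = 1000, total_snvs_N = 100)
#' bg$density  # 0.1
#' @export
make_background <- function(region_class = c("coding", "noncoding"),
                            total_bases_L, total_snvs_N) {
  region_class <- match.arg(region_class)
  if (!is.numeric(total_bases_L) || length(total_bases_L) != 1 ||
      is.na(total_bases_L) || total_bases_L <= 0) {
    invalid_argument("total_bases_L must be a single positive number")
  }
  if (!is.numeric(total_snvs_N) || length(total_snvs_N) != 1 ||
      is.na(total_snvs_N) || total_snvs_N < 0) {
    invalid_argument("total_snvs_N must be a single non-negative number")
  }
  structure(
    list(region_class = region_class,
         total_bases_L = as.numeric(total_bases_L),
         total_snvs_N = as.numeric(total_snvs_N),
         density = as.numeric(total_snvs_N) / as.numeric(total_bases_L)),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model %s> L = %s bases, N = %s SNV sites, density = %.6g per base\n",
              x$region_class, format(x$total_bases_L, big.mark = ","),
              format(x$total_snvs_N, big.mark = ","), x$density))
  invisible(x)
}
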