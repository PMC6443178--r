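# Readers/writers for every file the pipeline touches.  Dialects:
#   - HERV element tables: TSV with header, coordinates either 0-based
#     half-open (default, BED-like) or 1-based inclusive, selected by the
#     column map;
#   - SNVs: VCF 4.x (fixed columns; multi-allelic lines expanded; non-SNV
#     records skipped and counted) or TSV with 1-based positions;
#   - functional tracks: BED3+ (0-based half-open, never merged on read);
#   - scan results: TSV with p-values in scientific notation.
# Every violation of a dialect produces a located error (file + line), never
# silent corruption.

#' Column map for tabular HERV / SNV inputs
#'
#' Maps the logical field names the pipeline needs onto the column headers of
#' a user-supplied table, so supplementary tables with arbitrary headers can
#' be consumed without editing.
#'
#' @param element_id,chrom,start,end,group,supergroup,canonical,strand header
#'   names for each logical field (`supergroup`, `canonical`, `strand` may be
#'   `NA` if absent from the file).
#' @param coords `"bed0"` for 0-based half-open coordinates, `"one_based"` for
#'   1-based inclusive (converted on read).
#' @return list of class `column_map`.
#' @export
herv_column_map <- function(element_id = "element_id", chrom = "chrom",
                            start = "start", end = "end", group = "group",
                            supergroup = "supergroup", canonical = "canonical",
                            strand = "strand",
                            coords = c("bed0", "one_based")) {
  structure(list(element_id = element_id, chrom = chrom, start = start,
                 end = end, group = group, supergroup = supergroup,
                 canonical = canonical, strand = strand,
                 coords = match.arg(coords)),
            class = "column_map")
}

read_table_checked <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    colClasses = NULL, na.strings = c("NA", ""))
}

#' Read a HERV element annotation table
#'
#' TSV with a header; required logical columns are `element_id`, `chrom`,
#' `start`, `end`, `group` (resolved through the [herv_column_map()]).
#' Elements are returned sorted by (chromosome, start).  Unknown supergroup
#' labels map to `"Unclassified"` with a warning; a record with `end <= start`
#' raises an error naming its line.
#'
#' @param path file path.
#' @param column_map a [herv_column_map()].
#' @return a [herv_elements] table.
#' @export
read_herv_table <- function(path, column_map = herv_column_map()) {
  raw <- read_table_checked(path)
  required <- c("element_id", "chrom", "start", "end", "group")
  for (f in required) {
    col <- column_map[[f]]
    if (is.na(col) || !col %in% names(raw)) {
      format_error(sprintf("HERV table %s is missing required column '%s'",
                           path, col))
    }
  }
  getcol <- function(f, default = NA) {
    col <- column_map[[f]]
    if (!is.na(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  start <- as.numeric(getcol("start"))
  end <- as.numeric(getcol("end"))
  if (column_map$coords == "one_based") start <- start - 1
  bad <- which(!(end > start))
  if (length(bad)) {
    format_error(sprintf("%s line %d: end <= start after coordinate conversion",
                         path, bad[1] + 1L))  # +1 for the header line
  }
  canon <- getcol("canonical")
  if (is.character(canon)) {
    canon <- tolower(canon) %in% c("true", "t", "1", "yes", "canonical")
  }
  el <- herv_elements(
    element_id = getcol("element_id"), chrom = getcol("chrom"),
    start = start, end = end, group = getcol("group"),
    supergroup = normalize_supergroup(getcol("supergroup", "Unclassified")),
    canonical = as.logical(canon), strand = as.character(getcol("strand"))
  )
  el <- el[order(norm_chrom(el$chrom), el$start, el$end), , drop = FALSE]
  rownames(el) <- NULL
  class(el) <- c("herv_elements", "data.frame")
  el
}

#' Write a HERV element table
#'
#' TSV with the canonical column names (0-based half-open coordinates);
#' [read_herv_table()] with the default column map round-trips it exactly.
#'
#' @param elements a [herv_elements] table.
#' @param path output path.
#' @export
write_herv_table <- function(elements, path) {
  data.table::fwrite(as.data.frame(elements), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

## ---- SNVs -------------------------------------------------------------------

# percent-encode / decode VCF INFO values (VCF forbids whitespace and ';')
encode_info_value <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(" ", "%20", x, fixed = TRUE)
}
decode_info_value <- function(x) {
  x <- gsub("%20", " ", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

info_field <- function(info, key) {
  out <- rep(NA_character_, length(info))
  pat <- sprintf("(?:^|;)%s=([^;]*)", key)
  m <- regmatches(info, regexec(pat, info))
  hit <- lengths(m) == 2
  out[hit] <- vapply(m[hit], `[`, "", 2)
  decode_info_value(out)
}

#' Read somatic SNVs from VCF or TSV
#'
#' VCF: fixed columns only; multi-allelic lines expand to one record per ALT;
#' records that are not bi-allelic SNVs after expansion (indels, MNVs,
#' symbolic alleles) are skipped and counted (reported via a message and the
#' `"skipped"` attribute).  An optional cancer-type label is read from the
#' INFO keys `CANCER` or `DOID`, and a sample identifier from `SAMPLE`.
#' TSV: header columns `chrom`, `pos`, `ref`, `alt` and optionally
#' `cancer_label`, `sample_id`, `region_class`; positions are 1-based in both
#' dialects (matching VCF), converted to the internal convention at query
#' time.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @param default_region_class region class assigned to records that do not
#'   carry one.
#' @return an [snv_records] table with attribute `skipped` (count of non-SNV
#'   records dropped).
#' @export
read_snvs <- function(path, format = c("auto", "vcf", "tsv"),
                      default_region_class = "unassigned") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_snvs_vcf(path, default_region_class)
  else read_snvs_tsv(path, default_region_class)
}

read_snvs_vcf <- function(path, default_region_class) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  skipped <- 0L
  rec <- list()
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      format_error(sprintf("%s line %d: malformed VCF record (%d field(s))",
                           path, i, length(f)))
    }
    pos <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pos)) {
      format_error(sprintf("%s line %d: non-numeric POS '%s'", path, i, f[2]))
    }
    ref <- toupper(f[4])
    alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    info <- if (length(f) >= 8) f[8] else ""
    for (alt in alts) {
      if (nchar(ref) != 1 || nchar(alt) != 1 ||
          !(ref %in% NUCLEOTIDES) || !(alt %in% NUCLEOTIDES) || ref == alt) {
        skipped <- skipped + 1L
        next
      }
      rec[[length(rec) + 1L]] <- list(chrom = f[1], pos = pos, ref = ref,
                                      alt = alt, info = info)
    }
  }
  if (skipped > 0L) {
    message(sprintf("read_snvs: skipped %d non-SNV record(s) in %s",
                    skipped, path))
  }
  if (!length(rec)) {
    out <- empty_snvs()
  } else {
    info <- vapply(rec, `[[`, "", "info")
    cancer <- info_field(info, "CANCER")
    doid <- info_field(info, "DOID")
    cancer[is.na(cancer)] <- doid[is.na(cancer)]
    out <- snv_records(
      chrom = vapply(rec, `[[`, "", "chrom"),
      pos = vapply(rec, `[[`, 0, "pos"),
      ref = vapply(rec, `[[`, "", "ref"),
      alt = vapply(rec, `[[`, "", "alt"),
      cancer_label = cancer,
      region_class = default_region_class,
      sample_id = info_field(info, "SAMPLE")
    )
  }
  attr(out, "skipped") <- skipped
  out
}

read_snvs_tsv <- function(path, default_region_class) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, n = 50L)
  n_comment <- sum(cumprod(startsWith(lines, "#")))
  raw <- data.table::fread(path, sep = "\t", header = TRUE, skip = n_comment,
                           data.table = FALSE, na.strings = c("NA", ""))
  for (col in c("chrom", "pos", "ref", "alt")) {
    if (!col %in% names(raw)) {
      format_error(sprintf("SNV TSV %s is missing required column '%s'",
                           path, col))
    }
  }
  opt <- function(col, default) if (col %in% names(raw)) raw[[col]] else default
  snv_records(
    chrom = raw$chrom, pos = raw$pos, ref = raw$ref, alt = raw$alt,
    cancer_label = opt("cancer_label", NA_character_),
    region_class = opt("region_class", default_region_class),
    sample_id = opt("sample_id", NA_character_)
  )
}

#' Write SNVs as TSV
#'
#' Positions stay 1-based (declared in a header comment); round-trips through
#' [read_snvs()] exactly.
#'
#' @param snvs an [snv_records] table.
#' @param path output path.
#' @export
write_snvs_tsv <- function(snvs, path) {
  writeLines("# SNV positions are 1-based (VCF convention)", path)
  data.table::fwrite(as.data.frame(snvs), path, sep = "\t", na = "NA",
                     quote = FALSE, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Write SNVs as a minimal VCF 4.2 file
#'
#' Cancer label, sample id and region class are carried in the INFO column
#' (keys `CANCER`, `SAMPLE`, `RC`), percent-encoded where VCF forbids the raw
#' characters.
#'
#' @param snvs an [snv_records] table.
#' @param path output path.
#' @export
write_snvs_vcf <- function(snvs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hervscan",
    '##INFO=<ID=CANCER,Number=1,Type=String,Description="Cancer type label">',
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Sample identifier">',
    '##INFO=<ID=RC,Number=1,Type=String,Description="Region class">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snvs)) {
    info <- paste0(
      ifelse(is.na(snvs$cancer_label), "",
             paste0("CANCER=", encode_info_value(snvs$cancer_label), ";")),
      ifelse(is.na(snvs$sample_id), "",
             paste0("SAMPLE=", encode_info_value(snvs$sample_id), ";")),
      "RC=", snvs$region_class)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       snvs$chrom, as.integer(snvs$pos), snvs$ref, snvs$alt,
                       info), con)
  }
  invisible(path)
}

## ---- BED tracks -------------------------------------------------------------

#' Read a BED3+ file as a functional track
#'
#' 0-based half-open, tab-separated, no header (track/browser lines and `#`
#' comments are skipped).  Intervals are sorted but never merged — coverage
#' semantics are decided downstream.  A record with `start >= end` raises an
#' error naming its line.
#'
#' @param path BED file path.
#' @param name track name to attach.
#' @return a [functional_track].
#' @export
read_bed_track <- function(path, name = basename(path)) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !(startsWith(lines, "#") | startsWith(lines, "track") |
              startsWith(lines, "browser") | !nzchar(lines))
  idx <- which(keep)
  if (!length(idx)) return(functional_track(name, character(), numeric(), numeric()))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    format_error(sprintf("%s line %d: BED record has %d field(s), need >= 3",
                         path, idx[which(nf < 3)[1]], min(nf)))
  }
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    format_error(sprintf("%s line %d: invalid BED interval (start >= end or non-numeric)",
                         path, idx[bad[1]]))
  }
  functional_track(name, chrom, start, end)
}

#' Write intervals as BED3
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(intervals)) {
    writeLines(sprintf("%s\t%d\t%d", intervals$chrom,
                       as.integer(intervals$start), as.integer(intervals$end)),
               con)
  }
  invisible(path)
}

#' Read a BED4 file holding several named tracks
#'
#' Column 4 is the track name; returns one [functional_track] per distinct
#' name, in order of first appearance.
#'
#' @param path BED file path.
#' @return named list of [functional_track]s.
#' @export
read_track_set <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(raw) < 4) format_error(sprintf("%s: track set BED needs 4 columns", path))
  names(raw)[1:4] <- c("chrom", "start", "end", "name")
  out <- lapply(split(raw, factor(raw$name, levels = unique(raw$name))),
                function(d) functional_track(d$name[1], d$chrom, d$start, d$end))
  out
}

#' Write several named tracks as BED4
#' @param tracks named list of [functional_track]s.
#' @param path output path.
#' @export
write_track_set <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (nrow(tr)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", tr$chrom, as.integer(tr$start),
                         as.integer(tr$end), nm), con)
    }
  }
  invisible(path)
}

## ---- scan results -----------------------------------------------------------

RESULT_COLUMNS <- c("element_id", "group", "supergroup", "canonical", "chrom",
                    "length", "observed", "expected", "p_upper", "p_lower",
                    "direction", "significant")

#' Write scan results as TSV
#'
#' One row per tested element with columns `element_id`, `group`,
#' `supergroup`, `canonical`, `chrom`, `length`, `observed`, `expected`,
#' `p_upper`, `p_lower`, `direction`, `significant`; p-values in scientific
#' notation with 9 significant digits.
#'
#' @param results a [scan_elements()] result.
#' @param path output path.
#' @export
write_results_tsv <- function(results, path) {
  if (is.null(results)) invalid_argument("results must be non-null")
  df <- as.data.frame(results)
  out <- data.frame(
    element_id = df$element_id, group = df$group, supergroup = df$supergroup,
    canonical = df$canonical, chrom = df$chrom, length = df$length,
    observed = df$observed,
    expected = formatC(df$expected, format = "g", digits = 12),
    p_upper = formatC(df$p_upper, format = "e", digits = 8),
    p_lower = formatC(df$p_lower, format = "e", digits = 8),
    direction = df$direction, significant = df$significant,
    stringsAsFactors = FALSE
  )
  if (!nrow(df)) out <- out[0, , drop = FALSE]
  tryCatch(
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA"),
    error = function(e) io_error(sprintf("cannot write results to %s: %s",
                                         path, conditionMessage(e))))
  invisible(path)
}

#' Read back a results TSV written by [write_results_tsv()]
#' @param path file path.
#' @return data.frame with the result columns (numeric fields parsed).
#' @export
read_results_tsv <- function(path) {
  df <- read_table_checked(path)
  missing <- setdiff(RESULT_COLUMNS, names(df))
  if (length(missing)) {
    format_error(sprintf("results TSV %s is missing column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  for (col in c("length", "observed", "expected", "p_upper", "p_lower")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$canonical <- as.logical(df$canonical)
  df$significant <- as.logical(df$significant)
  df$chrom <- as.character(df$chrom)
  df$element_id <- as.character(df$element_id)
  df
}
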