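# Synthetic mutation landscapes with the statistical structure the scan
# assumes: non-overlapping elements placed uniformly, SNV sites arising as
# independent per-base Bernoulli events (uniform background rate, optional
# per-element rate spikes), alleles uniform over distinct nucleotides, and
# cancer labels drawn independently of position from a fixed mixture.
# Everything is reproducible from the seed.

SIM_GROUPS <- c(
  "HERV-H/LTR7" = "GE", "HERV-9/LTR12" = "GE", "HERV-W/LTR17/HERV17" = "GE",
  "HERV-IP10F/LTR10F" = "GE", "HML-2/HERV-K/LTR5" = "AB",
  "HML-8/HERV-K11I/MER11A" = "AB", "HERV-L/MLT2" = "S", "MST/MaLR" = "S",
  "HERV-S/HERV18/LTR18" = "S"
)

#' Simulation configuration
#'
#' Defaults describe a desk-scale landscape: a 10 Mb genome over 2
#' chromosomes, 200 non-overlapping elements of 5–15 kb, an exome-like 2%
#' coding fraction, and a per-base SNV rate of 2e-3, which puts per-element
#' expected counts in the ~20 range.  The default cancer mixture
#' (skin .766 / esophageal .154 / liver .080) is proportional to reported
#' per-element SNV means of the three dominant cancer types in pan-cancer
#' non-coding compilations.
#'
#' @param genome_length total genome size in bases.
#' @param n_chromosomes number of chromosomes (genome split evenly).
#' @param n_elements number of HERV elements to place.
#' @param element_length length-2 vector: uniform min/max element length.
#' @param coding_fraction fraction of the genome covered by exon intervals.
#' @param base_rate per-base SNV probability outside spiked elements.
#' @param spikes named numeric vector mapping element index (after placement,
#'   as a string) to a rate multiplier > 0.
#' @param cancer_mixture named proportions summing to 1.
#' @param tracks_coverage named per-track genome coverage fractions.
#' @param site_unique if `TRUE` (default) at most one SNV per base (site
#'   counting); if `FALSE` recurrent events at one base are allowed.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e7, n_chromosomes = 2,
                       n_elements = 200, element_length = c(5000, 15000),
                       coding_fraction = 0.02, base_rate = 2e-3,
                       spikes = NULL,
                       cancer_mixture = c("skin cancer" = 0.766,
                                          "esophageal cancer" = 0.154,
                                          "liver cancer" = 0.080),
                       tracks_coverage = c(lncRNA = 0.20, intron = 0.35,
                                           TFBS = 0.05, AS = 0.01,
                                           PE = 0.005, CpG = 0.01),
                       site_unique = TRUE, seed = 1L) {
  if (genome_length < 1 || n_chromosomes < 1) {
    invalid_argument("genome_length and n_chromosomes must be positive")
  }
  if (length(element_length) != 2 || element_length[1] > element_length[2] ||
      element_length[1] < 1) {
    invalid_argument("element_length must be c(min, max) with 1 <= min <= max")
  }
  if (coding_fraction < 0 || coding_fraction >= 1) {
    invalid_argument("coding_fraction must be in [0, 1)")
  }
  mult_max <- if (length(spikes)) max(spikes) else 1
  if (base_rate < 0 || base_rate * mult_max > 1) {
    invalid_argument("base_rate (times the largest spike multiplier) must lie in [0, 1]")
  }
  if (length(spikes) && (is.null(names(spikes)) || any(spikes <= 0))) {
    invalid_argument("spikes must be a named vector of positive multipliers")
  }
  if (abs(sum(cancer_mixture) - 1) > 1e-6 || any(cancer_mixture < 0)) {
    invalid_argument("cancer_mixture proportions must be non-negative and sum to 1")
  }
  if (any(tracks_coverage < 0 | tracks_coverage > 1)) {
    invalid_argument("tracks_coverage fractions must lie in [0, 1]")
  }
  structure(list(genome_length = genome_length,
                 n_chromosomes = as.integer(n_chromosomes),
                 n_elements = as.integer(n_elements),
                 element_length = as.numeric(element_length),
                 coding_fraction = coding_fraction, base_rate = base_rate,
                 spikes = spikes,
                 cancer_mixture = cancer_mixture / sum(cancer_mixture),
                 tracks_coverage = tracks_coverage,
                 site_unique = isTRUE(site_unique), seed = as.integer(seed)),
            class = "sim_config")
}

# uniformly place n non-overlapping intervals of the given lengths on [0, L)
# by distributing the free space as random gaps; returns 0-based starts
place_nonoverlapping <- function(lengths, L) {
  n <- length(lengths)
  if (n == 0L) return(numeric(0))
  free <- L - sum(lengths)
  if (free < 0) {
    invalid_argument("infeasible placement: intervals exceed the chromosome")
  }
  cuts <- sort(stats::runif(n, 0, free))
  floor(cuts) + cumsum(c(0, lengths[-n]))
}

# sample k distinct 0-based positions uniformly from a set of gap intervals
sample_gap_positions <- function(gaps, k, replace = FALSE) {
  if (k == 0L || nrow(gaps) == 0L) return(numeric(0))
  len <- interval_length(gaps)
  cum <- cumsum(len)
  idx <- if (replace) {
    ceiling(stats::runif(k) * cum[length(cum)])
  } else {
    sample(cum[length(cum)], k)
  }
  g <- findInterval(idx - 1, c(0, cum[-length(cum)]))
  g <- pmin(pmax(g, 1), nrow(gaps))
  gaps$start[g] + (idx - 1) - c(0, cum)[g]
}

#' Simulate a full mutation landscape
#'
#' Places non-overlapping elements uniformly across the genome, then draws
#' SNV sites independently per base: probability `base_rate * multiplier_i`
#' inside element `i` (multiplier 1 unless spiked), `base_rate` elsewhere.
#' Each SNV gets a uniform reference allele, a uniform distinct alternate
#' allele, a cancer label from the mixture, and a sample identifier.  Exon
#' intervals and functional tracks are placed independently so the coding
#' partition and overlap reports exercise realistic mixtures.  The same seed
#' reproduces identical output.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_landscape` with `elements` ([herv_elements]),
#'   `coding` (exon interval data.frame), `tracks` (named list of
#'   [functional_track]s), `snvs` ([snv_records], `region_class` unassigned),
#'   `chrom_lengths` (named), and `truth` (class `sim_truth`: `seed`,
#'   `base_rate`, `spiked_elements` as element_id -> multiplier,
#'   `cancer_mixture`).
#' @export
simulate_landscape <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed)
  L <- config$genome_length
  nc <- config$n_chromosomes
  chrom_lengths <- rep(floor(L / nc), nc)
  chrom_lengths[nc] <- L - sum(chrom_lengths[-nc])
  names(chrom_lengths) <- paste0("chr", seq_len(nc))

  ## elements: lengths, chromosome assignment, uniform non-overlapping starts
  lens <- floor(stats::runif(config$n_elements, config$element_length[1],
                             config$element_length[2] + 1))
  el_chrom <- sample(names(chrom_lengths), config$n_elements, replace = TRUE,
                     prob = chrom_lengths / L)
  starts <- numeric(config$n_elements)
  for (c in names(chrom_lengths)) {
    i <- which(el_chrom == c)
    if (length(i)) starts[i] <- place_nonoverlapping(lens[i], chrom_lengths[[c]])
  }
  ord <- order(el_chrom, starts)
  el_chrom <- el_chrom[ord]; starts <- starts[ord]; lens <- lens[ord]
  grp <- sample(names(SIM_GROUPS), config$n_elements, replace = TRUE)
  elements <- herv_elements(
    element_id = sprintf("E%04d", seq_len(config$n_elements)),
    chrom = el_chrom, start = starts, end = starts + lens, group = grp,
    supergroup = unname(SIM_GROUPS[grp]),
    canonical = stats::runif(config$n_elements) < 0.387
  )

  ## spikes keyed by element index -> element_id
  mult <- rep(1, config$n_elements)
  spiked <- numeric(0)
  if (length(config$spikes)) {
    idx <- as.integer(names(config$spikes))
    if (any(is.na(idx) | idx < 1 | idx > config$n_elements)) {
      invalid_argument("spike indices must address placed elements")
    }
    mult[idx] <- as.numeric(config$spikes)
    spiked <- stats::setNames(as.numeric(config$spikes),
                              elements$element_id[idx])
  }

  ## exons and tracks (independent placement; may overlap elements)
  coding <- place_cover(chrom_lengths, config$coding_fraction, piece = 150)
  tracks <- lapply(names(config$tracks_coverage), function(nm) {
    iv <- place_cover(chrom_lengths, config$tracks_coverage[[nm]], piece = 500)
    functional_track(nm, iv$chrom, iv$start, iv$end)
  })
  names(tracks) <- names(config$tracks_coverage)

  ## SNV sites: inside elements at spiked rates, outside at base_rate
  pos_chrom <- character(0); pos0 <- numeric(0)
  for (i in seq_len(config$n_elements)) {
    p <- min(1, config$base_rate * mult[i])
    k <- stats::rbinom(1, lens[i], p)
    if (k > 0) {
      off <- if (config$site_unique) sample.int(lens[i], k) - 1
             else floor(stats::runif(k) * lens[i])
      pos_chrom <- c(pos_chrom, rep(elements$chrom[i], k))
      pos0 <- c(pos0, elements$start[i] + off)
    }
  }
  for (c in names(chrom_lengths)) {
    el_c <- elements[elements$chrom == c, , drop = FALSE]
    gaps <- complement_intervals(el_c, c, chrom_lengths[[c]])
    gap_total <- sum(interval_length(gaps))
    k <- stats::rbinom(1, gap_total, config$base_rate)
    if (k > 0) {
      pos_chrom <- c(pos_chrom, rep(c, k))
      pos0 <- c(pos0, sample_gap_positions(gaps, k,
                                           replace = !config$site_unique))
    }
  }

  n <- length(pos0)
  if (n > 0) {
    ref_i <- sample.int(4, n, replace = TRUE)
    alt_i <- (ref_i - 1 + sample.int(3, n, replace = TRUE)) %% 4 + 1
    snvs <- snv_records(
      chrom = pos_chrom, pos = pos0 + 1, ref = NUCLEOTIDES[ref_i],
      alt = NUCLEOTIDES[alt_i],
      cancer_label = sample(names(config$cancer_mixture), n, replace = TRUE,
                            prob = config$cancer_mixture),
      region_class = "unassigned",
      sample_id = sprintf("S%03d", sample.int(25, n, replace = TRUE))
    )
    o <- order(norm_chrom(snvs$chrom), snvs$pos)
    snvs <- snvs[o, , drop = FALSE]
    rownames(snvs) <- NULL
    class(snvs) <- c("snv_records", "data.frame")
  } else {
    snvs <- empty_snvs()
  }

  structure(list(
    elements = elements, coding = coding, tracks = tracks, snvs = snvs,
    chrom_lengths = chrom_lengths,
    truth = structure(list(seed = config$seed, base_rate = config$base_rate,
                           spiked_elements = spiked,
                           cancer_mixture = config$cancer_mixture),
                      class = "sim_truth")
  ), class = "sim_landscape")
}

# cover roughly `fraction` of each chromosome with non-overlapping intervals
# of size `piece`, placed uniformly
place_cover <- function(chrom_lengths, fraction, piece) {
  out <- list()
  for (c in names(chrom_lengths)) {
    n <- floor(fraction * chrom_lengths[[c]] / piece)
    if (n < 1) next
    s <- place_nonoverlapping(rep(piece, n), chrom_lengths[[c]])
    out[[c]] <- data.frame(chrom = c, start = s, end = s + piece,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# complement of a set of disjoint sorted intervals within one chromosome
complement_intervals <- function(intervals, chrom, chrom_length) {
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = chrom, start = 0, end = chrom_length,
                      stringsAsFactors = FALSE))
  }
  iv <- intervals[order(intervals$start), , drop = FALSE]
  starts <- c(0, iv$end)
  ends <- c(iv$start, chrom_length)
  keep <- ends > starts
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

#' Worked-example fixture: four exon-overlapping hotspot elements
#'
#' The four elements whose exon-overlapping hotspots anchor the worked
#' example (lengths 264, 702, 1044, 1585 on chromosomes 1, 19, 14, 19;
#' observed nsSNV counts 35, 92, 116, 249), together with a coding background
#' calibrated so that the shortest element expects 20.47 SNVs
#' (density 20.47/264 per base, N = 2,867,887 sites).  `snvs` places exactly
#' the observed number of distinct sites inside each element so the full
#' pipeline reproduces the observed counts; `gene` records the overlapping
#' human gene per element.
#'
#' @return list with `elements` ([herv_elements]), `gene` (named by
#'   element_id), `observed` (named counts), `background`
#'   ([make_background()]), and `snvs` ([snv_records]).
#' @export
table2_fixture <- function() {
  elements <- herv_elements(
    element_id = c("6114", "4780", "4062", "4673"),
    chrom = c("1", "19", "14", "19"),
    start = c(175036994, 55238993, 20447009, 22932001),
    end = c(175036994, 55238993, 20447009, 22932001) +
      c(264, 702, 1044, 1585),
    group = c("HERV-9/LTR12", "MST/MaLR", "HERV-IP10F/LTR10F",
              "HERV-W/LTR17/HERV17"),
    supergroup = c("GE", "S", "GE", "GE"),
    canonical = FALSE
  )
  gene <- stats::setNames(c("TNN", "KIR2DL1", "OR4K15", "ZNF99"),
                          elements$element_id)
  observed <- stats::setNames(c(35, 92, 116, 249), elements$element_id)
  N <- 2867887
  background <- make_background("coding",
                                total_bases_L = round(N * 264 / 20.47),
                                total_snvs_N = N)
  labels <- c("skin cancer", "lung cancer", "colon cancer", "kidney cancer",
              "thyroid cancer")
  snv_list <- lapply(seq_len(nrow(elements)), function(i) {
    k <- observed[[elements$element_id[i]]]
    data.frame(chrom = elements$chrom[i],
               pos = elements$start[i] + seq_len(k),  # 1-based, inside [s, e)
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, snv_list)
  n <- nrow(sites)
  ref <- rep_len(c("C", "G", "A", "T"), n)
  alt <- rep_len(c("T", "A", "G", "C"), n)
  snvs <- snv_records(sites$chrom, sites$pos, ref, alt,
                      cancer_label = rep_len(labels, n),
                      region_class = "coding")
  list(elements = elements, gene = gene, observed = observed,
       background = background, snvs = snvs)
}
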