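---
title: "Detecting somatic mutation hotspots in HERV elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mutation hotspots in HERV elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervscan)
```

## The problem

Human endogenous retroviruses (HERVs) make up roughly 8% of the human
genome.  A systematically classified annotation set of ~3,100 elements —
each either *canonical* (a single HERV group) or *non-canonical* (a mosaic
of two or more groups), and each assigned to a supergroup (GE =
Gamma-/Epsilon-retrovirus-related, AB = Alpha-/Beta-retrovirus-related,
S = Spumavirus-related, plus uncertain Errantivirus-like and unclassified
bins) — makes it possible to ask whether particular elements accumulate
somatic single-nucleotide variants (SNVs) in cancer far beyond what their
size alone predicts.  Such elements ("hotspots") are candidate biomarkers
and candidate players in tumorigenesis, especially where they overlap
exons, lncRNAs, or regulatory sites.

`hervscan` implements that question as a reusable pipeline: map SNVs onto
elements by coordinate, test every element against a uniform-genome null,
control the family-wise error rate, and aggregate the hits by taxonomy,
cancer type, and DNA functional element.

## The model

The genome is partitioned into two region classes — protein-coding
(exon/CDS union) and non-coding (everything else) — and each class is
analysed separately, because their SNV compilations come from different
experimental designs (exome vs whole-genome sequencing) with very
different densities.  Retroviral ORFs (gag/pro/pol/env) do *not* count as
human protein-coding sequence: only intervals present in the supplied
coding annotation do.

Within a region class of $L$ bases carrying $N$ observed SNV sites, the
null hypothesis is that every base is equally likely to carry a site.  For
an element of length $n_F$:

$$p_F = \frac{n_F}{L}, \qquad n_E = N \, p_F,$$

and the observed count $n_O$ is referred to the binomial tail

$$P(X \ge n_O) = \sum_{n = n_O}^{N} \binom{N}{n} p_F^{\,n} (1 - p_F)^{N - n},
\qquad X \sim \mathrm{Binomial}(N, p_F).$$

`binomial_tail()` evaluates this through the regularized incomplete beta
function (`pbinom`), which is accurate to well below $10^{-300}$ — far
tails matter here, since genome-scale hotspots reach p-values of
$10^{-26}$ and beyond.  Significance is declared on the
*direction-matched* one-sided tail (upper for over-represented elements,
lower for depleted ones) below the Bonferroni cutoff $\alpha / n$, with
$\alpha = 0.05$ and $n$ the number of elements actually tested (an
explicit override reproduces published thresholds such as $0.05/58 =
8.62\times10^{-4}$ and $0.05/3130 = 1.60\times10^{-5}$).  A two-sided
option ($2 \min(p_\mathrm{up}, p_\mathrm{low})$, capped at 1) is available
but not the default, because published hotspot tables report
over-representation and depletion from one threshold applied per
direction.

### Why three tail modes

`scan_config(tail_mode = ...)` offers:

* `exact_binomial` (default) — the formula above, exact.
* `poisson` — the $N \to \infty$, $p_F \to 0$ limit with
  $\lambda = n_E$; at genome scale ($N \ge 10^5$, $p_F \le 10^{-3}$) it
  agrees with the exact tail to well under 1% and is useful as a
  cross-check.
* `normal_paper_compat` — the continuity-uncorrected normal approximation
  $z = (n_O - n_E)/\sqrt{n_E (1 - p_F)}$, upper tail.

The third mode exists because published per-element p-values computed from
the printed $(n_O, n_E)$ pairs are *not* reproducible with the exact
binomial: for the shortest worked-example element (length 264, $n_O = 35$,
$n_E = 20.47$) the exact upper tail is $\approx 2.15\times10^{-3}$,
whereas the printed value ($6.67\times10^{-4}$) is closest to the normal
approximation ($\approx 6.6\times10^{-4}$).  The package treats the exact
tail as authoritative — correctness over replication of an ambiguous
implementation — and keeps the compatibility mode for comparison.  Note
the practical consequence: at the $8.62\times10^{-4}$ threshold that
element is significant under the normal approximation but *not* under the
exact binomial.

### Counting sites vs events

Genome-scale compilations count *sites impacted by* SNVs, which collapses
recurrent mutations at one position.  Whether recurrences were collapsed
upstream is not always documented, so both modes are exposed:
`collapse_sites()` (and `cmd_scan(count_mode = "sites")`, the default)
collapses per (chromosome, position); `count_mode = "events"` keeps every
record.

### Coordinate conventions

Internally every interval is 0-based half-open (BED arithmetic); SNV
positions are 1-based on input and output (VCF convention) and converted
at query time: a position $p$ hits $[s, e)$ iff $s \le p - 1 < e$.
Chromosome names are prefix-tolerant (`chr1` and `1` unify).  Strand is
ignored — mapping is purely positional.  Elements may overlap each other;
each is tested marginally, and one SNV inside two overlapping elements
increments both observed counts, so per-element totals may exceed the SNV
count.  Element length is always `end - start` of the annotated interval.

### Background lengths

$L$ for the coding background is the *merged union* of the coding
intervals (overlapping exon annotations are not double-counted); $L$ for
the non-coding background is the declared genome length minus that union.
An optional exclusion set (assembly gaps, centromeric N-runs) can be
subtracted as well, since whether such regions were excluded upstream is
usually unstated; by default nothing is excluded.

### The fragment-sampling check

`fragment_ratio_scan()` implements the permutation-style sanity check on
the background: sample fixed-size windows (default 1000 bases) uniformly
with replacement inside a region, count SNVs per window, and compare the
mean per-base ratio with $N/L$.  Windows are placed entirely within single
region intervals, which is equivalent to rejecting and resampling any
placement that crosses a boundary.  It is seed-deterministic.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | — | conventional FWER target |
| `n_tests` | `"auto"` | tests | elements actually tested; explicit override available because published divisors (58, 3130) do not equal the printed element counts — most plausibly the number of elements with at least one SNV, but undocumented |
| `tail_mode` | `exact_binomial` | — | see above |
| `min_observed_to_test` | 1 | SNVs | an element with zero observed SNVs cannot be called over-represented and would only dilute the Bonferroni family |
| `fragment_size` | 1000 | bases | matches the published window size |

Ties $n_O = n_E$ (possible only when $n_E$ is integral) get direction
`"equal"` and are never significant.

## The synthetic generator

No pan-cancer SNV compilation can ship with the package, so
`simulate_landscape()` generates landscapes with exactly the structure the
null model assumes, plus controlled violations:

* non-overlapping elements placed uniformly (real HERVs can overlap; the
  engine supports that, but the generator keeps ground truth unambiguous);
* every base mutates independently: probability `base_rate` ×
  `multiplier` inside spiked elements, `base_rate` elsewhere; at most one
  SNV per base by default (site counting), with an event mode allowing
  recurrences;
* alleles uniform over distinct nucleotides; cancer labels drawn from a
  fixed mixture independently of position; all output reproducible from
  the seed.

Defaults state a desk-scale world, fixed once: a 10 Mb genome over 2
chromosomes, 200 elements of 5–15 kb, `base_rate` 2e-3 (so per-element
expected counts sit in the ~20 range where the binomial test has
interesting behaviour), an exome-like 2% coding fraction, and a cancer
mixture skin/esophageal/liver = 0.766/0.154/0.080, proportional to
reported per-element SNV means (144/29/15) of the three dominant cancer
types in pan-cancer non-coding data.  Track coverages (lncRNA 20%, intron
35%, TFBS 5%, AS 1%, PE 0.5%, CpG 1%) are loosely scaled to genome-wide
annotation shares.

What a green test does establish: family-wise error control under the
uniform null, power to recover 5× spikes at $n_E \ge 20$, exactness of the
interval arithmetic, and correct plumbing end to end.  What it does not:
robustness to mutational signatures, regional rate covariates (replication
timing, chromatin), clonality, or copy number — the generator deliberately
contains none of these, and the uniform null is known to be optimistic on
real genomes.

## Functional-element overlap

Published category proportions (lncRNA 60%, intron 22.2%, TFBS ~15%, AS
1.7%, PE 0.27%, CpG 0.2%) sum to ≈99.4%, suggesting near-exclusive
assignment, while the accompanying text says "at least one functional
element" — an ambiguity the package exposes rather than buries.
`functional_overlap()` therefore implements both modes: `exclusive`
(default; each SNV assigned to its highest-precedence overlapping track,
default precedence lncRNA ≻ intron ≻ TFBS ≻ AS ≻ PE ≻ CpG, i.e.
descending reported share) and `multi` (one count per overlapped track),
and `cmd_report()` writes both side by side.  Per-category numerators were
never published, so these proportions are property-tested (conservation,
mode dominance, brute-force equality) rather than value-matched.

## Numerical and degenerate-input choices

* `pbinom`/`ppois`-based tails; no hand-rolled summation in the
  implementation (direct pmf summation exists only as a test oracle).
* `p_upper(n_O) + p_lower(n_O - 1) = 1` holds to double precision and is
  asserted property-style.
* An element spanning its whole region ($p_F = 1$) yields an upper tail of
  1 at $n_O = N$ and can never be significant.
* Empty element lists and zero-SNV inputs produce empty results and exit
  status 0, not errors; malformed records produce located errors (file and
  line) with exit status 3.
* Proportions in group summaries are relative to one grouping universe and
  sum to 1 by construction; percentage rounding is one decimal by default
  with an integer-percent option, mirroring mixed published styles.

## Known limitations

* The uniform null ignores sequence-context mutation signatures and
  regional rate variation; on real data the over-representation calls are
  anti-conservative and should be read as a ranking, not calibrated
  p-values.
* Cancer-type labels are free-form strings; ontology (DOID) normalization
  must be supplied by the user as a lookup, since curated mappings are not
  reproducible from published material.
* Amino-acid positions for the functional-site join are taken from the
  input annotation as-is; no codon translation is performed.
* No liftover: all inputs must share one genome build.
* Compressed/indexed access (tabix/BGZF) is not implemented; inputs are
  plain text.
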