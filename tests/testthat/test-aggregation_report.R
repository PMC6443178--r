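# group summaries, cancer crosstabs, functional overlap, site annotation

test_that("summarize_by_group reproduces the published proportion splits", {
  res32 <- data.frame(direction = rep(c("under", "over"), c(28, 4)))
  s <- summarize_by_group(res32, "direction")
  expect_equal(pct(s$proportion[s$direction == "under"]), 87.5)
  expect_equal(pct(s$proportion[s$direction == "over"]), 12.5)

  res1820 <- data.frame(direction = rep(c("over", "under"), c(788, 1032)))
  s2 <- summarize_by_group(res1820, "direction")
  expect_equal(pct(s2$proportion[s2$direction == "over"], digits = 0), 43)
  expect_equal(pct(s2$proportion[s2$direction == "under"], digits = 0), 57)

  expect_equal(pct(66, 72), 91.7)

  empty <- summarize_by_group(res32[0, , drop = FALSE], "direction")
  expect_equal(nrow(empty), 0)
  expect_error(summarize_by_group(res32, "nope"),
               class = "herv_invalid_argument")
})

test_that("summaries are deterministic and order-invariant", {
  set.seed(73)
  x <- data.frame(supergroup = sample(c("GE", "AB", "S"), 500, TRUE,
                                      prob = c(.6, .3, .1)),
                  canonical = sample(c(TRUE, FALSE), 500, TRUE))
  a <- summarize_by_group(x, c("supergroup", "canonical"))
  b <- summarize_by_group(x[sample.int(500), ], c("supergroup", "canonical"))
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_true(!is.unsorted(rev(a$snv_count)))      # descending counts
  expect_equal(sum(a$proportion), 1, tolerance = 1e-9)
})

test_that("cancer_crosstab counts cells and conserves marginals", {
  a <- data.frame(element_id = "4673", cancer_label = "skin cancer")
  t1 <- cancer_crosstab(a)
  expect_equal(dim(t1), c(1, 1))
  expect_equal(unname(t1[1, 1]), 1L)

  unl <- data.frame(element_id = c("e1", "e2"),
                    cancer_label = c(NA, NA))
  t2 <- cancer_crosstab(unl)
  expect_equal(colnames(t2), "unlabeled")
  expect_equal(sum(t2), 2L)

  set.seed(79)
  mix <- c("skin cancer" = 0.7, "lung cancer" = 0.3)
  n <- 4000
  asg <- data.frame(element_id = sample(sprintf("e%d", 1:10), n, TRUE),
                    cancer_label = sample(names(mix), n, TRUE, prob = mix))
  tab <- cancer_crosstab(asg)
  expect_equal(sum(tab), n)
  expect_equal(rowSums(tab)[order(rownames(tab))],
               table(asg$element_id)[order(names(table(asg$element_id)))] |>
                 as.integer() |> setNames(sort(unique(asg$element_id))))
  # column marginals within 3 MC standard errors of the mixture
  for (lab in names(mix)) {
    p <- mix[[lab]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(sum(tab[, lab]) / n - p), 3 * se)
  }
  # marginals conserved under permutation
  perm <- tab[sample.int(nrow(tab)), sample.int(ncol(tab)), drop = FALSE]
  expect_equal(sort(rowSums(perm)), sort(rowSums(tab)))
  expect_equal(sum(perm), sum(tab))
})

test_that("functional_overlap: constructed multi/exclusive case", {
  tracks <- list(
    lncRNA = functional_track("lncRNA", "chr1", 100, 300),
    intron = functional_track("intron", "chr1", 200, 400))
  s <- snv_records("chr1", 250, "C", "G")  # inside both
  multi <- functional_overlap(s, tracks, "multi")
  expect_equal(unname(multi$counts), c(1, 1))
  excl <- functional_overlap(s, tracks, "exclusive",
                             precedence = c("lncRNA", "intron"))
  expect_equal(unname(excl$counts), c(1, 0))
  expect_equal(excl$per_snv, "lncRNA")

  away <- snv_records("chr1", 9999, "C", "G")
  none <- functional_overlap(away, tracks, "exclusive")
  expect_true(all(none$counts == 0))
  expect_equal(none$none, 1)

  expect_error(functional_overlap(s, tracks, "exclusive",
                                  precedence = "lncRNA"),
               class = "herv_invalid_argument")
})

test_that("multi-mode overlap equals brute-force membership on random data", {
  set.seed(83)
  tracks <- lapply(1:6, function(i) {
    iv <- rand_intervals(30, max_pos = 5000, max_len = 200)
    functional_track(paste0("t", i), iv$chrom, iv$start, iv$end)
  })
  names(tracks) <- paste0("t", 1:6)
  snvs <- rand_snvs(2000, max_pos = 5000)
  multi <- functional_overlap(snvs, tracks, "multi")
  for (nm in names(tracks)) {
    expect_equal(unname(multi$counts[nm]),
                 sum(bf_member(snvs, as.data.frame(tracks[[nm]]))))
  }
  # exclusive counts sum to #SNVs overlapping >= 1 track; multi >= exclusive
  excl <- functional_overlap(snvs, tracks, "exclusive")
  expect_equal(sum(excl$counts), nrow(snvs) - excl$none)
  expect_true(all(multi$counts >= excl$counts))
})

test_that("annotate_sites joins on (gene, aa_pos) with deduplication", {
  site_tab <- data.frame(
    gene = c("KIR2DL1", "KIR2DL1", "KIR2DL1", "TNN"),
    aa_pos = c(22, 22, 103, 664),
    effect = c("Gain|Phosphorylation", "Gain|Phosphorylation",
               "Gain|Phosphorylation", "Gain|Phosphorylation"))
  q <- data.frame(gene = c("KIR2DL1", "KIR2DL1", "ZNF99"),
                  aa_pos = c(22, 32, 620))
  ann <- annotate_sites(q, site_tab)
  expect_equal(ann$effect, c("Gain|Phosphorylation", "", ""))

  # duplicates with distinct effects join with ";" (set union, sorted)
  dup <- data.frame(gene = "G", aa_pos = 5,
                    effect = c("Loss|Glycosylation", "Gain|Phosphorylation",
                               "Loss|Glycosylation"))
  ann2 <- annotate_sites(data.frame(gene = "G", aa_pos = 5), dup)
  expect_equal(ann2$effect, "Gain|Phosphorylation;Loss|Glycosylation")

  ann3 <- annotate_sites(q, site_tab[0, ])
  expect_equal(ann3$effect, c("", "", ""))
})

test_that("functional_overlap_by_class joins categories with taxonomy", {
  el <- herv_elements(c("a", "b"), "chr1", c(0, 1000), c(500, 1500), "g",
                      supergroup = c("GE", "S"), canonical = c(TRUE, FALSE))
  tracks <- list(lncRNA = functional_track("lncRNA", "chr1", 0, 1500))
  s <- snv_records("chr1", c(100, 1100, 3000), c("C", "C", "C"),
                   c("G", "G", "G"))
  out <- functional_overlap_by_class(s, el, tracks)
  expect_equal(sum(out$snv_count), 2)  # third SNV hits no element
  expect_setequal(out$supergroup, c("GE", "S"))
})
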