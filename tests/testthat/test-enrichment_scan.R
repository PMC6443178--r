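# binomial/poisson tails, expected counts, Bonferroni control, the scan
# itself, and the random-fragment background check

test_that("expected_count reproduces the calibrated worked-example values", {
  bg <- table2_fixture()$background
  expect_equal(round(expected_count(264, bg), 2), 20.47)
  expect_equal(round(expected_count(702, bg), 2), 54.43)
  expect_equal(round(expected_count(1044, bg), 2), 80.95)
  expect_equal(expected_count(0, bg), 0)
  expect_error(expected_count(-1, bg), class = "herv_invalid_argument")
})

test_that("binomial_tail handles edge and hand-computed cases", {
  expect_equal(binomial_tail(0, 100, 0.3, "upper"), 1)
  expect_equal(binomial_tail(0, 7, 0.9, "upper"), 1)
  expect_equal(binomial_tail(5, 5, 0.2, "upper"), 0.2^5)
  expect_equal(binomial_tail(8, 10, 0.5, "upper"), 56 / 1024)
  expect_equal(binomial_tail(10, 10, 0.5, "lower"), 1)
  expect_error(binomial_tail(6, 5, 0.2), class = "herv_invalid_argument")
  expect_error(binomial_tail(1, 5, 1.2), class = "herv_invalid_argument")
})

test_that("binomial_tail equals direct pmf summation for N <= 500", {
  set.seed(53)
  for (i in 1:300) {
    N <- sample.int(500, 1)
    p <- runif(1)
    n_O <- sample.int(N + 1, 1) - 1
    expect_equal(binomial_tail(n_O, N, p, "upper"), bf_binom_upper(n_O, N, p),
                 tolerance = 1e-12)
    expect_equal(binomial_tail(n_O, N, p, "lower"), bf_binom_lower(n_O, N, p),
                 tolerance = 1e-12)
  }
})

test_that("tail identities and monotonicity hold", {
  set.seed(59)
  for (i in 1:50) {
    N <- sample.int(1000, 1)
    p <- runif(1)
    ks <- 0:N
    up <- binomial_tail(ks, N, p, "upper")
    expect_true(all(diff(up) <= 1e-15))           # non-increasing in n_O
    lo <- binomial_tail(pmax(ks - 1, 0), N, p, "lower")
    both <- up[-1] + lo[-1]                        # p_up(k) + p_lo(k-1) = 1
    expect_equal(both, rep(1, N), tolerance = 1e-12)
  }
  # deep tail stays finite, positive and accurate far below 1e-100
  deep <- binomial_tail(150, 1e6, 1e-5, "upper")
  expect_true(deep > 0)
  expect_equal(log10(deep), log10(8.427082e-118), tolerance = 1e-6)
})

test_that("poisson_tail: closed forms and agreement with the binomial", {
  expect_equal(poisson_tail(0, 3.7, "upper"), 1)
  expect_equal(poisson_tail(1, 1, "lower"), 2 / exp(1))
  expect_error(poisson_tail(1, -1), class = "herv_invalid_argument")

  # the worked-example regime: N ~ 2.9e6, lambda ~ 20.47
  N <- 2867887
  p <- 20.47 / N
  expect_equal(poisson_tail(35, 20.47, "upper"),
               binomial_tail(35, N, p, "upper"), tolerance = 5e-3)

  # agreement within 1% relative for N >= 1e5, p <= 1e-3, mid-to-far quantiles
  set.seed(61)
  for (i in 1:30) {
    N <- sample(c(1e5, 1e6, 5e6), 1)
    p <- 10^runif(1, -6, -3)
    lam <- N * p
    for (q in c(0.5, 0.9, 0.99, 0.9999)) {
      k <- stats::qbinom(q, N, p)
      b <- binomial_tail(k, N, p, "upper")
      po <- poisson_tail(k, lam, "upper")
      expect_lt(abs(po - b) / b, 0.01)
    }
  }
})

test_that("bonferroni_threshold reproduces the published cutoffs", {
  expect_equal(signif(bonferroni_threshold(0.05, 58), 3), 8.62e-4)
  expect_equal(signif(bonferroni_threshold(0.05, 3130), 3), 1.60e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), class = "herv_invalid_argument")
})

test_that("scan on the worked-example fixture reproduces the printed layer", {
  fx <- table2_fixture()
  res <- scan_elements(fx$elements, fx$snvs, fx$background,
                       scan_config(n_tests = 58))
  expect_equal(nrow(res), 4)
  expect_equal(attr(res, "threshold"), 0.05 / 58)
  m <- match(c("6114", "4780", "4062", "4673"), res$element_id)
  expect_equal(res$observed[m], c(35, 92, 116, 249))
  expect_equal(round(res$expected[m], 2), c(20.47, 54.43, 80.95, 122.90))
  expect_true(all(res$direction == "over"))
  # results ordered by ascending matched p-value
  expect_true(!is.unsorted(res$p_matched))
  # exact binomial at the printed inputs does NOT reproduce the printed
  # 6.67e-4 for the shortest element; it gives ~2.15e-3 ...
  expect_equal(res$p_upper[m[1]], 2.154241e-3, tolerance = 1e-4)
  # ... while the continuity-uncorrected normal mode lands near it
  resn <- scan_elements(fx$elements, fx$snvs, fx$background,
                        scan_config(n_tests = 58,
                                    tail_mode = "normal_paper_compat"))
  pn <- resn$p_upper[match("6114", resn$element_id)]
  expect_true(pn > 4e-4 && pn < 8e-4)
})

test_that("scan degenerate and tie cases behave as specified", {
  # element spanning the whole region: p_F = 1, upper tail at n_O = N is 1
  el <- herv_elements("all", "chr1", 0, 1000, "g")
  bg <- make_background("coding", 1000, 5)
  s <- snv_records(rep("chr1", 5), c(10, 20, 30, 40, 50), rep("C", 5),
                   rep("G", 5), region_class = "coding")
  res <- scan_elements(el, s, bg, scan_config())
  expect_equal(res$p_upper, 1)
  expect_false(res$significant)
  expect_equal(res$direction, "equal")  # n_O = n_E = 5 exactly

  # integral tie: direction "equal", never significant
  el2 <- herv_elements("half", "chr1", 0, 500, "g")
  bg2 <- make_background("coding", 1000, 10)
  s2 <- snv_records(rep("chr1", 5), 1:5, rep("A", 5), rep("G", 5),
                    region_class = "coding")
  res2 <- scan_elements(el2, s2, bg2, scan_config())
  expect_equal(res2$direction, "equal")
  expect_false(res2$significant)

  # empty element list -> empty results, not an error
  res0 <- scan_elements(el[0, ], s, bg, scan_config())
  expect_equal(nrow(res0), 0)

  # min_observed_to_test excludes zero-count elements from the family
  el3 <- herv_elements(c("hit", "misses"), "chr1", c(0, 600), c(100, 700), "g")
  res3 <- scan_elements(el3, s, bg, scan_config())
  expect_equal(attr(res3, "n_tests"), 1L)
  expect_equal(res3$element_id, "hit")
})

test_that("sum of expected counts over disjoint elements is N * bases / L", {
  set.seed(67)
  bg <- make_background("noncoding", 1e6, 12345)
  lens <- sample.int(5000, 40)
  starts <- cumsum(c(0, lens[-40] + 10))
  el <- herv_elements(sprintf("d%02d", 1:40), "chr1", starts, starts + lens, "g")
  expect_equal(sum(expected_count(lens, bg)),
               bg$total_snvs_N * sum(lens) / bg$total_bases_L)
})

test_that("manhattan_table exposes midpoints and -log10 matched p", {
  fx <- table2_fixture()
  res <- scan_elements(fx$elements, fx$snvs, fx$background,
                       scan_config(n_tests = 58))
  mt <- manhattan_table(res)
  expect_equal(nrow(mt), 4)
  expect_equal(mt$midpoint, (res$start + res$end) / 2)
  expect_equal(mt$neg_log10_p, -log10(res$p_matched))
})

test_that("fragment_ratio_scan: determinism, zero SNVs, LLN recovery", {
  region <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  expect_equal(fragment_ratio_scan(region, rand_snvs(0), 1000, 50,
                                   seed = 3)$observed_ratio, 0)
  set.seed(71)
  n <- rbinom(1, 2e6, 0.02)
  snvs <- snv_records("chr1", sample.int(2e6, n), "C", "G")
  a <- fragment_ratio_scan(region, snvs, 1000, 1000, seed = 9)
  b <- fragment_ratio_scan(region, snvs, 1000, 1000, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_equal(a$observed_ratio, sum(a$counts) / (1000 * 1000))
  se <- stats::sd(a$counts) / sqrt(1000) / 1000
  expect_lt(abs(a$observed_ratio - 0.02), 3 * se + 1e-4)

  expect_error(fragment_ratio_scan(data.frame(chrom = "1", start = 0, end = 500),
                                   snvs, 1000, 10),
               class = "herv_invalid_argument")
})
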