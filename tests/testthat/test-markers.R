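marker_frame <- function(id, female, male, support = 5L) {
  data.frame(marker_id = id, parent_female = female, parent_male = male,
             read_support = support, stringsAsFactors = FALSE)
}

test_that("marker typing follows parental presence", {
  mk <- marker_frame(c("m1", "m2", "m3", "m4"),
                     female = c(TRUE, FALSE, TRUE, FALSE),
                     male = c(FALSE, TRUE, TRUE, FALSE))
  geno <- matrix(rep(c(1L, 0L), 93), 4, 186, byrow = TRUE,
                 dimnames = list(mk$marker_id, sprintf("F%03d", 1:186)))
  got <- classify_and_filter_markers(mk, geno)
  expect_equal(got$marker_type, c("lm_ll", "nn_np", "hk_hk",
                                  "inconsistent"))
  expect_false(got$retained[4])
  expect_equal(got$drop_reason[4], "absent in both parents")
})

test_that("a perfect 1:1 marker is retained with zero chi-squared", {
  mk <- marker_frame("m1", TRUE, FALSE)
  geno <- matrix(rep(c(1L, 0L), 93), 1, 186,
                 dimnames = list("m1", sprintf("F%03d", 1:186)))
  got <- classify_and_filter_markers(mk, geno)
  expect_equal(got$seg_chi2, 0)
  expect_true(got$retained)
})

test_that("low call rate and distorted segregation are removed", {
  mk <- marker_frame(c("m1", "m2"), TRUE, FALSE)
  g1 <- c(rep(1L, 45), rep(0L, 46), rep(NA, 95))       # 49% called
  g2 <- c(rep(1L, 150), rep(0L, 36))                   # 150:36 under 1:1
  geno <- rbind(m1 = g1, m2 = g2)
  colnames(geno) <- sprintf("F%03d", 1:186)
  got <- classify_and_filter_markers(mk, geno)
  expect_false(got$retained[1])
  expect_equal(got$drop_reason[1], "low call rate")
  expect_false(got$retained[2])
  expect_equal(got$drop_reason[2], "distorted segregation")
  # hand-computed chi-squared for 150:36 against 93:93
  expect_equal(got$seg_chi2[2], (150 - 93)^2 / 93 + (36 - 93)^2 / 93)
  expect_lt(got$seg_p[2], 0.01)
})

test_that("read support below two removes a marker", {
  mk <- marker_frame("m1", TRUE, FALSE, support = 1L)
  geno <- matrix(rep(c(1L, 0L), 93), 1, 186,
                 dimnames = list("m1", sprintf("F%03d", 1:186)))
  got <- classify_and_filter_markers(mk, geno)
  expect_false(got$retained)
  expect_equal(got$drop_reason, "read support")
})

test_that("hk_hk markers are tested against 3:1", {
  mk <- marker_frame("m1", TRUE, TRUE)
  geno <- matrix(c(rep(1L, 140), rep(0L, 46)), 1, 186,
                 dimnames = list("m1", sprintf("F%03d", 1:186)))
  got <- classify_and_filter_markers(mk, geno)
  ref <- stats::chisq.test(c(140, 46), p = c(3, 1) / 4)
  expect_equal(got$seg_chi2, unname(ref$statistic))
  expect_true(got$retained)
})

test_that("two-point linkage closed forms hold", {
  # 100 informative progeny, 0 recombinants
  a <- rep(c(1L, 0L), 50)
  got <- pairwise_linkage(a, a)
  expect_equal(got$rf, 0)
  expect_equal(got$lod, 100 * log10(2))
  expect_true(got$groupable)

  # 50 recombinants of 100 -> rf 0.5, lod 0
  b <- a; b[seq(1, 100, by = 2)] <- 1L - b[seq(1, 100, by = 2)]
  half <- pairwise_linkage(a, b)
  expect_equal(half$rf, 0.5)
  expect_equal(half$lod, 0)
  expect_false(half$groupable)

  # rf = 0.45 exceeds the 0.4 grouping ceiling regardless of lod
  c45 <- a; flip <- sample(1:100, 45); c45[flip] <- 1L - c45[flip]
  r45 <- pairwise_linkage(a, c45)
  expect_equal(r45$rf, 0.45)
  expect_false(r45$groupable)

  # lod is strictly decreasing in rf for fixed n
  lods <- sapply(seq(5, 45, by = 5), function(k) {
    x <- a; x[seq_len(k)] <- 1L - x[seq_len(k)]
    pairwise_linkage(a, x)$lod
  })
  expect_true(all(diff(lods) < 0))

  # insufficient informative progeny
  few <- pairwise_linkage(c(1L, 0L, rep(NA, 98)), a)
  expect_false(few$groupable)
  expect_equal(few$reason, "too few informative progeny")
})

test_that("Kruskal-Wallis scan agrees with first-principles H and exact permutation", {
  y <- c(3.1, 5.2, 1.0, 7.4, 2.2, 6.6, 4.0, 5.9)
  g <- c(0, 1, 0, 1, 0, 1, 0, 1)
  geno <- matrix(g, 1, 8, dimnames = list("m1", sprintf("F%03d", 1:8)))
  got <- kw_scan(geno, stats::setNames(y, colnames(geno)))
  expect_equal(got$H, oracle_kw_h(y, g))
  # the exact permutation p and the chi-squared approximation agree on
  # the significance call at the scan's alpha
  exact_p <- oracle_kw_perm_p(y, g)
  expect_equal(got$significant, exact_p < 0.001)

  # ties are handled by the corrected statistic
  yt <- c(1, 1, 2, 2, 3, 3, 4, 4)
  gt <- kw_scan(matrix(g, 1, 8, dimnames = list("m1", NULL)), yt)
  expect_equal(gt$H, oracle_kw_h(yt, g))
})

test_that("degenerate Kruskal-Wallis inputs are non-evaluable or null", {
  # identical trait values -> H = 0 (tie correction collapses), p = 1
  geno <- matrix(c(0, 0, 0, 1, 1, 1), 1, 6, dimnames = list("m1", NULL))
  same <- kw_scan(geno, rep(5, 6))
  expect_true(is.na(same$H) || same$H == 0 || same$p == 1)

  # a single genotype class cannot be tested
  mono <- kw_scan(matrix(rep(1, 6), 1, 6, dimnames = list("m1", NULL)),
                  rnorm(6))
  expect_true(is.na(mono$p))
  expect_false(mono$significant)
})
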