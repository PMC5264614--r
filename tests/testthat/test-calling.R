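test_that("the four canonical evidence patterns call as documented", {
  expect_equal(call_site_state(3, 0, 0, 3), "hemi_mCCGG")
  expect_equal(call_site_state(0, 2, 2, 0), "full_CmCGG")
  expect_equal(call_site_state(0, 0, 2, 2), "full_mCCGG")
  expect_equal(call_site_state(2, 2, 0, 0), "unmethylated")
  expect_equal(call_site_state(1, 1, 0, 0), "no_call")  # below read floor
  expect_error(call_site_state(-1, 0, 0, 0), "non-negative")
})

test_that("caller equals the enumerated truth table on all counts in 0..4", {
  grid <- expand.grid(hc = 0:4, mc = 0:4, hb = 0:4, mb = 0:4)
  want <- mapply(oracle_call, grid$hc, grid$mc, grid$hb, grid$mb)
  got <- call_site_state(grid$hc, grid$mc, grid$hb, grid$mb)
  expect_equal(got, unname(want))
})

test_that("thresholds are configurable", {
  cfg <- run_config(min_total_reads = 8, min_reads_per_enzyme = 4)
  expect_equal(call_site_state(3, 0, 0, 3, cfg), "no_call")
  expect_equal(call_site_state(4, 0, 0, 4, cfg), "hemi_mCCGG")
})

test_that("population summary applies the two-sample and 2/3 rules", {
  # 10 samples: 8 hemi, 2 full -> hemi_fraction 0.8 > 2/3
  states <- matrix(c(rep("hemi_mCCGG", 8), rep("full_mCCGG", 2)),
                   nrow = 1)
  colnames(states) <- sprintf("S%02d", 1:10)
  rownames(states) <- "s1:0"
  summ <- summarize_population(states)
  expect_equal(summ$n_methylated, 10L)
  expect_equal(summ$hemi_fraction, 0.8)
  expect_equal(summ$site_class, "hemi")
  expect_true(summ$polymorphic)

  # methylated in exactly one sample -> dropped
  one <- matrix(c("hemi_mCCGG", rep("unmethylated", 9)), nrow = 1,
                dimnames = list("s1:0", sprintf("S%02d", 1:10)))
  expect_equal(nrow(summarize_population(one)), 0L)

  # all samples share full_mCCGG -> monomorphic
  mono <- matrix("full_mCCGG", 1, 10,
                 dimnames = list("s1:0", sprintf("S%02d", 1:10)))
  s <- summarize_population(mono)
  expect_true(s$monomorphic)
  expect_false(s$polymorphic)
  expect_equal(s$site_class, "full")
})

test_that("a recurring identical methylated state is required for retention", {
  # hemi in one sample, CmCGG in another: methylated twice but never
  # identically -> dropped under the default reading
  mixed <- matrix(c("hemi_mCCGG", "full_CmCGG", rep("unmethylated", 8)),
                  nrow = 1, dimnames = list("s1:0", sprintf("S%02d", 1:10)))
  expect_equal(nrow(summarize_population(mixed)), 0L)
})

test_that("population summary matches a direct per-site tally on random data", {
  set.seed(31)
  states <- matrix(sample(methylation_states(), 50 * 12, replace = TRUE),
                   50, 12,
                   dimnames = list(sprintf("s1:%d", (0:49) * 10),
                                   sprintf("S%02d", 1:12)))
  summ <- summarize_population(states)
  for (i in seq_len(nrow(summ))) {
    s <- states[sprintf("s1:%d", summ$position[i]), ]
    n_meth <- sum(s %in% c("hemi_mCCGG", "full_CmCGG", "full_mCCGG"))
    expect_equal(summ$n_methylated[i], n_meth)
    expect_equal(summ$n_called[i], sum(s != "no_call"))
    expect_equal(summ$hemi_fraction[i] + summ$full_fraction[i], 1)
    expect_gte(max(table(s[s %in% c("hemi_mCCGG", "full_CmCGG",
                                    "full_mCCGG")])), 2)
  }
  # partition property: every retained site is polymorphic xor monomorphic
  expect_true(all(xor(summ$polymorphic, summ$monomorphic)))
})

test_that("inheritance classification covers the documented patterns", {
  # parents share full_mCCGG, F1 uniform -> A2
  expect_equal(classify_inheritance(c("full_mCCGG", "full_mCCGG"),
                                    rep("full_mCCGG", 6))$class_label, "A2")
  # parents share hemi, F1 uniform -> A1
  expect_equal(classify_inheritance(c("hemi_mCCGG", "hemi_mCCGG"),
                                    rep("hemi_mCCGG", 6))$class_label, "A1")
  # de novo F1 methylation from unmethylated parents -> C group
  expect_equal(classify_inheritance(c("unmethylated", "unmethylated"),
                                    rep("hemi_mCCGG", 6))$class_label, "C1")
  expect_equal(classify_inheritance(c("unmethylated", "unmethylated"),
                                    rep("full_CmCGG", 6))$class_label, "C2")
  # discordant parents with segregating F1 -> D group
  got <- classify_inheritance(c("hemi_mCCGG", "unmethylated"),
                              c("hemi_mCCGG", "unmethylated",
                                "hemi_mCCGG"))
  expect_equal(got$parent_pattern, "disparate")
  expect_equal(got$class_label, "D2")
  # the two full states collapse for the classification
  expect_equal(classify_inheritance(c("full_CmCGG", "full_mCCGG"),
                                    rep("full_CmCGG", 4))$class_label,
               "A2")
  expect_error(classify_inheritance(c("no_call", "hemi_mCCGG"),
                                    "hemi_mCCGG"), "no_call")
})

test_that("inheritance classification ignores F1 order", {
  f1 <- c("hemi_mCCGG", "unmethylated", "full_mCCGG", "hemi_mCCGG")
  a <- classify_inheritance(c("hemi_mCCGG", "hemi_mCCGG"), f1)
  b <- classify_inheritance(c("hemi_mCCGG", "hemi_mCCGG"), rev(f1))
  expect_equal(a, b)
})
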