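make_ev <- function(sample_id, positions, hc, mc, hb, mb,
                    scaffold = "s1") {
  data.frame(sample_id = sample_id, scaffold = scaffold,
             position = positions, h_cleave = hc, m_cleave = mc,
             h_body = hb, m_body = mb, stringsAsFactors = FALSE)
}

test_that("bin methylation level follows the read-weighted site formula", {
  # 4 sites x 5 reads each; 2 sites methylated with all reads methylated
  ev <- make_ev("p1", c(0L, 100L, 200L, 300L),
                hc = c(3, 0, 3, 3), mc = c(2, 0, 2, 2),
                hb = c(0, 2, 0, 0), mb = c(0, 3, 0, 0))
  ev$h_body[3] <- 0  # keep 5-read totals
  calls <- call_states(ev)
  bin <- list(scaffold = "s1", start = 0L, end = 400L)
  # site 2 is full_mCCGG (5 methylated reads); sites 1,3,4 unmethylated
  lvl <- methylation_level(bin, calls, ev)
  expect_equal(lvl$denominator, 20)
  expect_equal(lvl$numerator, 5)
  expect_equal(lvl$level, 0.25)

  # all sites methylated with all reads from methylated fragments -> 1
  ev2 <- make_ev("p1", c(0L, 100L), hc = 0, mc = 0, hb = 5, mb = 5)
  lvl2 <- methylation_level(list(scaffold = "s1", start = 0L, end = 200L),
                            call_states(ev2), ev2)
  expect_equal(lvl2$level, 1)

  # no methylated sites -> 0; empty bin -> NA level
  ev3 <- make_ev("p1", 0L, hc = 3, mc = 3, hb = 0, mb = 0)
  expect_equal(methylation_level(list(scaffold = "s1", start = 0L,
                                      end = 100L),
                                 call_states(ev3), ev3)$level, 0)
  expect_true(is.na(methylation_level(list(scaffold = "s2", start = 0L,
                                           end = 100L),
                                      call_states(ev3), ev3)$level))
})

test_that("level is monotone as methylated reads are added", {
  base <- make_ev("p1", c(0L, 100L), hc = c(0, 3), mc = c(0, 3),
                  hb = c(2, 0), mb = c(2, 0))
  bin <- list(scaffold = "s1", start = 0L, end = 200L)
  lvls <- sapply(0:5, function(extra) {
    ev <- base
    ev$h_body[1] <- ev$h_body[1] + extra
    ev$m_body[1] <- ev$m_body[1] + extra
    methylation_level(bin, call_states(ev), ev)$level
  })
  expect_true(all(diff(lvls) >= 0))
})

test_that("metaprofile recovers constant depth and equal windowing", {
  genes <- gene_models(c("g1", "g2"), "s1", c(3000L, 9000L),
                       c(3800L, 10000L), c("+", "-"))
  depth <- list(s1 = rep(2, 20000))
  prof <- metaprofile(genes, depth, body_windows = 80, flank_windows = 20,
                      flank = 2000)
  expect_equal(prof$n_windows, 120L)
  expect_equal(prof$values, rep(2, 120), ignore_attr = TRUE)
})

test_that("metaprofile equals a window-by-window oracle and is order/strand stable", {
  set.seed(41)
  depth <- list(s1 = runif(30000))
  genes <- gene_models("g1", "s1", 10000L, 10800L, "+")
  prof <- metaprofile(genes, depth, body_windows = 80, flank_windows = 20,
                      flank = 2000)
  # body window width is 10 for an 800 bp gene and 80 windows
  d <- depth$s1
  body_means <- sapply(0:79, function(w) {
    mean(d[(10000 + w * 10 + 1):(10000 + (w + 1) * 10)])
  })
  expect_equal(prof$values[21:100], body_means, ignore_attr = TRUE)
  up_means <- sapply(0:19, function(w) {
    mean(d[(8000 + w * 100 + 1):(8000 + (w + 1) * 100)])
  })
  expect_equal(prof$values[1:20], up_means, ignore_attr = TRUE)

  # region order does not matter; a minus-strand copy is the reverse
  genes2 <- gene_models(c("a", "b"), "s1", c(10000L, 20000L),
                        c(10800L, 20800L), c("+", "+"))
  genes2r <- genes2[2:1, ]
  expect_equal(metaprofile(genes2, depth)$values,
               metaprofile(genes2r, depth)$values)
  gminus <- gene_models("g1", "s1", 10000L, 10800L, "-")
  expect_equal(metaprofile(gminus, depth)$values, rev(prof$values))

  # too-short regions are skipped with a warning
  short <- gene_models(c("g1", "tiny"), "s1", c(10000L, 100L),
                       c(10800L, 150L), c("+", "+"))
  expect_warning(p2 <- metaprofile(short, depth), "skipped")
  expect_equal(p2$values, prof$values)
})

test_that("context proportions count the three methylated states", {
  states <- c(rep("full_CmCGG", 5), rep("hemi_mCCGG", 5),
              rep("full_mCCGG", 5))
  calls <- make_calls(matrix(states, nrow = 15))
  props <- context_proportions(calls)
  expect_equal(as.numeric(props["overall", ]), rep(1 / 3, 3))

  only <- make_calls(matrix(rep("full_CmCGG", 4), nrow = 4))
  expect_equal(as.numeric(context_proportions(only)["overall", ]),
               c(1, 0, 0))

  none <- make_calls(matrix(rep("unmethylated", 4), nrow = 4))
  expect_error(context_proportions(none), "no methylated")
})

test_that("context proportions sum to one on random inputs", {
  set.seed(42)
  for (i in 1:10) {
    states <- sample(methylation_states(), 60, replace = TRUE)
    if (!any(states %in% c("hemi_mCCGG", "full_CmCGG", "full_mCCGG")))
      next
    props <- context_proportions(make_calls(matrix(states, nrow = 60)))
    expect_equal(sum(props["overall", ]), 1, tolerance = 1e-9)
  }
})
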