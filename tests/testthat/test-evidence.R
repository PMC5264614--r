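# One site at 0-based position 100 on s1; the cut position is 101 (C^CGG).
ev_sites <- data.frame(scaffold = "s1", position = 100L, strand = "+",
                       stringsAsFactors = FALSE)

# Write a small SAM file with the given 0-based half-open read spans.
write_sam <- function(spans, path, scaffold = "s1", len = 2000L) {
  lines <- c(sprintf("@SQ\tSN:%s\tLN:%d", scaffold, len))
  for (i in seq_len(nrow(spans))) {
    w <- spans$end[i] - spans$start[i]
    lines <- c(lines, sprintf("r%03d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                              i, spans$scaffold[i], spans$start[i] + 1L, w,
                              strrep("A", w)))
  }
  writeLines(lines, path)
  path
}

test_that("cleavage and body reads are classified by the stated rule", {
  spans <- data.frame(
    scaffold = "s1",
    start = c(101L, 51L, 50L, 98L, 300L),
    end = c(201L, 101L, 150L, 102L, 400L)
  )
  # starts at cut; ends at cut; spans the whole CCGG; partial; elsewhere
  sam <- write_sam(spans, tempfile(fileext = ".sam"))
  ev <- extract_evidence(sam, ev_sites, "p1", enzyme = "HpaII")
  expect_equal(ev$h_cleave, 2L)
  expect_equal(ev$h_body, 1L)
  expect_equal(ev$m_cleave, 0L)
  expect_equal(ev$m_body, 0L)

  evm <- extract_evidence(sam, ev_sites, "p1", enzyme = "MspI")
  expect_equal(evm$m_cleave, 2L)
  expect_equal(evm$m_body, 1L)
})

test_that("evidence counts match a per-read brute force and ignore read order", {
  set.seed(21)
  sites <- data.frame(scaffold = "s1",
                      position = c(100L, 500L, 1000L), strand = "+",
                      stringsAsFactors = FALSE)
  start <- sample(0L:1400L, 300, replace = TRUE)
  spans <- data.frame(scaffold = "s1", start = start,
                      end = start + sample(30:120, 300, replace = TRUE))
  sam <- write_sam(spans, tempfile(fileext = ".sam"))
  ev <- extract_evidence(sam, sites, "p1", enzyme = "HpaII")

  for (k in seq_len(nrow(sites))) {
    cls <- vapply(seq_len(nrow(spans)), function(i) {
      oracle_read_class(spans$start[i], spans$end[i], sites$position[k])
    }, "")
    expect_equal(ev$h_cleave[k], sum(cls == "cleave"))
    expect_equal(ev$h_body[k], sum(cls == "body"))
    # no double counting: categories never exceed overlapping reads
    overl <- sum(spans$start < sites$position[k] + 4L &
                   spans$end > sites$position[k])
    expect_lte(ev$h_cleave[k] + ev$h_body[k], overl)
  }

  shuffled <- spans[sample(nrow(spans)), ]
  sam2 <- write_sam(shuffled, tempfile(fileext = ".sam"))
  ev2 <- extract_evidence(sam2, sites, "p1", enzyme = "HpaII")
  expect_equal(ev2$h_cleave, ev$h_cleave)
  expect_equal(ev2$h_body, ev$h_body)
})

test_that("reads on unknown scaffolds are skipped with a warning", {
  spans <- data.frame(scaffold = c("s1", "sX"),
                      start = c(101L, 10L), end = c(200L, 60L))
  sam <- write_sam(spans[1, ], tempfile(fileext = ".sam"))
  # write both scaffolds into one SAM
  lines <- c("@SQ\tSN:s1\tLN:2000", "@SQ\tSN:sX\tLN:2000",
             sprintf("r1\t0\ts1\t102\t60\t99M\t*\t0\t0\t%s\t*",
                     strrep("A", 99)),
             sprintf("r2\t0\tsX\t11\t60\t50M\t*\t0\t0\t%s\t*",
                     strrep("A", 50)))
  sam <- tempfile(fileext = ".sam"); writeLines(lines, sam)
  expect_warning(ev <- extract_evidence(sam, ev_sites, "p1", "HpaII"),
                 "skipped")
  expect_equal(ev$h_cleave, 1L)
})

test_that("combine_evidence merges the two libraries of one sample", {
  h <- data.frame(sample_id = "p1", scaffold = "s1", position = 100L,
                  h_cleave = 3L, m_cleave = 0L, h_body = 1L, m_body = 0L)
  m <- data.frame(sample_id = "p1", scaffold = "s1", position = 100L,
                  h_cleave = 0L, m_cleave = 0L, h_body = 0L, m_body = 4L)
  both <- combine_evidence(h, m)
  expect_equal(nrow(both), 1L)
  expect_equal(both$h_cleave, 3L)
  expect_equal(both$m_body, 4L)
  # a missing MspI library leaves m-counts zero and the call downstream open
  solo <- combine_evidence(hpaii = h)
  expect_equal(solo$m_cleave + solo$m_body, 0L)
  expect_equal(call_states(solo)$state, "no_call")
})

test_that("evidence tables round-trip through TSV", {
  ev <- data.frame(sample_id = "p1", scaffold = "s1",
                   position = c(0L, 50L), h_cleave = c(2L, 0L),
                   m_cleave = c(2L, 0L), h_body = c(0L, 3L),
                   m_body = c(0L, 3L), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_evidence(ev, path)
  expect_equal(read_evidence(path), ev)
})
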