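# Independent brute-force oracles used to cross-check the implementation.

# Naive all-offsets CCGG scan (0-based positions).
naive_ccgg_scan <- function(seq) {
  n <- nchar(seq)
  pos <- integer(0)
  for (i in seq_len(max(0L, n - 3L))) {
    if (substr(seq, i, i + 3L) == "CCGG") pos <- c(pos, i - 1L)
  }
  pos
}

# Scalar decision procedure for one evidence vector, written as a direct
# transcription of the dual-digest conditions (thresholds: >= 4 total,
# >= 2 per enzyme).
oracle_call <- function(hc, mc, hb, mb) {
  if (hc + mc + hb + mb < 4) return("no_call")
  if (hc + hb < 2 || mc + mb < 2) return("no_call")
  if (hc >= 2 && mb >= 2 && mc == 0) return("hemi_mCCGG")
  if (mc >= 2 && hb >= 2 && hc == 0) return("full_CmCGG")
  if (hb >= 2 && mb >= 2 && hc == 0 && mc == 0) return("full_mCCGG")
  if (hc >= 2 && mc >= 2) return("unmethylated")
  "no_call"
}

# Per-read evidence classification against one site (0-based half-open
# read span; site position is the first C of CCGG).
oracle_read_class <- function(read_start, read_end, site_pos) {
  cut <- site_pos + 1L
  if (read_start == cut || read_end == cut) return("cleave")
  if (read_start <= site_pos && read_end >= site_pos + 4L) return("body")
  "none"
}

# Tie-corrected Kruskal-Wallis H computed from first principles.
oracle_kw_h <- function(y, g) {
  n <- length(y)
  r <- rank(y)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation p-value of the two-group KW statistic for tiny n.
oracle_kw_perm_p <- function(y, g) {
  g <- as.integer(factor(g))
  n1 <- sum(g == 1L)
  idx <- utils::combn(length(y), n1)
  h_obs <- oracle_kw_h(y, g)
  hs <- apply(idx, 2L, function(i) {
    gg <- rep(2L, length(y)); gg[i] <- 1L
    oracle_kw_h(y, gg)
  })
  mean(hs >= h_obs - 1e-12)
}

# A small fully-specified call matrix builder.
make_calls <- function(states, scaffold = "s1", positions = NULL,
                       samples = NULL) {
  # states: site x sample character matrix
  if (is.null(positions)) positions <- (seq_len(nrow(states)) - 1L) * 10L
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(states)))
  data.frame(
    sample_id = rep(samples, each = nrow(states)),
    scaffold = scaffold,
    position = rep(positions, ncol(states)),
    state = as.vector(states),
    stringsAsFactors = FALSE
  )
}
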