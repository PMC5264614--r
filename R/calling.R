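#' Call the methylation state of one CCGG site in one sample
#'
#' The dual-digest logic exploits the differential methylation sensitivity
#' of the isoschizomers HpaII and MspI at CCGG. A site is callable only when
#' it carries at least \code{min_total_reads} reads in total with at least
#' \code{min_reads_per_enzyme} reads from each enzyme library. The callable
#' patterns are:
#' \itemize{
#'   \item hemi_mCCGG: cleaved by HpaII only — \code{h_cleave >= 2},
#'     \code{m_body >= 2}, \code{m_cleave == 0};
#'   \item full_CmCGG: cleaved by MspI only — \code{m_cleave >= 2},
#'     \code{h_body >= 2}, \code{h_cleave == 0};
#'   \item full_mCCGG: cleaved by neither — \code{h_body >= 2},
#'     \code{m_body >= 2}, \code{h_cleave == 0}, \code{m_cleave == 0};
#'   \item unmethylated: cleaved by both — \code{h_cleave >= 2},
#'     \code{m_cleave >= 2}.
#' }
#' Any other pattern is conservatively a \code{no_call}.
#'
#' @param h_cleave,m_cleave,h_body,m_body Non-negative read counts (vectors
#'   are accepted and recycled to a common length).
#' @param cfg Configuration from [run_config()].
#' @return Character vector of states (see [methylation_states()]).
#' @examples
#' call_site_state(3, 0, 0, 3)   # hemi_mCCGG
#' call_site_state(0, 2, 2, 0)   # full_CmCGG
#' @export
call_site_state <- function(h_cleave, m_cleave, h_body, m_body,
                            cfg = run_config()) {
  n <- max(length(h_cleave), length(m_cleave), length(h_body),
           length(m_body))
  hc <- rep_len(as.integer(h_cleave), n)
  mc <- rep_len(as.integer(m_cleave), n)
  hb <- rep_len(as.integer(h_body), n)
  mb <- rep_len(as.integer(m_body), n)
  if (any(c(hc, mc, hb, mb) < 0, na.rm = TRUE) ||
      anyNA(c(hc, mc, hb, mb)))
    stop("read counts must be non-negative integers", call. = FALSE)

  k <- cfg$min_reads_per_enzyme
  total <- hc + mc + hb + mb
  callable <- total >= cfg$min_total_reads &
    (hc + hb) >= k & (mc + mb) >= k

  state <- rep("no_call", n)
  hemi <- hc >= k & mb >= k & mc == 0L
  cmcgg <- mc >= k & hb >= k & hc == 0L
  mccgg <- hb >= k & mb >= k & hc == 0L & mc == 0L
  unmeth <- hc >= k & mc >= k
  state[callable & hemi] <- "hemi_mCCGG"
  state[callable & cmcgg] <- "full_CmCGG"
  state[callable & mccgg] <- "full_mCCGG"
  state[callable & unmeth] <- "unmethylated"
  state
}

#' Call methylation states for an evidence table
#'
#' Vectorised application of [call_site_state()] over a site-evidence table
#' covering any number of samples and sites.
#'
#' @param evidence Evidence data.frame as from [combine_evidence()] or
#'   [read_evidence()].
#' @param cfg Configuration from [run_config()].
#' @return A calls data.frame: \code{sample_id}, \code{scaffold},
#'   \code{position}, \code{state}.
#' @export
call_states <- function(evidence, cfg = run_config()) {
  check_counts(evidence)
  data.frame(sample_id = evidence$sample_id,
             scaffold = evidence$scaffold,
             position = evidence$position,
             state = call_site_state(evidence$h_cleave, evidence$m_cleave,
                                     evidence$h_body, evidence$m_body, cfg),
             stringsAsFactors = FALSE)
}

#' Reshape calls to a site x sample state matrix
#'
#' @param calls Calls data.frame from [call_states()].
#' @return Character matrix, rows named \code{scaffold:position}, columns by
#'   sample; absent combinations are \code{no_call}.
#' @export
calls_matrix <- function(calls) {
  sites <- unique(site_key(calls$scaffold, calls$position))
  samples <- unique(calls$sample_id)
  m <- matrix("no_call", nrow = length(sites), ncol = length(samples),
              dimnames = list(sites, samples))
  m[cbind(match(site_key(calls$scaffold, calls$position), sites),
          match(calls$sample_id, samples))] <- calls$state
  m
}

#' Population-level site summary
#'
#' Tallies per-sample calls at every site, keeps sites where at least
#' \code{min_methylated_samples} samples share an identical methylated state,
#' and classifies each retained site as \code{hemi} or \code{full} when the
#' respective fraction of methylated samples exceeds
#' \code{majority_fraction} (default 2/3; the two full states are pooled),
#' else \code{mixed}. A site is monomorphic when every called sample shares
#' one state, polymorphic otherwise.
#'
#' @param calls Calls data.frame ([call_states()]) or a site x sample state
#'   matrix ([calls_matrix()]). At least two samples are required.
#' @param cfg Configuration from [run_config()].
#' @return A data.frame with one row per retained site: \code{scaffold},
#'   \code{position}, \code{n_called}, \code{n_methylated},
#'   \code{hemi_fraction}, \code{full_fraction}, \code{site_class},
#'   \code{polymorphic}, \code{monomorphic}.
#' @export
summarize_population <- function(calls, cfg = run_config()) {
  m <- if (is.matrix(calls)) calls else calls_matrix(calls)
  if (ncol(m) < 2L)
    stop("population summary requires at least two samples", call. = FALSE)

  tab <- t(apply(m, 1L, function(s) {
    s <- factor(s, levels = METH_STATES)
    as.integer(table(s))
  }))
  colnames(tab) <- METH_STATES
  n_called <- rowSums(tab[, setdiff(METH_STATES, "no_call"), drop = FALSE])
  n_hemi <- tab[, "hemi_mCCGG"]
  n_full <- tab[, "full_CmCGG"] + tab[, "full_mCCGG"]
  n_meth <- n_hemi + n_full
  ## "similarly methylated in >= 2 samples": an identical methylated state
  ## must recur, not merely any methylated state.
  max_same <- pmax(tab[, "hemi_mCCGG"], tab[, "full_CmCGG"],
                   tab[, "full_mCCGG"])
  keep <- max_same >= cfg$min_methylated_samples & n_called > 0L

  hemi_fr <- ifelse(n_meth > 0L, n_hemi / n_meth, NA_real_)
  full_fr <- ifelse(n_meth > 0L, n_full / n_meth, NA_real_)
  site_class <- ifelse(hemi_fr > cfg$majority_fraction, "hemi",
                       ifelse(full_fr > cfg$majority_fraction, "full",
                              "mixed"))
  n_states <- rowSums(tab[, setdiff(METH_STATES, "no_call"),
                          drop = FALSE] > 0L)
  mono <- n_states == 1L

  key <- strsplit(rownames(m), ":", fixed = TRUE)
  out <- data.frame(
    scaffold = vapply(key, `[`, "", 1L),
    position = as.integer(vapply(key, `[`, "", 2L)),
    n_called = as.integer(n_called),
    n_methylated = as.integer(n_meth),
    hemi_fraction = hemi_fr,
    full_fraction = full_fr,
    site_class = site_class,
    polymorphic = !mono,
    monomorphic = mono,
    stringsAsFactors = FALSE
  )
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
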