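#' Methylation level of a genomic bin
#'
#' The level of a bin is a read-weighted fraction of methylated CCGG sites:
#' the number of methylated CCGG sites, each multiplied by its reads from
#' methylated fragments, divided by the number of all CCGG sites, each
#' multiplied by its reads from all fragments. Reads "from methylated
#' fragments" are the evidence categories consistent with the called state
#' (HpaII cleavage + MspI body for hemi_mCCGG, MspI cleavage + HpaII body
#' for full_CmCGG, both bodies for full_mCCGG).
#'
#' @param bin List or data.frame row with \code{scaffold}, \code{start},
#'   \code{end} (0-based half-open).
#' @param calls Calls data.frame for one sample or pooled samples.
#' @param evidence Matching evidence data.frame.
#' @return A one-row data.frame: \code{scaffold}, \code{start}, \code{end},
#'   \code{numerator}, \code{denominator}, \code{level} (\code{NA} when the
#'   bin holds no covered site).
#' @export
methylation_level <- function(bin, calls, evidence) {
  if (bin$end <= bin$start) stop("empty bin", call. = FALSE)
  inside <- evidence$scaffold == bin$scaffold &
    evidence$position >= bin$start & evidence$position < bin$end
  ev <- evidence[inside, , drop = FALSE]
  key_ev <- paste(ev$sample_id, site_key(ev$scaffold, ev$position))
  key_ca <- paste(calls$sample_id, site_key(calls$scaffold, calls$position))
  state <- calls$state[match(key_ev, key_ca)]
  state[is.na(state)] <- "no_call"

  total <- ev$h_cleave + ev$m_cleave + ev$h_body + ev$m_body
  meth_reads <- ifelse(state == "hemi_mCCGG", ev$h_cleave + ev$m_body,
                ifelse(state == "full_CmCGG", ev$m_cleave + ev$h_body,
                ifelse(state == "full_mCCGG", ev$h_body + ev$m_body, 0)))
  num <- sum(meth_reads)
  den <- sum(total)
  data.frame(scaffold = bin$scaffold, start = bin$start, end = bin$end,
             numerator = num, denominator = den,
             level = if (den > 0) num / den else NA_real_,
             stringsAsFactors = FALSE)
}

#' Methylation levels over a tiling of the genome
#'
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param calls,evidence As for [methylation_level()].
#' @param bin_bp Bin width in bp.
#' @return Data.frame of per-bin levels (one row per non-empty bin).
#' @export
methylation_levels <- function(scaffold_lengths, calls, evidence,
                               bin_bp = 1000L) {
  out <- list()
  for (sc in names(scaffold_lengths)) {
    starts <- seq(0L, max(0L, scaffold_lengths[[sc]] - 1L), by = bin_bp)
    for (s in starts) {
      out[[length(out) + 1L]] <-
        methylation_level(list(scaffold = sc, start = s,
                               end = min(s + bin_bp,
                                         scaffold_lengths[[sc]])),
                          calls, evidence)
    }
  }
  do.call(rbind, out)
}

#' Gene-body methylation metaprofile
#'
#' Averages a per-base depth signal over gene models in a normalised
#' 5'-to-3' coordinate system: each gene body is divided into
#' \code{body_windows} proportional windows, and each 2000-bp (by default)
#' flank into \code{flank_windows} fixed-width windows. Per window the mean
#' depth is taken, then windows are averaged across genes. Minus-strand
#' genes are reversed so the profile always runs upstream flank, body,
#' downstream flank.
#'
#' @param genes Gene-model table ([gene_models()]).
#' @param depth Named list of per-base numeric depth vectors, one per
#'   scaffold (position 1 of the vector is scaffold coordinate 0).
#' @param body_windows Number of windows across the gene body (default 80).
#' @param flank_windows Number of windows per flank (default 20).
#' @param flank Flank length in bp (default 2000).
#' @param region_set Label stored with the profile.
#' @return An object of class \code{msap_metaprofile}: list with
#'   \code{values} (length \code{body_windows + 2 * flank_windows}),
#'   \code{n_windows}, \code{n_regions}, \code{body_windows},
#'   \code{flank_windows}, \code{region_set}.
#' @export
metaprofile <- function(genes, depth, body_windows = 80L,
                        flank_windows = 20L, flank = 2000L,
                        region_set = "gene_body") {
  profs <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    d <- depth[[g$scaffold]]
    if (is.null(d)) next
    if (g$end - g$start < body_windows) {
      warning(sprintf("gene %s shorter than %d bp; skipped", g$gene_id,
                      body_windows))
      next
    }
    base_at <- function(lo, hi) {        # 0-based half-open, clipped
      lo <- max(lo, 0L); hi <- min(hi, length(d))
      if (hi <= lo) return(numeric(0))
      d[(lo + 1L):hi]
    }
    up <- window_means(base_at(g$start - flank, g$start), flank_windows,
                       flank)
    body <- window_means(base_at(g$start, g$end), body_windows,
                         g$end - g$start)
    down <- window_means(base_at(g$end, g$end + flank), flank_windows,
                         flank)
    v <- c(up, body, down)
    if (g$strand == "-") v <- rev(v)
    profs[[length(profs) + 1L]] <- v
  }
  if (length(profs) == 0L)
    stop("no usable regions for the metaprofile", call. = FALSE)
  vals <- colMeans(do.call(rbind, profs))
  structure(list(values = vals, n_windows = length(vals),
                 n_regions = length(profs), body_windows = body_windows,
                 flank_windows = flank_windows, region_set = region_set),
            class = "msap_metaprofile")
}

## Mean of `x` split into n equal windows of a span of length `span`
## (x may be clipped at scaffold edges; missing bases count as depth 0).
window_means <- function(x, n, span) {
  if (span <= 0L) return(rep(0, n))
  x <- c(x, rep(0, span - length(x)))
  idx <- floor((seq_len(span) - 1L) * n / span) + 1L
  as.numeric(tapply(x, idx, mean))
}

#' @export
print.msap_metaprofile <- function(x, ...) {
  cat(sprintf("metaprofile over %d region(s) [%s]: %d windows (%d + %d + %d)\n",
              x$n_regions, x$region_set, x$n_windows, x$flank_windows,
              x$body_windows, x$flank_windows))
  cat("  mean depth range:", format(range(x$values)), "\n")
  invisible(x)
}

#' Proportions of the three methylated states
#'
#' Among all methylated calls, the fractions in state full_CmCGG,
#' hemi_mCCGG and full_mCCGG. When gene models are supplied the proportions
#' are additionally computed restricted to calls inside gene bodies or
#' promoters.
#'
#' @param calls Calls data.frame.
#' @param genes Optional gene-model table.
#' @return Data.frame with rows \code{overall} (and \code{genic} when genes
#'   are given) and columns \code{full_CmCGG}, \code{hemi_mCCGG},
#'   \code{full_mCCGG}; each row sums to 1.
#' @export
context_proportions <- function(calls, genes = NULL) {
  meth <- calls[is_methylated_state(calls$state), , drop = FALSE]
  if (nrow(meth) == 0L)
    stop("no methylated calls; proportions undefined", call. = FALSE)
  prop_of <- function(df) {
    tb <- table(factor(df$state,
                       levels = c("full_CmCGG", "hemi_mCCGG", "full_mCCGG")))
    as.numeric(tb) / sum(tb)
  }
  out <- data.frame(rbind(overall = prop_of(meth)))
  names(out) <- c("full_CmCGG", "hemi_mCCGG", "full_mCCGG")
  if (!is.null(genes)) {
    regions <- rbind(genes[c("gene_id", "scaffold", "start", "end",
                             "strand")],
                     promoter_regions(genes))
    gr <- intervals_to_granges(regions)
    hits <- GenomicRanges::findOverlaps(
      sites_to_granges(meth[c("scaffold", "position")]), gr)
    genic <- meth[unique(S4Vectors::queryHits(hits)), , drop = FALSE]
    if (nrow(genic) > 0L) out["genic", ] <- prop_of(genic)
  }
  out
}
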