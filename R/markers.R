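#' Type and filter dominant segregating markers
#'
#' Markers in an outbred F1 (CP) cross are typed from parental presence:
#' present in the female parent only = \code{lm_ll} (expected 1:1 in the
#' progeny), male parent only = \code{nn_np} (1:1), both parents =
#' \code{hk_hk} (3:1 present:absent under dominant scoring). A marker is
#' retained when
#' \itemize{
#'   \item its read support is at least \code{min_reads} (default 2),
#'   \item more than \code{cfg$marker_presence_fraction} of the progeny
#'     have a non-missing call,
#'   \item a chi-squared goodness-of-fit test of the present:absent counts
#'     against the expected ratio does not reject at
#'     \code{cfg$seg_alpha} (default 0.01).
#' }
#' Markers absent from both parents but present in progeny are
#' inconsistent and removed. Ambiguous heterozygous calls should be coded
#' \code{NA} upstream.
#'
#' @param markers Data.frame with columns \code{marker_id},
#'   \code{parent_female}, \code{parent_male} (logical presence) and a
#'   genotype matrix \code{geno} (see below), or alternatively the progeny
#'   calls in columns. The simplest layout: list-free data.frame plus a
#'   separate \code{geno} matrix argument.
#' @param geno Integer/logical matrix, markers x progeny: 1 = band present,
#'   0 = absent, \code{NA} = missing; rownames are marker ids.
#' @param cfg Configuration from [run_config()].
#' @param min_reads Minimum read support per marker (default 2); read
#'   support is taken from a \code{read_support} column when present,
#'   otherwise assumed satisfied.
#' @return The markers data.frame with added columns \code{marker_type},
#'   \code{n_called}, \code{presence_fraction}, \code{n_present},
#'   \code{seg_chi2}, \code{seg_p}, \code{retained}, \code{drop_reason}.
#' @export
classify_and_filter_markers <- function(markers, geno, cfg = run_config(),
                                        min_reads = 2L) {
  stopifnot(all(c("marker_id", "parent_female", "parent_male") %in%
                  names(markers)))
  geno <- geno[markers$marker_id, , drop = FALSE]
  n_prog <- ncol(geno)

  type <- ifelse(markers$parent_female & markers$parent_male, "hk_hk",
          ifelse(markers$parent_female, "lm_ll",
          ifelse(markers$parent_male, "nn_np", "inconsistent")))
  n_called <- rowSums(!is.na(geno))
  n_present <- rowSums(geno == 1L, na.rm = TRUE)
  pres_frac <- n_called / n_prog

  chi2 <- rep(NA_real_, nrow(markers)); pval <- rep(NA_real_, nrow(markers))
  for (i in seq_len(nrow(markers))) {
    if (type[i] == "inconsistent" || n_called[i] == 0L) next
    expect <- if (type[i] == "hk_hk") c(3, 1) / 4 else c(1, 1) / 2
    obs <- c(n_present[i], n_called[i] - n_present[i])
    ht <- suppressWarnings(stats::chisq.test(obs, p = expect))
    chi2[i] <- as.numeric(ht$statistic); pval[i] <- ht$p.value
  }

  support_ok <- if ("read_support" %in% names(markers))
    markers$read_support >= min_reads else rep(TRUE, nrow(markers))

  reason <- rep(NA_character_, nrow(markers))
  reason[!support_ok] <- "read support"
  reason[is.na(reason) & type == "inconsistent"] <- "absent in both parents"
  reason[is.na(reason) & pres_frac <= cfg$marker_presence_fraction] <-
    "low call rate"
  reason[is.na(reason) & !is.na(pval) & pval < cfg$seg_alpha] <-
    "distorted segregation"
  reason[is.na(reason) & is.na(pval)] <- "untestable"

  out <- markers
  out$marker_type <- type
  out$n_called <- as.integer(n_called)
  out$presence_fraction <- pres_frac
  out$n_present <- as.integer(n_present)
  out$seg_chi2 <- chi2
  out$seg_p <- pval
  out$retained <- is.na(reason)
  out$drop_reason <- reason
  out
}

#' Two-point linkage statistics for a marker pair
#'
#' Estimates the recombination fraction between two markers of the same
#' parental phase type as the fraction of informative progeny (both calls
#' non-missing) whose presence pattern differs, capped at 0.5, and the LOD
#' score of linkage
#' \deqn{LOD = n_{nr}\log_{10} 2(1-\hat r) + n_r\log_{10} 2\hat r,}
#' which is 0 at \eqn{\hat r = 0.5}. The pair is groupable when
#' \eqn{\hat r <} \code{cfg$max_rf} (default 0.4) and LOD >
#' \code{cfg$lod_threshold} (default 1).
#'
#' @param geno_a,geno_b Progeny presence vectors (1/0/NA) for the two
#'   markers, same individuals in the same order.
#' @param cfg Configuration from [run_config()].
#' @param min_informative Minimum informative progeny (default 10).
#' @return One-row data.frame: \code{n_informative}, \code{n_rec},
#'   \code{rf}, \code{lod}, \code{groupable}, \code{reason}.
#' @export
pairwise_linkage <- function(geno_a, geno_b, cfg = run_config(),
                             min_informative = 10L) {
  if (length(geno_a) != length(geno_b))
    stop("genotype vectors must have equal length", call. = FALSE)
  ok <- !is.na(geno_a) & !is.na(geno_b)
  n <- sum(ok)
  if (n < min_informative)
    return(data.frame(n_informative = n, n_rec = NA_integer_,
                      rf = NA_real_, lod = NA_real_, groupable = FALSE,
                      reason = "too few informative progeny",
                      stringsAsFactors = FALSE))
  n_rec <- sum(geno_a[ok] != geno_b[ok])
  rf <- min(n_rec / n, 0.5)
  lod <- lod_two_point(n - n_rec, n_rec, rf)
  data.frame(n_informative = n, n_rec = as.integer(n_rec), rf = rf,
             lod = lod,
             groupable = rf < cfg$max_rf & lod > cfg$lod_threshold,
             reason = NA_character_, stringsAsFactors = FALSE)
}

## LOD of the two-point likelihood ratio; 0*log(0) terms are 0.
lod_two_point <- function(n_nonrec, n_rec, rf) {
  term <- function(k, x) if (k == 0L) 0 else k * log10(x)
  term(n_nonrec, 2 * (1 - rf)) + term(n_rec, 2 * rf)
}

#' Single-marker Kruskal-Wallis QTL scan
#'
#' At each marker, progeny are grouped by genotype class and the raw trait
#' values compared with the Kruskal-Wallis rank-sum test (tie-corrected H,
#' p from the chi-squared distribution with k-1 df). A marker needs at
#' least two genotype classes with at least two observations each to be
#' evaluable. Significance is declared per test at \code{cfg$kw_alpha}
#' (default 0.001), with no genome-wide correction.
#'
#' @param geno Markers x progeny genotype matrix (any discrete coding;
#'   \code{NA} = missing).
#' @param trait Named numeric vector of trait values per progeny
#'   (names matching the columns of \code{geno}), or unnamed in column
#'   order.
#' @param cfg Configuration from [run_config()].
#' @return Data.frame with one row per marker: \code{marker_id},
#'   \code{n}, \code{k} (number of classes), \code{H}, \code{p},
#'   \code{significant}.
#' @export
kw_scan <- function(geno, trait, cfg = run_config()) {
  if (!is.null(names(trait))) {
    trait <- trait[colnames(geno)]
  } else if (length(trait) != ncol(geno)) {
    stop("trait length must match progeny count", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    ok <- !is.na(g) & !is.na(trait)
    g <- factor(g[ok]); y <- as.numeric(trait[ok])
    tab <- table(g)
    if (length(tab) < 2L || sum(tab >= 2L) < 2L)
      return(data.frame(marker_id = rownames(geno)[i],
                        n = as.integer(sum(ok)), k = length(tab),
                        H = NA_real_, p = NA_real_, significant = FALSE,
                        stringsAsFactors = FALSE))
    ht <- stats::kruskal.test(y, g)
    H <- as.numeric(ht$statistic); p <- ht$p.value
    if (!is.finite(H)) { H <- NA_real_; p <- NA_real_ }  # all-tied traits
    data.frame(marker_id = rownames(geno)[i], n = as.integer(sum(ok)),
               k = length(tab), H = H, p = p,
               significant = !is.na(p) && p < cfg$kw_alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
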