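#' Score methylation states as quantitative genotypes
#'
#' Encodes per-sample states on the additive scale used by the
#' methylation-phenotype scan: fully methylated = 1 (unit \code{a}), hemi =
#' 2/3, unmethylated = 0, \code{no_call} = \code{NA}. The unit is
#' irrelevant downstream because the Pearson correlation is scale
#' invariant.
#'
#' @param states Character vector of states, or a site x sample state
#'   matrix from [calls_matrix()].
#' @return Numeric vector or matrix of scores.
#' @examples
#' score_methylation(c("full_mCCGG", "hemi_mCCGG", "unmethylated"))
#' @export
score_methylation <- function(states) {
  sc <- function(s) {
    out <- rep(NA_real_, length(s))
    out[s %in% c("full_CmCGG", "full_mCCGG")] <- 1
    out[s == "hemi_mCCGG"] <- 2 / 3
    out[s == "unmethylated"] <- 0
    out
  }
  if (is.matrix(states)) {
    m <- matrix(sc(states), nrow = nrow(states),
                dimnames = dimnames(states))
    return(m)
  }
  sc(states)
}

#' Methylation-phenotype association for one site
#'
#' Pearson correlation between per-sample methylation scores and a trait,
#' on pairwise-complete samples. With overlap \eqn{N} below
#' \code{cfg$epiqtl_min_overlap} (default 20) the pair is non-evaluable.
#' Otherwise \eqn{t = r\sqrt{(N-2)/(1-r^2)}} and the two-tailed p-value is
#' \eqn{2(1 - F_t(|t|, N-2))}. Significance requires
#' p < \code{cfg$epiqtl_alpha} (default 0.01).
#'
#' @param scores Numeric vector of methylation scores (NA = missing).
#' @param trait Numeric vector of trait values, same samples.
#' @param cfg Configuration from [run_config()].
#' @return One-row data.frame: \code{n_overlap}, \code{r}, \code{t},
#'   \code{p}, \code{significant}, \code{reason} (\code{NA} when
#'   evaluable).
#' @export
associate <- function(scores, trait, cfg = run_config()) {
  if (length(scores) != length(trait))
    stop("scores and trait must have equal length", call. = FALSE)
  ok <- !is.na(scores) & !is.na(trait)
  n <- sum(ok)
  if (n < cfg$epiqtl_min_overlap)
    return(assoc_row(n, reason = "insufficient overlap"))
  x <- scores[ok]; y <- trait[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(assoc_row(n, reason = "zero variance"))
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  assoc_row(n, r = r, t = t, p = p,
            significant = p < cfg$epiqtl_alpha)
}

assoc_row <- function(n, r = NA_real_, t = NA_real_, p = NA_real_,
                      significant = FALSE, reason = NA_character_) {
  data.frame(n_overlap = as.integer(n), r = r, t = t, p = p,
             significant = significant, reason = reason,
             stringsAsFactors = FALSE)
}

#' Genome-wide methylation-phenotype association scan
#'
#' Runs [associate()] for every (site, trait) pair over a score matrix of
#' polymorphic sites and a sample x trait matrix, and flags sites
#' significant in at least two trials of one trait family as repeatable.
#'
#' @param score_matrix Numeric site x sample matrix ([score_methylation()]
#'   of a call matrix restricted to polymorphic sites).
#' @param trait_matrix Numeric sample x trait matrix
#'   ([phenotype_matrix()]); rownames must match the score matrix columns.
#' @param cfg Configuration from [run_config()].
#' @return List with \code{results} (one row per evaluable pair:
#'   \code{site}, \code{trait_code}, the [associate()] columns, and
#'   \code{repeatable}) and \code{significant_sites} (named list of
#'   significant site keys per trait).
#' @export
scan_qtl_epi <- function(score_matrix, trait_matrix, cfg = run_config()) {
  samples <- intersect(colnames(score_matrix), rownames(trait_matrix))
  if (length(samples) == 0L)
    stop("no shared samples between scores and traits", call. = FALSE)
  sm <- score_matrix[, samples, drop = FALSE]
  tm <- trait_matrix[samples, , drop = FALSE]

  out <- list()
  for (trait in colnames(tm)) {
    y <- tm[, trait]
    if (all(is.na(y))) {
      warning(sprintf("trait %s has no data; skipped", trait))
      next
    }
    rows <- lapply(rownames(sm), function(sk) {
      res <- associate(sm[sk, ], y, cfg)
      if (res$n_overlap == 0L) return(NULL)
      cbind(site = sk, trait_code = trait, res)
    })
    out[[trait]] <- do.call(rbind, rows)
  }
  results <- do.call(rbind, out)
  if (is.null(results))
    return(list(results = assoc_empty(), significant_sites = list()))
  rownames(results) <- NULL

  ## repeatable: significant in >= 2 distinct trials of one trait family
  sig <- results[results$significant, , drop = FALSE]
  results$repeatable <- FALSE
  if (nrow(sig) > 0L) {
    pairs <- unique(sig[c("site", "trait_code")])
    cnt <- table(pairs$site, trait_family(pairs$trait_code))
    rep_sites <- rownames(cnt)[apply(cnt >= 2L, 1L, any)]
    results$repeatable <- results$significant & results$site %in% rep_sites
  }
  sig_sites <- lapply(split(sig$site, sig$trait_code), unique)
  list(results = results, significant_sites = sig_sites)
}

assoc_empty <- function() {
  data.frame(site = character(), trait_code = character(),
             n_overlap = integer(), r = numeric(), t = numeric(),
             p = numeric(), significant = logical(), reason = character(),
             repeatable = logical(), stringsAsFactors = FALSE)
}
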