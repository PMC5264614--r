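#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the dual-enzyme CCGG typing conventions: a site is callable
#' only with at least 4 reads total and at least 2 reads from each enzyme
#' library; a population site class (hemi vs full) requires a >2/3 majority
#' among methylated samples; sites methylated in fewer than 2 samples are
#' discarded; methylation-phenotype associations require at least 20
#' overlapping samples and are declared at p < 0.01; marker segregation is
#' tested at p < 0.01 and the Kruskal-Wallis scan at p < 0.001.
#'
#' @param min_total_reads Minimum total reads (both libraries) to call a site.
#' @param min_reads_per_enzyme Minimum reads per enzyme library to call a site.
#' @param majority_fraction Fraction of methylated samples a state must exceed
#'   for the population hemi/full site class (default 2/3).
#' @param min_methylated_samples Minimum number of samples sharing an identical
#'   methylated state for a site to be retained (default 2).
#' @param dmr_window_bp Width in bp of the non-overlapping genome windows used
#'   by the DMR scan (default 1000).
#' @param dmr_min_diff Minimum number of methylated-CCGG differences inside a
#'   window for it to be testable (default 5).
#' @param dmr_alpha Chi-squared significance level for DMR windows.
#' @param epiqtl_alpha Two-tailed p-value cutoff for the methylation-phenotype
#'   scan (default 0.01).
#' @param epiqtl_min_overlap Minimum pairwise-complete sample overlap N for an
#'   association to be evaluable (default 20).
#' @param marker_presence_fraction Minimum fraction of progeny with a
#'   non-missing call for a marker to be retained (default 0.5, exclusive).
#' @param seg_alpha Goodness-of-fit level below which a marker is removed for
#'   distorted segregation (default 0.01).
#' @param kw_alpha Per-test type-I error rate of the Kruskal-Wallis scan
#'   (default 0.001).
#' @param lod_threshold Minimum LOD for two markers to be groupable.
#' @param max_rf Recombination-fraction ceiling for linkage grouping
#'   (default 0.4, exclusive).
#' @param promoter_span Promoter length in bp upstream of the TSS (default
#'   2000).
#' @param rng_seed Integer seed recorded with the configuration.
#'
#' @return An object of class \code{msap_config}: a named list of the
#'   validated settings.
#' @examples
#' cfg <- run_config()
#' cfg$min_total_reads
#' @export
run_config <- function(min_total_reads = 4L,
                       min_reads_per_enzyme = 2L,
                       majority_fraction = 2 / 3,
                       min_methylated_samples = 2L,
                       dmr_window_bp = 1000L,
                       dmr_min_diff = 5L,
                       dmr_alpha = 0.05,
                       epiqtl_alpha = 0.01,
                       epiqtl_min_overlap = 20L,
                       marker_presence_fraction = 0.5,
                       seg_alpha = 0.01,
                       kw_alpha = 0.001,
                       lod_threshold = 1.0,
                       max_rf = 0.4,
                       promoter_span = 2000L,
                       rng_seed = 1L) {
  cfg <- list(
    min_total_reads = as.integer(min_total_reads),
    min_reads_per_enzyme = as.integer(min_reads_per_enzyme),
    majority_fraction = majority_fraction,
    min_methylated_samples = as.integer(min_methylated_samples),
    dmr_window_bp = as.integer(dmr_window_bp),
    dmr_min_diff = as.integer(dmr_min_diff),
    dmr_alpha = dmr_alpha,
    epiqtl_alpha = epiqtl_alpha,
    epiqtl_min_overlap = as.integer(epiqtl_min_overlap),
    marker_presence_fraction = marker_presence_fraction,
    seg_alpha = seg_alpha,
    kw_alpha = kw_alpha,
    lod_threshold = lod_threshold,
    max_rf = max_rf,
    promoter_span = as.integer(promoter_span),
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("min_total_reads", "min_reads_per_enzyme",
              "min_methylated_samples", "dmr_window_bp", "dmr_min_diff",
              "epiqtl_min_overlap", "promoter_span")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("'%s' must be a count >= 1", nm), call. = FALSE)
  }
  probs <- c("majority_fraction", "dmr_alpha", "epiqtl_alpha",
             "marker_presence_fraction", "seg_alpha", "kw_alpha", "max_rf")
  for (nm in probs) {
    p <- cfg[[nm]]
    if (!is.numeric(p) || is.na(p) || p <= 0 || p >= 1)
      stop(sprintf("'%s' must lie strictly in (0, 1)", nm), call. = FALSE)
  }
  structure(cfg, class = "msap_config")
}

#' @export
print.msap_config <- function(x, ...) {
  cat("msapqtl run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

## The five per-sample methylation states used throughout the package.
METH_STATES <- c("unmethylated", "hemi_mCCGG", "full_CmCGG", "full_mCCGG",
                 "no_call")

#' Methylation state levels
#'
#' The five per-sample CCGG states used throughout the package:
#' \code{unmethylated}, \code{hemi_mCCGG} (hemi-methylated external cytosine),
#' \code{full_CmCGG} (fully methylated internal cytosine), \code{full_mCCGG}
#' (fully methylated external cytosine) and \code{no_call}.
#'
#' @return Character vector of the five state labels.
#' @export
methylation_states <- function() METH_STATES

## TRUE for states counted as methylated (hemi or full).
is_methylated_state <- function(state) {
  state %in% c("hemi_mCCGG", "full_CmCGG", "full_mCCGG")
}
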