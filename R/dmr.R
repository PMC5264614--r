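#' Scan for differentially methylated regions between two call sets
#'
#' Both call sets (e.g. two tissues or two genotypes) must cover the same
#' CCGG site universe. The genome is tiled into non-overlapping windows of
#' \code{cfg$dmr_window_bp}. Within a window only sites callable in both
#' sets are used, with hemi and full states collapsed to a binary
#' methylated status. A window is testable when the number of sites whose
#' status differs between the two sets reaches \code{cfg$dmr_min_diff}
#' (default 5); testable windows get a 2x2 chi-squared test (no continuity
#' correction) on (methylated, unmethylated) x (a, b), falling back to
#' Fisher's exact probability when an expected count is below 5. Windows
#' with p <= \code{cfg$dmr_alpha} are reported.
#'
#' @param calls_a,calls_b Calls data.frames for the two conditions.
#' @param cfg Configuration from [run_config()].
#' @param window_bp Window width override (defaults to
#'   \code{cfg$dmr_window_bp}).
#' @return Data.frame of significant windows: \code{scaffold},
#'   \code{start}, \code{end}, \code{n_sites}, \code{n_diff},
#'   \code{meth_a}, \code{unmeth_a}, \code{meth_b}, \code{unmeth_b},
#'   \code{chi2}, \code{p}, \code{significant} (always \code{TRUE}).
#' @export
scan_dmrs <- function(calls_a, calls_b, cfg = run_config(),
                      window_bp = cfg$dmr_window_bp) {
  key_a <- site_key(calls_a$scaffold, calls_a$position)
  key_b <- site_key(calls_b$scaffold, calls_b$position)
  common <- intersect(key_a, key_b)
  a <- calls_a[match(common, key_a), , drop = FALSE]
  b <- calls_b[match(common, key_b), , drop = FALSE]

  called <- a$state != "no_call" & b$state != "no_call"
  a <- a[called, , drop = FALSE]; b <- b[called, , drop = FALSE]
  if (nrow(a) == 0L) return(empty_dmrs())

  meth_a <- is_methylated_state(a$state)
  meth_b <- is_methylated_state(b$state)
  win <- (a$position %/% window_bp) * window_bp
  grp <- paste(a$scaffold, win, sep = "@")

  rows <- lapply(unique(grp), function(g) {
    i <- grp == g
    ma <- meth_a[i]; mb <- meth_b[i]
    n_diff <- sum(ma != mb)
    if (n_diff < cfg$dmr_min_diff) return(NULL)
    tab <- rbind(a = c(meth = sum(ma), unmeth = sum(!ma)),
                 b = c(meth = sum(mb), unmeth = sum(!mb)))
    ts <- contingency_test(tab)
    if (is.na(ts$p) || ts$p > cfg$dmr_alpha) return(NULL)
    parts <- strsplit(g, "@", fixed = TRUE)[[1L]]
    data.frame(scaffold = parts[1L],
               start = as.integer(parts[2L]),
               end = as.integer(parts[2L]) + as.integer(window_bp),
               n_sites = sum(i), n_diff = n_diff,
               meth_a = sum(ma), unmeth_a = sum(!ma),
               meth_b = sum(mb), unmeth_b = sum(!mb),
               chi2 = ts$chi2, p = ts$p, significant = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_dmrs())
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_dmrs <- function() {
  data.frame(scaffold = character(), start = integer(), end = integer(),
             n_sites = integer(), n_diff = integer(), meth_a = integer(),
             unmeth_a = integer(), meth_b = integer(), unmeth_b = integer(),
             chi2 = numeric(), p = numeric(), significant = logical(),
             stringsAsFactors = FALSE)
}

## 2x2 test: Pearson chi-squared without Yates correction; Fisher's exact
## probability when any expected count < 5. Degenerate margins -> p = NA.
contingency_test <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, p = NA_real_))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  } else {
    ht <- stats::chisq.test(tab, correct = FALSE)
    p <- ht$p.value; chi2 <- ht$statistic
  }
  list(chi2 = as.numeric(chi2), p = p)
}

#' Intersect DMRs with differential-expression calls
#'
#' A DMR is attached to a gene when its window overlaps the gene body or
#' the promoter (\code{promoter_span} bp upstream of the TSS). Only genes
#' whose differential-expression record passes the FDR gate are reported.
#'
#' @param dmrs DMR table from [scan_dmrs()].
#' @param genes Gene-model table ([gene_models()]).
#' @param de_table Data.frame with columns \code{gene_id} and
#'   \code{fdr_pass} (logical; e.g. FDR < 0.001 from the upstream DE
#'   analysis).
#' @return Data.frame: \code{gene_id}, \code{location} (\code{body} or
#'   \code{promoter}; body wins when a DMR spans both), the DMR window
#'   columns, and \code{de_fdr_pass} (always \code{TRUE}).
#' @export
intersect_dmr_deg <- function(dmrs, genes, de_table) {
  if (!all(c("gene_id", "fdr_pass") %in% names(de_table)))
    stop("de_table needs columns gene_id and fdr_pass", call. = FALSE)
  if (nrow(dmrs) == 0L) return(empty_dmr_deg())
  dmr_gr <- intervals_to_granges(dmrs[c("scaffold", "start", "end")])

  collect <- function(regions, location) {
    if (nrow(regions) == 0L) return(NULL)
    hits <- GenomicRanges::findOverlaps(
      dmr_gr, intervals_to_granges(regions), ignore.strand = TRUE)
    if (length(hits) == 0L) return(NULL)
    di <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
    data.frame(gene_id = regions$gene_id[gi], location = location,
               dmrs[di, c("scaffold", "start", "end", "n_diff", "chi2",
                          "p")],
               stringsAsFactors = FALSE)
  }
  out <- rbind(collect(genes[c("gene_id", "scaffold", "start", "end",
                               "strand")], "body"),
               collect(promoter_regions(genes), "promoter"))
  if (is.null(out)) return(empty_dmr_deg())
  ## body beats promoter for the same (gene, window)
  out <- out[order(out$gene_id, out$start, out$location), , drop = FALSE]
  out <- out[!duplicated(out[c("gene_id", "scaffold", "start")]), ,
             drop = FALSE]
  pass <- de_table$gene_id[as.logical(de_table$fdr_pass)]
  out <- out[out$gene_id %in% pass, , drop = FALSE]
  out$de_fdr_pass <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

empty_dmr_deg <- function() {
  data.frame(gene_id = character(), location = character(),
             scaffold = character(), start = integer(), end = integer(),
             n_diff = integer(), chi2 = numeric(), p = numeric(),
             de_fdr_pass = logical(), stringsAsFactors = FALSE)
}
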