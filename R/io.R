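#' Read or write a methylation-calls table
#'
#' Tab-separated with columns \code{sample_id}, \code{scaffold},
#' \code{position} (0-based), \code{state}.
#'
#' @param path File path.
#' @return \code{read_calls} returns the calls data.frame.
#' @export
read_calls <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "scaffold", "position", "state")
  if (!all(need %in% names(calls)))
    stop("calls table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(calls$state), METH_STATES)
  if (length(bad) > 0L)
    stop("unknown state(s): ", paste(bad, collapse = ", "), call. = FALSE)
  calls[need]
}

#' @rdname read_calls
#' @param calls Calls data.frame to write.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write sites or DMR windows as BED
#'
#' Emits 0-based half-open BED. Site tables get width-4 features covering
#' the CCGG; interval tables (with \code{start}/\code{end}) are written as
#' is, with the p-value-derived score \code{min(1000, -10 log10 p)} when a
#' \code{p} column is present.
#'
#' @param x Site table ([find_ccgg_sites()]) or DMR table ([scan_dmrs()]).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (all(c("start", "end") %in% names(x))) {
    score <- if ("p" %in% names(x))
      round(pmin(1000, -10 * log10(pmax(x$p, 1e-100)))) else 0L
    bed <- data.frame(x$scaffold, x$start, x$end,
                      paste0("win", seq_len(nrow(x))), score)
  } else {
    bed <- data.frame(x$scaffold, x$position, x$position + 4L,
                      paste0("site", seq_len(nrow(x))), 0L)
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated table with columns \code{gene_id}, \code{log2fc} and
#' either a logical \code{fdr_pass} column or a numeric \code{fdr} column
#' (gated at \code{fdr_cutoff}).
#'
#' @param path File path.
#' @param fdr_cutoff FDR threshold applied when only a numeric \code{fdr}
#'   column is present (default 0.001).
#' @return Data.frame with \code{gene_id}, \code{log2fc}, \code{fdr_pass}.
#' @export
read_de_table <- function(path, fdr_cutoff = 0.001) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(de))
    stop("DE table must have a gene_id column", call. = FALSE)
  if (!"fdr_pass" %in% names(de)) {
    if (!"fdr" %in% names(de))
      stop("DE table needs fdr_pass or fdr", call. = FALSE)
    de$fdr_pass <- de$fdr < fdr_cutoff
  }
  de$fdr_pass <- as.logical(de$fdr_pass)
  if (!"log2fc" %in% names(de)) de$log2fc <- NA_real_
  de[c("gene_id", "log2fc", "fdr_pass")]
}
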