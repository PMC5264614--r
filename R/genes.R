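#' Construct a gene-model table
#'
#' Gene models use 0-based half-open coordinates internally. The promoter is
#' the \code{promoter_span} bp immediately upstream of the transcription
#' start, respecting strand, truncated at the scaffold origin.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param scaffold Character vector of scaffold names.
#' @param start,end Integer vectors; 0-based half-open span of the gene body.
#' @param strand \code{"+"} or \code{"-"} per gene.
#' @param promoter_span Promoter length in bp (recycled; default 2000).
#' @return A data.frame of class \code{msap_genes} with columns
#'   \code{gene_id}, \code{scaffold}, \code{start}, \code{end},
#'   \code{strand}, \code{promoter_span}.
#' @examples
#' gene_models("g1", "chr1", 5000, 8000, "+")
#' @export
gene_models <- function(gene_id, scaffold, start, end, strand,
                        promoter_span = 2000L) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end))
    stop("gene start must be < end (0-based half-open)", call. = FALSE)
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  g <- data.frame(gene_id = as.character(gene_id),
                  scaffold = as.character(scaffold),
                  start = start, end = end,
                  strand = as.character(strand),
                  promoter_span = as.integer(rep_len(promoter_span,
                                                     length(gene_id))),
                  stringsAsFactors = FALSE)
  class(g) <- c("msap_genes", "data.frame")
  g
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) and BED coordinates (0-based
#' half-open) are both converted to the internal 0-based half-open
#' convention. For GFF3, features of type \code{gene} are used (all features
#' if none are typed \code{gene}); the \code{ID} or \code{Name} attribute
#' supplies the gene id.
#'
#' @param path Path to a \code{.gff}/\code{.gff3} or \code{.bed} file.
#' @param promoter_span Promoter length in bp attached to every model.
#' @return A gene-model table as from [gene_models()].
#' @export
read_gene_models <- function(path, promoter_span = 2000L) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if ("type" %in% names(md) && any(md$type == "gene")) {
    keep <- md$type == "gene"
    gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  }
  ids <- if ("ID" %in% names(md) && !all(is.na(md$ID))) as.character(md$ID)
         else if ("Name" %in% names(md) && !all(is.na(md$Name)))
           as.character(md$Name)
         else if ("name" %in% names(md)) as.character(md$name)
         else paste0("gene", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  gene_models(ids,
              as.character(GenomicRanges::seqnames(gr)),
              BiocGenerics::start(gr) - 1L,  # GRanges is 1-based inclusive
              BiocGenerics::end(gr),
              strand,
              promoter_span = promoter_span)
}

#' Promoter intervals for gene models
#'
#' @param genes A gene-model table from [gene_models()].
#' @return A data.frame (\code{gene_id}, \code{scaffold}, \code{start},
#'   \code{end}, \code{strand}) of 0-based half-open promoter spans upstream
#'   of each TSS; promoters running off the scaffold origin are truncated at
#'   0 and empty ones dropped.
#' @export
promoter_regions <- function(genes) {
  up <- genes$strand == "+"
  start <- ifelse(up, pmax(0L, genes$start - genes$promoter_span), genes$end)
  end <- ifelse(up, genes$start, genes$end + genes$promoter_span)
  out <- data.frame(gene_id = genes$gene_id, scaffold = genes$scaffold,
                    start = as.integer(start), end = as.integer(end),
                    strand = genes$strand, stringsAsFactors = FALSE)
  out[out$start < out$end, , drop = FALSE]
}

## 0-based half-open data.frame -> GRanges (1-based inclusive).
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

## Point sites (0-based) -> width-4 GRanges covering the CCGG.
sites_to_granges <- function(sites, width = 4L) {
  GenomicRanges::GRanges(
    seqnames = sites$scaffold,
    ranges = IRanges::IRanges(start = sites$position + 1L, width = width)
  )
}
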