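#' Count cleavage and body evidence at CCGG sites for one library
#'
#' Classifies aligned reads of a single enzyme library (HpaII or MspI)
#' against a set of CCGG sites. The enzymes cut C^CGG, i.e. immediately
#' after the first C, so the cut position of a site at 0-based
#' \code{position} is \code{position + 1}. A read is CLEAVAGE evidence when
#' its alignment starts or ends exactly at the cut position, and BODY
#' evidence when its aligned span covers the whole 4-mer
#' \code{[position, position + 4)} internally. Reads doing neither (partial
#' overlaps) carry no evidence. Assignment uses alignment coordinates only.
#'
#' @param alignments A \code{GAlignments} object, or the path to a BAM or SAM
#'   file (SAM is converted on the fly).
#' @param sites Site table from [find_ccgg_sites()].
#' @param sample_id Sample identifier attached to the output.
#' @param enzyme \code{"HpaII"} or \code{"MspI"}; decides which output
#'   columns (\code{h_*} or \code{m_*}) receive the counts.
#' @return An evidence data.frame (one row per site) with columns
#'   \code{sample_id}, \code{scaffold}, \code{position}, \code{h_cleave},
#'   \code{m_cleave}, \code{h_body}, \code{m_body}; the other enzyme's
#'   columns are zero.
#' @seealso [combine_evidence()] to merge the two libraries of one sample.
#' @export
extract_evidence <- function(alignments, sites, sample_id,
                             enzyme = c("HpaII", "MspI")) {
  enzyme <- match.arg(enzyme)
  aln <- as_galignments(alignments)
  starts <- BiocGenerics::start(aln) - 1L   # 0-based inclusive
  ends <- BiocGenerics::end(aln)            # 0-based exclusive
  scaf <- as.character(GenomicAlignments::seqnames(aln))

  known <- scaf %in% unique(sites$scaffold)
  if (any(!known)) {
    warning(sprintf("%d read(s) on scaffolds absent from the site list; skipped",
                    sum(!known)))
    starts <- starts[known]; ends <- ends[known]; scaf <- scaf[known]
  }

  counts <- count_cleave_body(starts, ends, scaf, sites)
  ev <- data.frame(sample_id = sample_id,
                   scaffold = sites$scaffold,
                   position = sites$position,
                   h_cleave = 0L, m_cleave = 0L, h_body = 0L, m_body = 0L,
                   stringsAsFactors = FALSE)
  if (enzyme == "HpaII") {
    ev$h_cleave <- counts$cleave; ev$h_body <- counts$body
  } else {
    ev$m_cleave <- counts$cleave; ev$m_body <- counts$body
  }
  ev
}

## Overlap-join reads against width-4 site ranges and classify each pair.
count_cleave_body <- function(starts, ends, scaf, sites) {
  n_sites <- nrow(sites)
  cleave <- integer(n_sites); body <- integer(n_sites)
  if (length(starts) > 0L && n_sites > 0L) {
    reads <- GenomicRanges::GRanges(scaf,
                                    IRanges::IRanges(start = starts + 1L,
                                                     end = ends))
    hits <- GenomicRanges::findOverlaps(reads, sites_to_granges(sites))
    ri <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    cut <- sites$position[si] + 1L
    is_cleave <- starts[ri] == cut | ends[ri] == cut
    is_body <- !is_cleave & starts[ri] <= sites$position[si] &
      ends[ri] >= sites$position[si] + 4L
    cleave <- tabulate_at(si[is_cleave], n_sites)
    body <- tabulate_at(si[is_body], n_sites)
  }
  list(cleave = cleave, body = body)
}

tabulate_at <- function(idx, n) {
  if (length(idx) == 0L) return(integer(n))
  tabulate(idx, nbins = n)
}

as_galignments <- function(x) {
  if (inherits(x, "GAlignments")) return(x)
  if (is.character(x) && length(x) == 1L) {
    path <- x
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    }
    return(GenomicAlignments::readGAlignments(path))
  }
  stop("alignments must be a GAlignments object or a BAM/SAM path",
       call. = FALSE)
}

#' Merge per-library evidence into one sample record
#'
#' One logical sample is the pair of its HpaII and MspI libraries under a
#' common \code{sample_id}. A missing library contributes zero counts for
#' that enzyme (and the site will be a \code{no_call} downstream).
#'
#' @param hpaii,mspi Evidence data.frames from [extract_evidence()]; either
#'   may be \code{NULL}.
#' @return A single evidence data.frame with summed counts per site.
#' @export
combine_evidence <- function(hpaii = NULL, mspi = NULL) {
  pieces <- Filter(Negate(is.null), list(hpaii, mspi))
  if (length(pieces) == 0L) stop("at least one library required", call. = FALSE)
  ev <- do.call(rbind, pieces)
  key <- interaction(ev$sample_id, ev$scaffold, ev$position, drop = TRUE)
  agg <- rowsum(ev[c("h_cleave", "m_cleave", "h_body", "m_body")], key,
                reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(sample_id = ev$sample_id[first],
                    scaffold = ev$scaffold[first],
                    position = ev$position[first],
                    agg, stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$scaffold, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read or write a site-evidence table
#'
#' Tab-separated with columns \code{sample_id}, \code{scaffold},
#' \code{position} (0-based), \code{h_cleave}, \code{m_cleave},
#' \code{h_body}, \code{m_body}.
#'
#' @param path File path.
#' @return \code{read_evidence} returns the evidence data.frame.
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "scaffold", "position", "h_cleave", "m_cleave",
            "h_body", "m_body")
  if (!all(need %in% names(ev)))
    stop("evidence table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  check_counts(ev)
  ev[need]
}

#' @rdname read_evidence
#' @param evidence Evidence data.frame to write.
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_counts <- function(ev) {
  cols <- c("h_cleave", "m_cleave", "h_body", "m_body")
  for (cl in cols) {
    if (any(ev[[cl]] < 0, na.rm = TRUE))
      stop("negative read counts in evidence", call. = FALSE)
  }
  invisible(TRUE)
}
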