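#' Locate CCGG sites in a reference
#'
#' Scans every reference sequence for occurrences of the HpaII/MspI
#' recognition site CCGG. Because CCGG is its own reverse complement, one
#' record per forward-strand occurrence covers both strands.
#'
#' @param reference A \code{Biostrings::DNAStringSet}, a named character
#'   vector of sequences, or the path to a FASTA file.
#' @return A data.frame with columns \code{scaffold} (character),
#'   \code{position} (integer, 0-based position of the first C) and
#'   \code{strand} (always \code{"+"}), sorted by (scaffold, position).
#' @examples
#' find_ccgg_sites(c(chr1 = "AACCGGTT"))
#' @export
find_ccgg_sites <- function(reference) {
  seqs <- as_dna_set(reference)
  if (length(seqs) == 0L) return(empty_sites())
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("reference sequences must be named", call. = FALSE)
  hits <- Biostrings::vmatchPattern("CCGG", seqs, fixed = TRUE)
  out <- lapply(seq_along(seqs), function(i) {
    st <- BiocGenerics::start(hits[[i]])
    if (length(st) == 0L) return(NULL)
    data.frame(scaffold = names(seqs)[i],
               position = as.integer(st - 1L),   # 1-based match -> 0-based
               strand = "+",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_sites())
  out <- out[order(out$scaffold, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_sites <- function() {
  data.frame(scaffold = character(), position = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

## Coerce a FASTA path, character vector or DNAStringSet to a DNAStringSet,
## rejecting non-IUPAC letters.
as_dna_set <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  if (is.character(reference)) {
    alphabet <- setdiff(Biostrings::DNA_ALPHABET, c("+", "-", "."))
    bad <- grepl(sprintf("[^%s.+-]", paste(alphabet, collapse = "")),
                 toupper(reference))
    if (any(bad))
      stop("reference contains non-IUPAC DNA characters", call. = FALSE)
    return(Biostrings::DNAStringSet(toupper(reference)))
  }
  stop("unsupported reference type", call. = FALSE)
}

## Internal site key "scaffold:position" used to join tables.
site_key <- function(scaffold, position) paste(scaffold, position, sep = ":")
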