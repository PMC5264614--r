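#' Default parent-to-F1 inheritance class table
#'
#' Methylated sites observed in both parents and the F1 progeny are grouped
#' into twelve heritability classes from the parental pattern and the F1
#' pattern. States are collapsed to hemi / full / unmethylated for this
#' classification (the two full states pool into "full"). The default table:
#' \itemize{
#'   \item A1/A2 — parents share a methylated state, F1 uniformly inherit it
#'     (A1 hemi, A2 full);
#'   \item B1-B4 — parents share a methylated state but the F1 depart from
#'     it: segregating F1 (B1 hemi parents, B3 full parents) or a uniformly
#'     changed/lost state (B2 hemi parents, B4 full parents);
#'   \item C1/C2 — parents unmethylated, F1 methylated de novo (C1 hemi,
#'     C2 full);
#'   \item D1-D4 — parents disagree: D1 uniform F1, D2 segregating F1,
#'     D3 F1 in a state absent from both parents, D4 methylation absent
#'     from the F1.
#' }
#' The table is a plain data.frame and can be replaced by the user wherever
#' a \code{class_table} argument is accepted.
#'
#' @return data.frame with columns \code{parent_pattern}
#'   (\code{both_hemi}, \code{both_full}, \code{both_unmethylated},
#'   \code{disparate}), \code{f1_pattern} (\code{uniform_parental},
#'   \code{segregating}, \code{novel}, \code{absent}), \code{f1_state}
#'   (disambiguates C1/C2; \code{NA} elsewhere) and \code{class_label}.
#' @export
default_class_table <- function() {
  data.frame(
    parent_pattern = c("both_hemi", "both_full",
                       "both_hemi", "both_hemi", "both_hemi",
                       "both_full", "both_full", "both_full",
                       "both_unmethylated", "both_unmethylated",
                       "both_unmethylated", "both_unmethylated",
                       "disparate", "disparate", "disparate", "disparate"),
    f1_pattern = c("uniform_parental", "uniform_parental",
                   "segregating", "novel", "absent",
                   "segregating", "novel", "absent",
                   "novel", "novel", "segregating", "segregating",
                   "uniform_parental", "segregating", "novel", "absent"),
    f1_state = c(NA, NA, NA, NA, NA, NA, NA, NA,
                 "hemi", "full", "hemi", "full",
                 NA, NA, NA, NA),
    class_label = c("A1", "A2", "B1", "B2", "B2", "B3", "B4", "B4",
                    "C1", "C2", "C1", "C2", "D1", "D2", "D3", "D4"),
    stringsAsFactors = FALSE
  )
}

## Collapse the five call states to hemi / full / unmethylated / NA.
collapse_state <- function(state) {
  out <- rep(NA_character_, length(state))
  out[state == "hemi_mCCGG"] <- "hemi"
  out[state %in% c("full_CmCGG", "full_mCCGG")] <- "full"
  out[state == "unmethylated"] <- "unmethylated"
  out
}

## Parental pattern from two collapsed states.
parent_pattern_of <- function(p1, p2) {
  if (p1 == p2) {
    switch(p1,
           hemi = "both_hemi",
           full = "both_full",
           unmethylated = "both_unmethylated")
  } else {
    "disparate"
  }
}

## F1 pattern from collapsed non-missing F1 states and the parent states.
## Precedence: absent (no methylated F1) > uniform_parental > segregating
## > novel.
f1_pattern_of <- function(f1, parents) {
  u <- unique(f1)
  if (all(f1 == "unmethylated")) return("absent")
  if (length(u) == 1L) {
    if (u %in% parents) return("uniform_parental")
    return("novel")
  }
  "segregating"
}

#' Classify the inheritance of one methylated site
#'
#' Derives the parental pattern and F1 pattern at a site and looks the pair
#' up in the class table. Both parent calls must be callable; F1
#' \code{no_call}s are ignored and at least one called F1 is required. The
#' result depends only on the multiset of F1 states, not their order.
#'
#' @param parent_states Length-2 character vector: the KU50-type (female)
#'   and SC124-type (male) parent states.
#' @param f1_states Character vector of F1 states.
#' @param class_table Class table, by default [default_class_table()].
#' @return A one-row data.frame: \code{parent_pattern}, \code{f1_pattern},
#'   \code{class_label} (\code{NA} when the pattern pair is absent from the
#'   table, e.g. a site methylated in no individual).
#' @examples
#' classify_inheritance(c("full_mCCGG", "full_mCCGG"),
#'                      rep("full_mCCGG", 5))   # A2
#' @export
classify_inheritance <- function(parent_states, f1_states,
                                 class_table = default_class_table()) {
  if (length(parent_states) != 2L)
    stop("exactly two parent states required", call. = FALSE)
  if (any(parent_states == "no_call"))
    stop("parent state is no_call; site must be skipped", call. = FALSE)
  p <- collapse_state(parent_states)
  f1 <- collapse_state(f1_states[f1_states != "no_call"])
  if (length(f1) == 0L)
    stop("no called F1 individuals at this site", call. = FALSE)

  pp <- parent_pattern_of(p[1L], p[2L])
  fp <- f1_pattern_of(f1, p)
  cand <- class_table[class_table$parent_pattern == pp &
                        class_table$f1_pattern == fp, , drop = FALSE]
  if (nrow(cand) > 1L && !all(is.na(cand$f1_state))) {
    ## C-group: disambiguate by the methylated F1 states (full wins a mix).
    f1_meth <- f1[f1 != "unmethylated"]
    aux <- if (any(f1_meth == "full")) "full" else "hemi"
    cand <- cand[cand$f1_state == aux, , drop = FALSE]
  }
  label <- if (nrow(cand) >= 1L) cand$class_label[1L] else NA_character_
  data.frame(parent_pattern = pp, f1_pattern = fp, class_label = label,
             stringsAsFactors = FALSE)
}

#' Classify inheritance for every site of a call matrix
#'
#' @param call_matrix Site x sample state matrix from [calls_matrix()].
#' @param parent_ids Length-2 character vector naming the two parent
#'   columns (female, male).
#' @param class_table Class table, by default [default_class_table()].
#' @return A data.frame with one row per classifiable site: \code{site}
#'   (the \code{scaffold:position} key), \code{parent_pattern},
#'   \code{f1_pattern}, \code{class_label}. Sites with an uncallable parent
#'   or no called F1 are skipped.
#' @export
classify_inheritance_sites <- function(call_matrix, parent_ids,
                                       class_table = default_class_table()) {
  stopifnot(length(parent_ids) == 2L, all(parent_ids %in%
                                            colnames(call_matrix)))
  f1_cols <- setdiff(colnames(call_matrix), parent_ids)
  rows <- lapply(rownames(call_matrix), function(sk) {
    ps <- call_matrix[sk, parent_ids]
    f1 <- call_matrix[sk, f1_cols]
    if (any(ps == "no_call") || all(f1 == "no_call")) return(NULL)
    cbind(site = sk, classify_inheritance(ps, f1, class_table))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = character(), parent_pattern = character(),
                      f1_pattern = character(), class_label = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## Generating recipes for the twelve classes, the single source of truth
## shared with the simulator. Each entry: collapsed parent states and an F1
## rule (uniform state, all-unmethylated, or a segregating pair).
class_recipes <- function() {
  list(
    A1 = list(parents = c("hemi", "hemi"), f1 = list(kind = "uniform", state = "hemi")),
    A2 = list(parents = c("full", "full"), f1 = list(kind = "uniform", state = "full")),
    B1 = list(parents = c("hemi", "hemi"), f1 = list(kind = "segregating", states = c("hemi", "unmethylated"))),
    B2 = list(parents = c("hemi", "hemi"), f1 = list(kind = "uniform", state = "full")),
    B3 = list(parents = c("full", "full"), f1 = list(kind = "segregating", states = c("full", "unmethylated"))),
    B4 = list(parents = c("full", "full"), f1 = list(kind = "uniform", state = "hemi")),
    C1 = list(parents = c("unmethylated", "unmethylated"), f1 = list(kind = "uniform", state = "hemi")),
    C2 = list(parents = c("unmethylated", "unmethylated"), f1 = list(kind = "uniform", state = "full")),
    D1 = list(parents = c("full", "unmethylated"), f1 = list(kind = "uniform", state = "full")),
    D2 = list(parents = c("full", "unmethylated"), f1 = list(kind = "segregating", states = c("full", "unmethylated"))),
    D3 = list(parents = c("full", "unmethylated"), f1 = list(kind = "uniform", state = "hemi")),
    D4 = list(parents = c("hemi", "unmethylated"), f1 = list(kind = "uniform", state = "unmethylated"))
  )
}
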