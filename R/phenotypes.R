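#' Level-based tolerance / recovery indices
#'
#' The cold-tolerance (greenhouse CTIG, field CTIF) and recovery (RIG, RIF)
#' indices summarise per-plant ordinal damage or recovery levels for a
#' clone as a weighted mean scaled to 0-100:
#' \deqn{I = 100 \cdot \frac{\sum_i level_i \cdot n_i}{max\_level \cdot \sum_i n_i}}
#' where \eqn{n_i} is the number of plants scored at \eqn{level_i}.
#' Greenhouse and field tolerance levels and field recovery levels run 0-4;
#' greenhouse recovery levels (kind \code{RLG}) run 1-4 and are shifted to
#' a 0-3 scale before weighting so the index still spans the full 0-100
#' range.
#'
#' @param levels Named numeric vector: names are the levels, values the
#'   plant counts (e.g. \code{c(`0` = 2, `2` = 4, `4` = 2)}).
#' @param kind One of \code{"CTLG"}, \code{"CTLF"}, \code{"RLF"} (levels
#'   0-4) or \code{"RLG"} (levels 1-4).
#' @param max_level Top level of the scale (default 4).
#' @return Index value in \code{[0, 100]}.
#' @examples
#' level_index(c(`0` = 2, `2` = 4, `4` = 2))  # 50
#' @export
level_index <- function(levels, kind = c("CTLG", "CTLF", "RLF", "RLG"),
                        max_level = 4L) {
  kind <- match.arg(kind)
  n <- as.numeric(levels)
  lev <- as.numeric(names(levels))
  if (length(n) == 0L || sum(n) <= 0)
    stop("at least one scored plant required", call. = FALSE)
  if (anyNA(lev)) stop("levels must be named by their numeric level",
                       call. = FALSE)
  lo <- if (kind == "RLG") 1L else 0L
  if (any(lev < lo | lev > max_level))
    stop(sprintf("levels for kind %s must lie in %d..%d", kind, lo,
                 max_level), call. = FALSE)
  if (kind == "RLG") {                  # shift 1-4 onto 0-3
    lev <- lev - 1L
    max_level <- max_level - 1L
  }
  100 * sum(lev * n) / (max_level * sum(n))
}

#' Leaf fall index
#'
#' Percentage of fallen leaves, from total leaves (NL, counted through leaf
#' scars) and fallen leaves (NLF).
#'
#' @param nlf Number of fallen leaves.
#' @param nl Total number of leaves; must be positive.
#' @return \code{100 * nlf / nl}.
#' @export
leaf_fall_index <- function(nlf, nl) {
  if (any(nl <= 0)) stop("total leaf count must be positive", call. = FALSE)
  if (any(nlf < 0 | nlf > nl))
    stop("fallen leaves must lie in [0, total leaves]", call. = FALSE)
  100 * nlf / nl
}

#' Storage-root dry-weight percentage
#'
#' From a fresh sample of mass \code{w1} grams (200 g by protocol) oven
#' dried to \code{w2} grams.
#'
#' @param w2 Dry mass in grams.
#' @param w1 Fresh mass in grams (default 200).
#' @return \code{100 * w2 / w1}.
#' @export
dry_weight_percent <- function(w2, w1 = 200) {
  if (any(w1 <= 0)) stop("fresh mass must be positive", call. = FALSE)
  if (any(w2 < 0 | w2 > w1))
    stop("dry mass must lie in [0, fresh mass]", call. = FALSE)
  100 * w2 / w1
}

#' Relative storage-root yield
#'
#' Yield at a test site relative to the yield of the same clone at a
#' reference site (e.g. a colder field relative to a warm one).
#'
#' @param yield_site Yield at the test site.
#' @param yield_reference Yield at the reference site; must be positive.
#' @return \code{yield_site / yield_reference}.
#' @export
relative_yield <- function(yield_site, yield_reference) {
  if (any(yield_reference <= 0))
    stop("reference yield must be positive", call. = FALSE)
  if (any(yield_site < 0)) stop("yield must be non-negative", call. = FALSE)
  yield_site / yield_reference
}

#' Starch content on a fresh-weight basis
#'
#' Converts a starch percentage measured per dry weight to a per fresh
#' weight basis using the dry-weight percentage.
#'
#' @param starch_dry_pct Starch content, percent of dry weight.
#' @param dw_pct Dry-weight percentage from [dry_weight_percent()].
#' @return Starch percent of fresh weight.
#' @export
starch_fresh_basis <- function(starch_dry_pct, dw_pct) {
  if (any(starch_dry_pct < 0 | dw_pct < 0))
    stop("percentages must be non-negative", call. = FALSE)
  starch_dry_pct * dw_pct / 100
}

#' Build a clone x trait matrix from raw phenotype records
#'
#' Applies the appropriate index formula per trait family and averages
#' replicate records of the same (clone, trait). Input records carry one
#' measurement each; columns used per family:
#' \itemize{
#'   \item CTIG/CTIF/RIG/RIF: \code{level}, \code{n_plants} (one row per
#'     level);
#'   \item LFIF: \code{nlf}, \code{nl};
#'   \item DW: \code{w2} and optional \code{w1};
#'   \item rSRY: \code{yield_site}, \code{yield_reference};
#'   \item FSC: \code{starch_dry_pct}, \code{dw_pct};
#'   \item SRY/NSR: pass-through \code{value}.
#' }
#'
#' @param records Data.frame with at least \code{clone_id},
#'   \code{trait_code} plus the family-specific columns above.
#' @return Numeric matrix, rows = clones, columns = trait codes.
#' @export
phenotype_matrix <- function(records) {
  if (!all(c("clone_id", "trait_code") %in% names(records)))
    stop("records need clone_id and trait_code", call. = FALSE)
  fam <- trait_family(records$trait_code)
  grp <- paste(records$clone_id, records$trait_code, sep = "\r")
  vals <- vapply(split(seq_len(nrow(records)), grp), function(i) {
    df <- records[i, , drop = FALSE]
    f <- fam[i[1L]]
    if (f %in% c("CTIG", "CTIF", "RIG", "RIF")) {
      kind <- switch(f, CTIG = "CTLG", CTIF = "CTLF", RIG = "RLG",
                     RIF = "RLF")
      cnt <- tapply(df$n_plants, df$level, sum)
      level_index(stats::setNames(as.numeric(cnt), names(cnt)), kind)
    } else if (f == "LFIF") {
      mean(leaf_fall_index(df$nlf, df$nl))
    } else if (f == "DW") {
      w1 <- if ("w1" %in% names(df) && !anyNA(df$w1)) df$w1 else 200
      mean(dry_weight_percent(df$w2, w1))
    } else if (f == "rSRY") {
      mean(relative_yield(df$yield_site, df$yield_reference))
    } else if (f == "FSC") {
      mean(starch_fresh_basis(df$starch_dry_pct, df$dw_pct))
    } else {
      mean(df$value)
    }
  }, numeric(1))
  ids <- do.call(rbind, strsplit(names(vals), "\r", fixed = TRUE))
  clones <- sort(unique(ids[, 1L]))
  traits <- sort(unique(ids[, 2L]))
  m <- matrix(NA_real_, length(clones), length(traits),
              dimnames = list(clones, traits))
  m[cbind(match(ids[, 1L], clones), match(ids[, 2L], traits))] <- vals
  m
}

#' Trait family of a trait code
#'
#' Strips the trailing trial number, so \code{CTIF3 -> CTIF},
#' \code{rSRY2 -> rSRY}. Used to group repeated measurements of the same
#' trait across trials.
#'
#' @param trait_code Character vector of trait codes.
#' @return Character vector of family names.
#' @export
trait_family <- function(trait_code) {
  sub("[-_]?[0-9]+$", "", trait_code)
}
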