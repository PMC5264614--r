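#' Simulation configuration
#'
#' Describes a synthetic outbred F1 (CP) mapping population modelled on a
#' two-parent cassava cross: 186 F1 clones plus the two parents, CCGG sites
#' on toy scaffolds with per-site inheritance classes, dominant markers
#' segregating 1:1 (parent-specific) or 3:1 (shared), read-level
#' cleavage/body evidence at roughly 5-fold depth, and phenotypes built
#' from planted site effects plus Gaussian noise. Class frequencies default
#' to A/D classes only, with D2-D4 carrying the majority of sites, the
#' composition reported for the cassava population.
#'
#' @param n_f1 Number of F1 individuals (default 186).
#' @param n_sites Number of CCGG sites (default 1000).
#' @param n_markers Number of dominant markers (default 500).
#' @param n_scaffolds Number of toy scaffolds (default 5).
#' @param n_genes Number of gene models (default 50).
#' @param class_frequencies Named numeric vector over the twelve
#'   inheritance classes; must sum to 1.
#' @param read_depth_mean Mean Poisson read depth per evidence category
#'   (default 5, the per-sample coverage of the emulated study).
#' @param evidence_noise_rate Probability that a read is recorded in the
#'   wrong evidence category (default 0.01).
#' @param full_variant_prob Probability that a fully methylated site is the
#'   internal-cytosine (CmCGG) variant rather than external (default 0.67,
#'   matching the reported excess of CmCGG calls).
#' @param marker_type_probs Named probabilities over \code{lm_ll},
#'   \code{nn_np}, \code{hk_hk}.
#' @param marker_missing_rate Probability a progeny marker call is missing.
#' @param effect_sites \code{NULL} or data.frame (\code{site} index,
#'   \code{trait_code}, \code{beta}) of planted phenotype effects.
#' @param sim_traits Trait codes to simulate (traits without planted
#'   effects are pure noise).
#' @param trait_noise_sd Standard deviation of the Gaussian trait noise.
#' @param seed Integer RNG seed; every simulator output is a pure function
#'   of the configuration including this seed.
#' @return Object of class \code{msap_sim_config}.
#' @export
sim_config <- function(n_f1 = 186L,
                       n_sites = 1000L,
                       n_markers = 500L,
                       n_scaffolds = 5L,
                       n_genes = 50L,
                       class_frequencies = c(A1 = 0.06, A2 = 0.24,
                                             D1 = 0.12, D2 = 0.28,
                                             D3 = 0.10, D4 = 0.20),
                       read_depth_mean = 5,
                       evidence_noise_rate = 0.01,
                       full_variant_prob = 0.67,
                       marker_type_probs = c(lm_ll = 0.4, nn_np = 0.4,
                                             hk_hk = 0.2),
                       marker_missing_rate = 0.05,
                       effect_sites = NULL,
                       sim_traits = c("CTIG", "CTIF1", "CTIF2", "SRY1"),
                       trait_noise_sd = 1,
                       seed = 1L) {
  bad <- setdiff(names(class_frequencies), names(class_recipes()))
  if (length(bad) > 0L)
    stop("unknown inheritance class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (abs(sum(class_frequencies) - 1) > 1e-8)
    stop("class_frequencies must sum to 1", call. = FALSE)
  if (evidence_noise_rate < 0 || evidence_noise_rate > 1)
    stop("evidence_noise_rate must be in [0, 1]", call. = FALSE)
  if (!is.null(effect_sites)) {
    stopifnot(all(c("site", "trait_code", "beta") %in%
                    names(effect_sites)))
    if (any(effect_sites$site < 1L | effect_sites$site > n_sites))
      stop("effect site index outside 1..n_sites", call. = FALSE)
  }
  structure(list(n_f1 = as.integer(n_f1), n_sites = as.integer(n_sites),
                 n_markers = as.integer(n_markers),
                 n_scaffolds = as.integer(n_scaffolds),
                 n_genes = as.integer(n_genes),
                 class_frequencies = class_frequencies,
                 read_depth_mean = read_depth_mean,
                 evidence_noise_rate = evidence_noise_rate,
                 full_variant_prob = full_variant_prob,
                 marker_type_probs = marker_type_probs,
                 marker_missing_rate = marker_missing_rate,
                 effect_sites = effect_sites,
                 sim_traits = sim_traits,
                 trait_noise_sd = trait_noise_sd,
                 seed = as.integer(seed)),
            class = "msap_sim_config")
}

#' Simulate the cross: parents, F1 states, markers, genes
#'
#' Draws an inheritance class per site from \code{class_frequencies},
#' assigns parental states from that class's recipe and F1 states from its
#' inheritance rule (the recipes are the same table the classifier uses,
#' see [default_class_table()]). Markers segregate Bernoulli(1/2) for
#' parent-specific types and Bernoulli(3/4) for shared (hk_hk) types. Gene
#' models and site coordinates are laid out on toy scaffolds.
#'
#' @param cfg Simulation configuration from [sim_config()].
#' @return Object of class \code{msap_truth}: list with \code{sites}
#'   (coordinates + generating class + full-state variant), \code{states}
#'   (site x sample matrix, parents first), \code{markers} and \code{geno}
#'   (marker table + progeny presence matrix), \code{genes},
#'   \code{scaffold_lengths}, \code{samples}, \code{parents}, \code{cfg}.
#' @export
simulate_cross <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  recipes <- class_recipes()
  parents <- c("KU50", "SC124")
  f1_ids <- sprintf("F%03d", seq_len(cfg$n_f1))
  samples <- c(parents, f1_ids)

  ## site coordinates: sites spread over scaffolds, irregular spacing
  scaffold <- sort(rep_len(sprintf("scf%02d", seq_len(cfg$n_scaffolds)),
                           cfg$n_sites))
  position <- unlist(lapply(split(seq_len(cfg$n_sites), scaffold),
                            function(i) cumsum(sample(40:200, length(i),
                                                      replace = TRUE))),
                     use.names = FALSE)
  cls <- sample(names(cfg$class_frequencies), cfg$n_sites, replace = TRUE,
                prob = cfg$class_frequencies)
  full_variant <- ifelse(stats::runif(cfg$n_sites) < cfg$full_variant_prob,
                         "full_CmCGG", "full_mCCGG")
  sites <- data.frame(scaffold = scaffold, position = as.integer(position),
                      strand = "+", class_label = cls,
                      full_variant = full_variant,
                      stringsAsFactors = FALSE)

  concrete <- function(collapsed, i) {
    ifelse(collapsed == "hemi", "hemi_mCCGG",
           ifelse(collapsed == "full", sites$full_variant[i], "unmethylated"))
  }
  states <- matrix(NA_character_, cfg$n_sites, length(samples),
                   dimnames = list(site_key(scaffold, position), samples))
  for (i in seq_len(cfg$n_sites)) {
    rec <- recipes[[cls[i]]]
    states[i, parents] <- concrete(rec$parents, i)
    rule <- rec$f1
    f1 <- if (rule$kind == "uniform") {
      rep(rule$state, cfg$n_f1)
    } else {
      draw <- sample(rule$states, cfg$n_f1, replace = TRUE)
      ## guarantee a genuinely segregating site
      if (length(unique(draw)) == 1L)
        draw[sample.int(cfg$n_f1, 1L)] <- setdiff(rule$states, draw[1L])
      draw
    }
    states[i, f1_ids] <- concrete(f1, i)
  }

  ## dominant markers
  mtype <- sample(names(cfg$marker_type_probs), cfg$n_markers,
                  replace = TRUE, prob = cfg$marker_type_probs)
  markers <- data.frame(
    marker_id = sprintf("mk%05d", seq_len(cfg$n_markers)),
    marker_type_true = mtype,
    parent_female = mtype %in% c("lm_ll", "hk_hk"),
    parent_male = mtype %in% c("nn_np", "hk_hk"),
    read_support = pmax(2L, stats::rpois(cfg$n_markers,
                                         cfg$read_depth_mean)),
    stringsAsFactors = FALSE)
  p_present <- ifelse(mtype == "hk_hk", 3 / 4, 1 / 2)
  geno <- matrix(stats::rbinom(cfg$n_markers * cfg$n_f1, 1L,
                               rep(p_present, cfg$n_f1)),
                 cfg$n_markers, cfg$n_f1,
                 dimnames = list(markers$marker_id, f1_ids))
  if (cfg$marker_missing_rate > 0) {
    geno[stats::runif(length(geno)) < cfg$marker_missing_rate] <- NA
  }

  ## gene models on the same scaffolds
  scaffold_lengths <- tapply(position, scaffold, max) + 500L
  g_scf <- sample(names(scaffold_lengths), cfg$n_genes, replace = TRUE)
  g_len <- sample(800:4000, cfg$n_genes, replace = TRUE)
  g_start <- vapply(seq_len(cfg$n_genes), function(i) {
    sample.int(max(1L, scaffold_lengths[[g_scf[i]]] - g_len[i]), 1L) - 1L
  }, integer(1))
  genes <- gene_models(sprintf("gene%03d", seq_len(cfg$n_genes)), g_scf,
                       g_start, g_start + g_len,
                       sample(c("+", "-"), cfg$n_genes, replace = TRUE))

  structure(list(sites = sites, states = states, markers = markers,
                 geno = geno, genes = genes,
                 scaffold_lengths = scaffold_lengths, samples = samples,
                 parents = parents, f1_ids = f1_ids, cfg = cfg),
            class = "msap_truth")
}

#' @export
print.msap_truth <- function(x, ...) {
  cat(sprintf("synthetic cross: %d sites x %d samples (2 parents + %d F1), %d markers, %d genes\n",
              nrow(x$sites), length(x$samples), length(x$f1_ids),
              nrow(x$markers), nrow(x$genes)))
  invisible(x)
}

#' Simulate read-level evidence from true states
#'
#' Inverts the calling rules: for each (sample, site) the two evidence
#' categories implied by the true state receive Poisson(
#' \code{read_depth_mean}) reads, floor-guarded at the per-enzyme minimum
#' so that the noiseless expectation is always callable; the other two
#' categories are zero. With \code{evidence_noise_rate > 0}, each read is
#' independently reassigned to a uniformly chosen other category with that
#' probability.
#'
#' @param truth Truth bundle from [simulate_cross()].
#' @param cfg Simulation configuration (defaults to the one inside
#'   \code{truth}).
#' @return Evidence data.frame as accepted by [call_states()].
#' @export
simulate_evidence <- function(truth, cfg = truth$cfg) {
  set.seed(cfg$seed + 1L)
  n_sites <- nrow(truth$sites)
  samples <- truth$samples
  n <- n_sites * length(samples)

  state <- as.vector(truth$states[, samples])
  draw <- function(m) pmax(2L, stats::rpois(m, cfg$read_depth_mean))
  counts <- matrix(0L, n, 4L,
                   dimnames = list(NULL, c("h_cleave", "m_cleave",
                                           "h_body", "m_body")))
  pattern <- list(hemi_mCCGG = c("h_cleave", "m_body"),
                  full_CmCGG = c("m_cleave", "h_body"),
                  full_mCCGG = c("h_body", "m_body"),
                  unmethylated = c("h_cleave", "m_cleave"))
  for (st in names(pattern)) {
    idx <- which(state == st)
    for (cat in pattern[[st]]) counts[idx, cat] <- draw(length(idx))
  }
  if (cfg$evidence_noise_rate > 0) {
    for (j in 1:4) {
      flips <- stats::rbinom(n, counts[, j], cfg$evidence_noise_rate)
      counts[, j] <- counts[, j] - flips
      others <- setdiff(1:4, j)
      ## split the flipped reads uniformly over the other three categories
      a <- stats::rbinom(n, flips, 1 / 3)
      b <- stats::rbinom(n, flips - a, 1 / 2)
      counts[, others[1L]] <- counts[, others[1L]] + a
      counts[, others[2L]] <- counts[, others[2L]] + b
      counts[, others[3L]] <- counts[, others[3L]] + (flips - a - b)
    }
  }
  data.frame(sample_id = rep(samples, each = n_sites),
             scaffold = rep(truth$sites$scaffold, length(samples)),
             position = rep(truth$sites$position, length(samples)),
             counts, stringsAsFactors = FALSE)
}

#' Simulate phenotypes with planted site effects
#'
#' Each simulated trait is a linear combination of methylation scores at
#' its planted effect sites plus Gaussian noise:
#' \eqn{y = \sum \beta \cdot score(site) + N(0, sd)}. Traits without
#' planted effects are pure noise. Only F1 individuals receive phenotypes.
#'
#' @param truth Truth bundle from [simulate_cross()].
#' @param cfg Simulation configuration (defaults to the one inside
#'   \code{truth}).
#' @return Numeric matrix, rows = F1 clone ids, columns = trait codes.
#' @export
simulate_phenotypes <- function(truth, cfg = truth$cfg) {
  set.seed(cfg$seed + 2L)
  scores <- score_methylation(truth$states[, truth$f1_ids, drop = FALSE])
  scores[is.na(scores)] <- 0
  traits <- unique(c(cfg$sim_traits,
                     if (!is.null(cfg$effect_sites))
                       cfg$effect_sites$trait_code))
  out <- matrix(0, length(truth$f1_ids), length(traits),
                dimnames = list(truth$f1_ids, traits))
  if (!is.null(cfg$effect_sites)) {
    for (i in seq_len(nrow(cfg$effect_sites))) {
      es <- cfg$effect_sites[i, ]
      out[, es$trait_code] <- out[, es$trait_code] +
        es$beta * scores[es$site, ]
    }
  }
  out + matrix(stats::rnorm(length(out), 0, cfg$trait_noise_sd),
               nrow(out), ncol(out))
}

#' Discretize a continuous trait onto ordinal levels
#'
#' Bins values into \code{n_levels} quantile classes labelled
#' \code{0 .. n_levels - 1}, as used to turn simulated continuous damage
#' scores into the 0-4 level scale of the tolerance indices.
#'
#' @param values Numeric vector.
#' @param n_levels Number of levels (default 5, i.e. levels 0-4).
#' @return Integer vector of levels.
#' @export
quantile_levels <- function(values, n_levels = 5L) {
  qs <- stats::quantile(values, probs = seq(0, 1,
                                            length.out = n_levels + 1L),
                        na.rm = TRUE)
  qs[1L] <- -Inf; qs[length(qs)] <- Inf
  as.integer(cut(values, breaks = unique(qs), labels = FALSE,
                 include.lowest = TRUE)) - 1L
}

#' Emit a reference FASTA matching simulated site coordinates
#'
#' Builds one DNA sequence per scaffold with the 4-mer CCGG planted at
#' exactly the simulated site positions and nowhere else, so that
#' [find_ccgg_sites()] on the emitted reference recovers the simulated
#' coordinates.
#'
#' @param truth Truth bundle from [simulate_cross()].
#' @param path Optional FASTA output path.
#' @return A \code{Biostrings::DNAStringSet} (invisibly written to
#'   \code{path} when given).
#' @export
sim_reference <- function(truth, path = NULL) {
  set.seed(truth$cfg$seed + 3L)
  seqs <- vapply(names(truth$scaffold_lengths), function(sc) {
    pos <- truth$sites$position[truth$sites$scaffold == sc]
    len <- truth$scaffold_lengths[[sc]]
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))
    s <- paste(chars, collapse = "")
    for (p in pos) substr(s, p + 1L, p + 4L) <- "CCGG"
    ## scrub accidental CCGGs outside the planted positions
    repeat {
      hits <- gregexpr("CCGG", s, fixed = TRUE)[[1L]]
      hits <- hits[hits > 0L] - 1L
      extra <- setdiff(hits, pos)
      if (length(extra) == 0L) break
      for (e in extra) {
        ## an accidental occurrence cannot overlap a planted one entirely;
        ## flip its first base not inside a planted CCGG
        off <- setdiff(e + 0:3, unlist(lapply(pos, `+`, 0:3)))[1L]
        substr(s, off + 1L, off + 1L) <- "A"
      }
    }
    s
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(truth$scaffold_lengths)
  if (!is.null(path)) Biostrings::writeXStringSet(dna, path)
  invisible(dna)
}
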