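---
title: "Methods: dual-enzyme CCGG methylation typing and epigenetic QTL mapping"
author: "msapqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-enzyme CCGG methylation typing and epigenetic QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapqtl)
```

## The measurement model

msapqtl analyses methylation-sensitive dual restriction-enzyme sequencing
of CCGG sites, the MSAP idea carried to sequencing depth. The isoschizomers
HpaII and MspI both recognise CCGG but differ in methylation sensitivity:
HpaII cuts only the unmethylated or hemi-methylated (external cytosine on
one strand) site, while MspI tolerates internal-cytosine methylation but
not external. Sequencing an EcoRI–HpaII and an EcoRI–MspI library per
sample therefore encodes the methylation state of every CCGG site in a
cleavage/body read pattern:

| state | HpaII cleavage | MspI cleavage | HpaII body | MspI body |
|---|---|---|---|---|
| unmethylated | yes | yes | – | – |
| hemi-mCCGG | yes | no | – | yes |
| full CmCGG (internal) | no | yes | yes | – |
| full mCCGG (external) | no | no | yes | yes |

A read is *cleavage* evidence when its alignment starts or ends exactly at
the cut position C^CGG (one base after the first C, the enzymes' canonical
cut), and *body* evidence when
it spans the whole 4-mer internally. Coordinates are 0-based half-open
throughout the package; emitted BED is 0-based half-open and GFF3 import
converts from 1-based inclusive.

`call_site_state()` requires at least 4 reads in total and at least 2 per
enzyme library; below that a site is `no_call`. The callable patterns are
the four rows above with a 2-read floor on each required category and an
exact-zero requirement on the forbidden cleavage categories. The read
threshold is usually stated in this protocol family as more-than-4 reads
alongside a 2-per-enzyme minimum; since 2 + 2 = 4, a strict more-than-4
reading contradicts the minima, so the total-at-least-4 reading is
adopted. Any pattern matching none of the four rows is conservatively
`no_call`, not unmethylated.

## Population summaries

`summarize_population()` keeps a site only when an *identical* methylated
state recurs in at least `min_methylated_samples` (default 2) samples.
A looser rule — any methylated state in at least two samples — would also
suppress singletons; the stricter identical-state reading was chosen
because it is additionally robust to two unrelated artefacts at one site. Retained sites are classed
`hemi` or `full` when the respective fraction of methylated samples
exceeds 2/3 (the two full states pool into `full`), else `mixed`; a site
is monomorphic when every called sample shares one state and polymorphic
otherwise. These two dichotomies partition the retained sites, which the
test suite asserts.

## Inheritance classes

Sites observed in the two parents and the F1 progeny are grouped into
twelve heritability classes (A1–A2, B1–B4, C1–C2, D1–D4) from the parental
pattern (identical hemi, identical full, both unmethylated, disparate) and
the F1 pattern (uniform parental state, segregating, novel state, absent).
Only the A/B/C/D structure of this scheme is fixed by convention — A =
faithfully inherited, B = departures from a shared parental state, C = de
novo gains from unmethylated parents, D = parentally disparate sites with
D2–D4 typically the largest classes. The numbered subdivision within each
letter is not standardised, so the default table in
`default_class_table()` is a declared stand-in consistent with those
constraints, and it is an explicit argument everywhere so a user with an
authoritative table can swap it in.
Pattern precedence when classifying F1 states is absent → uniform-parental
→ segregating → novel; a mixed de novo C-group site is typed C2 when any
full state is present.

The simulator draws sites from the same table (one shared source of
truth), so the classifier's recovery of generating classes is an exact
round-trip property rather than a statistical one.

## Landscape statistics

The region methylation level of a bin is read-weighted: the sum over
methylated CCGG sites of their reads from methylated fragments, divided by
the sum over all CCGG sites of all their reads. "Reads from methylated
fragments" are the evidence categories consistent with the called state.
Gene metaprofiles average a per-base depth signal over genes in a
normalised coordinate system: 80 proportional windows across the body and
20 fixed 100-bp windows per 2-kb flank (flanks are windowed separately
from the body, the standard metaplot convention). Minus-strand genes are reversed so
profiles read 5′→3′. Context proportions report the share of methylated
calls in each of CmCGG-full, mCCGG-hemi and mCCGG-full, overall and
restricted to gene bodies plus 2-kb promoters.

## DMR scan

`scan_dmrs()` tiles the genome into non-overlapping windows (1000 bp by
default; neither the width nor a sliding step is a published constant, so
both are configurable) and compares two call sets site by site with hemi
and full collapsed to a binary methylated status. A window is testable at
≥ 5 differing sites and significant at chi-squared p ≤ 0.05 on the 2×2
(methylated, unmethylated) × (condition) table. The chi-squared is
computed without continuity correction; when any expected count falls
below 5 the p-value comes from Fisher's exact test instead, because small
windows with few sites are the common case. The scan is symmetric in its
two arguments. DMR–DEG intersection maps windows onto gene bodies and
2-kb promoters and keeps genes passing the upstream differential-expression
FDR gate (< 0.001); a window spanning both compartments is reported as
`body`.

## Phenotype indices

The cold-tolerance and recovery indices summarise per-plant ordinal levels
as `100 · Σ(level·n) / (max·Σn)`. The weighted-mean-over-max form is
adopted as the standard phenology index: it is bounded on [0, 100] and
uses exactly the quantities the trait protocols define (a per-plant level
and a count per level); where published definitions of these indices are
incomplete, this form is a declared interpretive choice. Greenhouse
recovery levels run 1–4
and are shifted to 0–3 before weighting so the index still spans the full
range; both choices are deliberately interpretive and flagged here. Leaf
fall is `100·NLF/NL`, dry weight `100·w2/w1` with the 200-g fresh-sample
protocol default, relative yield a plain ratio, and starch is converted
from a dry- to a fresh-weight basis via the dry-weight percentage. Yield
and root-number measurements pass through unchanged.

## Association scans

Methylation genotypes are scored full = 1, hemi = 2/3, unmethylated = 0
(missing otherwise); the unit is irrelevant because the Pearson
correlation is scale invariant. `associate()` uses pairwise-complete
samples, requires an overlap of N ≥ 20, and computes
t = r·√((N−2)/(1−r²)) with a two-tailed p from the t distribution on N−2
degrees of freedom — the standard Pearson t-test (descriptions of this
scan sometimes state N−1 degrees of freedom; N−2 is the internally
consistent choice and is what is implemented). Significance is declared at p < 0.01 with no multiple-testing
correction, matching the emulated analysis; a site significant in at
least two distinct trials of one trait family is flagged repeatable.

Marker analysis types dominant markers from parental presence (lm×ll and
nn×np expect 1:1, hk×hk expects 3:1), and retains a marker when its read
support is ≥ 2, more than half the progeny have a non-missing call, and a
chi-squared goodness-of-fit test does not reject the expected ratio at
p < 0.01. The ">50% of individuals" rule is read as a call-rate filter:
under band-presence reading every 1:1 marker would hover at 50% presence
and half would fail at random, which is incompatible with retaining
true-ratio markers at ≈ 99%. Two-point linkage uses the direct
recombination-fraction estimate capped at 0.5 and the standard two-point
LOD, with grouping requiring rf < 0.4 and LOD above a configurable
threshold (default 1). A Fisher-exact independence pre-filter sometimes
listed in this protocol family has no well-defined contrast here and is
not implemented. The Kruskal–Wallis
scan calls the tie-corrected rank-sum test per marker on raw phenotypes at
a per-test α of 0.001, again without genome-wide correction; map ordering
and interval mapping are out of scope.

## The synthetic-data generator

`sim_config()` defaults describe the emulated study design: 186 F1 clones
plus two parents, mean read depth 5 per evidence category, dominant
markers at a 40/40/20 lm×ll / nn×np / hk×hk mix with 5% missing calls, and
inheritance classes restricted to A and D (the B and C classes were not
observed in the emulated population) with D2–D4 carrying the majority of
sites (frequencies A1 0.06, A2 0.24, D1 0.12, D2 0.28, D3 0.10, D4 0.20).
Fully methylated sites are the internal-cytosine variant with probability
0.67; together with the class recipes this reproduces the reported
methylated-call composition of roughly half CmCGG-full and a quarter each
hemi and mCCGG-full. The evidence noise rate defaults to 0.01, a
sequencing/assignment error of the order seen in reduced-representation
data.

Evidence generation inverts the calling rules: the two categories implied
by the true state receive Poisson reads floor-guarded at the 2-read
per-enzyme minimum, so a noiseless simulation is callable everywhere and
typing recovery is exactly 100% — the floor guard means depth is not a
mechanism for producing `no_call`s, and degradation is explored through
the per-read category-flip noise instead. Phenotypes are linear in the
methylation scores of planted effect sites plus Gaussian noise;
`quantile_levels()` discretises continuous scores onto the 0–4 level
scales where a level-based index is wanted.

What the generator does *not* emulate: linkage disequilibrium between
sites or markers (draws are independent), sequence-context biases,
batch/depth heterogeneity between samples, and shared environmental
structure in phenotypes. Passing tests therefore demonstrate correctness
of the statistical machinery under the declared model, not performance on
real populations with correlated sites and structured noise.

## Verification design and problem sizes

The package's checks run at sizes chosen to keep the full suite fast while
leaving no statistical property under-powered: the calling truth table is
exhaustive (625 evidence vectors); the noiseless round trip uses 2,000
sites × 52 samples (and 186 F1 in the acceptance script); null calibration
of the association scan uses 10,000 independent sites at N = 186, with the
observed significant fraction required to sit within three Monte-Carlo
standard errors of the nominal 0.01; the power study plants effects of
β ∈ {0.1, 0.25, 0.5, 1} at noise sd 1 on full/absent segregating sites
(score 1 vs 0, the strongest-contrast class) over 20 replicates, requiring
monotone detection and the β = 1 site to top its scan in every replicate;
segregation-filter calibration simulates 5,000 markers each at true 1:1
and 3:1 with n = 186. Fixed seeds make every stochastic check
reproducible.

## Known limitations

* The twelve-class table and the four level-index formulas are declared
  stand-ins where the source is incomplete; both are swappable.
* The DMR window geometry (width, tiling) is a configuration choice, not
  a published constant.
* `extract_evidence()` classifies by alignment coordinates only; it does
  not model soft-clipped cleavage ends or re-digestion.
* No multiple-testing correction is applied in either scan, by design
  fidelity; users wanting FDR control can apply `p.adjust` to the result
  tables.
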