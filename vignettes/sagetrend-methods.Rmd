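---
title: "Methods: tag filtering, exact count tests and trend clustering in sagetrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag filtering, exact count tests and trend clustering in sagetrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagetrend)
```

`sagetrend` analyses LongSAGE progression atlases: nine tag-count libraries
laid out as three biological replicates crossed with three disease stages
(androgen-sensitive, AS; responsive to androgen deprivation, RAD;
castration-recurrent, CR). This vignette documents the statistical models,
the conventions the package commits to where the field leaves room, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## The filter cascade and its accounting

A LongSAGE ditag read is `CATG + tag1 + revcomp(tag2) + CATG`; extraction
reads the first tag 5'→3' and reverse-complements the second, and the exact
ditag sequence is kept for duplicate counting. Filtering proceeds in three
stages, each per observation and independent of the others (so the filters
commute):

1. **Bad tags** — any tag containing at least one `N` base call is removed.
   The rule is "≥ 1 N" rather than "exactly one": an ambiguous call makes a
   17-mer unusable regardless of how many positions are affected.
2. **Quality factor** — `QF = prod(1 - 10^(-Q_i/10))` over the 17 per-base
   Phred scores is the probability that the whole tag was called correctly;
   tags with `QF < 0.95` are removed. This is the standard Phred semantics
   for a tag-level quality; the threshold is the conventional 95%.
3. **Linker-derived tags (LDTs)** — linkers occasionally self-ligate,
   producing ditags of linker sequence; such tags are removed by exact
   match against two user-supplied sequence sets ("type I" and "type II").
   The two sequences are configuration, not constants: the artifact classes
   are standard but their sequences are protocol-specific.

Duplicate ditags (occurrences of a ditag sequence beyond the first) are
**counted but not removed**. This is deliberate: the composition identities

```
total_minus_bad = unfiltered_total − n_bad
total_q95       = total_minus_bad − n_below_qf
final_total     = total_q95 − n_ldt_type1 − n_ldt_type2
```

only balance when duplicates remain in the totals, and the duplicate
percentage divides the *ditag* count by the post-bad-tag *tag* total — the
only arithmetic consistent with published composition tables. A removal
mode is not offered at the count level; callers who want unique-ditag
counting can deduplicate the ledger themselves.

## The exact count test

For a tag with count `x` in a library of size `N1` and `y` in a library of
size `N2`, the Audic–Claverie statistic conditions on `x` and evaluates `y`
under

\[ P(y \mid x) = \frac{(N_2/N_1)^y \,(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}, \]

a negative-binomial distribution with size `x + 1` and success probability
`N1/(N1+N2)`. All terms are accumulated in log space via `lgamma`; the
upper tail is summed forward in chunks until the remaining terms are below
1e−18 of the accumulated mass — never computed as `1 − lower`, which would
lose tails below ~1e−16 to floating-point cancellation.

Two conventions needed deciding, because the conditional test leaves them
open:

* **Two-sidedness.** The package uses the minimum-likelihood convention:
  the p-value is the sum of `P(k | x)` over all outcomes no more probable
  than the observed `y`. Unlike tail-doubling, this gives p = 1 at the
  conditional mode, so equal evidence — in particular `x = y = 0` — is
  never significant at *any* library-size ratio. (Tail-doubling calls
  `(0, 0)` significant once `N2/N1` is large, because the point mass at the
  mode of a very skewed geometric is small; that is an artifact, not
  evidence.)
* **Symmetry.** Conditioning on `x` and conditioning on `y` are equally
  defensible, and the conditional test is not exchange-symmetric on its
  own. The reported p is the average of the two conditioning directions,
  which makes `p(x, y, N1, N2) = p(y, x, N2, N1)` hold exactly.

The combined test remains conservative: under a null simulation with both
counts Poisson at equal concentration (`N = 1e5`, 10⁴ trials) the measured
rejection rate at p ≤ 0.05 stays below 0.05 (the acceptance script reports
it). No multiple-testing correction is applied by default, matching the
raw-threshold design at p ≤ 0.05 / 0.01 / 0.001; the cross-replicate
consistency rule (same direction, significant in *all* replicates) is the
error control actually used. Ties in direction (equal cpm) count as "none"
and are never consistent.

Trend labels are assigned per replicate from the signed significance
pattern of the two progression steps (AS→RAD, RAD→CR), refined by the net
AS→CR call, through the rule table returned by `trend_rules()` — a
configurable table because the letter taxonomy is presentation, not
statistics. The major groups follow the five-trend rule: both steps up (or
one step up with a net rise) is group 1; the mirror is group 2;
up-then-down is group 3 (peak at RAD); down-then-up is group 5 (valley);
everything else is group 4 (constant).

## Poisson-deviance K-means and consensus

Counts, not proportions, carry the information in SAGE: a 60/20/20 split of
15 tags and of 1500 tags are very different pieces of evidence. The
clustering distance is therefore the Poisson deviance of the count triple
`x` against stage means `lambda_j = sum(x) * c_j` for a centroid profile
`c`:

\[ d(x, c) = \sum_j \left( \lambda_j - x_j + x_j \log \frac{x_j}{\lambda_j} \right), \qquad 0 \log 0 := 0. \]

The maximum-likelihood centroid of a cluster is its summed member counts,
normalised — exactly the update used in the Lloyd alternation, so the
within-cluster dispersion is non-increasing by construction. Centroid
entries are floored at 1e−9 (then renormalised) so an empty stage never
produces `log 0`; emptied clusters are re-seeded with the worst-fit
profile. The exact distance of the original SAGE-specific algorithm lives
in its own publication; the deviance form here is the canonical
Poisson-model K-means objective, and `poissonc_fit()` is the documented
seam where a variant distance could be substituted.

Tags enter clustering when their summed count over the three stage
libraries exceeds 10 *and* they map uniquely sense to a transcript — the
abundance filter keeps profiles whose shape is estimable, the mapping
filter keeps tags with a biological identity.

"Clustering over 100 iterations" is implemented as 100 independently
seeded random-restart fits whose labels are aligned by greedy
centroid-correlation matching against the lowest-dispersion run; each tag
receives its modal aligned cluster and a stability score (the modal
fraction). A same-run iteration reading was rejected: Lloyd iterations
converge deterministically, so repeating them changes nothing, while
restarts genuinely explore the initialisation space.

The dispersion-vs-K curve reports, per K, the best of several restarts plus
a *nested* candidate (the previous best solution with its worst-fit profile
split off as a new centroid), which makes the curve non-increasing in K.
The elbow suggestion is the maximum second difference of the curve **on the
log scale**: dispersion spans orders of magnitude, and the raw-scale second
difference of a convex curve always peaks at the smallest K, whereas the
log scale locates where the *relative* decline stalls — the visual
inflection a practitioner would pick. K remains the analyst's decision; the
curve only reports.

Amalgamation into the five major trends is a rule on centroid percentages
`(a, r, c)` with a tolerance `tau` of 5 percentage points: a middle-stage
value above both ends by more than `tau` is a peak (group 3), below both a
valley (group 5); otherwise the end-to-end difference decides up (1), down
(2) or constant (4). Five points is half the spacing that an
equal-thirds profile leaves between visually distinct trends; it absorbs
sampling jitter without swallowing genuine monotone changes.

## Enrichment

Each cluster is contrasted against the rest of the clustered genes of the
same replicate in a 2×2 table per annotation term; genes are deduplicated
within a cluster (a two-tag gene counts once) and unannotated genes stay in
the margins. The Fisher score is the one-tailed hypergeometric upper tail
`P(X ≥ a)`; the EASE score recomputes that tail with `a` replaced by
`max(a − 1, 0)`, margins unchanged — a jackknife that penalises categories
carried by a single gene (one in-category member scores exactly 1). EASE
p ≥ Fisher p on every table. Replicate consensus counts, for each
(major group, term), the replicates in which the term is enriched at
EASE p ≤ 0.05; no multiple-testing correction, matching the threshold
design, with term pooling available through a user-supplied term→category
map. GO-graph propagation is out of scope: annotation semantics live
entirely in the input table.

## Library trees and signature projection

Library relatedness uses Pearson correlation over the union tag set with
absent tags counted as zero — raw counts by default (the correlation is
dominated by abundant tags either way; a cpm option exists), distance
`1 − r`. The topology comes from neighbour joining and branch lengths from
nonnegative least squares against the distance matrix (via `ape` and
`phangorn`); at nine leaves with clean data this coincides with a full
least-squares topology search, and the output is standard Newick. For an
unrooted tree, "the three same-stage libraries form a clade" is tested as
the existence of the corresponding bipartition.

PCA centers genes (no variance scaling by default — scaling is an option,
not an assumption) and decomposes by SVD; component signs are fixed by
making each component's largest-magnitude loading positive, so results are
deterministic across platforms. A sample's score on a component is the
plain Pearson correlation between its gene vector and the loading vector
("standard correlation" scoring), hence bounded in [−1, 1]. Group
separation after restricting to a gene signature is summarised by the mean
silhouette width in the top-3 score space plus the agreement of an
unsupervised 2-means partition with the labels — a testable surrogate for
"the groups separate in the projection".

## The synthetic atlas: what it emulates, and what it does not

The generator plants, per tag, one of eleven stage-weight patterns
amalgamated into the five major trends; the canonical patterns use relative
weights `1 : sqrt(e) : e` (and permutations) where `e` is the fold change
`effect_size`. Baseline abundances are log-normal (`sdlog = 1`), biological
replication adds mild per-(tag, replicate) log-normal noise
(`sdlog = 0.05`), and counts are drawn multinomially conditioned on an
exact library size, so composition accounting is integer-exact (a
pure-Poisson mode exists). The default trend mix (0.10 / 0.10 / 0.05 /
0.70 / 0.05) keeps most tags constant with balanced up/down regulation, so
the fixed-total constraint does not systematically tilt constant tags.
Contaminants are injected at configurable fractions with full ground truth:
N-base calls (0.3% of tags), low-QF tags (20%), linker-derived ditags
(6×10⁻⁴), duplicate ditags (4%) — ratios in the range observed in deep
LongSAGE libraries. Mapping classes and a five-term planted annotation
signal complete the atlas.

Validation sizes are chosen to exercise the statistics at realistic depth
while keeping runs short: planted-change recovery uses 2000 tag types at
50 000 tags per library (mean depth ~25, the regime where the exact test's
discreteness matters); clustering recovery uses 500 tag types at the same
library size. The latter is an identifiability decision, not a
convenience: with the combined-count > 10 filter, profiles summing to a few
dozen counts are not assignable to their trend group *by any method* — a
Bayes-optimal classifier given the true group profiles misassigns the same
low-count tags the clustering does — so a "well-separated groups" test
needs tags whose summed depth (here ~300) makes the groups actually
separable. The tree check uses a trend-rich mix (0.25 / 0.25 / 0.15 /
0.20 / 0.15), since stage clades are a claim about strong stage effects.

What passing these tests does **not** show about real data: the generator
draws independent tags (no shared transcripts, no sequence-composition
biases), its noise is exactly Poisson/multinomial (no overdispersion beyond
the mild replicate jitter), quality scores are clean two-regime Phred
draws, and the annotation signal is planted directly on trend groups.
Real libraries are overdispersed, their tag spectra heavier-tailed, their
artifacts correlated; results on the atlas bound what the pipeline can do
under its own model assumptions, nothing more.

## Degenerate inputs and tie-breaking

Reads shorter than 34 usable bases are skipped and counted, not fatal;
transcripts without a `CATG` site contribute no tag and are listed;
constant library vectors make `1 − r` undefined and raise an error naming
the library, as do constant sample vectors in correlation scoring.
Assignment ties in K-means break to the first (lowest-index) centroid;
modal-consensus ties break to the smallest cluster id. All randomness —
generator, restarts, consensus — derives from explicit seeds, and every
pipeline output records the parameters that produced it in a JSON
manifest.

## Known limitations

* The funnel's published marginal counts are reproduced from a synthetic
  map matching the printed class totals; per-tag identities of the original
  study are not all printed and are not reconstructed.
* Consistency counts on the published libraries themselves would require
  the deposited raw data; the package validates the rule's properties
  (threshold monotonicity, planted recovery) instead.
* The trend-label letters are a configurable taxonomy, not a canonical
  standard; only the five major groups carry cross-study meaning.
* EASE here modifies only the success count `a`; implementations that also
  shrink the list total give slightly different (still conservative)
  values.
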