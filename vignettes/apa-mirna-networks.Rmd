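---
title: "Binding-site avoidance by alternative polyadenylation and feed-forward loop scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site avoidance by alternative polyadenylation and feed-forward loop scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `apamirnet`, their
assumptions, the tunable parameters, the numerical conventions, and
the design decisions taken where the methodology was genuinely open.
It states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` compute themselves.

## 1. The problem

Alternative polyadenylation (APA) produces mRNA isoforms of the same
gene with 3'UTRs of different lengths. MicroRNA-binding sites are
concentrated in the 3'UTR, so preferential use of a proximal
cleavage site removes the distal part of the UTR — and any binding
sites in it — from the expressed transcripts. A cell population can
thereby escape ("avoid") regulation by specific microRNA families
without changing gene-level expression. The package asks two
questions per cell cluster:

1. Which microRNA families lose significantly more binding-site
   expression mass to APA in this cluster than expected under random
   cell-to-cluster assignment?
2. Which microRNA–TF–gene feed-forward loops are significantly
   coherent in this cluster, and which of them involve a family that
   is also avoided there?

## 2. Coordinates and the site-fate rule

All coordinates are mRNA-sense and 3'UTR-relative; genomic strand
handling belongs upstream. Binding sites are 0-based half-open
intervals `[start, end)`. A polyA-site isoform is described by its
`cleavage_pos`, the number of 3'UTR bases it retains. The fate rule
is:

> a site is **retained** on an isoform iff `end <= cleavage_pos`,
> otherwise **lost**.

A site truncated by even one base is counted as lost, because a
partial seed match is not expected to function. The boundary is
deliberately sharp and testable: `(150, 157)` against cleavage 157 is
retained, against 156 lost.

Only genes with at least two annotated polyA sites enter the
avoidance statistic: a single-site gene has no alternative isoform,
so "loss due to APA" is undefined for it.

## 3. The avoidance statistic and its permutation test

For cluster *c* and family *f*, over all eligible genes *g*, isoforms
*i* of *g*, sites *b* of *f* in *g*, and cells of *c*:

- **weighted mode (default):** the isoform's summed expression in the
  cluster is added to `L` if the site is lost on that isoform, else to
  `R`. This weights site loss by how much the cell population actually
  uses the truncating isoforms.
- **binary mode:** each isoform contributes 1 instead, if it is
  "used" in the cluster (detected in at least `binary_used_frac = 5%`
  of the cells), 0 otherwise. This counts site fates per used isoform
  and ignores expression magnitude.

Both are offered because "total binding sites lost versus retained"
admits either reading; weighted is the default and the mode all
calibration experiments use.

The test statistic is the lost fraction `S = L / (L + R)`, a strictly
monotone transformation of the ratio `L / R` (via `x / (1 - x)`), so
orderings — and hence permutation p-values — are identical, while
fully-lost families (`R = 0`) remain finite.

**Eligibility and testability.** Eligible genes are the multi-polyA
genes whose gene-level APA expression is detected in at least
`min_expr_frac = 10%` of the focal cluster's cells, evaluated once
under the observed labeling and held fixed across permutations (under
the exchangeable null the filter is label-independent in
distribution). A family is *testable* only if it has at least one
**APA-sensitive** site on an eligible gene — a site retained on some
isoform and lost on another of the same gene. Families without such a
site (e.g. all sites upstream of every cleavage site) have a
statistic that cannot respond to isoform choice; their permutation
distribution is degenerate and they are excluded from testing and
from the BH family count.

**Permutation design.** Cluster labels are shuffled across all cells
with every cluster's size preserved; the statistic is recomputed on
the permuted focal set; the default p-value is the add-one-smoothed

```
p = (1 + #{S_perm >= S_obs}) / (B + 1)
```

with `B = n_permutations` (default 10,000). The smoothed, ties-count
estimator never returns 0 and is exactly uniform on its support under
exchangeability. The literal estimator `#{S_perm > S_obs} / B` is
available via `smooth_permutation_p = FALSE` for strict procedural
fidelity; it returns 0 for statistics larger than every permuted
value, which is degenerate for constant statistics.

Each family draws its own independent permutation substream. Reusing
one set of shuffles for all families (the procedurally simpler
alternative) leaves every family's marginal p-value unchanged but
correlates them strongly, which inflates the variance of the *number*
of families called significant; independent substreams restore the
near-binomial behavior that calibration checks (and a reader of the
per-cluster significant-family counts) expect. BH correction is
applied within each cluster across its testable families — the
natural unit at which per-cluster family counts are reported.

**Seeds.** All substreams derive from one root seed by a
deterministic string hash keyed by the *content* of the focal
cluster's cell set (not its label), so results are independent of
cluster processing order and invariant under renaming clusters.

## 4. Differential expression plumbing

Node scores only require a table of BH-adjusted p-values per gene and
cluster. The built-in `wilcoxon_de()` computes a two-sided Wilcoxon
rank-sum test of each gene, cluster vs all other cells
(`stats::wilcox.test`: exact for small tie-free groups, normal
approximation otherwise; constant genes get p = 1), BH-adjusted
across the cluster's tested genes. Any other DE method can be
substituted as long as it produces the same table shape.
"Expressed" means a value strictly greater than zero; the 10%
prevalence threshold is configurable.

## 5. Feed-forward loops

From the four directed interaction kinds (miRNA→gene, miRNA→TF,
TF→gene, TF→miRNA), every triple (m, t, g) with `m→g`, `t→g` and at
least one cross edge is emitted exactly once, classified as
`mirna_centric` (only `m→t`), `tf_centric` (only `t→m`) or `feedback`
(both). The enumeration is join-based and verified against a cubic
brute-force scan. Output order is lexicographic in (m, t, g)
everywhere, for diffable files.

The expression filter keeps a loop iff its TF and gene pass the
cluster's 10% prevalence filter; a miRNA with an expression row must
pass too, but a miRNA absent from the matrix entirely is exempt —
scoring will simply drop its terms (small-RNA capture is the known
blind spot of standard single-cell protocols, and discarding every
loop with an uncaptured miRNA would empty the analysis).

**Scoring.** With `n` the focal cluster's size:

- node score: `qnorm(1 - p_adj)`, p clipped to `[1e-12, 1 - 1e-12]`;
  smaller adjusted p (stronger DE in either direction) gives a larger
  score. The DE sign is deliberately ignored — only adjusted
  p-values enter.
- edge score: Pearson correlation `r` of the two nodes'
  log-normalized values (`log1p` of library-size-scaled counts)
  over the cluster's cells, transformed to `|atanh(r)| * sqrt(n - 3)`
  with `r` clipped to `±(1 - 1e-7)`. The absolute value treats
  repression and activation as equally coherent; `signed_edges = TRUE`
  keeps the sign. Zero-variance vectors score 0 with a warning.
- overall score: the arithmetic mean of the available node and edge
  scores. A feedback loop contains both `m→t` and `t→m`, so the m–t
  correlation term is counted once per directed edge. If the miRNA
  has no expression row, its node score and all its incident edge
  scores are omitted; the TF node, gene node and TF→gene edge must
  always remain, otherwise the loop is unscorable.

**Significance.** Each candidate loop is compared against `B` random
triples — one miRNA, one TF, one gene drawn uniformly with
replacement from the cluster's candidate pools (expression-filtered;
expression-less miRNAs included) — scored under the observed loop's
edge-presence pattern and the same absent-miRNA drop rules, so
observed and null scores average comparable terms (random triples
generally have no edges in the graph, so a pattern must be imposed).
The p-value uses the same smoothed estimator as above (literal
`#{>=}/B` behind the flag), followed by BH across the cluster's
candidates. Significant loops sharing a center merge into MFFLs:
miRNA-centric loops group by miRNA, TF-centric by TF, and feedback
loops — which have two centers — join both groups; this loses no
information and sidesteps an arbitrary tie-break. Modules are finally
flagged when their center family (or any member family, reported
separately) is significantly avoided in the same cluster.

## 6. The synthetic-data generator

The generator emulates the statistical structure the analysis relies
on, with full ground truth:

- **Totals:** per-gene counts are negative binomial
  (`nb_mean = 2`, dispersion size `nb_dispersion = 2`), with per-gene
  means drawn log-normally (`sdlog = 0.5`) around `nb_mean` — a
  deliberately simple model with single-cell-like overdispersion.
- **Isoform usage:** `round(frac_multi_apa * n_genes)` genes (default
  16.6%) get 2–4 cleavage positions at least 50 nt apart; each
  multi-site gene's usage vector is Dirichlet(2, ..., 2), shared by
  all cells, and each cell's total is split across isoforms by
  binomial thinning, so isoform sums equal gene expression *exactly*.
- **Planted avoidance** (cluster, family, delta): usage mass `delta`
  of the affected genes moves to the most proximal site in that
  cluster; `delta = 1` zeroes all distal isoforms. Affected genes are
  multi-APA genes *free of any other family's APA-sensitive sites*,
  chosen disjointly across planted families. This matters: a usage
  shift changes the lost/retained balance of **every** family with
  sensitive sites on the shifted genes, so without the free-gene rule
  "unplanted" families are not null and recovery experiments are
  confounded. Sites that are not APA-sensitive are unaffected by
  usage shifts, so the planted effect is exactly attributable.
- **Planted loops** (cluster, m, t, g, rho, de_effect): the three
  edges are force-inserted, the three nodes' counts in the named
  cluster become Poisson-log-normal with a shared standard-normal
  latent factor weighted by `sqrt(rho)` (target pairwise correlation
  `rho` on the log scale; the realized correlation of log counts is
  attenuated by Poisson noise and is recorded as a target, not a
  value), and their means shift by `exp(de_effect)`.
- **miRNA expression** is simulated as ordinary rows named by family;
  `mirna_expression = FALSE` blanks them to exercise the drop rules.
- An optional Gaussian cluster-blob embedding supports the centroid
  distance summary.

By default there is **no** cluster effect on unplanted genes: the
unplanted configuration is fully exchangeable across cells, which is
exactly the regime in which a label-permutation p-value is uniform,
and is what the calibration experiments require. Real data are not
exchangeable — strong compositional differences between clusters can
shift lost/retained balances for reasons other than APA regulation —
so calibration on this generator validates the machinery, not the
biology of any particular dataset. Also not emulated: doublets,
ambient RNA, batch effects, UMI saturation, and read-level noise.

## 7. Numerical conventions and degenerate inputs

- Clips: adjusted p at `1e-12`, correlation at `1 - 1e-7`; both fixed
  constants, documented here.
- Ties in permutation tests count against the observed value
  (`>=`), the conservative direction.
- `L + R = 0` or no APA-sensitive site: family reported, `p = NA`,
  excluded from BH.
- Zero-variance expression: edge score 0 with a warning; constant
  genes: Wilcoxon p = 1.
- Permuted subsets with zero total mass (possible only in pathological
  inputs) count as ties.
- All counts are integer-valued and all RNG uses R's default
  Mersenne-Twister under derived seeds, so identical configuration
  and seed give bit-identical matrices and result files across
  platforms.

## 8. Validation experiment sizes

The test suite and the acceptance script validate the machinery at
desk scale, chosen so each experiment carries enough resolution for
its check: null calibration of the avoidance test on 2 clusters × 200
cells with 600 families (over 1,000 testable family × cluster pairs;
B = 1,000); power on 20 replicates of 10 planted pairs
(`delta = 0.8`, B = 2,000, 100 families, 1,200 genes); SFFL null
calibration on a graph yielding over 1,000 candidate loops
(B = 1,000) and recovery on 20 replicates of 3 planted loops
(`rho = 0.9`, `de_effect = 1.5`, B = 2,000); exhaustive-enumeration
oracles on toy instances. The Kolmogorov–Smirnov distance of an
*n*-sample to uniform concentrates around `0.83 / sqrt(n)`, which is
why the calibration experiments use four-digit pair counts for a 0.05
bound.

## 9. Known limitations

- The avoidance test conditions on the observed clustering; it does
  not propagate clustering uncertainty.
- Eligibility (the 10% filter) is computed under the observed
  labeling and held fixed across permutations.
- The SFFL correlation matrices are precomputed per cluster over the
  candidate pools; for pools of tens of thousands of genes this is
  memory-heavy and would need chunking.
- Gain of sites through 3'UTR lengthening is not tested — the
  statistic is one-sided toward loss.
- The miRNA-exemption rule means loops whose miRNA is uncaptured are
  judged on TF–gene evidence alone; modules aggregate such loops
  rather than resolving the missing evidence.
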