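---
title: "Methods: mechanism-of-action deconvolution with moadecon"
author: "moadecon authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanism-of-action deconvolution with moadecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moadecon)
```

# The problem

A small molecule changes a cellular phenotype, and transcriptomics of
treated versus vehicle cultures over several timepoints records the
downstream consequences. `moadecon` asks which upstream molecular events
best explain those consequences, using three largely independent lines of
evidence:

1. **network evidence** — which protein, if activated or inhibited, would
   propagate through a signed interaction network to produce the observed
   up/down pattern;
2. **pathway evidence** — which curated gene sets are over-represented
   among the differentially expressed genes;
3. **chemical evidence** — which protein targets the compound's structure
   resembles known binders of.

A process supported by all three streams is a far stronger mechanistic
hypothesis than one supported by any single stream, which is the package's
organising principle.

# Differential expression

## Model and assumptions

Expression is analysed on the log2 scale, one gene at a time, with
ordinary least squares on the fully crossed design

$$y = \mu + \text{treatment} \times \text{DIV} \; (+\; \text{plate}) + \varepsilon$$

where DIV (days in vitro) is a factor and plate enters as a fixed covariate
whenever the design has more than one plate level. The reported effects are
the within-DIV treatment contrasts. Assumptions: Gaussian residuals with a
shared per-gene variance across cells, and a design with every
treatment × DIV cell occupied (violations raise errors; a rank-deficient
design reports the aliased terms by name).

A mixed model with plate as a random effect would be the natural
alternative when plates are many; with the two or three plates typical of
this experiment size, a fixed plate covariate is deterministic, solver-free
and equivalent for balanced designs, so the package always uses the fixed
form and records that in the fit metadata.

## Within-gene FWER: single-step max-|t|

Each gene carries a family of three contrasts (one per DIV). The adjusted
p-value of contrast $j$ is

$$p_j^{\text{FWER}} = P\!\left(\max_k |T_k| \ge |t_j|\right)$$

under the joint null, where $(T_1,\dots,T_K)$ follows the multivariate t
distribution implied by the contrast correlation matrix and the residual
degrees of freedom. Because the design — and hence the correlation
structure — is identical for every gene, the tail is estimated once by
Monte-Carlo (default 20,000 draws, seeded and logged) and shared across
genes. A studentized-range procedure would assume exchangeable pairwise
differences; max-|t| handles a general contrast set, reduces to it for
balanced families, and is the standard single-step choice for this
situation. The implementation agrees with the `mvtnorm` integration oracle
to Monte-Carlo accuracy (tested), adjusted p-values are clamped to be at
least the raw ones, and a family of one contrast passes through unchanged.
Requesting fewer than 1,000 draws is allowed but flagged in the run log.

## The p\* resolution rule

Across genes, multiplicity is controlled on the *per-gene minimum* FWER
p-value: the minima are BH-adjusted, and

$$p^\* = \max\{\, \min_j p^{\text{FWER}}_{gj} : q_g < 0.05 \,\}$$

A contrast anywhere in the table is significant iff its FWER p-value is
**at or below** p\*. The boundary is inclusive so that the gene that
defines p\* is itself significant — with a strict inequality the gene whose
minimum equals p\* would be excluded despite passing the FDR step, which
would be self-contradictory. When no gene passes the FDR step, p\* is
undefined (`NA`) and nothing is significant.

DEG selection applies |log2FC| ≥ 1.5 and adjusted p ≤ 0.05, both
boundaries inclusive.

## Quantile normalisation

`normalizeQuantile()` (via limma) forces every sample onto the row-wise
mean of the sorted columns; ties share the mean of their would-be
quantiles. It removes scalar sample-level shifts (such as the plate
effects the generator plants) but also slightly shrinks genuine
fold-changes when many genes move in one direction; with the perturbation
fractions used here the effect is negligible.

# Ortholog mapping

Measurements move between identifier namespaces by *expansion first, then
aggregation*: a source gene with several targets has its row duplicated
per target; several sources sharing a target are averaged (arithmetic mean
of log2FC **and of p-values**). Averaging p-values is statistically
improper — the mean of two valid p-values is not a valid p-value — but it
is the convention this pipeline family uses, so it is the default;
`combineP = "fisher"` offers a proper combination behind a flag. The
single-pass order (expand, then aggregate) also resolves the otherwise
unspecified case where a source both expands and shares a target with
another source. Unmapped identifiers are dropped and reported.

# Enrichment and overlap statistics

Over-representation is the one-sided hypergeometric upper tail with the
background fixed to *every measured gene* — the cell-type-specific
transcriptome — not the genome; using the genome as background would
manufacture enrichment for anything brain-expressed. Sets are intersected
with the background before testing, BH adjustment runs within a
collection, and significance is adjusted p ≤ 0.05.

The overlap coefficient between two pathway sets is
$|A \cap B| / \min(|A|,|B|)$, reported to two decimals; an empty input
makes the coefficient undefined, reported as 0 with a flag rather than an
error so that tabulations over many comparisons stay rectangular.

Disease-list overlap unions the scored lists, builds the 2×2 table over
the background, and reports the *sample* odds ratio (Haldane 0.5
correction only when a cell is zero) with the two-sided Fisher exact
p-value. Two-sided is the conservative default when the direction of
association is not pre-specified.

# TF and pathway activity

The gene statistic is log2FC gated at p ≤ 0.05 (non-significant genes
contribute exactly zero — the gate mirrors the significance convention
used throughout the pipeline). A TF's raw score is the regulon-sign
weighted sum of its targets' statistics; the normalised score (NES)
standardises against a null built from gene-label permutations (default
1,000, seeded). The NES is location-scale invariant to positive rescaling
of the statistics up to Monte-Carlo error. Regulons with no measured
target are omitted with a log entry; fewer than three measured targets
flags low confidence. Discretisation for causal reasoning maps
NES ≥ 1.96 → +1, NES ≤ −1.96 → −1, else 0, boundaries inclusive; 1.96 is
the two-sided 5% normal quantile, matching the p ≤ 0.05 convention. The
exact statistic used by external regulon-enrichment tools is not
reproduced here and no equivalence is claimed; any regulon table with
(tf, target, sign) rows can be supplied, including published ones.

# Causal reasoning

## Propagation

An hypothesis (protein $h$, sign $\sigma$) predicts the state of every
node reachable within path length $\Delta$: breadth-first shortest paths,
predicted state = $\sigma$ × product of edge signs along a shortest path.
If two equal-length shortest paths disagree, the node is *ambiguous* and
predicted 0 — the established convention for sign propagation on shortest
paths, preferable to arbitrarily trusting one path. Predictions at
$\Delta = k$ are a superset of those at $k-1$ with identical values where
both are defined (the implementation is checked against brute-force
enumeration of minimum-length simple paths on small graphs).

## Scoring and the permutation null

Over nodes with a nonzero prediction and nonzero observation, agreement
scores +1 and disagreement −1. Significance permutes the observed multiset
across all measured nodes: p = fraction of permutations with score at
least the observed one. With ≤ 8 measured nodes the null is enumerated
exactly (so small worked examples are deterministic); otherwise Monte-Carlo
with a fixed seed. `rankHypotheses()` evaluates every (protein, sign, Δ)
triple; all hypotheses at a given Δ share one seeded permutation ensemble,
which makes p-values comparable across hypotheses and keeps the
20-seed recovery suites tractable. Ranking is by score descending, ties by
p ascending then protein id, so output order is total and deterministic.

## Consensus, reconstruction, pooling

Consensus nodes are the (protein, sign) hypotheses significant at the
greatest number of Δ levels, ties all retained. Their subnetwork is the
union of *every* sign-concordant shortest path (≤ Δmax) from a consensus
node to each observed entity it explains; every edge comes from the source
network. Hypothesis sets from multiple setups (algorithm × network ×
condition) are pooled by recovery frequency; the default threshold is half
the number of setups, rounded up — "most frequently" made concrete —
and the pooled regulators can be displayed connected by the
prior-knowledge edges among them. Pooling is by protein, with the sign
retained in the frequency table, since different setups may disagree on
sign while agreeing on the protein.

# Ligand-based target prediction

Fingerprints are ECFP4-equivalent: circular substructures of radius 2
hashed to 2048 bits, computed by OpenBabel and OR-folded from its native
length. Different SMILES spellings of a molecule give identical bits
(tested); bit-level equality with other ECFP4 implementations is *not*
claimed, and similarity values can differ from other toolkits in the
second decimal.

The per-target predictor is a transparent similarity-weighted kNN rather
than pre-trained classifiers: at threshold $T$ a training compound is
active iff its activity ≤ $T$ µM (thresholds tighten from 100 to 0.1 µM),
and

$$P(\text{active}) = \frac{\sum_{i \in kNN} T_i y_i}{\sum_{i \in kNN} T_i}$$

over the $k = 5$ most similar training compounds with data for the target,
ties in similarity broken by compound id for determinism. The
applicability-domain percentile compares the query's mean similarity to
its $k$ nearest training compounds against the leave-self-out distribution
of the same statistic over the training set — a 0–100 score of how deep
inside the training chemistry the query sits. Nearest-neighbour
similarities are fully reproducible; probability values are a stand-in
with the same interface as classifier-based predictors, and no numerical
equivalence to any particular pre-trained model is claimed.

The two reference structures shipped in `inst/extdata/` for the
nearest-neighbour check were reconstructed from their published structural
descriptions relative to anle138b (see the file's README); they reproduce
the published ECFP4 Tanimoto similarities (0.50, 0.45) under an
independent fingerprint implementation to within rounding.

# Evidence integration

The reversal analysis classes genes significant in both the insult and
treatment signatures by sign pattern (reversed-up / reversed-down /
concordant), with single-signature genes kept as "single-sided".

The evidence matrix requires an *explicit process map* — named processes
with their member genes/targets and pathway ids — because assigning a
pathway or target to a biological process is a curation judgment, not a
computation; making the map a versioned input keeps the integration
reproducible and auditable. A process receives target-stream evidence when
a prediction passes probability ≥ 0.5 and applicability ≥ 50,
regulator-stream evidence when a pooled regulator maps to it, and
pathway-stream evidence when a significantly enriched set maps to it.
Ranking is by stream count, then total evidence volume, then label;
processes with evidence from at least one stream form the headline list
and those with two or more the consensus tier. Literature plausibility and
phenotype concordance remain human judgments and are deliberately not
computed.

# The synthetic-data generator

`simulateNetwork` draws distinct ordered node pairs uniformly (no
self-loops, no opposite-sign parallel edges), each inhibitory with a
configurable probability. `simulateExperiment` plants regulators whose
depth-2 downstream genes (regulator → TF → transcript, the chain the
analysis assumes; ambiguous-sign genes are left untouched) shift by
`effectSize` × (DIV / max DIV) in the treated arm — the linear-in-time
schedule reproduces the qualitative pattern of DEG counts growing with
time in culture, with no quantitative match to any particular dataset
attempted. Expression is generated directly as Gaussian log2 abundance
(baseline N(7, 1.5²)), because the pipeline consumes log2 summaries; a
count-level generator is out of scope. Plate effects are a single scalar
per plate, N(0, plateSd²).

Default study conditions: 2 treatments × DIV {3, 7, 14} × 3 replicates,
plates balanced with replicates; `effectSize = 2`, `noiseSd = 0.3`,
`plateSd = 0.2` — replicate-level variance and plate magnitude are not
published for the motivating experiment, so these are free parameters
chosen once at values a transcriptomics practitioner would call a strong,
clean in-vitro perturbation; they are deliberately not tuned.

What the generator does *not* emulate: count-level sampling noise and
mean–variance coupling, correlated co-expression modules,
batch-by-treatment confounding, incomplete or erroneous network prior
knowledge, and real chemistry in the bioactivity corpus (fingerprints
there are synthetic bit-vectors with controlled Tanimoto to the query).
Passing the planted-truth suites therefore demonstrates internal
correctness and calibration of the algorithms, not performance on real
data.

`simulateGenesets` plants enriched sets drawing 80% of members from the
perturbed genes; `simulateAnnotations` controls the ortholog-map
multiplicities, the disease-list odds ratio, regulons equal to the
network's signed edges, and the bioactivity corpus with planted actives on
one target among the high-similarity neighbours.

# Numerical choices and degenerate inputs

* Zero-noise limit: residuals at machine precision are clamped (standard
  errors below 1e-12 are treated as exact zeros; contrasts below 1e-8 in
  absolute value get t = 0, others t = ±∞) so the noiseless generative
  identity holds exactly instead of manufacturing spurious significance
  from 1e-16-scale residuals.
* Monte-Carlo p-values are plain fractions (no +1 smoothing), matching the
  exact-enumeration definition; exact and Monte-Carlo nulls agree within
  binomial error (tested).
* Empty query → all enrichment p = 1; empty set within background →
  p = 1; overlap coefficient of an empty set → 0 with `undefined = TRUE`;
  two empty fingerprints → Tanimoto 0 with a flag; observed states all
  zero → hypothesis score 0 with p = 1.
* All randomised procedures take explicit seeds, and every derived seed
  used by `runPipeline` is a small deterministic function of the master
  seed.

# Test problem sizes

The packaged suites run on deliberately small instances chosen to keep the
full test run in a couple of minutes while leaving the statistical checks
well-powered: networks of 30–120 nodes with mean out-degree 3, 150–500
genes, 18-sample designs, 20 seeds for recovery rates (causal top-1 ≥ 90%,
enrichment top-ranking ≥ 95%, end-to-end three-stream convergence ≥ 90%),
100 seeds for the global-null FDR check and 200 for the
independence-null odds-ratio check. Exhaustive oracles (hypergeometric
combinatorics, path enumeration, permutation enumeration) run on
backgrounds ≤ 30, graphs ≤ 12 nodes and supports ≤ 8, where exact
computation is feasible.

# Known limitations

* The factorial fit is OLS; no empirical-Bayes variance moderation, so
  power at very small replicate counts is below what moderated-t methods
  achieve.
* Averaged p-values after ortholog mapping (the default, for fidelity to
  the convention) are not valid p-values; switch on the Fisher option when
  downstream calibration matters.
* The kNN target predictor shares only its interface with
  classifier-based tools; probabilities are not comparable across corpora
  of different density.
* Causal reasoning assumes the signed network is correct and complete
  within Δmax; missing edges bias scores toward hubs with many measured
  descendants.
* The process map is curated input; the integration can only rank
  processes someone thought to define.
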