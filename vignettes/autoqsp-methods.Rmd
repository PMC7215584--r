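---
title: "Models and design choices in autoqsp"
author: "autoqsp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in autoqsp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`autoqsp` implements a quantitative systems pharmacology workflow for drug
catalogs annotated with a modulator category (activator / inhibitor /
dual-modulator) and a known drug–target edge list: matrix-factorization
prediction of novel interactions, structural and functional drug–drug
similarity, category-stratified pathway over-representation, and
bipartite-network promiscuity summaries. This vignette documents the
models, their tunable parameters, the synthetic-data generator used for
validation, and the design decisions taken where the design was genuinely
open. It states no empirical result that the package's test suite or
`scripts/acceptance.R` does not itself compute.

# The PMF interaction predictor

The known interactions between $N$ drugs and $M$ targets form a sparse
binary matrix $R$. `fit_pmf()` factorizes $R \approx U^\top V$ with
$U \in \mathbb{R}^{D\times N}$, $V \in \mathbb{R}^{D\times M}$ by
minimising

$$\sum_{(i,j)\in\mathrm{obs}} (R_{ij} - U_i\cdot V_j)^2
  + \lambda_u\|U\|^2 + \lambda_v\|V\|^2$$

with per-sample stochastic gradient descent. Interaction data are
positive-only: absence of an edge is not evidence of non-interaction. The
observed set therefore consists of the known positives (plus any explicit
negatives supplied to `build_matrix()`), augmented every epoch with
`neg_ratio` × (number of positives) unobserved cells drawn uniformly and
scored as soft zeros. Resampling the negatives each epoch avoids committing
to any fixed set of presumed non-interactions.

Parameters and defaults:

* `D = 50` — latent dimension. Suits database-scale matrices; for
  controlled experiments match the world's generative rank, or select by
  held-out AUC (`holdout_split()` + `evaluate_holdout()`).
* `learning_rate = 0.05`, `lambda_u = lambda_v = 0.05` — chosen by a
  multi-seed recovery sweep on matched-rank synthetic worlds; heavier
  regularisation than the classical 0.01 noticeably stabilises recovery on
  sparse worlds where each drug carries only a handful of positives.
* `epochs = 200`, with early stopping once the relative objective change
  stays below `tol = 1e-5` for `tol_window = 10` consecutive epochs.
* `neg_ratio = 1`; `init_sd = 0.1` (Gaussian factor initialisation).
* A non-finite epoch objective aborts with a message suggesting a smaller
  learning rate.

Fitting is deterministic given (matrix, hyperparameters, `seed`): the seed
drives initialisation, negative resampling and sample order.

**Confidence mapping.** The reconstruction $U_i\cdot V_j$ is clamped to
$[0,1]$ (`score_pairs()`); a raw, unclamped view is available with
`raw = TRUE`. Whether such confidences are calibrated probabilities or
merely normalized reconstruction values is a modelling convention, not
something the data decide; the clamp is the declared default because it
keeps the "reconstruction of a 0/1 matrix" reading literal. A logistic
mapping can be layered on the raw scores by users who prefer it.

**Selection rule.** `select_predictions()` keeps, per drug, unknown pairs
with confidence *strictly* greater than `threshold = 0.6` within the
`top_k = 40` highest-ranked candidates — the convention balancing
sensitivity against specificity in database-scale interaction prediction.
Ties are broken lexicographically by target id after confidence, making the
output deterministic; known pairs are never re-emitted.

# Drug–drug similarity

*Structural*: Tanimoto coefficient $|a\wedge b|/|a\vee b|$ between binary
fingerprints; the companion distance is $1-$similarity. "Tanimoto
distance" and "similarity below 0.5" are only jointly consistent when
distance means $1-$similarity, which is the reading adopted throughout.
Drugs without a usable fingerprint are excluded, not imputed. When only
SMILES are available, `fingerprint_from_smiles()` computes the OpenBabel
FP2 path-based 1024-bit 2D fingerprint through `ChemmineOB`; precomputed
fingerprints always take precedence, and the synthetic generator emits
fingerprints directly (no SMILES), so the chemistry backend is optional.

*Functional*: cosine distance $1 - (d_i\cdot d_j)/(|d_i||d_j|)$ between the
drugs' binary target-profile vectors over the known edges; the matrix
reports $1-$distance so both kinds are comparable similarity heatmaps.
Drugs with no known targets have an undefined profile norm and are
excluded with a logged count.

`heatmap_order()` returns the leaf order of average-linkage hierarchical
clustering on $1-$similarity (`stats::hclust`), which is the testable part
of a clustered heatmap; rendering is left to the user's plotting stack.

# Pathway over-representation

For a query target set of size $m$ against a collection over a universe of
$M$ targets, each set of size $K$ with overlap $k_0$ is scored by the
upper-tail hypergeometric probability

$$P \;=\; \sum_{k=k_0}^{\min(K,m)}
 \frac{\binom{K}{k}\binom{M-K}{m-k}}{\binom{M}{m}},$$

evaluated in log space via `stats::phyper` for numerical stability, with
the conventions $P=1$ for $k_0 \le 0$ and $P=0$ for $k_0>\min(K,m)$.
Benjamini–Hochberg step-up adjustment (`stats::p.adjust`) is applied across
*all* sets of the collection. The test suite cross-checks both against
independent references: exhaustive subset enumeration over the full
parameter grid $M \le 12$, and a hand-written step-up implementation on
random p-vectors.

**The universe is an explicit, mandatory input.** Over-representation
p-values are meaningless without a declared background, and reasonable
backgrounds (all genes, all annotated genes, all druggable targets) differ
substantially. `load_gene_sets()` takes the universe as an argument and
otherwise uses the union of all set members; query members outside the
universe are dropped with a logged count. A prose definition of $M$ as a
count of pathways rather than of universe members would be dimensionally
inconsistent with the formula above; the formula governs.

**Reporting conventions.** Two views are emitted, clearly labelled:
ranked-by-p tables (with `rank` assigned after sorting by p, ties broken
by set id) and a filtered view at raw $p<0.05$ (`significant_sets()`,
`adjusted = FALSE`), matching the two conventions commonly used for
pathway lists. FDR filtering uses `adjusted = TRUE`.

**Discreteness.** Hypergeometric p-values are discrete: the attainable
level closest below a nominal cutoff is generally smaller than the cutoff,
so under a true null the fraction of sets with $p<0.05$ falls slightly
short of 5% even for perfectly calibrated tests. The null-calibration test
therefore compares the observed rejection fraction against the *exact
attained level* of each test (computable from its $(K, m, M)$), within 3
binomial standard deviations, and additionally checks the fraction never
exceeds nominal 5% by more than 3 SD.

`enrich_by_category()` builds the query of category $c$ as the union of
targets of the drugs labelled $c$ — known edges by default, plus predicted
edges when requested — and also reports the pooled union query.

# Network summaries

The degree of a modulator is its number of connected targets; known and
predicted layers are always counted separately, and drug-side and
target-side totals both equal the edge count (an invariant under test).
Histogram bins default to $\{1, 2\text{–}4, 5\text{–}9, \ge 10\}$ (a
separate 0 bin appears when degree-0 drugs exist), separating single-target
drugs from highly promiscuous ones; the frequent-target threshold defaults
to $\ge 5$ known modulators. Both breakpoints are configuration, not
constants. Mean degrees are conventionally reported to one decimal place.
Each drug belongs to exactly one category — the dual-modulator class is a
distinct label, not a pair of memberships — which makes the 7-region
overlap partition of the three category target sets well defined.

`run_pipeline()` chains load → PMF fit → prediction selection → similarity
→ enrichment (known-only and known+predicted) → summaries, writes every
result table as TSV plus a plain-text manifest of inputs, hyperparameters,
seed and thresholds, and aborts with the stage name on failure. The
manifest deliberately contains no timestamps so that identical
configuration and seed yield a byte-identical output bundle.

# The synthetic-data generator

`generate_world()` produces worlds with known ground truth so that every
pipeline stage can be validated by planted-signal recovery rather than by
fixture files. The generative model, in full:

1. **Latent factors.** Per world, `n_drug_classes` (default 6) drug
   prototypes and `n_target_families` (default 8) target prototypes are
   drawn from $\mathcal N(0, I_D)$. Each drug/target picks a prototype
   uniformly and adds $\mathcal N(0, \texttt{class\_sd}^2 I)$ noise
   (default 0.1), normalised so factors keep unit marginal scale. Real
   chemogenomics matrices are block-structured — drugs cluster into
   chemotype/mechanism classes, targets into protein families — and this
   structure is what makes low-rank recovery from a handful of positives
   per drug statistically possible at all. Pilot experiments with pure
   i.i.d. Gaussian factors showed that even the Bayes-optimal ranking from
   the true factors cannot separate held-out positives well at realistic
   densities, and a maximum-likelihood fit initialised *at the true
   factors* drifts away from them: an i.i.d. world at ~1% density simply
   does not contain enough information per drug. The prototype mixture is
   therefore both the more realistic and the statistically meaningful
   choice.
2. **Observation link.** The score $s_{ij} = U_i\cdot V_j$ plus
   $\mathcal N(0, \texttt{noise\_sd}^2)$ noise (default 0.1) passes through
   a logistic link with temperature `link_scale` (default 0.25) and an
   intercept $b$ solved by `uniroot` so the expected edge count equals
   `density`·N·M:
   $$p_{ij} = \sigma\!\big((s_{ij}+\varepsilon_{ij})/\tau + b\big).$$
   Calibration happens in the link's natural-parameter space — an
   intercept, exactly as in logistic regression — rather than by
   multiplying $\sigma(s)$ by a constant. A multiplicative rescale maps
   every pair beyond the sigmoid's saturation onto one common rate,
   erasing the rank information among precisely the high-affinity pairs a
   predictor must learn to order. The temperature models the sharp
   thresholding of continuous binding affinity into a detected/undetected
   interaction.
3. **Categories** are sampled i.i.d. with the configured proportions
   (default 174:31:20 over 225, the composition of a curated autophagy
   modulator catalog).
4. **Fingerprints.** Bit $b$ of drug $i$ is Bernoulli with probability
   $\sigma(w_b\cdot U_i/\sqrt D)$ for fixed random projections $w_b$, so
   drugs with similar latent vectors share more bits (verified by a
   correlation test). Synthetic drugs carry fingerprints only — no
   attempt at valid SMILES or real chemistry.
5. **Pathway sets.** Each of `n_pathways` sets (default 294) draws a base
   membership probability uniformly from `pathway_prob_range` (default
   0.03–0.08) and includes each target independently. A *plant*
   `list(pathway, category, odds)` multiplies the membership probability
   by `odds` for targets that interact with drugs of that category in the
   world's edge set; a plant that would push a probability above 1 is
   rejected as infeasible. Unplanted sets are exchangeable with the query,
   so their p-values follow the exact hypergeometric null.

Every artifact is a pure function of (configuration, seed): the master
seed deterministically derives one sub-stream per stage (factors,
categories, edges, fingerprints, pathways), so stages can be re-sampled
independently. `write_world()` emits the standard TSV/GMT files, making a
synthetic world indistinguishable from real input at the interface level.

Default world dimensions (225 drugs, 993 targets, density 0.008, 294
pathway sets) mirror the curated-catalog scale; full-database worlds are
closer to 0.1% density and can be requested explicitly.

**What the generator does not emulate.** Real catalogs have non-random
missingness (heavily studied drugs accumulate edges), curation errors,
correlated pathway memberships, annotation-driven fingerprint similarity,
and target family labels tied to biology. Passing recovery tests on these
worlds therefore demonstrates correctness of the implementations and
identifiability under the stated generative assumptions — not performance
guarantees on any particular real database.

# Validation experiments and problem sizes

The test suite exercises each stage at fixed, documented scales:

* *Exact recovery*: a fully observed 6×8 rank-1 binary matrix (a
  thresholded outer product of bimodal factors) is reconstructed at
  correlation > 0.99 with $D=1$ and vanishing regularisation; the epoch
  objective is non-increasing within 1%.
* *Held-out recovery*: a 200×400 world of generative rank 5 at density
  0.01; 10% of positives held out; fit at $D=5$, 200 epochs,
  `neg_ratio = 1`. Held-out ranking AUC must reach 0.90, and a
  label-permuted control (same positive count scattered uniformly) must
  stay at chance (≤ 0.55).
* *Planted enrichment*: 50 replicate worlds of 300 drugs × 800 targets at
  density 0.02 with 50 sets (base membership 0.08–0.12) and an odds-3
  plant on the inhibitor category (planted set size ≥ 30 in every
  replicate); the planted set must reach BH-adjusted $p<0.01$ in ≥ 90% of
  replicates. 40 null worlds check calibration as described above and
  that ≥ 95% of them contain no FDR-significant set.
* *Oracle equality*: hypergeometric tail vs subset enumeration on the full
  $M\le 12$ grid (tolerance 1e-12); BH vs an independent step-up reference
  on 1000 random vectors; Tanimoto/cosine vs set-enumeration oracles on
  1000 random short fingerprints.
* *Determinism*: two `run_pipeline()` runs with one configuration and seed
  produce byte-identical output bundles.

These sizes keep the default suite near a minute of runtime while leaving
each experiment enough replicates for its stated bound.

# Known limitations

* The PMF confidence scale is a convention (clamped reconstruction), not a
  calibrated probability; thresholds tuned on one database do not
  automatically transfer.
* Squared-error PMF with implicit negatives is the implemented objective;
  Bayesian posterior sampling and side-information fusion (e.g. chemical
  similarity kernels) are out of scope.
* Identifiers are opaque case-sensitive strings; no gene-symbol
  normalisation or identifier mapping is attempted, and supplying
  mixed-convention inputs is the caller's responsibility.
* Enrichment p-values inherit the usual caveats of over-representation
  analysis: they condition on the universe choice and ignore dependence
  between overlapping sets.
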