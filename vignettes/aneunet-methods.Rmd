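---
title: "Methods: disease-module separation and driver prioritization on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-module separation and driver prioritization on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneunet)
```

`aneunet` compares related diseases — its motivating case is the family of
human aneurysm subtypes — through two complementary network analyses: a
*proximity* analysis that scores how entangled two disease gene sets are on
a background protein–protein interaction (PPI) network, and a *driver*
analysis that ranks genes of each disease by their network closeness to
known disease genes in a disease-specific differential co-expression
network, filtered by differential expression. This vignette states the
models, their assumptions, the tunable parameters, and the choices made
where the procedure was genuinely underdetermined.

## Separation score

For gene sets $A$ and $B$ mapped onto an undirected, unweighted PPI network,

$$ s_{AB} = \langle d_{AB} \rangle - \frac{\langle d_{AA}\rangle + \langle d_{BB}\rangle}{2}, $$

where $\langle d_{AB}\rangle$ averages, over every gene of $A$ and every
gene of $B$ (all $|A| + |B|$ contributions), the shortest-path hop distance
to the nearest gene of the other set, and $\langle d_{AA}\rangle$ averages
each member's distance to the nearest *other* member of its own set. A gene
in $A \cap B$ contributes $0$ to the cross term (the gene is at distance
zero from the other set), which forces $s_{AB} \le 0$ for heavily
overlapping sets and makes the self-score $s_{AA} = -\langle
d_{AA}\rangle$. Averaging both directions over $|A|+|B|$ terms makes
$s_{AB}$ exactly symmetric, which the pairwise heatmap representation
presumes. Distances come from breadth-first search
(`igraph::distances()`); the test suite checks them against an independent
Floyd–Warshall implementation.

Two degenerate situations require conventions. A **singleton set** has no
"other member", so $\langle d_{AA}\rangle = 0$ — the established
single-gene-disease convention, which keeps $s_{AB}$ finite. **Unreachable
pairs** (genes in different connected components) are excluded from the
means, with the excluded fraction logged; assigning them an arbitrary large
constant would let a single stray component dominate the mean, whereas
exclusion only narrows the evidence base. If *no* finite cross distance
exists the pair is an error, not a number. Disease genes absent from the
network are dropped per set (`restrict_to_network()`), and sets with fewer
than `min_genes = 20` genes are excluded from the study before any scoring
(inclusive boundary: a 20-gene set stays).

No permutation significance test is attached to $s_{AB}$: the score is
reported raw, as a descriptive distance, and interpreted by ordering.

## Differential co-expression network

For one disease with a case/control expression study, Pearson correlation
and its two-sided t-test p-value ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df)
are computed for every *candidate edge* separately in case samples and in
control samples. An edge is a differential co-expression edge (DCE) when
$p < \alpha$ (default $0.05$, deliberately uncorrected) **in either
group**. The DCN is the intersection of the DCEs with the background PPI
edges, every weight set to 1, and its node set is the endpoints of
retained edges — no isolated genes enter the walk.

Candidate edges are the PPI edges themselves, not all gene pairs: since the
DCN is intersected with the PPI anyway, restricting first is equivalent and
reduces the cost from $O(G^2)$ to $O(|E|)$ correlations.

The "in either group" rule is implemented literally as an OR: it selects
edges significantly co-expressed in at least one condition, which includes
edges co-expressed in *both*. Whether "significant in exactly one" was ever
the intent cannot be decided from the rule's usual statement, so the
literal OR is the default and `rule = "and"` is available for sensitivity
analysis. Constant gene vectors have no defined correlation; they yield a
not-significant sentinel rather than an error, so one flat probe cannot
abort a run. No multiple-testing correction is applied to edge p-values —
a faithful reproduction of the thresholding convention this analysis
follows, not a statistical recommendation.

## Degree-biased random walk with restart

Seeds are the disease's known genes present in the DCN. The walker either
restarts at a seed (probability $1-d$) or steps from node $u$ to a
neighbor $v$ with probability

$$ P(u \to v) = \frac{\deg(v)}{\sum_{w \in N(u)} \deg(w)}, $$

i.e. transitions are biased toward high-degree targets — the minimal
operationalization of the assumption that hub genes are more likely
transit points from upstream seed nodes. On a regular graph this reduces
to the plain uniform walk. The stationary distribution of

$$ p \leftarrow d\,T p + (1-d)\,r $$

is found by power iteration from $p_0 = r$, stopping when the $L_1$ change
drops below `tol = 1e-10` (far stricter than ranking stability requires;
cap 10,000 iterations, error on non-convergence). Scores sum to 1 at every
iteration and the result matches the direct solve
$p = (1-d)(I - dT)^{-1} r$ to below $10^{-8}$ in the tests.

Parameter choices:

* **Damping factor** `damping = 0.85` is the *continuation* probability
  (restart probability 0.15), following the PageRank convention the term
  comes from.
* **Restart vector** defaults to uniform mass over the seeds present in
  the DCN. An `"expression"` mode weighting seeds by their absolute
  moderated t-statistic is provided as an explicit option — the upstream
  tool this mechanism reimplements accepts an expression matrix without
  documenting its role, so the neutral choice is the default and the
  expression-weighted variant is opt-in.
* **Ties** in score are broken lexicographically by gene id, making
  rankings fully deterministic.
* **Seeds are kept in the ranking**, flagged by `is_seed`: known disease
  genes legitimately rank high and downstream users can filter.

The final per-disease candidate list is the intersection of the top
`top_k = 100` ranked genes with the differentially expressed genes; the
subset chain (candidates $\subseteq$ top-k $\subseteq$ DCN nodes
$\subseteq$ PPI nodes) is asserted on every run.

## Moderated differential expression

Each gene gets an ordinary two-group fit: mean difference
(case − control), pooled variance $s^2$, residual df
$n_1 + n_2 - 2$. Gene variances are then shrunk toward a scaled
inverse-$\chi^2$ prior with hyperparameters $(d_0, s_0^2)$ fitted by the
method of moments on $\log s^2$: the mean and variance of
$e_g = \log s^2_g - \psi(df/2) + \log(df/2)$ are matched to their
digamma/trigamma expressions and the trigamma equation
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(df/2)$ is solved by Newton
iteration on the strictly decreasing trigamma function. When the empirical
log-variance dispersion does not exceed the sampling value
$\psi'(df/2)$, $d_0 = \infty$ and all genes share
$s_0^2 = \exp(\bar e)$. The moderated statistic

$$ \tilde t_g = \frac{\bar x_{g,case} - \bar x_{g,ctrl}}
   {\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}}, \qquad
   \tilde s_g^2 = \frac{d_0 s_0^2 + df\, s_g^2}{d_0 + df} $$

is referred to a t distribution on $d_0 + df$ df (the normal when
$d_0 = \infty$); $d_0 = 0$ recovers the ordinary pooled t exactly, and a
zero-variance gene is rescued by the prior rather than producing an
undefined statistic. P-values are two-sided (both regulation directions
matter), Benjamini–Hochberg adjusted, and a gene is a DEG when the
adjusted p falls below `deg_alpha = 0.05` — no fold-change filter is
added. Where the package's own estimates can be compared with `limma` on
heterogeneous-variance data, they agree to $10^{-6}$; the one deliberate
difference is the $d_0 = \infty$ branch, where the log-moment scale
$\exp(\bar e)$ is used rather than the arithmetic mean of the variances.

Inputs are assumed normalized and log-scale. A deterministic heuristic
(`maybe_log2()`) applies $\log_2(x+1)$ when the 99th percentile exceeds 50
— values that large are read as linear-scale intensities — and logs the
action loudly; negative values alongside linear-scale detection are an
error rather than a guess.

## Over-representation analysis

Candidate lists are tested against user-supplied GMT annotation terms with
the hypergeometric upper tail $P(X \ge k)$ (equivalently the one-sided
Fisher exact test), BH-adjusted across terms. The universe defaults to the
background PPI gene space — the candidate pool the walk actually draws
from — because an annotation database's full gene universe is neither
stable nor reconstructible offline. Terms are clipped to the universe and
kept when their in-universe size lies in `[5, 2000]`, the common ORA
window; both bounds are configurable. No GO-graph trimming or ranked
(GSEA-style) variant is provided.

## Synthetic benchmark: what it emulates, and what it does not

The generator produces, at desk scale, data with exactly the statistical
structure the pipeline assumes:

* `generate_ppi(n, m)` — connected scale-free network by preferential
  attachment ($(n-m)\,m$ edges), emulating interactome topology where
  degree bias matters.
* `plant_modules()` — disease gene sets grown by seeded BFS so they are
  topologically localized, with *exact* pairwise overlap counts
  ($\lceil f \cdot \text{size} \rceil$ shared genes for designated pairs,
  0 otherwise): the controllable handle behind separation-ordering tests.
* `wire_drivers()` — per disease, non-module genes adjacent to ≥ 3 module
  genes (edges added when needed); each driver–module edge is planted as a
  DCE, each module gene claimed by at most one driver so every planted
  correlation is realizable, and drivers join the planted DEGs.
* `generate_expression()` — baseline $\mathcal N(8, \sigma)$
  log2-intensities; for each planted DCE the target is regressed onto its
  source in case samples only to reach expected Pearson $r$ (controls stay
  null, so the planted edges are recovered under either reading of the
  either/both rule); planted DEGs get a $+\Delta$ case shift, which leaves
  correlations untouched.

Default study conditions (`synthetic_benchmark()`): 1000-node network with
$m = 3$, six 30-gene modules with modules 1–2 sharing half their genes,
5 drivers per disease, 10 case / 10 control samples, $r = 0.8$,
$\Delta = 1.5$. The residual sd $\sigma = 0.5$ was chosen a priori as a
typical within-group sd of normalized log2 microarray intensities
(0.2–0.5 in practice); with $\Delta = 1.5$ it yields strong but not
trivial DEG signal at $n = 10/10$. Desk scale keeps the full 20-replicate
recovery benchmark under two minutes on one CPU; interactome-scale inputs
(≈16k nodes, ≈200k edges) remain reachable through the same functions by
configuration.

Passing these benchmarks demonstrates that the implementation recovers the
structure it models — planted correlation, planted shifts, planted
topology. It does **not** demonstrate robustness to what real expression
data contain and the generator deliberately omits: platform and batch
effects, correlated baseline co-expression beyond the planted edges,
heavy-tailed noise, probe-mapping ambiguity, and curation bias in disease
gene sets. Conclusions about real diseases still require the usual
external validation.

## Numerical and degenerate-input conventions

* All randomness flows from explicit integer seeds (`withr::with_seed`);
  nothing touches the caller's RNG state, and identical seeds give
  byte-identical outputs.
* Edge lists are canonicalized (lexicographically smaller id first,
  self-loops dropped, duplicates collapsed); all written outputs use this
  ordering plus 6-significant-digit floats, so files are byte-stable.
* Gene identifiers are opaque case-sensitive strings; no symbol/ID mapping
  is attempted — identifier harmonization across network, gene sets and
  expression belongs to data preparation.
* Duplicate expression rows collapse to the highest-mean row (the common
  probe-collapse convention); genes with any missing value are dropped,
  since both the correlation p-value and the moderated t assume complete
  vectors.
* $|r| = 1$ maps to $p = 0$; infinite t-statistics map to $p = 0$; the BH
  front door accepts these zeros but rejects values outside $[0, 1]$.
* A disease without an expression study is reported as `"skipped"` rather
  than failing the whole run, so proximity-only diseases are handled
  structurally.

## Known limitations

* The degree-biased transition rule is one defensible reading of a
  one-sentence assumption ("higher-degree genes are likelier transit
  targets"); other weightings (e.g. biasing by seed-side degree, or
  $\deg^\gamma$) are not implemented.
* The separation score is reported without significance calibration;
  comparing scores across networks of very different density is not
  meaningful.
* Raw per-edge $p < 0.05$ DCE selection admits a predictable ~9.75% of
  null edges ($1 - 0.95^2$); the DCN is therefore noisy by construction,
  and the walk's restart mass — not edge cleanliness — carries most of the
  signal.
* ORA treats genes as exchangeable; no correction for gene length,
  network degree or annotation redundancy is made.
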