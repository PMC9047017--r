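---
title: "Methods: targeted hub attacks on functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted hub attacks on functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in `hubfail`,
the choices behind their defaults, what the synthetic cohort does and does
not emulate, and the numerical conventions that make every run reproducible.

## The analysis in one paragraph

Starting from per-subject region-by-time matrices (90 regions in the default
parcellation), the pipeline (i) builds each subject's binary functional
network by Pearson correlation and thresholding, (ii) selects the network
hub as the region with the highest eigenvector centrality on the control
group's mean network, (iii) simulates failure of that hub with the
Crucitti–Latora–Marchiori (CLM) load-capacity cascade and takes the
isolation fault matrix (all hub edges removed) as the post-attack network,
and (iv) quantifies reorganisation by the clustering coefficient, global
efficiency, and the rich / feeder / local decomposition of connection
weights, compared across a patient (JME) and a control (HC) group with
FDR-corrected t-tests and ANOVAs, plus the correlation between patients'
disease durations and their rich connection sums.

## Network construction

For regions $x$ and $y$ with time series $x_n, y_n$, the edge statistic is
the Pearson correlation
$r(x, y) = \sum_n (x_n - \bar x)(y_n - \bar y) \big/
\sqrt{\sum_n (x_n - \bar x)^2 \sum_n (y_n - \bar y)^2}$.
An edge is placed when $r > T$ with $T = 0.3$ by default. Three conventions
are fixed deliberately:

* **The threshold applies to raw $r$, not Fisher $z$.** The conventional
  0.3 cut-off is quoted on the correlation scale; `fisher_z()` is provided
  because variance-stabilised values are the right scale for averaging and
  group statistics, but binarisation never passes through it. (At any fixed
  threshold the two rules give identical networks anyway, since $\tanh$ is
  monotone; keeping the rule on $r$ avoids advertising a dependence that
  does not exist.)
* **Strict inequality.** $r$ exactly equal to the threshold gives no edge.
* **Negative correlations never form edges**; there is no absolute-value
  option.

A constructed network is acceptable when its density lies in $[0.10, 0.50]$,
its mean degree exceeds $2\ln N$ ($\approx 9.0$ for $N = 90$), and it has no
isolated nodes; `network_checks()` reports these rules without modifying
anything.

Group-level networks are prevalence networks: `group_mean_network()`
averages the subjects' binary adjacencies, and `mean_binary_network()`
thresholds the prevalence (default 0.3, i.e. an edge must be present in
more than 30% of subjects) where a single binary group network is needed —
for hub selection and the quality gate. Rich-node *selection* instead ranks
the raw prevalence strengths (weighted row sums), so it uses the full mean
network without re-binarisation.

## Eigenvector centrality and hub selection

Centrality solves $\lambda x = A x$ for the Perron eigenvector of the
binary adjacency $A$, computed by power iteration from the uniform positive
start vector with L2 normalisation each step. Two implementation details
matter:

* The iteration applies $I + A$ rather than $A$. Both have the same
  eigenvectors, and the shift removes the period-two oscillation plain
  power iteration exhibits on bipartite graphs (a 3-node path already
  shows it). The reported eigenvalue is the Rayleigh quotient of $A$.
* Convergence is declared when successive normalised iterates differ by
  less than `tol = 1e-10` in max-norm within `max_iter = 1000`; otherwise
  the vector is returned flagged `converged = FALSE` with a warning.

The attack target is the argmax score; all rankings break ties by label
order, so results are deterministic. Centrality is computed on the
**control group's** mean network by default: the published analyses this
package mirrors report a single centrality table rather than per-subject
ones, and selecting on the control network guarantees the same region is
attacked in both groups. `selection_group` in `pipeline_config()` changes
this.

## The CLM cascade

The CLM model works on transmission efficiencies: each edge carries
$e_{ij} = 1/d_{ij}$, initially 1 on every edge of the binary network. The
load $L_i(t)$ of node $i$ is the number of shortest paths between ordered
pairs $(s, t)$, $s \ne t \ne i$, passing through $i$ as an intermediate
node, with link lengths $1/e_{ij}$ and **all co-optimal shortest paths
counted** (an unnormalised betweenness count). Capacities are fixed at
$C_i = a \, L_i(0)$ with tolerance $a \ge 1$ (default 1.2; smaller values
make cascades easier; there is no canonical value, so it is a sweepable
parameter). An attack zeroes the efficiencies of the hub's edges
permanently. Each step then updates every remaining edge:
$e_{ij}(t{+}1) = e_{ij}(0)\, C_i / L_i(t)$ if $L_i(t) > C_i$, else
$e_{ij}(0)$.

Conventions chosen where the update rule is silent:

* **Doubly-overloaded edges** get the *smaller* of the two prescribed
  values — conservative, symmetric, deterministic.
* **Attacked edges are exempt from restoration**; otherwise the
  else-branch would heal the attack.
* Path-length ties are declared at relative tolerance `1e-9`; unreachable
  pairs contribute nothing.
* Convergence: no overloaded node *and* max-norm efficiency change below
  `1e-12`; cap `max_iter = 100`. With large $a$ the final state equals the
  pure isolation network exactly.

Downstream comparisons use `mode = "isolation"` — the fault matrix in
which exactly the hub's edges are removed — because that is the matrix the
rich-club statistics are defined on; `mode = "cascade_final"` additionally
removes edges whose efficiency the cascade drives to zero and is provided
as an extension.

## Graph metrics and the rich club

Clustering is $c_i = 2e_i / (k_i(k_i-1))$ with $c_i = 0$ for degree below 2
(kept in the mean, so the average stays defined on attacked networks).
Global efficiency is the mean inverse hop distance over ordered pairs with
disconnected pairs contributing 0.

The rich-club coefficient at degree threshold $k$ is
$\phi(k) = 2E_{>k} / (N_{>k}(N_{>k}-1))$ over the nodes of full-network
degree strictly greater than $k$, evaluated for $k = 1 \dots N-1$ and
undefined when fewer than two nodes survive. Normalisation divides by the
mean $\phi(k)$ of 100 degree-preserving Maslov–Sneppen rewirings
(10 attempted double-edge swaps per edge, per-replicate seeds
`base_seed + r`); a density-only null would make the ratio meaningless.
The ensemble mean at each $k$ uses only replicates where $\phi$ is defined,
and the ratio is formed mean-then-ratio, matching the single
$\phi_{random}(k)$ denominator convention. `phi_norm_greater_test()` runs
the one-sided one-sample t-test of $\phi_{norm} > 1$ over the defined
range as the operational rich-club criterion.

Rich nodes are the top 10% (9 of 90) by strength of the control mean
network, ties broken by label order, and **the same set is applied to both
groups** — the comparison is then about the same anatomical set of
connections, not about differently-selected sets. Per-group selection is
available (`select_rich_nodes()` on any group's mean network) for the
alternative reading. Connections split into rich (both endpoints rich),
feeder (one rich), and local (neither); the three sums partition the total
edge weight exactly.

## Group statistics

The battery runs four contrasts — HC-vs-JME before the attack, HC
before-vs-after, JME before-vs-after, HC-vs-JME after — on each of the
three connection classes: 12 two-sided pooled-variance t-tests (Welch by
flag) plus the matching one-way ANOVAs (for two groups $F = t^2$).
Benjamini–Hochberg FDR correction is applied within each contrast's family
of three classes by default; a single global family over all 12 tests is a
flag. The pre/post comparisons are independent-samples by default (a
paired design would also be defensible; the tests mirrored here are
two-sample). Significance is reported at $q < 0.05$, with $q < 0.01$
annotated separately. The duration analysis is a Pearson correlation with
two-sided p between patients' disease durations and their pre-attack rich
connection sums.

## The synthetic cohort

No public cohort exists for this design, so `generate_cohort()` produces
one with the statistical structure the analysis assumes — it is the
package's study population, not a fixture. Defaults: two groups of 37
subjects, 90 regions, 190 timepoints (200 acquired minus 10 discarded for
scanner equilibration in the emulated protocol), patient durations uniform
on [12, 84] months (mean ≈ 48, matching the emulated clinical cohort's
mean duration of about 47 months; with only a mean and spread to target,
the simplest bounded distribution is used).

The ground-truth correlation matrix is built from planted blocks:

* a **rich block**: regions 1–9 mutually correlated at
  `base_correlation = 0.45`;
* **background communities**: the 81 remaining regions partitioned into 9
  communities, correlated within at `background_correlation = 0.40`;
* **feeder couplings**: each rich region correlated at
  `feeder_correlation = 0.35` with every member of one community;
* a **designated hub**: region 1, whose community is enlarged by 3 members,
  giving it the highest degree, strength, and eigenvector centrality of
  the control mean network by construction.

This block-and-factor design is exactly positive semidefinite at the
defaults (each block corresponds to a latent factor, and the factor
loadings sum to less than unit variance per region), so the nearest-PSD
repair — eigenvalue clipping at zero followed by rescaling to unit
diagonal, which keeps the generator total over the whole configuration
space — is a no-op on the defaults and only engages for extreme user
configurations. A plain sparse random background at the density the
construction rules require is strongly indefinite, and its repair distorts
the planted correlations below the edge threshold; the community structure
avoids that while also being the more realistic model of a parcellated
cortex.

The default correlation levels are deliberately moderate. At 190
timepoints, a planted correlation of 0.45 gives per-subject edge
prevalence around 0.99 — reliably present but not saturated, so
subject-level connection sums retain variance and the group t-tests are
well-defined. Substantially higher values would freeze the rich block in
every subject (degenerate tests); lower values would fall below the 0.3
edge threshold.

**Observation noise.** `noise_sd` adds iid Gaussian noise, and the latent
signal covariance is rescaled (to $(1+\sigma^2)C - \sigma^2 I$) so that the
*observed* series has exactly the designated correlation matrix — noise
changes the sampling variability story, not the target correlations. This
keeps "rich-block correlation equals `base_correlation`" true as stated.
The rescaling requires $\lambda_{\min}(C) \ge \sigma^2/(1+\sigma^2)$;
violations are errors naming `noise_sd`.

**The patient deficit.** In the JME arm, affected rich-block correlations
are reduced by `patient_rich_deficit + duration_effect * duration`,
floored at zero. With the default `deficit_scope = "hub"` the reduction
applies only to rich edges incident to the designated hub: the emulated
disease is a *hub* pathology, so patients and controls have identical
structure away from the hub, and isolating the hub in both groups leaves
them indistinguishable — which is exactly the attack signature the
analysis is designed to detect (group difference before, none after).
`deficit_scope = "block"` spreads the deficit over the whole rich block;
under that regime a residual group difference survives the attack, which
is a different disease model, not a different analysis. The deficit size
(0.15 plus 0.002 per month) is a free choice calibrated once so that the
planted effect is detectable at n = 37 per group while leaving the
deficient edges near the detection threshold — which is what makes the
duration gradient visible in edge prevalence.

**What the generator does not emulate.** Haemodynamics, scanner physics,
motion, physiological nuisance structure, spatial autocorrelation between
neighbouring parcels, heavy-tailed or autocorrelated noise, and
between-subject variability in the *location* of the hub. Passing tests
therefore demonstrate that the pipeline recovers the planted
population-level pattern from finite noisy samples — not that the pattern
exists in any clinical population.

**After the attack, feeder sums drop in both groups** (the hub's feeder
edges are removed), so the within-group pre/post feeder contrasts come out
significant on the synthetic cohort even though the emulated study reports
them null; with partial deficits the patient group's pre/post rich
contrast can also reach significance. These are consequences of the
generator's clean, low-variance structure, and they are not part of the
replication criteria, which cover the pre-attack group difference confined
to rich connections, its disappearance after the attack, and the control
group's pre/post rich drop.

## Problem sizes and determinism

Every stochastic step takes an explicit seed (generator seed, rewiring
`base_seed + replicate`), and identical configuration plus seeds give
bit-identical results; the run manifest records parameters and file
hashes. The test suite exercises the full default cohort (37 + 37) for
replication-style checks (25 replicate seeds for the attack pattern, 50
for the duration sign) and a reduced cohort — 10 subjects per group, 100
timepoints, identical network structure — for the 500-replicate null
calibration and other simulation-heavy properties; oracle comparisons run
exhaustively on all 4-node graphs and on random 5–7-node graphs, where
brute-force enumeration is feasible, and on 50 random connected graphs up
to 30 nodes for the centrality oracle.

## Known limitations

* Loads are recomputed globally each step (O(N·E + N³) per iteration in
  the worst case); the implementation is comfortable at N = 90 but not
  tuned for networks orders of magnitude larger.
* The cascade's `cascade_final` mode is provided for completeness; all
  group-level statistics in the published design consume the isolation
  fault matrix, so the cascade dynamics affect only the trace and
  efficiency diagnostics.
* The rich-club null preserves degrees but not connectedness or community
  structure; normalised coefficients below the maximum degree of a highly
  modular network should be read with that in mind.
* With `deficit_scope = "block"`, the post-attack group contrast retains a
  true difference; the replication criteria apply to the default hub
  scope.
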