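---
title: "Information-flow correlations between diseases: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-flow correlations between diseases: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseaseflow)
```

## The model

`diseaseflow` scores similarity between genetic diseases by how information
flows through the protein interactome, not merely by how many genes two
diseases share. The data is a heterogeneous undirected network with two node
types: proteins, linked when they interact, and diseases, each attached to
the proteins encoded by its associated genes. PPI edges carry weight 1 and
attachment edges carry weight `beta` (default 1; only the ratio matters, and
the package verifies that rescaling both together changes nothing).

A random walker starts at a disease, steps to one of the disease's
associated proteins uniformly (forced, because all attachment edges share
one weight), and then walks the protein layer: from protein $i$ with total
incident weight $s_i$ it moves to an interacting protein $j$ with
probability $1/s_i$ per edge, and terminates — is absorbed — with probability
$a_i = \beta\,m_i / s_i$, where $m_i$ is the number of diseases attached to
$i$. Every disease node is absorbing: walks both start and end at diseases.
The *weight* $w_i$ of protein $i$ for a disease is the expected number of
visits the walker makes to $i$ before absorption. Collecting the weights
gives the disease's weight vector over all proteins, and the
**correlation** between two diseases is the cosine of the angle between
their weight vectors — a number in $[0,1]$ because weights are nonnegative.

Treating only the start disease as absorbing would be degenerate on an
undirected network: expected visits between returns to a single absorbing
state are proportional to the stationary distribution, so every disease
would produce a parallel weight vector and all correlations would equal 1.
Absorbing at *all* disease nodes is what makes the profiles informative,
and is how this package reads "walks start and terminate at diseases".

With $Q$ the protein-to-protein sub-stochastic matrix ($Q_{ij} = 1/s_i$ on
PPI edges) and $S(d)$ the start distribution of disease $d$, the weight
vector is the corresponding row of the absorbing-chain fundamental matrix:

$$ w(d)^\top = S(d)^\top (I - Q)^{-1}, $$

computed by one sparse LU solve of $(I - Q^\top)\,w = S(d)$; all diseases
share the factorization. Two invariants are checked throughout the test
suite: every entry is nonnegative and finite, and
$\sum_i w_i a_i = 1$ to $10^{-10}$ — each walk is absorbed exactly once.
An independent Monte-Carlo simulator (`simulate_walks()`) replays the walk
literally and must agree with the solve within four standard errors; it
shares no code with the linear-algebra path.

### Pruning

Expected visit counts are finite only if absorption is certain, so
`prune_unreachable()` removes every protein whose PPI connected component
contains no disease-attached protein. Proteins that appear only in the
association table (no known interactions) are deliberately *kept* as
isolated nodes: a walk started at such a protein is absorbed immediately,
so two diseases sharing only that gene still obtain correlated weight
vectors — gene sharing is subsumed rather than discarded.

## Overlapping clustering

Diseases are clustered softly on the unit sphere of their normalized weight
vectors $\hat w(d)$. Each of $K$ clusters is itself a unit weight vector
$v_k$ over proteins. The fit alternates:

* **E-step** — membership of disease $d$ in cluster $k$ is
  $P_{dk} \propto C(\hat w(d), v_k)^\gamma$, normalized so each row sums
  to 1 (uniform if all cosines are 0);
* **M-step** — $v_k \propto \sum_d P_{dk}\, \hat w(d)$, re-normalized.

Initial centers come from greedy farthest-first seeding (first center: the
disease with the largest total weight; each next: the disease maximizing
the minimum cosine distance to the chosen centers; exact ties broken by a
seeded draw). After convergence (max membership change below `tol = 1e-6`,
cap `max_iter = 500`), cluster pairs with mutual cosine above 0.999 are
merged, memberships summed, and a final E-step run.

The sharpness exponent $\gamma$ deserves comment. At $\gamma = 1$
memberships are directly proportional to correlations — the most literal
reading of "membership probabilities based on correlations" — but the
iteration then has an attractive degenerate fixed point in which every
cluster vector sits at the global centroid. Whether that fixed point
captures the dynamics depends on how orthogonal the clusters are: in a
production-scale interactome weight vectors live in a space of tens of
thousands of proteins and between-family cosines are tiny, but on networks
of tens to hundreds of proteins (everything a desk-scale test can build)
between-module cosines are of order 0.3, and at $\gamma = 1$ the fit
verifiably collapses to a single cluster on the package's own planted-module
fixtures. The default is therefore $\gamma = 5$, the smallest integer at
which the planted structure is recovered robustly across seeds while
memberships remain soft and overlapping; $\gamma$ stays user-configurable,
and $K$ defaults to $\lceil\sqrt{n_\text{diseases}}\rceil$ (model selection
is out of scope).

## What-if edits and certified error bounds

`apply_edit()` replaces a disease's gene associations (or adds a new
disease); the previous associations are discarded unless re-supplied, which
supports in-silico experiments on adding or removing gene links. Re-solving
the whole model after each edit is the expensive path, so `approx_whatif()`
computes only the *edited* disease's weight vector exactly in the edited
network and scores it against the frozen base model — frozen disease
vectors for correlations, frozen cluster vectors for memberships. The price
is that everyone else's vectors did change a little; the package therefore
reports, next to every approximate number, a *certified upper bound* on the
error of freezing, derived as follows.

An edit changes attachments at the protein set $A$ (the symmetric
difference of the old and new gene sets), changing only the rows of the
transition kernel at $A$. Couple the base and edited walks so they move
identically until they first differ at a visit to some $p \in A$; the
per-visit divergence probability is the total-variation distance between
the two kernels at $p$,

$$ \varepsilon_p = \frac{\beta}{\min(s_p^{\text{pre}}, s_p^{\text{post}}) + \beta}, $$

which covers both added attachments ($s^{\text{post}} = s^{\text{pre}} +
\beta$) and removed ones ($s^{\text{pre}} = s^{\text{post}} + \beta$).
Before divergence the walks coincide, so the expected number of divergence
opportunities at $p$ is at most $w_p(e)$, the unedited disease's weight at
$p$. After divergence, each walk contributes at most $L_{\max}$ further
expected visits, where $L_{\max} = \max_{p \in A} \max(t_p, t'_p)$ and
$t_p$ ($t'_p$) is the total expected visit count of a walk started at $p$
in the base (edited) chain — both come from a single extra solve of
$(I-Q)\,t = \mathbf 1$ per chain. The edited chain's $t'$ matters because
removing an attachment reduces absorption and can lengthen walks. This
gives, for every unedited disease $e$, an $\ell_1$ perturbation bound

$$ \Delta_1(e) = \Big(\sum_{p \in A} w_p(e)\,\varepsilon_p\Big)\,(1 + L_{\max}), $$

from which the user-facing bounds follow by standard inequalities:

* **correlation**: $\lvert\cos(x, \hat w(e)) - \cos(x, \hat w'(e))\rvert
  \le \lVert \hat w(e) - \hat w'(e)\rVert_2 \le 2\Delta_1(e)/\lVert
  w(e)\rVert_2$, clamped to 1;
* **cluster drift**: with $u_k = \sum_d P_{dk} \hat w(d)$ the unnormalized
  M-step sum, $\lVert \hat u_k - \hat u'_k \rVert_2 \le 2 B_k / \lVert
  u_k\rVert_2$ where $B_k$ sums each disease's contribution
  $P_{dk} \cdot 2\Delta_1(d)/\lVert w(d)\rVert_2$ (the edited disease
  contributes its exactly-known vector difference; a brand-new disease
  contributes its full possible unit mass);
* **membership**: if each cosine $C_k$ is off by at most $\delta$ (with the
  $\gamma$-power absorbed via $|C^\gamma - C'^\gamma| \le \gamma|C - C'|$
  on $[0,1]$), then each normalized membership is off by at most
  $\delta(1+K)/(S - K\delta)$ for $S = \sum_j C_j^\gamma$, clamped to 1
  when $S \le K\delta$.

A no-op edit has $A = \varnothing$ and all bounds are exactly zero. The
exact path, `exact_whatif()`, recomputes every weight vector and refits the
clustering *warm-started from the base cluster vectors*; a cold restart
could land in a permuted or different local optimum, which would make
per-cluster comparison meaningless. The test suite validates soundness
empirically: over batches of random edits (including new diseases and full
association replacements), every reported bound must dominate the true
|approximate − exact| difference. The EM refit can in principle drift
beyond the one-step bound the algebra covers; the conservative constants
(total-variation $\varepsilon_p$, $\ell_1 \ge \ell_2$, the factor-2
normalization inequalities) absorb that in practice, and the empirical
soundness check is the contract.

## Synthetic fixtures

`generate_fixture()` builds networks with planted ground truth: each module
is a random spanning tree (guaranteeing connectivity) plus independent
within-module edges at `p_within`; modules are interlinked at `p_between
< p_within`; each disease draws `genes_per_disease` genes without
replacement from one module. Module labels are returned for recovery tests
only — the core API never sees them. Default sizes (3 modules × 15
proteins, 4 diseases per module, 3 genes each, `p_within = 0.3`,
`p_between = 0.01`) are chosen to emulate a small disease-family landscape:
modules dense enough to hold a diffusing walk, sparse cross-talk, and
Mendelian-style few-gene associations. What the generator does *not*
emulate: scale-free degree distributions, hub proteins shared across many
diseases, noisy or missing associations, and the sheer dimensionality of a
real interactome — so passing tests demonstrate correctness of the
machinery, not biological performance on production data.

`tiny_fixtures()` carries three hand-solved networks used as frozen
oracles, e.g. the two-protein path D1–P1–P2–D2 with weight vectors
$(4/3, 2/3)$ / $(2/3, 4/3)$ and correlation exactly $0.8$.

## Numerical choices and problem sizes

* Node ordering is lexicographic by ID, fixed at build time; all outputs
  are byte-stable given identical inputs and seeds.
* The linear systems are solved by sparse LU (`Matrix::solve` on
  `dgCMatrix`); at the package's intended scales (up to a few thousand
  proteins) a direct solve is both exact and fast.
* Rank cutoffs expand across *exact* float ties only (deterministic
  pipeline, no tolerance); near-ties at $10^{-12}$ are not expanded.
* The significance floor ($10^{-6}$ by default) annotates query output and
  never filters it; on small networks correlations are large and the
  annotation is trivially true, but on high-dimensional networks typical
  correlations are tiny and the floor becomes informative.
* Test and validation sizes: hand-solved 2–4 protein networks for exactness
  at $10^{-12}$; planted-module networks of 16–45 proteins and 4–12
  diseases for properties; $10^5$ Monte-Carlo walks for solver validation;
  100 random edits for bound soundness. These sizes make the whole suite
  run in well under a minute while exercising every code path.

## Known limitations

* Association edges are unweighted (all share `beta`); evidence-weighted
  attachments would change the start distribution and absorption model.
* PPI edits are out of scope for the what-if machinery — only a disease's
  attachment set can be edited.
* The membership error bound covers the one-step drift of cluster vectors;
  full EM re-convergence is controlled empirically, not analytically.
* $K$ is user-chosen; no model selection is attempted.
* Identifiers are opaque strings; no cross-database gene/protein ID
  reconciliation is performed.
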