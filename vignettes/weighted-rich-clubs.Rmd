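---
title: "Measuring topological and weighted rich clubs with randomized controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring topological and weighted rich clubs with randomized controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richclub)
```

## The problem

In many networks — brain connectomes, air-transport systems, collaboration
networks — the most prominent nodes form a *rich club*: they interact with
one another more than chance would predict. Prominence ("richness") can be
any node property by which all nodes can be ranked; in practice it is most
often the degree $k$ (number of incident links) or, in weighted networks,
the strength $s$ (sum of incident link weights). At a richness threshold
$r$, the club is the set of $N$ nodes whose richness is *strictly* greater
than $r$; ties at the boundary are excluded together, since there is no
principled way to break them.

For an unweighted club the classical coefficient is the link density among
the rich nodes,

$$\phi(r) = \frac{2E}{N(N-1)},$$

with $E$ the number of intra-club links and $P = N(N-1)/2$ the number of
possible ones. In weighted networks the natural quantity is the *weighted
connectedness* $C$, the sum of the weights of the links between club
members, and the coefficient generalizes to

$$\phi = \frac{C}{F},$$

where $F$ is the *maximal possible* weighted connectedness — the largest
$C$ the club could attain under domain-specific assumptions about how links
and weights may be rearranged.

## Nine definitions of F

`maximal_connectedness()` implements nine variants of $F$, organised along
two axes. The *link budget* says how many links could carry weight into the
club: `P` (new intra-club links may be created, up to $P$), `E` (the
intra-club link count is frozen), or `all` (weights may be redistributed
over every link of the network). The *weight source* says where those
links' weights come from: `capped` (any link could carry weight up to a cap
$W_{max}$, as in correlation networks where weights cannot exceed 1),
`global` (weights are tied to links and the strongest links of the whole
network are placed in the club), or `local` (only links already attached to
a club member may be rewired inward; intra-club links count among the
candidates, which guarantees $F \ge C$).

Two cells deserve comment because they are the least constrained by the
taxonomy's text. For `(all, capped)` we define $F = \min(L, P)\,W_{max}$,
with $L$ the network's link count: every existing link could carry the cap,
but a club can physically hold at most $P$ links. For `(P, global)` and
`(P, local)` the budget may exceed the number of candidate links, in which
case all candidates are used — one cannot select more links than exist, and
this keeps $F$ finite.

## Why the denominator should be a control ensemble

Even randomly wired networks show $\phi > 0$, so any rich-club coefficient
must be normalized against randomized controls that preserve the richness
sequence:

$$\phi_{norm}(r) = \frac{\phi(r)}{\phi_{rand}(r)}.$$

The key algebraic observation is that if the controls respect the same
rearrangement assumptions as $F$, then $F$ is *identical* in the real
network and in every control, and cancels:

$$\phi_{norm} = \frac{C/F}{C_{rand}/F} = \frac{C}{C_{rand}}.$$

The denominator choice therefore moves entirely into the choice of control
ensemble, which is where it belongs: mismatching $F$ and the controls (for
example, an $E$-links denominator normalized against controls that move
links and change $E$) silently conflates topological and weighted effects.
The test suite asserts the cancellation to machine precision for
control/variant pairs in which $F$ is exactly invariant: the `(P, capped)`
variant under the topology-preserving control, and `(all, global)` under
degree-preserving rewiring of unit-weight networks.

## The three control families

`phi_norm_curve()` evaluates $\phi_{norm} = C/\bar C_{rand}$ at every
unique richness value, with $\bar C_{rand}$ the *mean* over `n_rand`
controls (the mean, not the median, is the convention the reference
analyses use; `n_rand = 1000` by default, and all ensembles are
reproducible through integer seeds).

* **Topological** (`topological_control()`): degree-preserving
  randomization by repeated double-edge swaps starting from the real
  network, 10 swaps per link by default, rejecting any swap that would
  create a self-loop or duplicate link. Starting from an existing
  realization means the degree sequence is preserved by construction and
  realizability can never fail. Weights are ignored (set to 1) in both the
  network and the controls, so the curve is the classical unweighted
  normalization: it detects preferential link *placement*.
* **Weighted** (`weighted_control()`): the link set is kept fixed; the
  weight multiset is globally permuted over the links and then rescaled by
  symmetric iterative proportional fitting — each sweep multiplies
  $w_{ij}$ by $\sqrt{f_i f_j}$ with $f_i$ the ratio of target to current
  strength — until every node's strength is within relative tolerance
  `tol` of its original value (default $10^{-3}$, iteration cap 10,000;
  non-convergence is an error that reports the worst deviation, which can
  occur on degenerate topologies such as trees, where leaf strengths pin
  individual weights). This decorrelates weights from link placement while
  closely preserving the strength sequence: it detects preferential weight
  *allocation* on the existing topology. Rescaled weights are real-valued
  even for integer inputs; no re-rounding is applied because only weight
  sums enter $C$.
* **Mixed** (`mixed_control()`): degree-preserving rewiring followed by
  weight permutation and rescaling toward the *original* strength sequence.
  The resulting signal compounds topology and weights and cannot attribute
  a club to either alone; it is provided because the compound question is
  sometimes the intended one, and because it is what an unmatched
  $F$/control pair measures inadvertently.

For directed networks, `directed_weight_shuffle()` permutes each node's
outgoing (or incoming) weights among themselves, preserving out- (in-)
strengths exactly; the orientation is carried by a directed igraph. This is
the only function that touches direction — the analysis path proper is
undirected.

Club membership inside an ensemble is recomputed from each control's own
richness values. For degree richness this is equivalent to freezing the
real network's clubs (every control preserves the degree sequence, so club
sizes match at every threshold); for strength or custom richness,
recomputation is the only faithful reading.

## Significance

Each defined threshold gets a two-sided empirical p-value with add-one
correction, $p = 2\min(r^+, r^-)/(n+1)$ capped at 1, where $r^+$ counts
controls with $C_{rand} \ge C$ (plus one) and $r^-$ the mirror count.
Two-sided, because clubs carrying *less* weight than chance are a finding
(connectome analyses report exactly that pattern); add-one, because it
makes the p-value valid (super-uniform under the null) at any ensemble
size. No correction across thresholds is applied by default — matching
standard practice for these curves — but `p_adjust = "BH"` opts in to
Benjamini–Hochberg. Thresholds whose club has fewer than two members, or
where $\bar C_{rand} = 0$, propagate `NA` through `phi_norm`, `p_value`
and `significant`; they are never zero-filled, and a zero ensemble mean
against a positive observed $C$ additionally raises a warning rather than
returning infinity.

## What the synthetic generators emulate

`er_weighted()` draws Erdős–Rényi topologies with i.i.d. link weights
(uniform, lognormal, or constant) — the fully unstructured baseline.
`plant_topological_club()` wires a designated node set at a higher
intra-set link probability (`club_p` vs `baseline_p`), with weights i.i.d.
everywhere: structure purely in link placement.
`plant_weighted_club()` keeps a single ER topology, anchors the club to the
highest-degree nodes of that fixed topology (so that degree-based richness
can find it), and multiplies intra-club weights by `boost`: structure
purely in weight allocation, with the link set untouched. Boosting is
multiplicative rather than re-sampling so that a single knob controls
effect size and weight-permuting controls remain applicable.

The suite uses these generators at sizes chosen to exercise the method at
realistic density while keeping ensembles cheap: $n = 100$, link
probability 0.1 (0.05 for the planted-topology case), clubs of 10,
ensembles of 200 controls, 50 replicates or seeds per experiment, and
brute-force cross-checks on networks of at most 8 nodes where exhaustive
pair enumeration is feasible.

What passing these tests shows — and what it does not. The generators
produce independent-link topologies with homogeneous weight laws; real
networks have degree heterogeneity, spatial and modular constraints, and
weight–degree correlations that these fixtures deliberately lack. Tests on
planted structure therefore validate the *logic* of the dissociation
(weighted planting moves only the weighted curve; topological planting
moves the topological and, generically, the mixed curve), not the power of
the method on any particular empirical network.

## Numerical and design choices

* Strict inequality at the threshold; tied nodes always share membership.
* The threshold grid is every unique richness value in the network,
  including the maximum (whose club is empty and undefined) so curves cover
  the full range.
* Undefined coefficients are `NA`, never 0 or Inf, and propagate.
* The strength-rescaling tolerance `tol` bounds a small deterministic bias
  in $\bar C_{rand}$ for the weighted and mixed ensembles (relative order
  `tol` at worst); at thresholds where the Monte-Carlo error is tiny this
  bias, not sampling noise, limits how exactly $\phi_{norm}$ centres on 1.
* Ensemble reproducibility: child seeds for the `n_rand` controls are drawn
  once under the caller's seed, so ensembles are deterministic given
  (network, kind, `n_rand`, seed) and controls are independent across the
  ensemble.
* Equal-weight networks are a fixed point of the weighted control
  (permuting equal weights is invisible and rescaling is the identity),
  which provides an exact $\phi_{norm} = 1$ invariant used in the tests.

## Known limitations

* Detection power at modest planted effect sizes is limited by how well the
  degree ranking separates the planted set. With a planted intra-club link
  probability of 0.6 over a 0.05 baseline ($n = 100$, club of 10), planted
  degrees (mean ≈ 9.9, sd ≈ 2.5) interleave with the background tail
  (mean ≈ 5), so degree-threshold clubs are diluted with background nodes
  and roughly a quarter of realizations yield no significant threshold
  anywhere on the topological curve. Stronger planting, larger clubs, or a
  richness parameter better aligned with the planted structure restore
  power; this is a property of threshold-based club definitions, not of the
  normalization.
* The weighted control realizes "uncorrelated weights with a preserved
  strength sequence" as permutation plus proportional rescaling; other
  realizations of the same constraints exist, and decorrelation holds only
  up to what strength preservation itself enforces.
* Degree-preserving rewiring samples graphs by swap chains from the
  observed network; it is the standard configuration-model null, not an
  exactly uniform sampler over the degree-sequence class.
* No directed, link-richness, or attribute-preserving variants of the
  analysis path are provided.
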