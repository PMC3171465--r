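---
title: "Detecting specificity-determining positions: models and design choices"
author: "sdpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting specificity-determining positions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpscan)
```

## Scope and assumptions

`sdpscan` scores functional specialization in a family of paralogous
protein groups, one alignment column at a time. Its inputs are a multiple
sequence alignment and a classification of sequences into groups of
orthologues; the classification is taken as given, never inferred. The
framework is deliberately phylogeny-free: each group is assumed to be a
fair sample of orthologues of comparable evolutionary breadth, each column
is treated independently, and a group's residue-type choices at one
position are summarized by their frequency distribution alone. All scores
are relative — they are meaningful only within one alignment, which is why
every score is min–max rescaled against the other positions of the same
family before anything is combined.

Two kinds of specialized positions are distinguished. A *determinant* of a
group is conserved in that group while the other groups evolve at
arbitrary, possibly high, rates — a single-group property. A *discriminant*
is conserved within every group but as a different type in each — a
family-wide property. Each column can be placed in a cube with coordinates
(conservation of group 1, conservation of group 2, overlap): the corner
`(1, 1, 1)` is a column conserved as the same type everywhere, `(1, 1, 0)`
a discriminant, `(1, *, 0)` a determinant of group 1, and `(0, 0, 0)` a
fully variable column — diametrically opposite the discriminant corner,
not the conserved one.

## The free-evolution model

Exchangeability of amino-acid types enters through a continuous-time
Markov model. A rate matrix `Q` is assembled from a PAML-dialect file
(19 rows of lower-triangular exchangeabilities `s_ij` and 20 equilibrium
frequencies) as `Q_ij = s_ij * pi_j`, diagonals set so rows sum to zero,
then rescaled so that `-sum(pi_i * Q_ii) = 1`: time is measured in expected
substitutions per site. The bundled default is the WAG general replacement
matrix (`inst/extdata/wag.paml`); any PAML-dialect matrix can be supplied
instead, since the framework is matrix-agnostic.

Transition probabilities `P(t) = exp(Qt)` are computed by the reversible
symmetrization trick: `diag(sqrt(pi)) %*% Q %*% diag(1/sqrt(pi))` is
symmetric, so one eigendecomposition at model-load time makes `P(t)` for
any `t` a cheap reconstruction. Entries are clipped at zero and rows
renormalized to absorb eigen-roundoff (the unit tests hold `P(t)` to
row-stochasticity within 1e-9 and to the semigroup law within 1e-8, and
cross-check against a dense matrix exponential).

A position free of constraints, starting from a single ancestral type `a`,
has expected distribution `P(t)[a, ]` after time `t`; for long times every
such distribution collapses onto the stationary `pi`. These free
distributions supply the "expected" halves of the observed-minus-expected
corrections below.

### Effective divergence time

The corrections need a time at which to evaluate the free expectation. For
every non-empty (position, group) profile we find the time `t*` at which
the free distribution rooted at the profile's ancestral type maximizes its
overlap with the observed distribution; the family-wide `t_eff` is the
unweighted mean of those optima over all profiles. Choices fixed here:

* the ancestral type of a profile is its majority type; exact ties are
  broken in favour of the tied type whose free distribution (maximized
  over the time grid) overlaps the observed profile most, then by
  alphabet order;
* the search grid is `{0}` plus 64 log-spaced points in `[1e-3, 20]`
  substitutions/site, followed by golden-section refinement of interior
  optima to `|dt| < 1e-3`; boundary optima are returned as-is, so a
  profile equal to `pi` reports the grid ceiling of 20 and a fully
  conserved profile reports exactly 0;
* the overlap maximized is the same normalized overlap `o` used for
  scoring (below);
* one `t_eff` per family, used for every position and group. Averaging
  per-group or per-position estimates instead is defensible, but a single
  family-wide value keeps the corrected scores comparable across columns,
  which is all the downstream min–max rescaling requires.

## The score algebra

### Conservation (first character of the scorer id)

* `e` — column entropy `H = -Σ f ln f`, in nats (the base is irrelevant
  after rescaling); 0·ln 0 = 0 throughout.
* `r` — `H_obs − H_exp(a, t_eff)`: the entropy minus what free evolution
  from the ancestral type would have accumulated. Negative values mean
  stronger conservation than drift explains. This orients the correction
  the intuitive way: a conserved isoleucine — a type with cheap escape
  routes to valine and leucine — signals more pressure than a conserved
  tryptophan, whose immobility is expected. Divergence-from-background
  measures (`kl_from_stationary`) order these two cases the other way
  round, which is why they are provided only as a reference.
* `j` — Jensen–Shannon divergence between the profile and `pi`
  (equal-weight mixture; bounded by ln 2).
* `0` — no conservation information; implemented as the constant 1/2 so
  combiners remain well-defined and ranking depends on overlap alone.

Raw values are min–max rescaled per group across positions (a constant
vector maps to all zeros), `e` and `r` are complemented so that
1 = conserved, and empty profiles (gap-only columns) propagate `NA`.

### Overlap (second character)

* `o` — the package's preferred measure: `pᵀq / (‖p‖ ‖q‖)`, the overlap of
  the *normalized* distributions. It is exactly 1 for identical
  distributions irrespective of their variability and exactly 0 for
  disjoint supports — the property that keeps conservation and overlap
  information separate, and the reason it is also used inside the
  effective-time search.
* `f` — squared difference `Σ (p_α − q_α)²` (GroupSim's overlap): 0 only
  at identity, but its disjoint-support value depends on the columns'
  variability (2 for two indicators, 1 for two two-type uniforms), so the
  two information sources mix.
* `eq9` — the unnormalized inner product `pᵀq`: 0 at disjoint supports as
  expected, but spread-dependent at identity (1 for matching indicators,
  1/k for matching k-type uniforms) — the complementary failure mode.
* `klg` / `sh` — relative entropy between the groups (reference
  distribution floored at 1e-6 and renormalized to stay finite) and its
  symmetrized Jensen–Shannon counterpart ("sequence harmony"), which is
  universally 0 at identity and ln 2 at disjoint supports.
* `m` — mutual information between residue type and group membership,
  restricted to the two groups of the pair.
* `r` — the exchangeability-corrected overlap
  `o(p, q) − o(P(t_eff)[a_1, ], P(t_eff)[a_2, ])`: observed overlap minus
  the overlap free drift from the two ancestral types would produce. It is
  0 when both profiles equal their free expectations. Note the direction
  this implies: two groups conserved as different but highly exchangeable
  types (Ile vs Val) forgo a *large* expected overlap and are therefore
  judged more strongly diverged than groups conserved as types that could
  hardly overlap anyway (Trp vs Asp). This is the overlap-side mirror of
  the conserved-isoleucine argument above.

Before combination all overlap ids are oriented so that 1 = identical,
0 = most diverged: `o` passes through; `r` and `eq9` are min–max rescaled
over positions; `f`, `m`, `klg`, `sh` measure divergence and are negated
first. Rankings — the package's actual output — are invariant to these
affine normalizations.

### Combined scores (third character + model)

With conservation `C_g` and pairwise overlaps `v_gh` in `[0, 1]`, the
penalty terms are:

* *discriminant*: `1 − C_g` for every group and `v_gh` for every pair;
* *determinant of T*: `1 − C_T` and `v_Tg` for `g ≠ T` — non-target
  conservation and non-target pairs are excluded *exactly* (a
  property-based test perturbs them over 1000 random triplets and demands
  bit-identical scores);
* *conservation-only*: `1 − C_g` for every group;
* *nonconserved-nonoverlap*: `C_g` and `v_gh` (the "interesting-looking"
  fourth corner, included for completeness).

The Euclidean combiner returns the root of the mean of squared terms, the
linear combiner the plain mean; dividing by the number of terms is this
package's normalization, chosen so both variants live in `[0, 1]`. Only
the ranking is contractual, and the ROC evaluation is invariant to any
positive rescaling. Smaller = more specific; ties are broken by position
index. Multi-group mutual information is available as a separate ranking
model (ranked descending) for reference.

## Input handling

Alignments are read via `Biostrings` (FASTA and Stockholm); rows are
uppercased, `.` becomes `-`, and letters outside the canonical 20-letter
alphabet (B, Z, J, U, O, …) are mapped to `X` with a warning. All vectors
and matrices are indexed in the PAML alphabet order
A R N D C Q E G H I L K M F P S T W Y V, shared with the rate-matrix file
dialect. Gaps and `X` are excluded from counts and frequencies
renormalized; a group column with no countable residue is flagged empty
and excluded from scoring; positions whose gap fraction exceeds 0.5 in any
group are flagged (`high_gap`) but still scored. Every group must have at
least two sequences; sequence weighting is deliberately absent (the
fair-sample assumption). Positions are 0-based internally and 1-based in
every user-facing report. Annotation handling enforces one further rule:
positions fully conserved across all groups are removed from positive
sets at load time — a universally conserved residue cannot evidence
specificity.

## ROC evaluation

`roc_curve()` sweeps a threshold down the ranked list, one step per
distinct score value, and reports the true-positive rate against either
the fraction of *all* non-positive residues above threshold
(`non_positive`, appropriate when untested residues dominate the universe)
or the fraction of confirmed negatives (`confirmed_negative`, the standard
false-positive rate). With this tie handling the trapezoid AUC equals the
probability that a random positive outranks a random negative with ties
counted half — an identity the tests verify against an O(n²) brute-force
oracle. When the negative set is the complement of the positives the two
modes coincide.

## The synthetic generator

`simulate_family()` provides ground truth without any external data. Under
a star phylogeny it draws, per column, an ancestral type from `pi` and
then: `conserved_all` columns repeat that type everywhere;
`determinant` columns fix the target group at the ancestral type and draw
every other group's residues i.i.d. from `P(t_free)[anc, ]`;
`discriminant` columns fix each group at a distinct type (the first being
the ancestral, the rest drawn uniformly without replacement, so no
exchangeability bias is planted); `free` columns draw everything i.i.d.
from the free distribution. Simulation is bit-reproducible under its seed.

The standard study conditions used by the tests and the acceptance script
are two groups of 40 sequences, 200 columns mixed as 20 determinant + 20
discriminant + 80 free + 80 conserved, and `t_free = 2` substitutions per
site — sizes chosen to resemble a well-sampled two-paralogue comparison
while keeping the whole suite fast; smaller families (6–20 sequences,
12–60 columns) are used where only mechanics are exercised.

What the generator does *not* emulate matters for interpreting results on
it:

* no tree structure within groups, no indels, no alignment error, no
  rate heterogeneity within a class — planted signal is cleaner than real
  signal;
* free columns share one distribution across groups, so between-group
  noise is purely multinomial;
* most importantly, a planted determinant's non-target group drifts to an
  almost disjoint type distribution at `t_free = 2`, which is itself
  strong type-by-group assortment. Mutual information therefore detects
  planted determinants nearly perfectly here, and the synthetic benchmark
  cannot reproduce the weakness MI shows on real determinant-type
  divergence, where non-target groups keep variability overlapping the
  target's type. Passing (or failing) MI comparisons on this generator
  says little about MI on real families — the corresponding check in the
  acceptance suite is kept literal and its outcome reported as measured.
* a perfectly discriminant column is also a perfect determinant (conserved
  target, zero target overlap), so discriminant columns are excluded from
  both the positive and the negative set when planted determinants are
  evaluated, and the confirmed-negative ROC convention is the meaningful
  one for the planted benchmark.

One structural fact about the two-group grid is worth knowing: with the
`0` conservation id, determinant and discriminant scorers are monotone
transforms of each other (penalty sets `{1/2, v}` vs `{1/2, 1/2, v}`), so
those eight grid cells produce identical rankings by construction and can
only ever tie.

## Degenerate inputs and numerical conventions

Natural logarithms throughout; `0 ln 0 = 0`; KL floors its reference at
1e-6 (JS-type measures need no floor). Min–max rescaling of a constant
vector returns zeros rather than NaN. Empty profiles raise errors in
scalar scoring functions and propagate `NA` through matrix-level scoring
and ranking (`NA` scores sort last). `P(t)` demands `t >= 0`;
`transition_matrix` clips negative entries at the 1e-12 level only.
Rate-matrix files must have strictly positive frequencies — a zero
stationary frequency would break both the symmetrization and the KL
scores.

## Known limitations

Beyond the generator caveats: the method inherits the fair-sample
assumption (no correction for phylogenetic redundancy or biased taxon
sampling); per-column independence ignores co-evolution; gap treatment is
the simplest defensible choice (exclude and renormalize, flag above 50%);
the effective time is a single family-wide compromise that will misfit
families with strongly heterogeneous group divergences; and absolute score
values are not comparable across alignments — only rankings within one
family are meaningful.
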