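---
title: "hmmsieve: models, filter, calibration, and benchmark methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hmmsieve: models, filter, calibration, and benchmark methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmsieve)
```

This vignette is the package's account of its science: the profile-HMM
model and its construction, the four-stage acceleration filter, E-value
calibration, the iterative search, the decoy benchmark, and the design
choices made where the design was genuinely open.  Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The profile HMM

A model has `M` match positions.  Position `k` carries match emission
probabilities `p_k(a)` over the 20 amino acids, insert emissions (fixed
to the background, so insert residues score 0 bits), and transition
probabilities for M→M/I/D, I→M/I, and D→M/D.  All scoring is log-odds in
bits against a null model of i.i.d. background residues: the match score
is `m_k(a) = log2 (p_k(a) / f(a))`.  The background defaults to the
Robinson–Robinson frequencies, overridable via `amino_background()`.

**Local/local semantics.** `configure_local()` puts uniform entry
probability `1/M` on every match state and uniform exit `1/M`; an
alignment may match any model interval against any subsequence, and
flanking unmatched residues cost nothing (they are emitted by the null
on both sides of the odds ratio).  Bit scores are therefore directly the
log-odds of the matched region.

**Building from an alignment** (`build_profile()`):

* Columns with weighted residue occupancy ≥ 50% become match states;
  the rest are insert columns.  `.` and `-` both count as gaps, case is
  ignored, and degenerate codes are resolved (B→D, Z→E, U→C, O→K, X→the
  most frequent background residue) so the scoring alphabet stays
  closed.
* Rows are weighted by Henikoff position-based weights, then the *total*
  weight is rescaled so that the mean match-state relative entropy
  `mean_k Σ_a p_k(a) log2(p_k(a)/f(a))` hits a target, 1.3 bits by
  default.  This is the information-content style of sequence weighting:
  it makes model sharpness independent of how redundantly a family was
  sampled (ten identical rows give exactly the model of one row).  The
  target is a tunable (`relent_target`) because different corpora are
  built to different information densities; 1.3 bits/position is a
  conventional operating point for remote-homology models.
* Emissions get a substitution-mixture pseudocount: the column's
  weighted composition is pushed through the BLOSUM62-conditional
  distribution `q(a|b) ∝ f(a)·2^(S_ab/2)` and added with total weight 5.
  This keeps log-odds sane for sparse columns without estimating
  Dirichlet mixtures.
* Transitions use weighted counts plus light pseudocounts
  (M: 1.0/0.1/0.1, I and D: 0.5/0.5).

**Single-sequence models** (`seq_profile()`) put one observed count on
the query residue plus 5 counts of its BLOSUM62-conditional profile, with
fixed mildly gap-averse transitions (M→M 0.975).  They stand in for a
pairwise pre-search when the iterative procedure starts from one
sequence.

## Exact scoring

`viterbi_score()` and `forward_score()` are exact dynamic programming in
bits; Forward accumulates in log2 space with stable log-sum-exp, and is
always ≥ Viterbi.  Traceback ties are broken deterministically (state
priority M > D > I, continuation before entry) so traces are
reproducible.  `viterbi_window()` restricts both the matched subsequence
and the matched model states to half-open windows; narrowing a window
can never raise the score.  The kernels are compiled (Rcpp) — the test
suite checks them against exhaustive enumeration of every legal state
path on small models, which is the only practical independent oracle.

Coordinates throughout the package are 0-based and half-open, which
keeps diagonal and window arithmetic free of ±1 cases.

## The acceleration filter

Per database sequence, in order, short-circuiting on failure:

1. **Words** (`enumerate_words()`): every 4-mer anchored at model
   position `k ∈ [0, M−4]` whose summed match emission score exceeds θ
   — strictly, following "above a threshold" semantics; boundary
   behavior is unit-tested.  Words are anchored: the same string at
   another position is a different word, because extension needs the
   diagonal.  The scanner is a table-driven DFA over 4-mer codes
   (`word_automaton()`, `scan_words()`).
2. **Extension** (`extend_word_hit()`): ungapped, along the diagonal,
   summing match emission scores only (no transitions); each side stops
   when the running score falls δ/2 below the best seen, keeping the
   best endpoint.  Hits must score strictly above μ to qualify
   (`qualify_hits()`), and overlapping same-diagonal hits are merged,
   keeping the best — otherwise two overlapping words from one ungapped
   segment would satisfy the two-hit rule by themselves.  Merging is a
   flag (`merge_overlaps`) since the alternative (count distinct word
   occurrences) is defensible too.
3. **Two-hit rule** (`two_hit()`): at least two qualified hits.
4. **Window gate** (`window_gate()`): windowed Viterbi over the
   inclusive span of all qualified hits, in both coordinates, must
   strictly exceed η.  With more than two hits we span them all — the
   conservative reading that can only enlarge the window and therefore
   never lose a domain the hits delimit.  The span includes the hits
   rather than only the gap between them, again the choice that cannot
   miss.

Thresholds are in bits; `-Inf` disables a stage.  Models with `M < 4`
have no words, so they bypass the filter entirely rather than silently
discarding everything.  Defaults θ=6, δ=2, μ=7, η=20 are the tuned
operating point for models built at default settings; `filter_params()`
exposes them, and sweep code may pass arbitrary lists.

The contract that matters: the filter selects, it never rescores.
`hmm_search()` recomputes each survivor's score with the requested final
algorithm, so filtered-in hits are bit-for-bit identical to an
unfiltered run — the suite asserts exact equality on a 500-sequence
synthetic database, along with threshold monotonicity (raising θ, μ, or
η never grows the passed set; raising δ never shrinks it).

## E-value calibration

`calibrate_profile()` scores `n` random background sequences (default
2000; lengths normal with mean 325, sd 200, clamped at 50 — a
conventional protein length model, chosen because per-sequence maxima
over realistic lengths are what search encounters), fits a Gumbel by
maximum likelihood, and stores
`(μ̂, λ)`.  E-values are `E = N·(1 − exp(−exp(−λ(s − μ̂))))`.

The fit is **left-censored at the sample median** by default: scores
below the censor point enter the likelihood only as censoring mass.  The
bulk of a local-alignment score distribution is not Gumbel, and an
uncensored fit lets the bulk drag λ upward, producing conservative
E-values an order of magnitude off in the tail that searches actually
use.  Censored fitting anchors λ on the tail (empirically close to the
theoretical ln 2 per bit for Viterbi) and makes calibration *honest*:
the suite's pooled check over 20 models × 5000 fresh decoys finds the
number of hits at E ≤ e within Poisson 3σ of e.  `censor_frac = 0`
recovers the plain fit.  The λ equation is solved by Newton iteration on
the profile likelihood (tolerance 1e-6), location in closed form.

**Forward scores** are calibrated with the same Gumbel machinery.  That
is an approximation, and a visible one: the Forward null tail decays
slower than any single Gumbel fitted from 2000 samples, so Forward
E-values in the far tail run a few-fold anti-conservative.
Exponential-tail Forward statistics are deliberately out of scope;
consumers who need calibrated significance should use Viterbi scoring,
and the iterative search does.

## Iterative search

`jackhmmer(query, db)`:

1. Initial members: single-sequence model of the query, calibrated,
   filtered Viterbi search; targets with E < 1e-3 are admitted as the
   subsequences covered by their alignment envelopes.  (An internal
   scorer plays the role a fast pairwise pre-search would; it keeps the
   package self-contained and the envelope semantics identical across
   iterations.)
2. Loop, at most `max_iter` (default 7) times: align all members to the
   current model by Viterbi traceback (match states become uppercase
   columns, insertions lowercase `.`-padded columns), rebuild with
   `build_profile()`, recalibrate, search, admit targets with E-value
   strictly below the iteration's scheduled cutoff
   (`1e-5, 1e-5, 1e-4, 3e-4, 3e-4, ...`, last value repeated).  The
   loosening schedule is what lets genuinely remote members enter at
   later iterations once the model has absorbed intermediates.
3. Stop when no new member appears.  Members are never dropped (E-values
   of early members can fluctuate across rebuilds; dropping would let
   the member set oscillate), and a target keeps its first envelope.

The final model is rebuilt from the final alignment and calibrated for
Forward scoring — and additionally for Viterbi, so downstream decoy
screening can use the honestly-calibrated statistic.

## Synthetic families and the decoy benchmark

`generate_family()` draws an ancestor i.i.d. from the background (or
accepts one, which is how nested subfamilies at controlled divergence
are built), then derives members by per-site substitution — replacements
drawn *from the background*, so expected identity is analytic — and
geometric indels (mean 1.5, cap 10; enough to exercise the D/I states
without destroying detectability), embedding each member in random
background flanks.  The true core alignment is recorded.  Defaults (120
residues, 20 members, 15% substitution, 1% indel, flanks 0–30) mirror a
compact single-domain protein family of realistic diversity.

What this emulates — and what it does not: members are conditionally
independent given one ancestor; there is no phylogenetic correlation,
no rate variation across sites, no compositional bias, and decoys are
uniform permutations (composition-preserved, order-destroyed) rather
than biologically confusable non-homologs.  Passing the suite therefore
shows the machinery is correct and calibrated on clean conditions, not
that sensitivity numbers transfer to curated structural benchmarks.

`make_test_db()` pools families with shuffled decoys and labels ordered
(query, target) pairs: same family = true homolog, decoy = false hit,
cross-family = ambiguous.  Ambiguous pairs count toward neither truth
class — the decoy-only definition of a false positive avoids ever
mislabeling an unannotated real relationship as an error.  Benchmark
statistics pool hits across queries under one global E-value threshold
(`tp_vs_epq()`, `min_error_rate()`), ties collapse to one threshold
step, and one best hit per (query, target) pair is kept.
`bootstrap_diff()` resamples the query set with replacement and takes
the middle `conf × reps` order statistics of the per-replicate TP
difference.

## Numerical choices and degenerate inputs

* Forward accumulates `log2(2^a + 2^b)` via the shifted form; `-Inf`
  short-circuits.
* Gumbel Newton iterations shift by the sample maximum before
  exponentiating; a non-positive λ step falls back to halving.
* Degenerate calibration samples (all scores equal) and samples under
  100 scores are errors, as are empty windows, empty FASTA records,
  ragged alignments, and alignments with zero match columns.
* Equal-scoring Viterbi paths resolve by fixed state priority; equal
  extended-hit scores resolve to the earlier sequence start.

## Problem sizes in the checks

The suite and acceptance script run, by choice, at desk scale: oracle
equivalence on models with M ≤ 3 against all sequences of length ≤ 4
over a 4-letter alphabet; word enumeration against full 20⁴ brute force
at M = 6; 1000 random extension triples; a 500-sequence database for
the score-identity contract; an 81-point threshold grid; calibration
honesty pooled over 20 models × 5000 decoys; and families of 8–25
members for the sensitivity and iteration studies.  These sizes make
every number recomputable in minutes while keeping the statistical
assertions (Poisson 3σ, retention ≥ 95%, zero admitted decoys)
meaningful.

## Known limitations

* Single-domain architecture: no looping re-entry state, so multiple
  domain hits in one target are reported as one best envelope.
* Forward E-values are approximate (above); Viterbi's are calibrated.
* The entropy-weighting target (1.3 bits) is a convention, not a fit to
  any corpus; change `relent_target` when emulating sharper or softer
  model builds.
* Uniform-permutation decoys do not model compositional bias, the
  hardest confounder in real databases.
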