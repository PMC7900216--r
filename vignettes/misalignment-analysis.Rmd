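---
title: "Misalignment-length analysis of mtDNA deletion breakpoints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Misalignment-length analysis of mtDNA deletion breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

Mitochondrial DNA deletions are flanked by a 5' breakpoint (on the L-strand
side that is retained) and a 3' breakpoint.  A long-standing mechanistic
question is how long the DNA-DNA misalignment (hybridization of L-strand and
H-strand segments at non-allelic positions) that mediates a deletion is:
non-homologous end joining operates with 0-5 nt of homology, micro-homology
mediated end joining with up to ~25 nt, and recombination-like pathways with
much longer tracts.  `mtMisalign` infers, for a catalog of deletions, the
fraction attributable to each misalignment length on a grid of lengths
`l = 0, 5, 10, 15, 20, 25, 50, 75, 100` nt, where `l = 0` is a
hybridization-independent (uniform) component.

For one deletion with breakpoints `(p5, p3)` the package:

1. extracts a `2W+1 = 201`-nt L-strand window centered on `p5` and a 201-nt
   H-strand window centered on `p3` (the H-strand is the reverse complement
   of the deposited reference; both windows are read from the circular
   genome);
2. for every position pair `(i, j)` in the `201 x 201` window of analysis and
   every length `l`, sums the hybridization partition function `Z` over the
   `l x l` duplexes - one l-mer from each strand - that overlap the pair
   (segments may extend past the window edge; they are read from the genome,
   not truncated);
3. tiles the window with `b x b = 10 x 10`-nt bins covering offsets
   `-W .. W-1` (20 x 20 = 400 bins; the single offset `+W` is dropped because
   201 is not divisible by 10) and normalizes the bin sums to the *relative
   bin propensity*; the entry of interest is the bin containing the
   breakpoint, `p_l`, with `p_0 = 1/400` fixed for the uniform component;
4. models the per-deletion likelihood as the mixture
   `sum_l theta_l p_(i,l)` and estimates the simplex weights `theta` by
   maximum likelihood over the whole catalog.  `theta_l` is read as the
   fraction of deletions associated with l-nt misalignments, reported also as
   grouped sums: short (0-5 nt), medium (10-25 nt), long (>= 50 nt).

## The thermodynamic ensemble

`duplex_partition_function()` computes
`Z = sum over configurations exp(-dG/RT)` for two strands under a fixed
admissibility grammar: antiparallel intermolecular duplexes only, non-crossing
base pairs organized into helices of stacked pairs.  A stack is either a
Watson-Crick/Watson-Crick nearest-neighbor doublet or a tabulated isolated
internal single mismatch (mismatches must be flanked by WC pairs, so helices
have WC termini and every helix has at least two pairs - a lone pair has no
nearest-neighbor energy).  Helices are separated by internal loops or bulges
of total unpaired size `s`, scored by a Jacobson-Stockmayer penalty
`dG_loop(s) = a + b log(s)` with `a = 2.4`, `b = 1.3` kcal/mol and a maximum
size of 30 nt.  Each configuration pays one duplex-initiation penalty
(1.937 kcal/mol) plus 0.060 kcal/mol per A.T-closing end; the unhybridized
state is excluded (`Z = 0` when no configuration exists, e.g. no WC pair
anywhere).  Positions pairing with `N` are unpairable.

Parameters live in a plain-text packaged table
(`inst/extdata/nn_unified_dna37.tsv`): the unified WC dG37 set and published
internal single-mismatch contexts at 37 C and 1 M NaCl, without salt
correction.  The loop coefficients are a compromise between the published
bulge scale (~4.0 kcal/mol at size 1) and internal-loop scale (~3.2 at size
3); they and the temperature are configurable fields of the
`NNParameterSet`.  Because the downstream analysis uses propensities
*relative* to the surrounding window, the mixture weights are insensitive to
the absolute energy scale; they can shift with the relative WC/mismatch/loop
balance, which is why the parameter table is packaged, documented and
swappable.

The dynamic program runs over cells `(i, k)` with three states (first pair of
a helix; helix with >= 2 pairs ending WC; helix ending in an internal
mismatch) and uses per-diagonal prefix sums for the loop transition, giving
`O(n m maxloop)` per duplex.  Its independent oracle,
`enumerate_configurations()`, exhaustively lists admissible configurations by
depth-first search and must agree with the DP to a relative 1e-9 (tested on
hundreds of random pairs, and exposed to users via `run_validate()`).  Energies
use `R = 0.0019872` kcal/mol/K and `T = 310.15` K by default.

## Numerical organization

Naively each window requires ~`(2W + l)^2` duplex partition functions per
length.  `propensity_engine()` instead computes, once per length, the duplex
`Z` for every (L-start, H-start) pair over the union bounding box of all
requested windows and stores a summed-area table; a position-pair propensity
is then a constant-time box sum, and window maps, bin sums and profiles are
assembled from it.  This mirrors pre-computing partition functions over the
analyzed arc, and makes catalogs with overlapping windows (and bootstrap
replicates) cheap.  When the union box would exceed `max_cells` (default
4e6 cells per length) the engine falls back to per-breakpoint grids.
Summed-area subtraction can produce tiny negative box sums by cancellation;
these are clamped to zero.  An all-zero window (possible on pathological
input such as all-N sequence) falls back to the uniform bin distribution with
a warning so likelihoods stay finite.

## Fitting

`fit_mixture()` maximizes `sum_i log(sum_l theta_l P[i,l])` on the simplex by
EM (responsibilities `r_il = theta_l P_il / sum theta P`, update
`theta_l <- mean_i r_il`), uniform start, relative log-likelihood tolerance
1e-9, at most 10,000 iterations.  The objective is concave, so EM converges
to the global optimum; the uniform start is the documented tie-break on flat
ridges, and an optional multi-start mode (random Dirichlet starts) checks for
agreement.  Non-identifiability is flagged when the smallest eigenvalue of
the observed information on the simplex tangent space falls below 1e-8 of
the largest.  Neighboring grid lengths (e.g. 15 and 20 nt) have correlated
components, so per-length weights carry more uncertainty than the grouped
short/medium/long sums - the grouped sums are the primary readout.

`bootstrap_sd()` draws, for each original deletion, a length from the fitted
weights and then a bin within that deletion's own window with probability
equal to the relative bin propensity at that length; the breakpoint is placed
at the bin's first offset, so the resampled pair's own breakpoint bin is
exactly the drawn patch.  Each of the `B = 100` replicates is refit and the
sample standard deviation of the grouped weights is reported, matching how
error bars are usually drawn on grouped bars.  Whether the original analyses
drew their in-silico error-bar datasets from the fitted mixture or from a
null is not documented; the parametric choice here is an assumption and is
stated as such.

## What the simulator emulates

`synthetic_genome()` draws an i.i.d. circular genome at a requested GC
content (default 16,000 nt at GC 0.44, matching mammalian mtDNA composition)
with optional planted perfect repeats.  `simulate_breakpoints()` draws, per
deletion, a length from `theta_true` and then a candidate breakpoint pair
from a regular lattice (stride 10 nt, equal to the bin size, over two
candidate arcs - defaults 3001-3200 x 9001-9200 - so 5' and 3' breakpoints
are well separated, as in real deletions).

Two placement modes are provided because the choice matters:

* `"bin"` (default): the pair is drawn with probability proportional to
  `h(x) * q_l(x)`, where `q_l(x)` is the relative breakpoint-bin propensity
  of the pair's *own window* - the exact component the mixture model fits -
  and `h` is a shared base measure calibrated on the candidate lattice.
  The calibration matters: the mixture likelihood normalizes within each
  deletion's window, making it a pseudo-likelihood over positions, and its
  MLE is consistent only when every length component assigns the same total
  mass over the sampling space.  On candidate arcs that are small relative
  to the window (a necessity at validation scale), windows normalize over
  sequence the lattice does not cover, and the component integrals of the
  raw `q_l` differ several-fold across lengths - enough for EM to zero a
  30% component entirely.  `h` is therefore the maximum-entropy measure
  under which every simulated length integrates the fitted likelihood
  identically (and no other grid length integrates it more), obtained from
  a smooth convex dual.  With that construction, parameter recovery is a
  well-posed experiment: with n = 2000 deletions and
  `theta* = (0.2 @ l=0, 0.5 @ l=5, 0.3 @ l=20)` the fitted weights recover
  the truth to within a few percent per length (the acceptance suite
  requires max error <= 0.05).
* `"lattice"`: the pair is drawn proportional to its *raw* position-pair
  propensity, with no within-window normalization - the most literal
  reading of "breakpoints occur where misalignment is stable".  At desk
  scale every window shares the same hotspot bins, the within-window
  relative propensity of sampled pairs is typically *below* the uniform
  1/400, and the fit collapses toward the l = 0 component; on arcs tens of
  window-widths long (the full major arc) the two modes coincide, but that
  regime is beyond a desk-scale validation.  The lattice mode is retained
  for studying exactly this generative mismatch.

True lengths are emitted in a `true_l` side channel so evaluation never
re-infers them.  The simulator does not emulate sequencing error, PCR
artifacts, clonal expansion, or deletion-size distributions; passing tests
therefore show estimator correctness under the stated model, not robustness
to those real-data features.

## Sizes, defaults, and their rationale

* `W = 100` (201-nt windows), `b = 10`, grid `0..100` nt: the analysis
  conventions of the method.
* Candidate arcs of 200 nt with stride 10 (441 candidate pairs) keep the
  validation study's shared duplex grids near `(400 + l)^2` cells per length;
  the full nine-length study (simulate 2000 deletions, build grids, fit)
  runs in a few minutes on one CPU.  Unit tests use smaller windows
  (`W = 10..50`) and reduced grids; the vignette-scale defaults are stated in
  `simulation_spec()`.
* A planted perfect repeat is recovered by the profile argmax at its length
  for lengths up to ~2 bins (tested at 5 and 10 nt).  For a repeat much
  longer than the bin (e.g. 25 nt) the single perfect duplex overlaps
  position pairs across `~(2l/b)^2` bins, capping the breakpoint-bin share
  (near 0.15), so the argmax may sit at a shorter length even though `p_25`
  is an order of magnitude above uniform; tests assert the elevation rather
  than the argmax there.  Relatedly, a planted perfect *5-mer* is close to
  the chance level of random 5-mer matches in a 201-nt window - short
  perfect repeats are not thermodynamically distinctive, which is part of
  the method's motivation.

## Known limitations

* The exact thermodynamic parameterization of the original analyses is not
  public; absolute `Z` values here can differ by a model-dependent factor,
  which cancels in relative propensities but can shift per-length weights.
  Reproduction of published per-dataset grouped weights therefore requires
  the published compendium and reference genomes (not redistributable here)
  and should be read with the parameter-set configuration in mind.
* No salt/Mg correction, no intramolecular structure (hairpins,
  G-quadruplexes), no dangling ends, no pseudoknots.
* The mixture cannot separate mechanisms with similar misalignment lengths,
  and binning deliberately discards the orientation of the misalignment
  relative to the breakpoint.
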