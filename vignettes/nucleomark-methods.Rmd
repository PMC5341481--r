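---
title: "Position-specific Markov models of nucleosome affinity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific Markov models of nucleosome affinity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomark)
```

## The problem

A nucleosome wraps 147 bp of DNA around the histone octamer, and different
sequences wrap at very different energetic cost.  The space of 147-bp
sequences holds $4^{147} \approx 3.2\times10^{88}$ members, so the affinity
function cannot be tabulated; it must be parameterised.  A widely used
parameterisation treats the nucleosomal sequence as a *position-specific
Markov chain*: the probability of the base at position $n$ depends only on
the $m$ preceding bases, with probabilities that change along the wrap
(the ~10-bp helical phasing of the superhelix makes position matter).

`nucleomark` implements this model family, the conversion from sequence
probability to free energy, genome-scale energy-landscape scanning, and a
benchmarking framework that measures how well the Markov approximation
reproduces a ground-truth energy model.  Because real training ensembles
(in-vitro nucleosome maps) confound DNA mechanics with experimental bias,
the ground truth here is a deliberately tractable biophysical stand-in —
the "toy" nucleosome model — for which every quantity of interest has a
closed form.

## The Markov model

For a window $S = S_1 \dots S_L$ ($L = 147$) and order $m$, the model is

$$
P(S) \;=\; \frac{\prod_{n=m+1}^{L} P_n\!\big(S_{n-m} \cap \dots \cap S_n\big)}
               {\prod_{n=m+1}^{L-1} P_n\!\big(S_{n-m} \cap \dots \cap S_{n-1}\big)},
$$

the joint/marginal rewriting of the chain rule under the order-$m$
assumption.  Order 0 reduces to a product of position-specific
mononucleotide probabilities; order 1 is the classic dinucleotide model;
order 2 the trinucleotide extension.  The numerator $(m{+}1)$-mer tables
are counted from a training ensemble of aligned 147-bp sequences
(`count_oligos()`); the denominator $m$-mer tables are **derived by exact
marginalization** of the numerator tables (`marginalize_last()`), never
recounted, so numerator and denominator can never disagree about the same
marginal.  All evaluation is in natural-log space (147 factors would
underflow otherwise); the free energy is $F(S) = -kT\,\log P(S)$ with an
unknown additive constant, so only differences between sequences are
meaningful.

Internally `markov_fit()` precomputes, once, a per-position *conditional*
log-probability matrix with the zero-probability policy already applied;
scoring a sequence or a genome window is then pure table lookup, which is
what makes landscape scans of megabase genomes cheap.

### Zero-probability policies

A $(m{+}1)$-mer never observed at some position leaves a zero in the table,
and a single zero factor would annihilate $P(S)$ for every sequence
carrying it.  Three policies are provided:

* `flat_quarter` — substitute the affected *conditional* factor with the
  information-free value 0.25 (the affected position contributes
  $\log 0.25$ regardless of context).  This treats a zero as "the ensemble
  carries no information here", not as "this sequence is impossible".
* `smoothed` — intended together with `smooth = TRUE`, which replaces each
  probability by the average over positions $n-1, n, n+1$ (the 3-bp
  positional smoothing used by models trained on experimental maps whose
  positional resolution is limited); residual zeros that survive smoothing
  still fall back to 0.25.
* `strict` — raise an "ensemble failure" error naming the position and
  k-mer.

The policy slot only decides what happens *when a required probability is
zero*; whether tables are smoothed is a separate fit-time choice.  When the
tables are strictly positive no policy ever fires and all three give
bit-identical scores — the test suite asserts this.

Two open choices were resolved as follows.  Boundary positions of the 3-bp
smoothing average over the two available neighbours (the interior rule
truncated), and smoothed rows are renormalized to sum to one; both choices
are recorded in the table metadata.  Training ensembles are used as given,
with no reverse-complement symmetrization by default: the sampler that
generates them does not impose strand symmetry, and silently symmetrizing
would hide that property of the data.

## The toy nucleosome model

The ground-truth model assigns one angle $\theta_n$ to each of the
$L-1$ base-pair steps and the energy

$$
E(S, \theta) = \sum_n \tfrac12 K(d_n)\,(\theta_n - \theta_0(d_n))^2
             + \tfrac12 \kappa\,(\theta_n - c_n)^2
             + \sum_n \tfrac12 \lambda\,(\theta_{n+1} - \theta_n)^2 ,
$$

with $d_n$ the dinucleotide at step $n$.  It is a one-degree-of-freedom
caricature of rigid-base-pair DNA mechanics: dinucleotide-dependent
stiffness $K$ and intrinsic angle $\theta_0$, a harmonic constraint of
stiffness $\kappa$ pulling each step towards the histone-imposed periodic
profile $c_n = A\cos(2\pi n/p + \phi)$ with $p = 10$ bp, and an optional
nearest-step coupling $\lambda$.  The shipped defaults (16 $K$ values
log-uniform in 5–50 $kT_{\mathrm{room}}$/angle², $\theta_0$ in $\pm 0.3$,
$\kappa = 20$, $A = 0.2$, $\lambda = 0$, drawn once and frozen in
`inst/extdata/toy_default_params.json`) were chosen so that landscapes show
the ~10-bp periodic, sequence-dependent structure characteristic of real
nucleosome energy landscapes while every oracle below stays exact.

Energies are expressed in units of room-temperature $kT$; the default
working inverse temperature is $\beta = 6$, i.e. sampling at **1/6 of room
temperature**, the convention under which probability-based nucleosome
models are compared with biophysical ones (some finite temperature is
needed for the statistical machinery; low temperature sharpens sequence
preferences).

Because $E$ is quadratic in $\theta$, everything is Gaussian:

* `exact_free_energy()` — $F(S) = E(\theta^*) - \tfrac{kT}{2}\big[(L-1)\log(2\pi kT) - \log\det M\big]$
  with $M$ tridiagonal and $\theta^* = M^{-1}b$, evaluated by an
  $O(L)$ LDL$^\mathsf{T}$ factorization in compiled code;
* `exact_mean_energy()` — equipartition: $\langle E\rangle_S = E(\theta^*) + (L-1)kT/2$;
* `toy_step_free_energies()` — for $\lambda = 0$ the free energy
  decomposes into per-step terms
  $f_n(d) = \tfrac12 K_{\mathrm{eff}}(d)(\theta_0(d) - c_n)^2 + \tfrac{kT}{2}\log\frac{K(d)+\kappa}{2\pi kT}$,
  $K_{\mathrm{eff}} = K\kappa/(K+\kappa)$;
* `transfer_matrix_marginals()` — with $\lambda = 0$ the sequence
  distribution $P(S) \propto \prod_n e^{-\beta f_n(d_n)}$ is an
  inhomogeneous nearest-neighbour Markov field, whose exact
  position-specific k-mer marginals follow from forward–backward products
  of $4\times4$ transfer matrices.

The last point is the central correctness lever: **for $\lambda = 0$ the
order-1 Markov model built from the exact marginals reproduces the toy
model's sequence distribution exactly** (a nearest-neighbour Markov field
*is* an inhomogeneous order-1 chain).  The test suite verifies this to
$10^{-8}$ over all $4^8$ sequences at window length 8 — the same structural
reason the dinucleotide model approximates nearest-neighbour-dominated
biophysical models well.  With $\lambda > 0$ correlations extend beyond
nearest neighbours and no finite-order model is exact, which is what makes
the $\lambda > 0$ setting the interesting benchmark.

## Mutation Monte Carlo

Training ensembles are generated by a Metropolis chain over the joint
(sequence, configuration) space: elementary moves are either a spatial
perturbation of one angle (uniform in $\pm\delta$) or the mutation of one
base to a uniformly chosen alternative, selected with probability
`mutation_fraction`.  Both proposals are symmetric, so detailed balance
with respect to $e^{-\beta E(S,\theta)}$ holds by construction; recording
sequences marginalizes the angles and samples $P(S)$.

The chain's burn-in, thinning and move mix are not dictated by theory;
they were *convergence-tested against the transfer-matrix oracle*: with the
defaults (one sweep = $L$ moves, 200 burn-in sweeps, thinning 10 sweeps,
mutation fraction 0.5, $\delta = 0.15$), the position-specific mono- and
dinucleotide frequencies of $10^5$ samples agree with the exact marginals
within 4-sigma binomial bounds for well over 95% of cells.  The samplers
use their own explicitly seeded mt19937 stream (raw 32-bit draws scaled by
hand, no implementation-defined distribution objects), so ensembles are
bit-reproducible across platforms and independent of R's RNG state.

## Landscapes and the benchmark

`compute_landscape()` scores every 147-bp window of a genome (windows
containing `N` are excluded and their starts recorded).  Coordinates are
0-based half-open, and the landscape position of a window is its start
(the dyad sits at start + 73; the benchmark only needs consistent
indexing).  Landscapes carry unknown offsets, so `normalize_landscape()`
applies the Boltzmann normalization over the scored window set —
$\sum_w e^{-v_w/kT} = 1$ — a pure additive shift, idempotent, after which
landscapes from different models are directly comparable.  Each landscape
is normalized with its own $kT$, both sides at the working temperature.

The benchmark separates three aspects of prediction quality:

* **full signal** — RMSD between normalized landscapes;
* **local average** — RMSD after an 11-bp centered running average
  (about one helical period), capturing the slowly varying overall
  affinity; positions without full support are trimmed (5 at each end) —
  the edge rule is this package's choice and is recorded in the output;
* **periodic component** — full minus local average, the ~10-bp
  oscillation whose frequency and phase any useful model must get right.

Each RMSD is expressed relative to an information-free "bad model": a
Boltzmann-normalized uniform landscape for the full and averaged signals
(it becomes the constant $kT\log N$), and, for the periodic component —
where a uniform landscape would still be "right" twice per period — the
reference's own periodic signal shifted by half a period
($\mathrm{round}(10/2) = 5$ bp) to push it out of phase.  Comparisons are
always restricted to the positions both landscapes share, so edge-trimming
and N-masking cannot misalign signals.  Whether percentages should be
computed on normalized or mean-centered signals is not uniquely
determined; the Boltzmann normalization is used throughout, consistently
for models and baselines.

## Problem sizes and what the tests show

The package's own acceptance experiments run at desk scale, chosen so each
oracle stays exact or statistically sharp:

* exactness and telescoping checks enumerate all $4^8$ sequences at window
  length 8;
* sampler checks use $10^5$ MMC samples at window length 20 against the
  transfer matrix, and 10 plain-MC mean energies of $3\times10^4$ recorded
  samples each against equipartition (3 standard errors, batch-means SE);
* the benchmark experiment uses the full 147-bp window, a 5-kb random
  genome (~4850 windows), $\lambda = 20$ and a $3\times10^5$-sequence MMC
  ensemble, repeated over three seeds.

$\lambda = 20$ (comparable to the smaller stiffnesses $K$) makes
beyond-nearest-neighbour correlations strong enough that model order
genuinely matters.  Under these conditions the landscape RMSD decreases
strictly from the mono- to the di- to the trinucleotide model.  The
ensemble size matters for that ordering: pilot runs showed that below
$\sim10^5$ sequences the trinucleotide model's sampling noise (and its
zero-probability substitutions on rare contexts of the uniform random
genome) can outweigh its smaller correlation bias, so the ordering only
stabilises for ensembles of a few $10^5$ sequences — mirroring the
crossover scale reported for experimentally sized ensembles, where the
trinucleotide description pays off only from several $10^5$ sequences.

What these tests do **not** show: the toy model is not a parameterised
biophysical nucleosome model (one angle per step, no 6-dof base-pair
mechanics, no unwrapping), the random genomes carry none of the
composition biases of real chromosomes, and the MMC ensembles are ideal —
no experimental noise, no duplicate reads, no strand or protocol bias.
Benchmark percentages here calibrate the *approximation error of the
Markov family relative to a known ground truth*, not the error to be
expected on any particular organism.

## Numerical choices and degenerate inputs

* Probabilities are evaluated in log space; $kT$ multiplies only at the
  boundary (`free_energy`, landscapes).
* The marginal table derived at fit time satisfies
  joint-marginalized-over-last-base exactly; per-position table rows must
  sum to 1 within $10^{-9}$ or construction fails.
* The $0/0$ conditional (context marginal also zero) is information-free
  and yields 0.25 under the flat policy; an unseen *leading* $m$-mer
  contributes $(1/4)^m$.
* Tridiagonal $M$ is positive definite whenever all $K > 0$ or
  $\kappa > 0$; the constructor enforces $K > 0$.
* Landscapes require strictly increasing positions and finite values;
  `local_average()` refuses fewer than 11 points; running averages are
  index-based, so landscapes with N-gaps should be decomposed per
  contiguous block if sub-bp alignment matters.
* `simulate()` from a fitted model renormalizes conditionals from the
  joint row; an all-zero context row falls back to a uniform draw.

## Reproducing the benchmark

`scripts/acceptance.R --seed 1 --out results/acceptance.json` reruns the
whole chain — oracles, sampler checks, the $\lambda = 20$ pipeline and the
size sweep — from scratch against the installed package and writes the
resulting numbers as JSON; the README describes each reported quantity.
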