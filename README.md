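# nucleomark

Position-specific Markov models of nucleosome–DNA affinity, with a
tractable biophysical ground truth to benchmark them against.

## The problem

Nucleosomes — 147 bp of DNA wrapped around a histone octamer — bind
different sequences with very different affinity, and these preferences
shape chromatin organisation.  With $4^{147} \approx 3.2\times10^{88}$
possible wrapped sequences, affinity must be modelled, not tabulated.  The
standard bioinformatic approach treats a nucleosomal sequence as a
position-specific Markov chain of order $m$:

$$
P(S) = \frac{\prod_{n=m+1}^{147} P_n(S_{n-m}\cap\dots\cap S_n)}
            {\prod_{n=m+1}^{146} P_n(S_{n-m}\cap\dots\cap S_{n-1})},
\qquad
F(S) = -kT \log P(S),
$$

with position-specific $(m{+}1)$-mer probabilities counted from an
ensemble of high-affinity sequences (order 0 = mononucleotide, 1 =
dinucleotide, 2 = trinucleotide model).  Such models are fast enough to
score every 147-bp window of a genome, but how accurate are they?  Testing
them against experimental maps conflates model error with experimental
bias.  `nucleomark` instead benchmarks them against a quadratic "toy"
nucleosome model — dinucleotide-dependent step stiffness plus a ~10-bp
periodic constraint — whose free energies, thermal mean energies and
sequence marginals all have closed forms, and which can generate training
ensembles of any size by Mutation Monte Carlo (MMC: Metropolis moves in
the joint space of sequence and conformation, so that recorded sequences
sample the Boltzmann sequence distribution).

The package is for computational biologists who fit or use
oligonucleotide nucleosome-affinity models and want to know how model
order, training-ensemble size, probability smoothing and
zero-probability handling affect landscape accuracy.

## Worked example

Generate a training ensemble from the toy model, fit the dinucleotide
model, scan a genome and benchmark against the exact landscape:

```r
library(nucleomark)

toy <- toy_nucleosome_model(window_length = 40, lambda = 5)
ens <- mmc_sample(toy, mmc_config(n_samples = 20000, seed = 1), as = "matrix")

fit <- markov_fit(ens, order = 1, kT = toy$kT)
fit
#> Position-specific Markov model, order 1 (dinucleotide)
#>   window length: 40 bp; trained on 20000 sequences
#>   zero policy: flat_quarter

genome <- random_genome(2000, seed = 2)
approx <- normalize_landscape(compute_landscape(genome, fit))
exact  <- normalize_landscape(compute_landscape(genome, toy, what = "mean_energy"))
benchmark_model(approx, exact)
#> Benchmark report [markov-order-1] (1961 windows)
#>   full      RMSD   0.2188 kT   bad   2.7496 kT   rel    8.0%
#>   average   RMSD   0.1916 kT   bad   2.5846 kT   rel    7.4%
#>   periodic  RMSD   0.1032 kT   bad   1.9328 kT   rel    5.3%
```

Reading the report: the dinucleotide model reproduces the exact landscape
with a full-signal RMSD of 0.22 kT — 8% of the scale set by an
information-free uniform landscape ("bad" model) — and captures both the
slowly varying affinity (7.4% of its baseline) and the ~10-bp periodic
component (5.3% of the out-of-phase baseline).  All energies are in units
of room-temperature kT; the toy
model works at 1/6 of room temperature (`beta = 6`), the convention for
comparing probability-based and biophysical nucleosome models.

A command-line interface mirrors the R API (`simulate`, `train`, `score`,
`landscape`, `benchmark`, `sweep`, `demo`); after installation:

```sh
Rscript exec/nucleomark simulate --n 10000 --seed 1 --out ensemble.fasta
Rscript exec/nucleomark train --order 1 --in ensemble.fasta --out model/
Rscript exec/nucleomark score --model model/ --in seqs.fasta --out scores.tsv
```

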