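# petmix

Bayesian truncated-Poisson mixture modelling of ChIA-PET chromatin
interactions.

ChIA-PET (chromatin interaction analysis by paired-end tag sequencing)
detects protein-mediated chromatin loops genome-wide, but its
cluster-level output mixes true loops with random-ligation noise, and the
noise rate varies systematically with genomic distance, local enrichment,
GC content and mappability. petmix is for analysts holding cluster-level
ChIA-PET output (anchor pairs plus inter-ligation PET counts) who want
statistically calibrated significant-interaction calls with those biases
corrected.

## The model

The PET count `y_i` of anchor pair `i`, conditioned on `y_i >= k`
(default `k = 2`), follows a two-component mixture of
(k-1)-truncated Poisson distributions:

    y_i ~ (1 - W_1i) * p_T(y | lam0_i, k) + W_1i * p_T(y | lam1_i, k)

    log(lam0_i) = b0 + b1*log(enr_i) + b2*log(gc_i)
                + b3*log(map_i) + b4*log(dis_i)        (intrachromosomal)
    lam1_i = lam0_i + C,  C > 0

with priors `b_j ~ N(0, 3^2)`, `C` half-normal `N(0, 3^2)` on the
positive axis, and `W_1i ~ Beta(mc_i, mean(mc))` driven by the pair's
marginal PET count `mc_i = mc_A + mc_B - y_i`, so hub anchors are more
credible a priori. Interchromosomal pairs are fitted separately without
the distance term. A pair is significant when its posterior signal
probability `P(Z_i = 1 | Y)` exceeds 0.5. Inference is adaptive
Metropolis-within-Gibbs MCMC (conjugate Gibbs draws for the weights),
gated on split-Rhat < 1.05 over every parameter. Validation tooling
includes posterior predictive checks and aggregate peak analysis (APA)
with the peak-to-lower-left (P2LL) score. See
`vignettes/mixture-model.Rmd` for the full account.

## Worked example

Simulate a dataset from the model's own generative process (so the truth
is known), fit it, and extract significant interactions:

```r
library(petmix)

sds <- generate_dataset(simulation_config(n_pairs = 300, seed = 3))
fit <- fit_interactions(sds$dataset,
                        mcmc_config(chains = 4, warmup = 300, iter = 300,
                                    seed = 11))
fit
#> <pet_fit> 300 pairs, 100 signal / 200 noise, max Rhat 1.024 (converged)

mean((fit$labels == "signal") == (sds$true_labels == 1))
#> [1] 0.9233333

sig <- significant_interactions(fit, sds$dataset, min_count = 3)
nrow(sig)
#> [1] 100
```

Of the 300 simulated pairs, 100 exceed the 0.5 posterior-signal
threshold, recovering 92% of the true labels — close to the exact-Bayes
limit for this noise level — and all of them also clear the >= 3 PET
reporting filter (called loops are rarely that weak). Every parameter's split-Rhat sits below the 1.05
convergence gate; had it not, `significant_interactions()` would refuse
to emit calls. The `credible_intervals()` accessor returns posterior
means and central 95% intervals for the link coefficients and the signal
offset `C`.

The same pipeline runs from the shell over BEDPE/BED/bedGraph/FASTA
inputs. The launcher installs with the package — put it on your PATH
with, e.g.,
`alias petmix="$(Rscript -e 'cat(system.file("exec","petmix",package="petmix"))')"`:

```sh
petmix simulate --out fixtures --n-pairs 200 --seed 1
petmix run --interactions fixtures/clusters.bedpe \
           --self-ligation fixtures/self_ligation.bed \
           --genome fixtures/genome.fa \
           --mappability fixtures/mappability.bedgraph \
           --out results --seed 1
```

`run` writes `annotated.tsv` (pairs + covariates), per-class
`results_intra.tsv` / `results_inter.tsv` (covariates, marginal counts,
responsibilities to 6 decimals, labels) with a `.meta.json` provenance
sidecar, and `significant_*.bedpe` holding signal-labelled pairs with at
least 3 supporting PETs (the reporting convention; the model itself is
fitted on all pairs with `y >= 2`).

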