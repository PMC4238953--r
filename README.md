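# metabonet

Hierarchical mixed-membership modelling of community metabolic networks.

Shotgun metagenomes can be summarized as per-sample counts of metabolic
*reactions* (e.g. via EC-number annotation against a KEGG-style reaction
catalog). `metabonet` decomposes such reaction-abundance tables into latent
community-level metabolic phenotypes, without reference to pre-defined
pathways:

* each **sample** n is a mixture of K **metabosystems** with weights
  θ<sub>n</sub> ~ Dirichlet(α<sub>θ</sub>);
* each **metabosystem** k is a mixture of L **subnetworks** with weights
  φ<sub>k</sub> ~ Dirichlet(α<sub>φ</sub>);
* each **subnetwork** l carries a substrate distribution δ<sub>l</sub> and a
  product distribution γ<sub>l</sub> over the C catalog compounds
  (Dirichlet(α<sub>δ</sub>), Dirichlet(α<sub>γ</sub>)).

Every reaction instance ("token") in a sample draws a metabosystem
Z ~ Cat(θ<sub>n</sub>) and a subnetwork Y ~ Cat(φ<sub>Z</sub>); the reaction
hyper-edge is decomposed into its J substrate–product pairs, whose
substrates are drawn from δ<sub>Y</sub> and products from γ<sub>Y</sub> —
the pairs of one reaction are coupled through the single shared subnetwork
label. Inference is by collapsed Gibbs sampling over the per-token (Z, Y)
labels with θ, φ, δ, γ integrated out; the conditional for one token is the
product of the sample-level and metabosystem-level predictive terms with
exact Dirichlet-multinomial predictives (ascending-factorial form) for its
J substrate and J product slots. All four concentrations default to 0.01,
which favours sparse, interpretable mixtures.

On top of the sampler the package provides the standard downstream
summaries: posterior means of θ, φ, δ, γ, per-subnetwork reaction profiles,
metabosystem *reaction compositions* and their Jensen–Shannon divergence
(JSD) matrices across runs and L values, optimal component matching
(assignment problem) to resolve label switching, and extraction of
**principal** (φ<sub>kl</sub> > 2/L), **discriminatory** (absolute
log-ratio membership score ≥ log 2) and **core** subnetworks, plus
principal reactions (profile mass ≥ 2/R). A generative simulator with
recorded ground truth supports end-to-end validation.

## Worked example

Simulate a small dataset from the generative process, fit it with
deliberately misspecified concentrations, and inspect the decomposition:

```r
library(metabonet)

params <- sim_params(N = 12, C = 60, K = 3, L = 8, mean_reactions = 300,
                     alpha_theta_gen = 0.1, alpha_phi_gen = 0.1, seed = 42)
sim <- simulate_dataset(params)

spec <- model_spec(K = 3, L = 8, alpha = 0.01)
fit <- run_sampler(sim$dataset, sim$catalog, spec,
                   sampler_schedule(burn_in = 100, n_retained = 100, lag = 5,
                                    seed = 7))
summ <- summarize_posterior(fit, diagnose_switching = FALSE)
round(head(summ$theta_mean, 4), 3)
#>         M1    M2    M3
#> S001 0.221 0.567 0.212
#> S002 0.455 0.267 0.278
#> S003 0.150 0.003 0.846
#> S004 0.001 0.000 0.999
```

Each row is one sample's posterior-mean metabosystem mixture: sample S004
is essentially pure metabosystem 3, S002 a genuine mixture. Comparing with
the simulation's ground truth after resolving the arbitrary component
labelling:

```r
perm <- match_components(t(sim$truth$theta_true), t(summ$theta_mean),
                         method = "l1")
mean(rowSums(abs(sim$truth$theta_true - summ$theta_mean[, perm])))
#> [1] 0.09966515
```

a mean per-sample L1 error of about 0.10 across the K = 3 weights, despite
fitting with α = 0.01 while the data were generated at α = 0.1. The
subnetwork structure:

```r
principal_subnetworks(summ$phi_mean)$union
#> [1] 2 4 6 8
core_subnetworks(summ$phi_mean)
#> named integer(0)
```

Four of the eight subnetworks carry more than twice the uniform weight
(2/L = 0.25) in at least one metabosystem; none is abundant in *every*
metabosystem here, so there is no core subnetwork in this small example.

The same pipeline is available from a shell:

```sh
metabonet simulate --out-dir sim --n-samples 40 --seed 1
metabonet fit --catalog sim/catalog.tsv --abundance sim/abundance.tsv \
              --k 3 --l 10 --pairing zip --seed 1 --out-dir fit
metabonet analyze --summary-dir fit --out-dir analysis
```

Every run writes a `manifest.json` recording all parameters and seeds.

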