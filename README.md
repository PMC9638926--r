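# nucleoidCCF

Chromosome fragmentation as a quantitative probe of bacterial nucleoid
structure.

## What this is for

When an *E. coli*-sized (~5 Mb) circular chromosome is shattered into ~50 kb
pieces, at least `L / 50 kb = 100` double-strand breaks have occurred. The
nucleoid is classically drawn as a rosette of ~50 large DNA loops (100 kb
each) anchored at a central protein scaffold. Those two numbers are in
tension with a third: precipitation assays recover only a few percent of the
broken DNA as nucleoid-free. This package is for researchers who want to
make that argument quantitative. It provides:

* **Break simulation** on a circular genome under four mechanisms: uniform
  random two-ended breaks, breaks targeted at scaffold attachments (loop
  bases), breaks at envelope attachments (loop apexes), and replication
  fork collapse;
* **In-silico PFGE and Southern probes**: partition of DNA mass into
  well / compression zone / fragmentation smear and origin/terminus probe
  signals per compartment;
* **A release model**: the expected nucleoid-free DNA fraction for `b`
  breaks against `a` attachments, by seeded Monte Carlo and by the closed
  form

  ```
  E[f_rel] = b (b − 1) / ((a + b)(a + b − 1)),   b ≥ 2
  ```

  (the probability that both special points flanking a random locus are
  cuts), verified in the test suite against a brute-force oracle;
* **Inference**: background subtraction, inversion of an observed release
  fraction into an attachment-count estimate with bootstrap CI, z-score
  scenario discrimination, first-order fitting of the ATP-dependent release
  phase `f(t) = f0 + A(1 − exp(−k t))`, and the transcription share
  `(Δ_full − Δ_rif) / Δ_full`;
* **A synthetic-data generator** reproducing the statistical structure of
  gel-quantified release tables (2% background, ~5% at 45 min of treatment,
  post-treatment ATP-dependent rise with a rifampicin-sensitive
  component), so the whole inference pipeline is testable offline.

## Worked example

```r
library(nucleoidCCF)
genome <- circular_genome()          # 5 Mb circle, ori at 0, ter opposite

estimate_dsb_count(5e4, genome)      # mean 50 kb fragments ...
#> [1] 100                           # ... imply >= 100 breaks
loop_size(genome, 50)                # the classical 50-loop rosette
#> [1] 1e+05                         # = 100 kb of DNA per loop

# what would a 50-attachment nucleoid release at 100 breaks?
expected_release_closed_form(50, 100)
#> [1] 0.442953                      # ~44% -- an order more than observed

# invert the observed ~3% net release instead:
invert_attachment_count(0.03, 100, sem = 0.01, rng_seed = 1)
#> <attachment_estimate> a_hat = 475 [345, 968] (b = 100, closed_form_inversion)

# three break-placement scenarios against a 50-loop rosette (10 apexes):
st <- scenario_table(genome, a = 50, b = 100, n_envelope = 10,
                     n_replicates = 1e4, rng_seed = 61)
sapply(st, function(p) p$released_fraction_mean)
#>            random scaffold_targeted envelope_targeted
#>         0.2381086         0.8000000         0.0000000

# first-order ATP-dependent release kinetics and transcription share:
fit_release_kinetics(data.frame(
  time_min = c(0, 15, 30, 45, 60),
  released_fraction = c(0.050, 0.095, 0.117, 0.128, 0.133)))
#> <kinetic_fit> f0 = 0.0500, A = 0.0882, k = 0.04766 /min
transcription_share(0.09, 0.03)
#> [1] 0.6666667                     # two-thirds transcription-driven
```

Reading: envelope-targeted breaks release nothing (every loop keeps its
base contact), scaffold-targeted breaks release most of the DNA, and random
breaks an intermediate amount — so a small observed release is consistent
only with random breaks against a much denser attachment set (~475 contacts)
than the classical rosette.

## Pipeline and CLI

```r
cfg <- read_run_config(system.file("extdata", "config_default.json",
                                   package = "nucleoidCCF"))
res <- run_pipeline(cfg)   # writes TSVs + summary.json + log to cfg$outdir
```

or from the shell:

```sh
Rscript -e 'nucleoidCCF::nucleoid_cli()' run --seed 1 --out results
Rscript -e 'nucleoidCCF::nucleoid_cli()' release --a 475 --b 100 --out results
```

Subcommands: `simulate-breaks`, `gel`, `release`, `infer`, `kinetics`,
`synth`, `run`.

## Layout

* `R/` — genome/attachment model, break models, gel + probe model, release
  model, inference, synthetic data, pipeline/CLI
* `tests/testthat/` — unit, property and acceptance tests (oracle-checked)
* `vignettes/nucleoid-release-model.Rmd` — model assumptions, parameter
  table, generator scope, numerical choices, limitations
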