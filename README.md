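# masc — mappability-sensitive cross-correlation

`masc` estimates the **mean DNA fragment length** of single-end short-read
sequencing experiments (ChIP-seq and similar), a quantity that peak
callers and browser-track read extension depend on but that single-end
data do not record.

## Who it is for

Anyone with single-end aligned reads in BED format who needs a reliable
fragment-length estimate — in particular for datasets where the classical
strand cross-correlation fails because of the **phantom peak** at the read
length.

## The statistic

Let `f(b)` and `g(b)` be binary indicators of read 5′-origins on the
positive and negative strands (a `+` read aligned to `[s, e)` credits
`f(s)`; a `-` read credits `g(e−1)`; duplicates are collapsed). The
fragment length is estimated as

    d̂ = argmax_d  r(d),    r(d) = Pearson correlation of f(b) and g(b+d)

searched over d = 0…500 by default. Unmappable genome positions force
*shared* structural zeros into `f` and `g` offset by R−1 (R = read
length), which inflates r(d) near the read length — the phantom peak.
The mappability-sensitive correlation (**MaSC**) computes r(d) only over
the *doubly-mappable* positions at each shift,

    DM_d = { b : b ∈ M_R  and  b + d − R + 1 ∈ M_R } ∩ chromosome bounds,

with per-shift means and variances over DM_d (binary profiles, so
σ² = μ(1−μ)). This removes the phantom and restores the fragment-length
peak. Two interchangeable backends are provided: sorted-interval lists
and packed 64-bit bit vectors (C++, shifted AND + popcount).

## Worked example

A simulated 1 Mb genome, 30% unmappable, weakly enriched — the regime
where the naive estimator breaks:

```r
library(masc)

params <- simulation_params(unmappable_fraction = 0.3,
                            enrichment_fraction = 0.1, seed = 1)
map <- simulate_mappability(params)
sim <- simulate_experiment(params, map)
true_mean_fragment_length(sim$fragments)
#> [1] 149.9953

profiles <- reads_to_profiles(sim$reads, c(chr1 = params$genome_size))
profiles
#> StrandProfiles: 1 chromosome(s), R = 36, 17183 +-origins, 17059 --origins, 576 duplicates removed

naive <- smooth_curve(naive_cross_correlation(profiles, 0, 500))
masc  <- smooth_curve(masc_cross_correlation(profiles, map, 0, 500))

estimate_fragment_length(naive, failure_threshold = 50)
#> Fragment length estimate: 44 bp [naive-approx, whole-genome, smoothed, range 0..500, peak r = 0.008795, FAILURE (below threshold)]
estimate_fragment_length(masc, failure_threshold = 50)
#> Fragment length estimate: 143 bp [masc, whole-genome, smoothed, range 0..500, peak r = 0.01073]
```

The naive curve peaks at 44 bp — at the phantom plateau near the 36 bp
read length, classified as a failure by the `< R + 14` rule — while MaSC
recovers 143 bp against a true mean of 150.0 bp. With strong enrichment
(`enrichment_fraction = 0.8`, fully mappable genome) both estimators land
within ~2 bp of the truth.

## Command line

```sh
Rscript exec/masc simulate --out-prefix sim --seed 7
Rscript exec/masc estimate --reads sim.reads.bed --map sim.map.bed \
    --method masc --scope wg --out-prefix run
```

`estimate` writes a raw+smoothed curve table (TSV), an estimate report
(raw and smoothed argmax, failure flag), and a JSON sidecar with the full
resolved configuration; `--scope bc` adds per-chromosome estimates with
mean ± 2SE and a failure percentage. Exit codes: 0 success, 1 usage
error, 2 data error.

## Package layout

* `R/` — I/O (BED6 reads, BED3/bedGraph mappability, TSV curve tables),
  strand profiles, both correlation backends, smoothing/estimation,
  simulator, CLI.
* `src/` — bit-vector kernel (Rcpp).
* `vignettes/fragment-length-estimation.Rmd` — model, assumptions,
  parameter choices, numerical decisions, simulator scope, limitations.
* `tests/testthat/` — unit, property and acceptance suites, including a
  brute-force positionwise oracle.
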