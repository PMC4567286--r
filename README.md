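# micropair

Do the two members of a breeding pair carry more similar microbial
communities than chance would produce? `micropair` implements the
downstream community analysis for small paired-host 16S amplicon surveys —
the setting where a handful of male–female pairs (often from more than one
colony) have been sampled at moderate sequencing depth and the question is
whether social partners share microbiota. It is aimed at molecular
ecologists who have an OTU count table, a rooted phylogeny of the OTUs and
per-sample metadata, and who want the standard diversity summaries plus
dedicated permutation tests of within-pair similarity that remain valid at
very small sample sizes.

## What it computes

**Alpha diversity** per sample: observed richness, Chao1
(`S_obs + F1²/(2·F2)`, bias-corrected `S_obs + F1(F1−1)/(2(F2+1))` when no
doubletons), Good's coverage `1 − F1/N`, Faith's phylogenetic diversity
(total branch length of the rooted subtree spanning the observed OTUs),
and rarefaction curves.

**Beta diversity** at a fixed rarefied depth (default 1,600 reads):
Hellinger distance (Euclidean on square-rooted proportions, bounded by
√2), and unweighted / weighted UniFrac.

**Aggregation** of each OTU across hosts via the corrected moment estimate
of the negative-binomial parameter k,

    k = (m² − s²/n) / (s² − m),

undefined for under- or equi-dispersed OTUs; small k means a highly
aggregated distribution (k > 20 is near-Poisson).

**Within-pair similarity**, tested two ways:

* *sample-centred*: the observed mean within-pair distance against a null
  of random male–female bijections;
* *OTU-centred*: for each OTU, the Spearman correlation r between male and
  female relative abundances across pairs; the observed statistic is the
  mean Fisher-z-transformed correlation, CORor = mean(atanh r), and the
  null reshuffles which male is paired with which female. Both tests
  report add-one permutation p-values, p = (1 + #extreme)/(B + 1), and a
  standardised effect size

        SES = (CORor − mean CORsim) / sd CORsim,

  where CORsim are the null realisations.

A synthetic paired-community generator (`simulate_paired_community()`)
with tunable within-pair correlation, zero inflation and colony structure
lets every stage run — and be tested — without any external data.

## Worked example

```r
library(micropair)

sim  <- simulate_paired_community(rho = 0.5, seed = 42)  # 7 pairs, 300 OTUs
prop <- relative_abundance(sim$table)
keep <- filter_otus(sim$table, min_individuals = 4, min_total_proportion = 0.001)

otu_centred_test(prop, sim$metadata, setdiff(names(keep), "sample_id"),
                 B = 1000, seed = 7)
#> <pair_perm_test> mean_fisher_z_spearman_within_pair
#>   observed = 0.31344  (null mean 0.0176637, sd 0.0603765 over 1000 permutations)
#>   SES = 4.899
#>   p (lower / upper / two-tailed) = 1 / 0.001998 / 0.003996
#>   units contributing: 146;  seed: 7
```

The observed mean Fisher-z correlation (0.313) sits far above the null
(0.018 ± 0.060): members of a pair share community structure, two-tailed
p ≈ 0.004 at B = 1000. The same dataset's aggregation summary shows the
strongly aggregated regime typical of host-associated communities:

```r
k_summary(k_table(keep))
#> # A tibble: 1 × 6
#>   n_otus n_defined n_undefined median_k   q1_k  q3_k
#> 1    148       148           0    0.119 0.0557 0.226
```

and the sample-centred test on rarefied Hellinger distances agrees
(within-pair distances smaller than random pairings):

```r
d <- hellinger_dist(rarefy(sim$table, 1600, seed = 8))
tidy(sample_centred_test(d, sim$metadata, B = 1000, seed = 9))
#>   statistic                  estimate null_mean null_sd   ses p_lower p_upper p.value
#> 1 mean_within_pair_hellinger     1.14      1.23  0.0284 -3.34 0.00300   0.998 0.00599
```

`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) chains
all stages — alpha, rarefied distances, k table, both permutation tests —
and writes TSV/JSON outputs plus a manifest recording seeds, the resolved
configuration and every warning (dropped samples, undefined correlations
or k estimates), so nothing is filtered silently.

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(null-distribution histograms, rarefaction curves, distance heatmaps).

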