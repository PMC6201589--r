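# siteMarkers

Attribution of microbiome samples to human body sites from 16S OTU count
tables — with biomarkers that are *directly* associated with a site rather
than riding along on microbe–microbe dependencies.

## The problem

Given an OTU table (counts of operational taxonomic units across samples)
and per-sample body-site and study labels, three questions recur in
microbial ecology and forensics:

1. **Which OTUs are genuine site biomarkers?** Univariate tests report every
   OTU whose presence correlates with a site, but many of those associations
   are *indirect*: an OTU may track a site only because it depends on
   another microbe that is endemic there. `siteMarkers` implements local
   causal discovery — semi-interleaved HITON-PC from the Generalized Local
   Learning (GLL) family — over conditional G-tests on the binarized table.
   An OTU X survives for site T only if no conditioning set **Z** of other
   admitted OTUs (|**Z**| ≤ max-k) makes it independent of the site
   indicator:

   G = 2·N·MI(X; T | **Z**),  compared against the χ² tail at
   df = (levels(X)−1)(levels(T)−1)·(#non-empty strata).

   Candidates enter through a Benjamini–Hochberg-screened univariate pass;
   surviving markers get a sign (+1 presence-associated / −1
   absence-associated, the sign of ad−bc in the 2×2 table), an NMI strength,
   and a prevalence.

2. **Can a site be detected inside a mixture?** Two-source mixtures are
   simulated by drawing n reads multinomially from
   p = (1−F)·p_target + F·p_background, with n the correspondingly weighted
   average of the parent depths. AUC gradients over mixture fractions
   quantify detection limits, and an F1-optimal decision-threshold table is
   fitted on mixed *training* samples (the classifier itself never trains on
   mixtures).

3. **How well can sites be classified across heterogeneous studies?** A
   probability Random Forest (ranger) is tuned by stratified nested
   cross-validation (macro-F1 objective; grid over tree count and
   mtry = {½, 1, 2}·√p), class-weighted against imbalance, and calibrated
   per class by isotonic regression on out-of-fold scores. Reports include
   per-class/macro F1, study-inverse-weighted F1, row-normalized confusion
   matrices, biased subsets, and study learning curves.

Because real multi-study corpora are not shippable, the package includes a
first-class synthetic generator (`generateDataset`) that plants the
structure the pipeline is supposed to find: direct PA/NA markers per site,
indirect OTUs whose presence depends on the site *only through* a direct
parent marker, study-specific detection dropout, log-normal depths, and
noise OTUs — with the full ground truth returned for parameter-recovery
checks.

## Worked example

```r
library(siteMarkers)

cfg <- generatorConfig(n_sites = 3, samples_per_site = rep(150, 3),
                       n_noise = 60, n_indirect = 9)
ose <- generateDataset(cfg, seed = 42)
ose <- filterLowRichness(ose)          # drop samples with < 20 unique OTUs

bset <- discoverMarkers(binarizeCounts(ose), bodySite(ose))
bset
#> BiomarkerSet with 21 marker records across 3 sites
#>         PA NA indet
#>   site1  5  3     0
#>   site2  5  2     0
#>   site3  5  1     0

unlist(recoveryMetrics(bset, groundTruth(ose)))
#>  direct_precision     direct_recall indirect_excluded
#>         0.9411765         0.6666667         1.0000000

relab <- relativeAbundance(ose)
plan <- makeCvPlan(bodySite(ose), 5, seed = 1)
tr <- plan$assignments != 1            # fold 1 held out
model <- trainModel(relab[, tr], bodySite(ose)[tr],
                    grid = hyperGrid(500, 1), seed = 2)
f1 <- f1Report(predictSite(model, relab[, !tr]), bodySite(ose)[!tr])
round(f1$per_class, 3)
#> site1 site2 site3
#> 0.926 0.943 0.939
```

Of the 17 distinct OTUs discovered, 16 are planted direct markers
(precision 0.94), and every indirectly associated OTU is discarded by the
conditioning step (`indirect_excluded = 1`) even though a plain univariate
screen flags them. Recall (0.67 here) rises with sample size — under the
package's reference conditions (5 sites × 300 samples) nearly all planted
markers are recovered. The held-out macro-F1 of 0.936 comes from a forest
trained on 80% of the filtered samples.

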