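# Heavy shared fixtures, built once per test run and cached: the default
# synthetic dataset (the package's reference study conditions) and the
# marker discovery / classifier results derived from it.

.fixtures <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixtures$ose))
    .fixtures$ose <- generateDataset(generatorConfig(), seed = 11)
  .fixtures$ose
}

default_binary <- function() {
  if (is.null(.fixtures$bin))
    .fixtures$bin <- binarizeCounts(default_dataset())
  .fixtures$bin
}

default_screens <- function() {
  if (is.null(.fixtures$screens)) {
    bin <- default_binary()
    bs <- bodySite(default_dataset())
    sites <- sort(unique(bs))
    .fixtures$screens <- lapply(sites, function(s)
      univariateScreen(bin, as.integer(bs == s)))
    names(.fixtures$screens) <- sites
  }
  .fixtures$screens
}

default_markers <- function() {
  if (is.null(.fixtures$bset))
    .fixtures$bset <- discoverMarkers(default_binary(),
                                      bodySite(default_dataset()))
  .fixtures$bset
}

# 5-fold outer plan on the default dataset; fold 1 is the held-out split.
default_split <- function() {
  if (is.null(.fixtures$split)) {
    bs <- bodySite(default_dataset())
    plan <- makeCvPlan(bs, 5, seed = 3)
    .fixtures$split <- list(train = plan$assignments != 1,
                            test = plan$assignments == 1)
  }
  .fixtures$split
}

# BiomarkerSet holding exactly the planted direct markers of a ground truth
# (used by the trait-enrichment tests, which need a known marker universe).
make_marker_set <- function(gt) {
  rows <- lapply(names(gt@direct_pa), function(s) rbind(
    data.frame(otu_id = gt@direct_pa[[s]], site = s, sign = 1L,
               strength_nmi = 0.5, prevalence = 10,
               importance_percentile = NA_real_, stringsAsFactors = FALSE),
    data.frame(otu_id = gt@direct_na[[s]], site = s, sign = -1L,
               strength_nmi = 0.5, prevalence = 10,
               importance_percentile = NA_real_, stringsAsFactors = FALSE)))
  new("BiomarkerSet", markers = do.call(rbind, rows), tests = list(),
      config = list())
}

default_model <- function() {
  if (is.null(.fixtures$model)) {
    ose <- default_dataset()
    relab <- relativeAbundance(ose)
    sp <- default_split()
    .fixtures$model <- trainModel(relab[, sp$train],
                                  bodySite(ose)[sp$train], seed = 5)
  }
  .fixtures$model
}
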