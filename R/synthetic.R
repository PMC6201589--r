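#' Configuration of the synthetic OTU-table generator
#'
#' Fixes the statistical structure of generated datasets: multi-class site
#' structure, multi-study membership with study-specific detection dropout
#' (emulating primer/amplification bias), log-normal sequencing depth, planted
#' direct positive (PA) and negative (NA) site markers, indirectly associated
#' OTUs whose presence depends on the site only through a direct parent
#' marker, and background noise OTUs.
#'
#' The defaults define the package's reference study conditions: 5 body sites
#' with 300 samples each (1500 samples), 8 studies, 5 PA + 3 NA direct markers
#' per site (40 direct), 25 indirect and 200 noise OTUs.
#'
#' @param n_sites number of body-site classes (>= 2).
#' @param samples_per_site integer vector of per-site sample counts,
#'   length `n_sites`.
#' @param n_studies number of studies samples are assigned to.
#' @param study_dropout_range length-2 probability range; each (study, OTU)
#'   pair draws an extra nondetection probability uniformly from it.
#' @param depth_log_mean,depth_log_sd log-normal sequencing-depth parameters
#'   (depths are rounded up to at least 1 read).
#' @param n_direct_pa_per_site,n_direct_na_per_site planted direct markers per
#'   site.
#' @param n_indirect,n_noise counts of indirectly associated and noise OTUs.
#' @param p_high,p_base,p_low presence probabilities: PA marker in its own
#'   site, background everywhere, NA marker in its own site. Must satisfy
#'   `p_low < p_base < p_high`.
#' @param q1,q0 presence probability of an indirect child given its parent
#'   present / absent (`q0 < q1`).
#' @param abundance_log_mean,abundance_log_sd log-normal parameters of the
#'   conditional (presence) abundance weights.
#'
#' @return A validated list of class `"GeneratorConfig"`.
#' @seealso [generateDataset()]
#' @export
generatorConfig <- function(n_sites = 5,
                            samples_per_site = rep(300L, n_sites),
                            n_studies = 8,
                            study_dropout_range = c(0, 0.2),
                            depth_log_mean = log(5000),
                            depth_log_sd = 0.7,
                            n_direct_pa_per_site = 5,
                            n_direct_na_per_site = 3,
                            n_indirect = 25,
                            n_noise = 200,
                            p_high = 0.9, p_base = 0.25, p_low = 0.05,
                            q1 = 0.8, q0 = 0.05,
                            abundance_log_mean = 0, abundance_log_sd = 1) {
  cfg <- list(n_sites = as.integer(n_sites),
              samples_per_site = as.integer(samples_per_site),
              n_studies = as.integer(n_studies),
              study_dropout_range = as.numeric(study_dropout_range),
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              n_direct_pa_per_site = as.integer(n_direct_pa_per_site),
              n_direct_na_per_site = as.integer(n_direct_na_per_site),
              n_indirect = as.integer(n_indirect),
              n_noise = as.integer(n_noise),
              p_high = p_high, p_base = p_base, p_low = p_low,
              q1 = q1, q0 = q0,
              abundance_log_mean = abundance_log_mean,
              abundance_log_sd = abundance_log_sd)
  class(cfg) <- "GeneratorConfig"
  validateGeneratorConfig(cfg)
  cfg
}

validateGeneratorConfig <- function(cfg) {
  if (cfg$n_sites < 2)
    stop("invalid GeneratorConfig: n_sites must be >= 2")
  if (length(cfg$samples_per_site) != cfg$n_sites)
    stop("invalid GeneratorConfig: samples_per_site must have length n_sites")
  if (cfg$n_studies < 1)
    stop("invalid GeneratorConfig: n_studies must be >= 1")
  probs <- c(cfg$study_dropout_range, cfg$p_high, cfg$p_base, cfg$p_low,
             cfg$q1, cfg$q0)
  if (any(probs < 0 | probs > 1))
    stop("invalid GeneratorConfig: all probabilities must lie in [0, 1]")
  if (!(cfg$p_low < cfg$p_base && cfg$p_base < cfg$p_high))
    stop("invalid GeneratorConfig: requires p_low < p_base < p_high")
  if (!(cfg$q0 < cfg$q1))
    stop("invalid GeneratorConfig: requires q0 < q1")
  if (diff(cfg$study_dropout_range) < 0)
    stop("invalid GeneratorConfig: study_dropout_range must be increasing")
  invisible(cfg)
}

#' Generate a synthetic OTU dataset with planted ground truth
#'
#' Draws, for each sample, a site and study assignment and a log-normal
#' sequencing depth; for each OTU a Bernoulli presence state with
#' site-dependent probability (`p_high` / `p_base` / `p_low` for PA / noise /
#' NA; indirect children use `q1` / `q0` conditional on their parent's
#' realized presence, hence depend on the site only through the parent).
#' Presence is then thinned by the sample's study-specific dropout, and counts
#' are allocated multinomially across present OTUs with log-normal abundance
#' weights, so every sample's column sum equals its drawn depth exactly.
#'
#' @param config a [generatorConfig()].
#' @param seed integer master seed; all stochastic stages derive their own
#'   seeds from it, so outputs are byte-identical for a fixed seed.
#' @return An [OtuSet] whose `metadata()` carries the [GroundTruth].
#' @examples
#' ose <- generateDataset(generatorConfig(n_sites = 2,
#'                                        samples_per_site = c(20, 20),
#'                                        n_noise = 30, n_indirect = 4),
#'                        seed = 1)
#' groundTruth(ose)
#' @export
generateDataset <- function(config = generatorConfig(), seed) {
  validateGeneratorConfig(config)
  if (missing(seed)) stop("generateDataset requires an explicit seed")
  sites <- paste0("site", seq_len(config$n_sites))
  n <- sum(config$samples_per_site)
  body_site <- rep(sites, times = config$samples_per_site)
  sample_ids <- sprintf("sample_%04d", seq_len(n))
  studies <- paste0("study", seq_len(config$n_studies))

  # OTU universe and planted roles
  pa <- lapply(seq_along(sites), function(i)
    sprintf("pa_%s_%02d", sites[i], seq_len(config$n_direct_pa_per_site)))
  names(pa) <- sites
  na <- lapply(seq_along(sites), function(i)
    sprintf("na_%s_%02d", sites[i], seq_len(config$n_direct_na_per_site)))
  names(na) <- sites
  ind_ids <- if (config$n_indirect > 0)
    sprintf("ind_%03d", seq_len(config$n_indirect)) else character(0)
  noise_ids <- if (config$n_noise > 0)
    sprintf("noise_%03d", seq_len(config$n_noise)) else character(0)
  otu_ids <- c(unlist(pa, use.names = FALSE), unlist(na, use.names = FALSE),
               ind_ids, noise_ids)
  m <- length(otu_ids)

  study_id <- withr::with_seed(derive_seed(seed, 1),
                               sample(studies, n, replace = TRUE))

  # indirect children attach to direct PA parents (cycled if more children
  # than parents)
  parents <- unlist(pa, use.names = FALSE)
  if (config$n_indirect > 0 && !length(parents))
    stop("indirect OTUs require at least one direct PA marker as parent")
  edges <- if (config$n_indirect > 0) {
    data.frame(parent = rep_len(parents, config$n_indirect),
               child = ind_ids, q1 = config$q1, q0 = config$q0,
               stringsAsFactors = FALSE)
  } else {
    data.frame(parent = character(0), child = character(0),
               q1 = numeric(0), q0 = numeric(0))
  }

  dropout <- withr::with_seed(derive_seed(seed, 2), {
    matrix(runif(config$n_studies * m,
                 config$study_dropout_range[1], config$study_dropout_range[2]),
           nrow = config$n_studies, ncol = m,
           dimnames = list(studies, otu_ids))
  })

  # Pre-thinning presence probabilities for non-indirect OTUs
  prob <- matrix(config$p_base, nrow = m, ncol = n,
                 dimnames = list(otu_ids, sample_ids))
  for (s in sites) {
    prob[pa[[s]], body_site == s] <- config$p_high
    prob[na[[s]], body_site == s] <- config$p_low
  }

  present <- withr::with_seed(derive_seed(seed, 3), {
    pres <- matrix(rbinom(m * n, 1L, as.vector(prob)), nrow = m,
                   dimnames = dimnames(prob))
    # study-specific detection dropout thins everything that was present
    drop_ps <- t(dropout[study_id, , drop = FALSE])  # m x n
    keep <- matrix(rbinom(m * n, 1L, 1 - as.vector(drop_ps)), nrow = m)
    pres <- pres * keep
    # indirect children: presence depends only on the parent's observed state
    if (nrow(edges)) {
      for (k in seq_len(nrow(edges))) {
        q <- ifelse(pres[edges$parent[k], ] == 1L, edges$q1[k], edges$q0[k])
        child <- rbinom(n, 1L, q)
        keep_child <- rbinom(n, 1L, 1 - drop_ps[edges$child[k], ])
        pres[edges$child[k], ] <- child * keep_child
      }
    }
    pres
  })

  counts <- withr::with_seed(derive_seed(seed, 4), {
    depth <- pmax(1L, as.integer(ceiling(rlnorm(n, config$depth_log_mean,
                                                config$depth_log_sd))))
    w <- matrix(rlnorm(m * n, config$abundance_log_mean,
                       config$abundance_log_sd), nrow = m)
    cts <- matrix(0L, nrow = m, ncol = n, dimnames = dimnames(prob))
    for (j in seq_len(n)) {
      pres_j <- present[, j] == 1L
      if (!any(pres_j)) pres_j[sample.int(m, 1)] <- TRUE  # guarantee depth > 0
      p <- w[pres_j, j]
      cts[pres_j, j] <- as.integer(rmultinom(1, depth[j], p / sum(p)))
    }
    cts
  })

  gt <- new("GroundTruth", direct_pa = pa, direct_na = na,
            indirect_edges = edges, noise_otus = noise_ids, dropout = dropout)
  OtuSet(counts, body_site = body_site, study_id = study_id,
         ground_truth = gt)
}

#' Generate a synthetic genus-level trait table with one planted enrichment
#'
#' Assigns each OTU its own synthetic genus and draws physiological traits
#' (aerobicity, gram stain, cell shape, spore formation, motility) from a
#' background distribution, except for the PA markers of one designated site,
#' which receive a planted trait profile with elevated probability. A
#' configurable fraction of (genus, category) entries is left missing.
#'
#' @param gt a [GroundTruth].
#' @param enriched_site site whose PA markers carry the planted profile
#'   (`NULL` for a null table with no planted signal).
#' @param enriched_traits named character vector, category -> sub-category, of
#'   the planted profile. The default mirrors a gut-like profile: anaerobic,
#'   rod shaped, spore forming, motile.
#' @param p_enriched probability that an enriched genus carries each planted
#'   sub-category.
#' @param p_background probability that any other genus carries a given
#'   sub-category (remaining mass is spread uniformly over the alternatives).
#' @param missing_fraction fraction of (genus, category) entries labelled
#'   missing.
#' @param seed integer seed.
#' @return list with `traits` (data.frame: `genus`, `category`, `value`) and
#'   `genus_map` (data.frame: `otu_id`, `genus`).
#' @export
generateTraitTable <- function(gt, enriched_site = NULL,
                               enriched_traits = c(aerobicity = "anaerobe",
                                                   shape = "rod",
                                                   spores = "yes",
                                                   motility = "motile"),
                               p_enriched = 0.9, p_background = 0.2,
                               missing_fraction = 0.1, seed = 1) {
  stopifnot(p_enriched >= 0, p_enriched <= 1,
            p_background >= 0, p_background <= 1,
            missing_fraction >= 0, missing_fraction <= 1)
  vocab <- traitVocabulary()
  bad <- setdiff(names(enriched_traits), names(vocab))
  if (length(bad)) stop("unknown trait categories: ", paste(bad, collapse = ", "))
  otus <- c(unlist(gt@direct_pa, use.names = FALSE),
            unlist(gt@direct_na, use.names = FALSE),
            indirectOtus(gt), gt@noise_otus)
  genus_map <- data.frame(otu_id = otus, genus = paste0("genus_", otus),
                          stringsAsFactors = FALSE)
  enriched_otus <- if (!is.null(enriched_site)) {
    if (!enriched_site %in% names(gt@direct_pa))
      stop("enriched_site not found in ground truth: ", enriched_site)
    gt@direct_pa[[enriched_site]]
  } else character(0)

  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(genus_map)), function(i) {
      otu <- genus_map$otu_id[i]
      out <- lapply(names(vocab), function(cat) {
        if (runif(1) < missing_fraction) return(NULL)
        subs <- vocab[[cat]]
        # the "focal" sub-category of each planted category occurs with
        # probability p_background in ordinary genera and p_enriched in the
        # enriched site's PA markers; other categories use subs[1] as focal
        focal <- if (cat %in% names(enriched_traits))
          enriched_traits[[cat]] else subs[1]
        p_hit <- if (otu %in% enriched_otus && cat %in% names(enriched_traits))
          p_enriched else p_background
        value <- if (runif(1) < p_hit) focal
                 else sample(setdiff(subs, focal), 1)
        data.frame(genus = genus_map$genus[i], category = cat, value = value,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    })
    traits <- do.call(rbind, rows)
  })
  if (is.null(traits))
    traits <- data.frame(genus = character(0), category = character(0),
                         value = character(0))
  list(traits = traits, genus_map = genus_map)
}

#' Fixed vocabulary of physiological trait categories
#'
#' @return named list, category -> character vector of admissible
#'   sub-categories.
#' @export
traitVocabulary <- function() {
  list(aerobicity = c("aerobe", "anaerobe", "facultative"),
       gram = c("positive", "negative"),
       shape = c("rod", "spherical", "helical"),
       spores = c("yes", "no"),
       motility = c("motile", "non-motile"))
}
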