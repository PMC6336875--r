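## End-to-end drivers over the module functions: simulate a full profiling
## experiment (reference, ground truth, per-replicate libraries and sorted
## pools) and score it through F / G / z / binary profiles.

#' Simulate a complete domain-insertion profiling experiment
#'
#' For each domain and replicate an independent insertion library is drawn
#' (the study design regenerates the library in each replicate of the
#' workflow), sorted into SE/NSE pools with the ground-truth
#' surface-expression probabilities, and sequenced to the configured depth.
#'
#' @param config a `dip_config`
#' @param n_residues reference length in codons (437 gives 435 scoreable
#'   sites)
#' @param domains domain names
#' @param class_fractions passed to [simulate_truth()]
#' @param seed master seed (defaults to the config seed); all child seeds
#'   derive from it
#' @return list with `reference`, `truth`, `config`, `counts`
#'   (`counts[[domain]][[replicate]]` = list of `se`/`nse` `dip_counts`)
#' @export
simulate_experiment <- function(config = sim_config(),
                                n_residues = 437,
                                domains = c("PDZ", "Cib81"),
                                class_fractions =
                                  default_class_fractions(n_residues - 2),
                                seed = config$seed) {
  reference <- make_reference(n_residues, seed = derive_seed(seed, 1))
  truth <- simulate_truth(reference, class_fractions = class_fractions,
                          domains = domains, seed = derive_seed(seed, 2))
  counts <- list()
  i <- 10L
  for (d in domains) {
    counts[[d]] <- list()
    for (r in seq_len(config$n_replicates)) {
      i <- i + 2L
      lib <- simulate_library(reference, config, seed = derive_seed(seed, i))
      counts[[d]][[r]] <- simulate_sort_counts(
        lib, truth, d, config, replicate_seed = derive_seed(seed, i + 1L),
        replicate = r)
    }
  }
  list(reference = reference, truth = truth, config = config,
       counts = counts)
}

#' Score a simulated experiment
#'
#' Runs the score ladder per domain: per-replicate enrichment F, replicate
#' mean G, z-scores and binarized profiles.
#'
#' @param experiment output of [simulate_experiment()]
#' @return list per domain with elements `profiles` (per-replicate F),
#'   `mean` (G), `z`, `binary`
#' @export
score_experiment <- function(experiment) {
  out <- list()
  for (d in names(experiment$counts)) {
    profiles <- lapply(experiment$counts[[d]],
                       function(rep) enrichment(rep$se, rep$nse))
    g <- mean_profile(profiles)
    out[[d]] <- list(profiles = profiles, mean = g,
                     z = zscore_profile(g), binary = binarize(g))
  }
  out
}
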