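#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a discovery cohort of autistic children with two
#' latent gut-microbiome subpopulations: compositional genus counts with a
#' planted differential signature (including one genus pair with opposing
#' direction), lower community evenness in subpopulation 2, CARS sensory
#' and social items shifted upward in subpopulation 2, and designated brain
#' regions whose volumes decrease with the sensory domain score.
#'
#' @param n_samples Cohort size (default 78).
#' @param n_genera Number of genera (default 60).
#' @param n_signature Planted signature size (default 12).
#' @param mixing_proportion Proportion of subpopulation 1, the less severe
#'   group (default 0.6).
#' @param log_effect Mean log-abundance shift of signature genera between
#'   subpopulations (default 1.5).
#' @param evenness_gap Extra relative spread of per-sample log-normal
#'   dispersion in subpopulation 2 (default 0.5; its noise SD is
#'   `sigma_noise * (1 + evenness_gap)`), producing the lower community
#'   evenness there without shifting non-signature genus locations.
#' @param cars_shift Latent upward shift of sensory and social CARS items
#'   in subpopulation 2, applied before rounding to the half-point grid
#'   (default 0.5).
#' @param ados_shift ADOS total shift in subpopulation 2 (default 2).
#' @param brain_slope Volume change (mm^3) per sensory-domain point in the
#'   linked regions (default -150).
#' @param depth Sequencing depth for multinomial count sampling
#'   (default 20000).
#' @param sigma_base SD of baseline genus log-means (default 1).
#' @param sigma_noise Per-sample log-normal noise SD (default 0.6).
#' @param cars_item_mean,cars_item_sd Latent item score distribution
#'   (defaults 2.3 and 0.6).
#' @param n_regions,n_linked_regions Brain regions simulated and how many
#'   are sensory-linked (defaults 12 and 3).
#' @param region_noise_sd Volume noise SD in mm^3 (default 500).
#' @param seed Integer seed; one global seed drives independent named
#'   substreams (labels, abundance, behavior, brain, tree) so adding a
#'   stage never perturbs earlier draws.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 78, n_genera = 60,
                              n_signature = 12, mixing_proportion = 0.6,
                              log_effect = 1.5, evenness_gap = 0.5,
                              cars_shift = 0.5, ados_shift = 2,
                              brain_slope = -150, depth = 20000,
                              sigma_base = 1, sigma_noise = 0.6,
                              cars_item_mean = 2.3, cars_item_sd = 0.6,
                              n_regions = 12, n_linked_regions = 3,
                              region_noise_sd = 500, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$mixing_proportion <= 0 || cfg$mixing_proportion >= 1)
    stop("mixing_proportion must lie in (0, 1)", call. = FALSE)
  if (cfg$n_signature > cfg$n_genera)
    stop("n_signature must be <= n_genera", call. = FALSE)
  if (cfg$n_signature < 2)
    stop("n_signature must be >= 2 (the opposite pair)", call. = FALSE)
  if (cfg$log_effect < 0 || cfg$evenness_gap < 0 || cfg$cars_shift < 0)
    stop("log_effect, evenness_gap and cars_shift must be >= 0",
         call. = FALSE)
  if (cfg$depth < 1 || cfg$n_samples < 4)
    stop("need depth >= 1 and n_samples >= 4", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Simulate a synthetic cohort with ground truth
#'
#' Genus abundances are drawn as log-normal intensities (baseline log-mean
#' per genus; signature genera shifted by the per-genus effect in
#' subpopulation 2; baseline log-means spread wider in subpopulation 2),
#' converted to proportions and multinomially sampled to counts at the
#' configured depth, so every count row sums exactly to `depth`. CARS items
#' are drawn on a latent normal scale, shifted in subpopulation 2, rounded
#' to the half-point grid and clipped to \[1, 4\]; totals are computed after
#' rounding. Brain volumes are region baselines plus `brain_slope` times
#' the sensory domain score for linked regions, plus noise. The genus tree
#' is a random bifurcation with exponential branch lengths.
#'
#' @param config A [simulation_config()].
#' @param truth Optional `truth` element of a previous [simulate_cohort()]
#'   call: the new cohort reuses its population parameters (baseline genus
#'   log-means, planted signature and effects, region baselines), drawing
#'   fresh samples — a held-out test cohort from the same population, as
#'   in a discovery/test replication design.
#' @param sample_prefix Prefix for generated sample ids (default "S";
#'   use a different prefix for test cohorts to keep ids distinct).
#' @return List with `abundance` (counts `abundance_table`), `metadata`
#'   (data frame), `brain` (volume matrix), `tree` ([ape::phylo]), `truth`
#'   (latent labels, planted signature, opposite pair, per-genus effects,
#'   baseline parameters), and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), truth = NULL,
                            sample_prefix = "S") {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n <- cfg$n_samples
  genera <- if (is.null(truth)) sprintf("Genus%03d", seq_len(cfg$n_genera))
            else names(truth$effects)
  if (length(genera) != cfg$n_genera)
    stop("config n_genera does not match supplied truth", call. = FALSE)
  samples <- sprintf("%s%03d", sample_prefix, seq_len(n))

  # latent subpopulation labels, stratified so both occur
  labels <- withr_seed(substream_seed(cfg$seed, "labels"), {
    n1 <- max(1, min(n - 1, round(cfg$mixing_proportion * n)))
    sample(rep(c(1L, 2L), c(n1, n - n1)))
  })

  # planted signature and per-genus effects (alternating sign; the first
  # two signature genera are the opposite pair: one up in each group)
  if (is.null(truth)) {
    truth_seed <- substream_seed(cfg$seed, "truth")
    signature <- withr_seed(truth_seed, sort(sample(genera, cfg$n_signature)))
    effects <- stats::setNames(rep(0, cfg$n_genera), genera)
    signs <- rep(c(-1, 1), length.out = cfg$n_signature)
    effects[signature] <- signs * cfg$log_effect
    opposite_pair <- c(a = signature[1], b = signature[2])
    mu <- withr_seed(truth_seed + 1L,
                     stats::setNames(stats::rnorm(cfg$n_genera, 0,
                                                  cfg$sigma_base), genera))
    # the opposite pair must actually flip dominance between groups, so
    # its two baselines share a scale: genus a sits log_effect/2 above b
    # in subpopulation 1 and, after the -/+ shifts, 3*log_effect/2 below
    # in subpopulation 2; a random baseline gap would mask the flip
    pair_mean <- mean(mu[opposite_pair])
    mu[opposite_pair["a"]] <- pair_mean + cfg$log_effect / 4
    mu[opposite_pair["b"]] <- pair_mean - cfg$log_effect / 4
  } else {
    signature <- truth$planted_signature
    effects <- truth$effects
    opposite_pair <- truth$opposite_pair
    mu <- truth$mu
  }

  abundance <- withr_seed(substream_seed(cfg$seed, "abundance"), {
    counts <- matrix(0L, n, cfg$n_genera,
                     dimnames = list(samples, genera))
    for (i in seq_len(n)) {
      # Subpopulation 2 gets the signature shifts plus wider per-sample
      # dispersion (the evenness gap); baseline log-means are shared so
      # non-signature genera stay location-neutral between groups.
      mu_i <- if (labels[i] == 2L) mu + effects else mu
      sd_i <- cfg$sigma_noise *
        (1 + if (labels[i] == 2L) cfg$evenness_gap else 0)
      log_int <- mu_i + stats::rnorm(cfg$n_genera, 0, sd_i)
      p <- exp(log_int - max(log_int))
      counts[i, ] <- stats::rmultinom(1, cfg$depth, p / sum(p))[, 1]
    }
    counts
  })

  metadata <- withr_seed(substream_seed(cfg$seed, "behavior"), {
    shifted_items <- sort(unique(c(7:9, c(1, 2, 4, 5, 10:15))))
    items <- matrix(stats::rnorm(n * 15, cfg$cars_item_mean,
                                 cfg$cars_item_sd), n, 15)
    items[labels == 2L, shifted_items] <-
      items[labels == 2L, shifted_items] + cfg$cars_shift
    items <- pmin(pmax(round(items * 2) / 2, 1), 4)
    colnames(items) <- cars_item_cols()
    ados <- pmax(0, round(stats::rnorm(n, 16, 3.3) +
                            cfg$ados_shift * (labels == 2L), 1))
    md <- data.frame(sample_id = samples, items,
                     cars_total = rowSums(items), ados_total = ados,
                     age_years = round(stats::runif(n, 3, 12), 1),
                     sex = ifelse(stats::runif(n) < 0.85, "male", "female"),
                     stringsAsFactors = FALSE)
    validate_metadata(md)
  })

  sensory <- score_domains(metadata)$distorted_sensory_response
  linked <- c("lPCC", "lSTG", "rMOG")[seq_len(min(3, cfg$n_linked_regions))]
  if (cfg$n_linked_regions > 3)
    linked <- c(linked, sprintf("linked%02d", seq_len(cfg$n_linked_regions - 3)))
  regions <- c(linked,
               sprintf("region%02d",
                       seq_len(max(0, cfg$n_regions - cfg$n_linked_regions))))
  brain <- withr_seed(substream_seed(cfg$seed, "brain"), {
    baselines <- stats::setNames(
      seq(4000, 12000, length.out = length(regions)), regions)
    vol <- matrix(0, n, length(regions), dimnames = list(samples, regions))
    for (r in regions) {
      slope <- if (r %in% linked) cfg$brain_slope else 0
      vol[, r] <- baselines[r] + slope * sensory +
        stats::rnorm(n, 0, cfg$region_noise_sd)
    }
    pmax(vol, 1)
  })

  tree <- withr_seed(substream_seed(cfg$seed, "tree"), {
    tr <- ape::rtree(cfg$n_genera, br = function(k) stats::rexp(k, 10))
    tr$tip.label <- sample(genera)
    tr
  })

  truth_out <- list(latent_label = stats::setNames(labels, samples),
                    planted_signature = signature,
                    opposite_pair = opposite_pair,
                    effects = effects, mu = mu,
                    brain = list(linked_regions = linked,
                                 slope = cfg$brain_slope))
  list(abundance = abundance_table(abundance, mode = "counts"),
       metadata = metadata, brain = brain, tree = tree, truth = truth_out,
       config = cfg)
}

#' Simulate a null cohort (all planted effects zero)
#'
#' Convenience wrapper forcing `log_effect`, `evenness_gap`, `cars_shift`,
#' `ados_shift` and `brain_slope` to zero, so the two latent groups are
#' exchangeable. Used for type-I-error suites.
#'
#' @param config A [simulation_config()] whose effect fields are overridden.
#' @return Same structure as [simulate_cohort()].
#' @export
null_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- unclass(config)
  cfg$log_effect <- 0
  cfg$evenness_gap <- 0
  cfg$cars_shift <- 0
  cfg$ados_shift <- 0
  cfg$brain_slope <- 0
  simulate_cohort(do.call(simulation_config, cfg))
}

#' Write a simulated cohort to a directory
#'
#' Emits `abundance.tsv`, `metadata.tsv`, `brain_volumes.tsv`, `tree.nwk`
#' and `truth.tsv` (per-sample latent labels plus a genus effect table
#' `truth_effects.tsv`) in the package's standard formats.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    brain = file.path(dir, "brain_volumes.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.tsv"),
    effects = file.path(dir, "truth_effects.tsv"))
  write_abundance_table(cohort$abundance, paths["abundance"])
  write_metadata(cohort$metadata, paths["metadata"])
  utils::write.table(
    data.frame(sample_id = rownames(cohort$brain), cohort$brain,
               check.names = FALSE),
    paths["brain"], sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$tree, paths["tree"])
  utils::write.table(
    data.frame(sample_id = names(cohort$truth$latent_label),
               latent_label = cohort$truth$latent_label),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(genus = names(cohort$truth$effects),
               effect = cohort$truth$effects,
               in_signature = names(cohort$truth$effects) %in%
                 cohort$truth$planted_signature,
               opposite_pair = names(cohort$truth$effects) %in%
                 cohort$truth$opposite_pair),
    paths["effects"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
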