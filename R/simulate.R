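#' Simulation configuration with planted ground truth
#'
#' Parameters of the synthetic disease contrast and agent library used to
#' validate the screen end to end.  Defaults describe a bulk-transcriptome
#' scale disease contrast with a strong planted signal and a library in
#' which one agent in ten truly reverses the disease:
#' 5,000 genes, 10 case / 10 control samples, 10% of genes differentially
#' expressed with planted |log2FC| ~ N(1.5, 0.5) of random sign,
#' per-sample log2 noise SD 0.5; 200 agents of which 20 are reversers and
#' 20 mimickers at reversal strength 0.8 with agent log2 noise SD 0.3.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group.
#' @param de_fraction Fraction of genes with planted differential
#'   expression, in `[0, 1]`.
#' @param de_log2fc_mean,de_log2fc_sd Mean and SD of planted |log2FC|
#'   (log2 units); each planted gene gets a random sign.
#' @param noise_sd Per-sample log2 measurement noise SD.
#' @param n_agents,n_reversers,n_mimickers Library composition;
#'   `n_reversers + n_mimickers <= n_agents`, the rest are null agents.
#' @param reversal_strength beta in (0, 1]: a reverser's log2 profile is
#'   `-beta * disease_log2fc` plus noise; a mimicker's is `+beta * ...`.
#' @param agent_noise_sd Log2 noise SD added to reverser/mimicker profiles.
#' @param seed Mandatory integer seed: every generator in the package is
#'   fully deterministic given the configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000L, n_case = 10L, n_control = 10L,
                              de_fraction = 0.1,
                              de_log2fc_mean = 1.5, de_log2fc_sd = 0.5,
                              noise_sd = 0.5,
                              n_agents = 200L, n_reversers = 20L,
                              n_mimickers = 20L,
                              reversal_strength = 0.8, agent_noise_sd = 0.3,
                              seed) {
  if (missing(seed) || !is_count_scalar(seed)) {
    rv_validation_error("'seed' is mandatory and must be a non-negative integer")
  }
  counts <- list(n_genes = n_genes, n_case = n_case, n_control = n_control,
                 n_agents = n_agents)
  for (nm in names(counts)) {
    if (!is_count_scalar(counts[[nm]]) || counts[[nm]] < 1) {
      rv_validation_error(sprintf("'%s' must be a positive integer", nm))
    }
  }
  if (!is_count_scalar(n_reversers) || !is_count_scalar(n_mimickers) ||
      n_reversers + n_mimickers > n_agents) {
    rv_validation_error("'n_reversers' + 'n_mimickers' must not exceed 'n_agents'")
  }
  if (!is_scalar_number(de_fraction) || de_fraction < 0 || de_fraction > 1) {
    rv_validation_error("'de_fraction' must lie in [0, 1]")
  }
  if (!is_scalar_number(reversal_strength) ||
      reversal_strength <= 0 || reversal_strength > 1) {
    rv_validation_error("'reversal_strength' must lie in (0, 1]")
  }
  for (nm in c("de_log2fc_mean", "de_log2fc_sd", "noise_sd",
               "agent_noise_sd")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0) {
      rv_validation_error(sprintf("'%s' must be a non-negative number", nm))
    }
  }
  structure(list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 de_fraction = de_fraction,
                 de_log2fc_mean = de_log2fc_mean,
                 de_log2fc_sd = de_log2fc_sd, noise_sd = noise_sd,
                 n_agents = as.integer(n_agents),
                 n_reversers = as.integer(n_reversers),
                 n_mimickers = as.integer(n_mimickers),
                 reversal_strength = reversal_strength,
                 agent_noise_sd = agent_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a case/control expression matrix with planted DE genes
#'
#' Baseline log2 expression per gene is drawn from Normal(5, 2); a fraction
#' `de_fraction` of genes receives a planted case-group shift of log2FC
#' ~ Normal(de_log2fc_mean, de_log2fc_sd) with random sign; independent
#' Normal(0, noise_sd) log2 noise is added per gene and sample; values are
#' exponentiated to the linear scale.  Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene`, `log2fc` — 0 for non-DE genes — and `is_de`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  baseline <- stats::rnorm(config$n_genes, mean = 5, sd = 2)
  n_de <- round(config$de_fraction * config$n_genes)
  truth <- numeric(config$n_genes)
  if (n_de > 0) {
    de_idx <- sample.int(config$n_genes, n_de)
    truth[de_idx] <- stats::rnorm(n_de, config$de_log2fc_mean,
                                  config$de_log2fc_sd) *
      sample(c(-1, 1), n_de, replace = TRUE)
  }
  n_samples <- config$n_case + config$n_control
  groups <- c(rep("case", config$n_case), rep("control", config$n_control))
  samples <- c(sprintf("case_%02d", seq_len(config$n_case)),
               sprintf("control_%02d", seq_len(config$n_control)))
  shift <- outer(truth, as.numeric(groups == "case"))
  log2x <- baseline + shift +
    matrix(stats::rnorm(config$n_genes * n_samples, 0, config$noise_sd),
           config$n_genes, n_samples)
  vals <- 2^log2x
  dimnames(vals) <- list(genes, samples)
  list(matrix = expression_matrix(vals, groups),
       truth = data.frame(gene = genes, log2fc = truth, is_de = truth != 0,
                          stringsAsFactors = FALSE))
}

#' Simulate an agent library with planted reversers, mimickers and nulls
#'
#' Given the planted disease log2 fold changes, a reverser's log2 profile
#' is `-beta * disease_log2fc + Normal(0, agent_noise_sd)` per gene, a
#' mimicker's is `+beta * disease_log2fc + Normal(0, agent_noise_sd)`, and
#' a null agent's is an independent permutation of the disease log2FC
#' magnitudes with random signs — same marginal effect-size distribution,
#' no gene-level association with the disease.  Roles are assigned to
#' agent ids in a seeded random order.  Internally the generator draws from
#' a stream seeded at `config$seed + 1`, so that an expression matrix and a
#' library built from the same configuration are independent.
#'
#' @param disease_truth The `truth` data.frame from
#'   [simulate_expression()], or a named numeric vector of log2 fold
#'   changes.
#' @param config A [simulation_config()].
#' @return List with `library` (an [agent_library()]) and `labels`
#'   (data.frame `agent_id`, `role` in {reverser, mimicker, null}).
#' @export
simulate_agent_library <- function(disease_truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.data.frame(disease_truth)) {
    truth <- disease_truth$log2fc
    names(truth) <- disease_truth$gene
  } else {
    truth <- disease_truth
  }
  if (is.null(names(truth)) || length(truth) == 0L) {
    rv_validation_error("'disease_truth' must supply named log2 fold changes")
  }
  set.seed(config$seed + 1L)
  n <- length(truth)
  ids <- sprintf("agent_%03d", seq_len(config$n_agents))
  roles <- sample(c(rep("reverser", config$n_reversers),
                    rep("mimicker", config$n_mimickers),
                    rep("null", config$n_agents - config$n_reversers -
                          config$n_mimickers)))
  beta <- config$reversal_strength
  profiles <- vector("list", config$n_agents)
  for (i in seq_len(config$n_agents)) {
    log2p <- switch(roles[i],
      reverser = -beta * truth + stats::rnorm(n, 0, config$agent_noise_sd),
      mimicker = beta * truth + stats::rnorm(n, 0, config$agent_noise_sd),
      null = sample(abs(truth)) * sample(c(-1, 1), n, replace = TRUE))
    fc <- 2^log2p
    names(fc) <- names(truth)
    profiles[[i]] <- fc_profile(fc, contrast_id = ids[i])
  }
  names(profiles) <- ids
  list(library = agent_library(profiles),
       labels = data.frame(agent_id = ids, role = roles,
                           stringsAsFactors = FALSE))
}

#' Simulate a gene-set collection, optionally with one enriched set
#'
#' Draws `n_sets` random sets from the universe.  When `enriched_in` is
#' given, the first set (named `"enriched_set"`) over-samples those genes
#' with weight `oversample_rate` relative to the rest of the universe.
#' Deterministic given the seed.
#'
#' @param universe Character vector of gene symbols.
#' @param n_sets Number of sets.
#' @param set_size_range Length-2 integer range of set sizes (uniform).
#' @param enriched_in Optional character vector (e.g. a DEG list) that the
#'   designated set over-samples.
#' @param oversample_rate Sampling weight of `enriched_in` members in the
#'   designated set (default 5).
#' @param seed Integer seed.
#' @return A [gene_set_collection()]; the name of the designated enriched
#'   set (or `NULL`) is stored in its `enriched_set` attribute.
#' @export
simulate_gene_sets <- function(universe, n_sets = 50L,
                               set_size_range = c(20L, 200L),
                               enriched_in = NULL, oversample_rate = 5,
                               seed) {
  if (missing(seed) || !is_count_scalar(seed)) {
    rv_validation_error("'seed' is mandatory and must be a non-negative integer")
  }
  universe <- unique(toupper(as.character(universe)))
  if (length(set_size_range) != 2L || max(set_size_range) > length(universe)) {
    rv_validation_error("'set_size_range' must fit inside the universe")
  }
  set.seed(as.integer(seed))
  sizes <- sample(set_size_range[1]:set_size_range[2], n_sets, replace = TRUE)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set_%03d", seq_len(n_sets))
  enriched_name <- NULL
  for (i in seq_len(n_sets)) {
    if (i == 1L && !is.null(enriched_in)) {
      w <- ifelse(universe %in% toupper(enriched_in), oversample_rate, 1)
      sets[[i]] <- sample(universe, sizes[i], prob = w)
      names(sets)[1] <- enriched_name <- "enriched_set"
    } else {
      sets[[i]] <- sample(universe, sizes[i])
    }
  }
  coll <- gene_set_collection(sets, universe = universe, name = "simulated")
  attr(coll, "enriched_set") <- enriched_name
  coll
}

#' Simulate a disease/treatment profile pair with a target Spearman rho
#'
#' Generates two fold-change profiles whose log2 values are bivariate
#' normal with Pearson correlation `r = 2 * sin(pi * target_rho / 6)` —
#' the inverse of the classical normal-score relation
#' `rho_S = (6 / pi) * asin(r / 2)` — so that the population Spearman
#' correlation between the profiles equals `target_rho`.  Used to check
#' that [validate_reversal()] recovers a planted anti-correlation of the
#' modest magnitude typical of treatment-reversal contrasts.
#'
#' @param n_genes Number of shared genes.
#' @param target_rho Planted Spearman correlation, in (-1, 1).
#' @param seed Integer seed.
#' @param log2fc_sd Marginal SD of the log2 fold changes (default 1).
#' @return List with `disease` and `treatment` ([fc_profile()] objects) and
#'   `pearson_r`, the latent normal correlation used.
#' @export
simulate_reversal_pair <- function(n_genes = 10000L, target_rho = -0.2,
                                   seed, log2fc_sd = 1) {
  if (missing(seed) || !is_count_scalar(seed)) {
    rv_validation_error("'seed' is mandatory and must be a non-negative integer")
  }
  if (!is_scalar_number(target_rho) || abs(target_rho) >= 1) {
    rv_validation_error("'target_rho' must lie strictly inside (-1, 1)")
  }
  set.seed(as.integer(seed))
  r <- 2 * sin(pi * target_rho / 6)
  z1 <- stats::rnorm(n_genes)
  z2 <- stats::rnorm(n_genes)
  genes <- sprintf("G%05d", seq_len(n_genes))
  disease <- 2^(log2fc_sd * z1)
  treatment <- 2^(log2fc_sd * (r * z1 + sqrt(1 - r^2) * z2))
  names(disease) <- names(treatment) <- genes
  list(disease = fc_profile(disease, "disease_vs_normal"),
       treatment = fc_profile(treatment, "treated_vs_untreated"),
       pearson_r = r)
}
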