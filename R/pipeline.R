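#' Default pipeline configuration
#'
#' Returns the full run configuration as a nested list; every key can be
#' overridden by the user config passed to [run_pipeline()].  Unknown keys
#' are rejected, so typos fail loudly rather than silently using defaults.
#'
#' @param seed Integer seed used by all stochastic stages.
#' @param run_id Run identifier; outputs go under
#'   `<output_dir>/<run_id>/`.
#' @param output_dir Output root directory (default `"runs"`).
#' @return Nested list of stage parameters.
#' @export
default_run_config <- function(seed = 1L, run_id = "run1",
                               output_dir = "runs") {
  list(
    run_id = run_id,
    output_dir = output_dir,
    seed = as.integer(seed),
    stages = c("simulate", "fc", "signature", "screen", "validate",
               "deg", "ora"),
    inputs = list(matrix = NULL, design = NULL, library = NULL,
                  gene_sets = NULL, measurements = NULL),
    simulate = list(n_genes = 5000L, n_case = 10L, n_control = 10L,
                    de_fraction = 0.1, de_log2fc_mean = 1.5,
                    de_log2fc_sd = 0.5, noise_sd = 0.5,
                    n_agents = 200L, n_reversers = 20L, n_mimickers = 20L,
                    reversal_strength = 0.8, agent_noise_sd = 0.3,
                    n_sets = 50L, set_size_min = 20L, set_size_max = 200L,
                    oversample_rate = 5),
    fc = list(pseudocount = 1, mean_type = "arithmetic",
              library_size_normalize = FALSE),
    signature = list(up_threshold = 1.50, down_threshold = 0.67),
    deg = list(up_threshold = 2.0, down_threshold = 0.5),
    screen = list(sided = "two", universe = "shared"),
    validate = list(alpha = 0.05)
  )
}

# merge user config into defaults, rejecting unknown keys at every level
merge_config <- function(default, user, path = "") {
  if (is.null(user)) return(default)
  if (!is.list(user)) {
    rv_validation_error(sprintf("config section '%s' must be a mapping", path))
  }
  unknown <- setdiff(names(user), names(default))
  if (length(unknown)) {
    rv_validation_error(sprintf("unknown config key(s)%s: %s",
                                if (nzchar(path)) paste0(" in '", path, "'") else "",
                                paste(unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(default[[nm]]) && !is.null(names(default[[nm]]))) {
      default[[nm]] <- merge_config(default[[nm]], user[[nm]],
                                    path = if (nzchar(path)) paste(path, nm, sep = ".") else nm)
    } else {
      default[[nm]] <- user[[nm]]
    }
  }
  default
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      rv_validation_error(sprintf("config file not found: %s", config))
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    rv_validation_error("'config' must be a list or a YAML/JSON file path")
  }
  merge_config(default_run_config(), config)
}

stage_error <- function(stage, message) {
  rv_stop(sprintf("[stage %s] %s", stage, message), "revscreen_stage_error")
}

#' Run the screening pipeline
#'
#' Executes the requested stages in order — `simulate` (synthetic inputs
#' with planted truth), `fc` (fold-change profile from the expression
#' matrix), `signature` (up/down signature at the screening thresholds),
#' `screen` (agent ranking), `validate` (Spearman reversal of the
#' top-ranked agent's profile against the disease profile), `deg` (DEG
#' extraction at the stricter thresholds), `ora` (over-representation of
#' the DEGs), and `metrics` (caliper volumes for a measurements table) —
#' writing all outputs plus a JSON manifest under
#' `<output_dir>/<run_id>/`.  Reruns with the same configuration and
#' inputs are bit-identical.
#'
#' When `simulate` is not requested, input paths must be supplied under
#' `config$inputs` (matrix + design, library as long TSV, gene sets as
#' GMT).  Any stage failure aborts with a stage-labeled error.
#'
#' @param config Nested list, or path to a YAML/JSON file, overriding
#'   [default_run_config()]; unknown keys are rejected.
#' @return The run manifest (also written to `manifest.json`):
#'   configuration echo, package version, stages run, and per-file MD5
#'   checksums and row counts.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_run_config(config)
  out_dir <- file.path(cfg$output_dir, cfg$run_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- list()
  note <- function(name, path, rows) {
    files[[name]] <<- list(path = path, md5 = unname(tools::md5sum(path)),
                           rows = rows)
  }
  stages_run <- character()
  st <- list()  # cross-stage state

  if ("simulate" %in% cfg$stages) {
    sc <- cfg$simulate
    sim_cfg <- simulation_config(
      n_genes = sc$n_genes, n_case = sc$n_case, n_control = sc$n_control,
      de_fraction = sc$de_fraction, de_log2fc_mean = sc$de_log2fc_mean,
      de_log2fc_sd = sc$de_log2fc_sd, noise_sd = sc$noise_sd,
      n_agents = sc$n_agents, n_reversers = sc$n_reversers,
      n_mimickers = sc$n_mimickers,
      reversal_strength = sc$reversal_strength,
      agent_noise_sd = sc$agent_noise_sd, seed = cfg$seed)
    sim <- simulate_expression(sim_cfg)
    lib <- simulate_agent_library(sim$truth, sim_cfg)
    st$matrix <- sim$matrix
    st$truth <- sim$truth
    st$library <- lib$library
    st$labels <- lib$labels

    mat_df <- data.frame(gene = rownames(sim$matrix$values),
                         signif(sim$matrix$values, 6),
                         check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(out_dir, "matrix.tsv")
    write_tsv(mat_df, p); note("matrix", p, nrow(mat_df))
    p <- file.path(out_dir, "design.tsv")
    write_tsv(data.frame(sample = colnames(sim$matrix$values),
                         group = sim$matrix$groups), p)
    note("design", p, ncol(sim$matrix$values))
    p <- file.path(out_dir, "library.tsv")
    write_agent_library(lib$library, p)
    note("library", p, length(lib$library) * sim_cfg$n_genes)
    degs_true <- sim$truth$gene[sim$truth$is_de]
    st$gene_sets <- simulate_gene_sets(
      universe = sim$truth$gene, n_sets = sc$n_sets,
      set_size_range = c(sc$set_size_min, sc$set_size_max),
      enriched_in = degs_true, oversample_rate = sc$oversample_rate,
      seed = cfg$seed + 2L)
    p <- file.path(out_dir, "gene_sets.gmt")
    write_gmt(st$gene_sets, p); note("gene_sets", p, length(st$gene_sets$sets))
    p <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(de_genes = sim$truth$gene[sim$truth$is_de],
           log2fc = stats::setNames(as.list(sim$truth$log2fc[sim$truth$is_de]),
                                    sim$truth$gene[sim$truth$is_de]),
           agent_roles = stats::setNames(as.list(lib$labels$role),
                                         lib$labels$agent_id),
           enriched_set = attr(st$gene_sets, "enriched_set")),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("truth", p, sum(sim$truth$is_de))
    stages_run <- c(stages_run, "simulate")
  } else {
    inp <- cfg$inputs
    if (!is.null(inp$matrix)) {
      if (is.null(inp$design)) stage_error("fc", "matrix given without design")
      st$matrix <- read_expression_matrix(inp$matrix, inp$design)
    }
    if (!is.null(inp$library)) st$library <- load_agent_library(inp$library)
    if (!is.null(inp$gene_sets)) st$gene_sets <- load_gmt(inp$gene_sets)
  }

  if ("fc" %in% cfg$stages) {
    if (is.null(st$matrix)) stage_error("fc", "no expression matrix available")
    st$disease_fc <- compute_fc(
      st$matrix, pseudocount = cfg$fc$pseudocount,
      mean_type = cfg$fc$mean_type,
      library_size_normalize = isTRUE(cfg$fc$library_size_normalize),
      contrast_id = "disease_vs_normal")
    p <- file.path(out_dir, "disease_fc.tsv")
    write_fc_profile(st$disease_fc, p)
    note("disease_fc", p, length(st$disease_fc))
    stages_run <- c(stages_run, "fc")
  }

  if ("signature" %in% cfg$stages) {
    if (is.null(st$disease_fc)) stage_error("signature", "no fold-change profile")
    st$signature <- extract_signature(
      st$disease_fc, signature_config(cfg$signature$up_threshold,
                                      cfg$signature$down_threshold))
    p <- file.path(out_dir, "signature.json")
    write_signature(st$signature, p)
    note("signature", p, length(signature_genes(st$signature)))
    stages_run <- c(stages_run, "signature")
  }

  if ("screen" %in% cfg$stages) {
    if (is.null(st$disease_fc)) stage_error("screen", "no fold-change profile")
    if (is.null(st$library)) stage_error("screen", "no agent library")
    st$screen <- screen_library(
      st$disease_fc, st$library,
      sig_config = signature_config(cfg$signature$up_threshold,
                                    cfg$signature$down_threshold),
      sided = cfg$screen$sided, universe = cfg$screen$universe)
    p <- file.path(out_dir, "screen.tsv")
    write_screen_tsv(st$screen, p)
    note("screen", p, nrow(st$screen$scores))
    p <- file.path(out_dir, "excluded.tsv")
    write_tsv(st$screen$excluded, p)
    note("excluded", p, nrow(st$screen$excluded))
    stages_run <- c(stages_run, "screen")
  }

  if ("validate" %in% cfg$stages) {
    if (is.null(st$screen)) stage_error("validate", "screen stage must run first")
    top_id <- st$screen$scores$agent_id[1]
    val <- validate_reversal(st$library$agents[[top_id]], st$disease_fc,
                             alpha = cfg$validate$alpha)
    p <- file.path(out_dir, "validation.json")
    jsonlite::write_json(c(list(agent_id = top_id), val), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("validation", p, 1L)
    stages_run <- c(stages_run, "validate")
  }

  if ("deg" %in% cfg$stages) {
    if (is.null(st$disease_fc)) stage_error("deg", "no fold-change profile")
    st$degs <- extract_degs(
      st$disease_fc, signature_config(cfg$deg$up_threshold,
                                      cfg$deg$down_threshold))
    p <- file.path(out_dir, "degs.txt")
    writeLines(sort(signature_genes(st$degs)), p)
    note("degs", p, length(signature_genes(st$degs)))
    stages_run <- c(stages_run, "deg")
  }

  if ("ora" %in% cfg$stages) {
    if (is.null(st$degs)) stage_error("ora", "deg stage must run first")
    if (is.null(st$gene_sets)) stage_error("ora", "no gene-set collection")
    res <- ora(signature_genes(st$degs), st$gene_sets)
    p <- file.path(out_dir, "ora.tsv")
    write_tsv(signif_cols(res), p)
    note("ora", p, nrow(res))
    stages_run <- c(stages_run, "ora")
  }

  if ("metrics" %in% cfg$stages) {
    if (is.null(cfg$inputs$measurements)) {
      stage_error("metrics", "no measurements table supplied")
    }
    meas <- add_tumor_volumes(read_tsv(cfg$inputs$measurements))
    p <- file.path(out_dir, "measurements_volumes.tsv")
    write_tsv(signif_cols(meas), p)
    note("metrics", p, nrow(meas))
    stages_run <- c(stages_run, "metrics")
  }

  manifest <- list(run_id = cfg$run_id,
                   package = "revscreen",
                   version = as.character(utils::packageVersion("revscreen")),
                   stages = stages_run,
                   config = cfg,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
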