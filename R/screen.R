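#' Screen an agent library against a disease signature
#'
#' The core of the reverse-transcriptomics screen.  For every agent in the
#' library the disease and agent signatures (thresholded at `sig_config`)
#' are intersected into a signed 2x2 overlap table, scored with Fisher's
#' exact test ([fisher_exact()]), and the two fold-change profiles are
#' correlated with Spearman's rho ([spearman_reversal()]).  Agents with no
#' shared signature genes (or fewer than 3 shared measured genes) cannot be
#' scored; they are excluded from the ranking and reported separately.
#'
#' Benjamini-Hochberg adjustment is applied across the scored agents,
#' separately for the Fisher and Spearman p-values.  Agents are ranked by
#' ascending rho (most anti-correlated first), ties broken by ascending
#' odds ratio, then lexicographically by agent id — a deterministic order
#' that does not depend on library input order.  An agent with rho > 0 is
#' flagged concordant: it mimics rather than reverses the disease.
#'
#' @param disease_fc The disease [fc_profile()] (e.g. tumor vs normal).
#' @param library An [agent_library()].
#' @param sig_config Thresholds used for both the disease and the agent
#'   signatures; default [signature_config()] (1.50 / 0.67).
#' @param sided Sidedness of the Fisher test; default `"two"`.
#' @param universe Gene universe for Spearman: `"shared"` (whole FC
#'   profiles, default) or `"signature"` (disease signature genes only).
#' @return An object of class `reversal_screen`: list with
#'   \describe{
#'     \item{scores}{data.frame of ranked agents with columns `rank`,
#'       `agent_id`, `rho`, `rho_p`, `rho_q`, `odds_ratio`, `fisher_p`,
#'       `fisher_q`, `a`, `b`, `c`, `d`, `n_shared`, `concordant`.}
#'     \item{excluded}{data.frame (`agent_id`, `reason`) of unscorable
#'       agents.}
#'     \item{disease_signature}{the disease `gene_signature` used.}
#'     \item{config}{echo of the scoring options.}
#'   }
#' @examples
#' set.seed(1)
#' fc <- fc_profile(setNames(2^rnorm(50), paste0("G", 1:50)), "disease")
#' rev <- fc_profile(1 / fc$fc, "reverser")
#' scr <- screen_library(fc, agent_library(list(reverser = rev)))
#' scr$scores$rho  # -1
#' @export
screen_library <- function(disease_fc, library,
                           sig_config = signature_config(),
                           sided = c("two", "less", "greater"),
                           universe = c("shared", "signature")) {
  sided <- match.arg(sided)
  universe <- match.arg(universe)
  stopifnot(inherits(disease_fc, "fc_profile"))
  if (!inherits(library, "agent_library")) {
    rv_validation_error("'library' must be an agent_library")
  }
  disease_sig <- extract_signature(disease_fc, sig_config)
  if (length(signature_genes(disease_sig)) == 0L) {
    rv_validation_error("disease signature is empty at the given thresholds")
  }

  rows <- list()
  excluded <- list()
  for (id in agent_ids(library)) {
    agent_fc <- library$agents[[id]]
    agent_sig <- suppressWarnings(extract_signature(agent_fc, sig_config))
    tab <- tryCatch(signed_overlap_table(disease_sig, agent_sig),
                    revscreen_overlap_error = function(e) NULL)
    if (is.null(tab)) {
      excluded[[id]] <- "no shared signature genes"
      next
    }
    sp <- tryCatch(
      spearman_reversal(disease_fc, agent_fc, universe = universe,
                        signature = disease_sig),
      revscreen_overlap_error = function(e) NULL,
      revscreen_constant_error = function(e) NULL)
    if (is.null(sp)) {
      excluded[[id]] <- "Spearman rho not computable on shared genes"
      next
    }
    fe <- fisher_exact(tab, sided = sided)
    rows[[id]] <- data.frame(
      agent_id = id, rho = sp$rho, rho_p = sp$p,
      odds_ratio = fe$odds_ratio, fisher_p = fe$p,
      a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      n_shared = sp$n_shared, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    rv_validation_error("no agent in the library could be scored")
  }
  scores <- do.call(rbind, rows)
  scores$fisher_q <- stats::p.adjust(scores$fisher_p, method = "BH")
  scores$rho_q <- stats::p.adjust(scores$rho_p, method = "BH")
  ord <- order(scores$rho, scores$odds_ratio, scores$agent_id)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  scores$concordant <- scores$rho > 0
  scores <- scores[, c("rank", "agent_id", "rho", "rho_p", "rho_q",
                       "odds_ratio", "fisher_p", "fisher_q",
                       "a", "b", "c", "d", "n_shared", "concordant")]
  rownames(scores) <- NULL

  excluded_df <- if (length(excluded)) {
    data.frame(agent_id = names(excluded),
               reason = unlist(excluded, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(agent_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(scores = scores, excluded = excluded_df,
                 disease_signature = disease_sig,
                 config = list(sig_config = sig_config, sided = sided,
                               universe = universe)),
            class = "reversal_screen")
}

#' @export
print.reversal_screen <- function(x, ...) {
  cat(sprintf("Reversal screen: %d agents ranked, %d excluded\n",
              nrow(x$scores), nrow(x$excluded)))
  top <- utils::head(x$scores[, c("rank", "agent_id", "rho", "odds_ratio")], 10L)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Top-ranked agents of a screen
#'
#' @param screen A `reversal_screen`.
#' @param n Number of top rows (default 10, the customary shortlist size).
#' @return data.frame of the first `n` ranked agents.
#' @export
top_agents <- function(screen, n = 10L) {
  stopifnot(inherits(screen, "reversal_screen"))
  utils::head(screen$scores, n)
}

#' Write screen results to TSV
#'
#' Columns `rank, agent_id, rho, rho_p, rho_q, odds_ratio, fisher_p,
#' fisher_q, a, b, c, d, n_shared`, in deterministic rank order; floats at
#' 6 significant digits.
#'
#' @param screen A `reversal_screen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  stopifnot(inherits(screen, "reversal_screen"))
  cols <- c("rank", "agent_id", "rho", "rho_p", "rho_q", "odds_ratio",
            "fisher_p", "fisher_q", "a", "b", "c", "d", "n_shared")
  write_tsv(signif_cols(screen$scores[, cols]), path)
}
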