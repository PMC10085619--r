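#' Signed overlap table between a disease and an agent signature
#'
#' Builds the 2x2 contingency table of direction agreement between two gene
#' signatures, restricted to genes that belong to at least one direction of
#' both signatures: \tabular{lll}{
#'   \tab agent up \tab agent down \cr
#'   disease up \tab a \tab b \cr
#'   disease down \tab c \tab d \cr
#' }
#' Anti-correlation (signature reversal) loads the off-diagonal cells b and
#' c, giving an odds ratio below 1; concordance loads a and d.
#'
#' @param disease,agent `gene_signature` objects.
#' @return An object of class `overlap_table` with integer cells `a`, `b`,
#'   `c`, `d`.
#' @examples
#' d <- extract_signature(fc_profile(c(X = 2, Y = 2, Z = 0.5)))
#' a <- extract_signature(fc_profile(c(X = 0.5, Y = 0.5, Z = 2)))
#' signed_overlap_table(d, a)  # b = 2, c = 1
#' @export
signed_overlap_table <- function(disease, agent) {
  stopifnot(inherits(disease, "gene_signature"),
            inherits(agent, "gene_signature"))
  tab <- overlap_table(
    a = length(intersect(disease$up, agent$up)),
    b = length(intersect(disease$up, agent$down)),
    c = length(intersect(disease$down, agent$up)),
    d = length(intersect(disease$down, agent$down)))
  if (tab$a + tab$b + tab$c + tab$d == 0L) {
    rv_overlap_error(sprintf(
      "no shared signature genes between '%s' and '%s'",
      disease$source_contrast, agent$source_contrast))
  }
  tab
}

#' @rdname signed_overlap_table
#' @param a,b,c,d Non-negative integer cell counts (disease-up/agent-up,
#'   disease-up/agent-down, disease-down/agent-up, disease-down/agent-down).
#' @export
overlap_table <- function(a, b, c, d) {
  cells <- list(a = a, b = b, c = c, d = d)
  for (nm in names(cells)) {
    if (!is_count_scalar(cells[[nm]])) {
      rv_validation_error(sprintf(
        "cell '%s' must be a single non-negative integer", nm))
    }
  }
  structure(lapply(cells, function(x) as.integer(round(x))),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("disease up", "disease down"),
                              c("agent up", "agent down")))
  print(m)
  invisible(x)
}

#' Fisher's exact test on a signed overlap table
#'
#' The odds ratio is the sample cross-ratio `(a*d)/(b*c)`; when any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to every cell before taking
#' the ratio (the uncorrected value is also returned, with `Inf`/`0`/`NaN`
#' allowed).  The p-value is the exact conditional probability from the
#' hypergeometric distribution of cell `a` given the table margins:
#' two-sided sums all point probabilities no larger than the observed one.
#' Signature reversal shows up as OR < 1.
#'
#' @param table An [overlap_table()].
#' @param sided `"two"` (default), `"less"` (alternative OR < 1, the
#'   reversal direction) or `"greater"`.
#' @return List with `odds_ratio` (corrected when a cell is 0),
#'   `odds_ratio_raw`, `p`, and `sided`.
#' @examples
#' fisher_exact(overlap_table(1, 9, 9, 1))$odds_ratio  # 1/81
#' @export
fisher_exact <- function(table, sided = c("two", "less", "greater")) {
  sided <- match.arg(sided)
  if (!inherits(table, "overlap_table")) {
    table <- do.call(overlap_table, as.list(table)[c("a", "b", "c", "d")])
  }
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  n <- a + b + cc + d
  if (n == 0L) rv_validation_error("overlap table is all zero")

  or_raw <- (a * d) / (b * cc)          # may be Inf, 0 or NaN
  odds_ratio <- if (min(a, b, cc, d) == 0L) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    or_raw
  }

  # cell a | margins  ~  Hypergeometric(m = a+b, n = c+d, k = a+c)
  m1 <- a + b; m2 <- cc + d; k <- a + cc
  p <- switch(sided,
    less = stats::phyper(a, m1, m2, k),
    greater = stats::phyper(a - 1, m1, m2, k, lower.tail = FALSE),
    two = {
      support <- max(0L, k - m2):min(k, m1)
      dens <- stats::dhyper(support, m1, m2, k)
      obs <- dens[support == a]
      # relative tolerance guards against ties in point probabilities
      # being split by floating-point rounding
      sum(dens[dens <= obs * (1 + 1e-7)])
    })
  list(odds_ratio = odds_ratio, odds_ratio_raw = or_raw,
       p = min(1, p), sided = sided)
}

#' Spearman correlation between two fold-change profiles
#'
#' Computes Spearman's rho as the Pearson correlation of average (midrank)
#' ranks of the two linear fold-change vectors over the shared gene
#' universe.  Because ranks are invariant under strictly monotone
#' transforms, the result is identical whether profiles are correlated on
#' the linear or the log scale.  The p-value uses the t-distribution
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom; for very small overlaps a seeded permutation p-value is
#' available instead.
#'
#' @param disease_fc,agent_fc `fc_profile` objects.
#' @param universe `"shared"` (default): all genes measured in both
#'   profiles, i.e. the whole FC profiles; `"signature"`: restrict to
#'   the genes of `signature`.
#' @param signature A `gene_signature`; required when
#'   `universe = "signature"`.
#' @param permutation If `TRUE`, the p-value is estimated by permutation
#'   (recommended when fewer than 10 genes are shared).
#' @param n_perm Number of permutations (default 10000).
#' @param perm_seed Seed for the permutation null; required when
#'   `permutation = TRUE`.
#' @return List with `rho`, `p`, `n_shared` and `p_method`
#'   (`"t-approximation"` or `"permutation"`).
#' @export
spearman_reversal <- function(disease_fc, agent_fc,
                              universe = c("shared", "signature"),
                              signature = NULL,
                              permutation = FALSE, n_perm = 10000L,
                              perm_seed = NULL) {
  universe <- match.arg(universe)
  stopifnot(inherits(disease_fc, "fc_profile"),
            inherits(agent_fc, "fc_profile"))
  shared <- intersect(names(disease_fc$fc), names(agent_fc$fc))
  if (universe == "signature") {
    if (!inherits(signature, "gene_signature")) {
      rv_validation_error(
        "universe = \"signature\" requires a gene_signature in 'signature'")
    }
    shared <- intersect(shared, signature_genes(signature))
  }
  n <- length(shared)
  if (n < 3L) {
    rv_overlap_error(sprintf(
      "only %d shared gene(s) between '%s' and '%s'; need at least 3",
      n, disease_fc$contrast_id, agent_fc$contrast_id))
  }
  x <- disease_fc$fc[shared]
  y <- agent_fc$fc[shared]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    rv_stop("Spearman rho undefined: a fold-change vector is constant over the shared universe",
            "revscreen_constant_error")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)

  if (permutation) {
    if (is.null(perm_seed)) {
      rv_validation_error("'perm_seed' is required when permutation = TRUE")
    }
    set.seed(as.integer(perm_seed))
    null_rho <- replicate(n_perm, stats::cor(rx, sample(ry)))
    p <- (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
    p_method <- "permutation"
  } else {
    p <- spearman_t_p(rho, n)
    p_method <- "t-approximation"
  }
  list(rho = rho, p = p, n_shared = n, p_method = p_method)
}

# two-sided p from the t approximation; rho = +/-1 gives p = 0
spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Validate signature reversal of a treatment contrast
#'
#' Checks whether a treatment-induced fold-change profile (treated vs
#' untreated) runs opposite to the disease fold-change profile (disease vs
#' normal), using Spearman correlation over the full shared gene universe.
#' The result is labeled `"reversal"` when rho < 0 with p below `alpha`,
#' `"concordant"` when rho > 0 with p below `alpha`, and `"inconclusive"`
#' otherwise.
#'
#' @param treatment_fc,disease_fc `fc_profile` objects.
#' @param alpha Significance level for the label (default 0.05).
#' @return List with `rho`, `p`, `n_shared`, `label`.
#' @export
validate_reversal <- function(treatment_fc, disease_fc, alpha = 0.05) {
  res <- spearman_reversal(disease_fc, treatment_fc, universe = "shared")
  label <- if (res$p < alpha && res$rho < 0) {
    "reversal"
  } else if (res$p < alpha && res$rho > 0) {
    "concordant"
  } else {
    "inconclusive"
  }
  list(rho = res$rho, p = res$p, n_shared = res$n_shared, label = label)
}
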