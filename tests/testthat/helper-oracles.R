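# Independent oracles used across the suite.  These deliberately avoid the
# code paths of the implementation: combinatorial enumeration via lchoose()
# instead of dhyper()/phyper(), and a hand-rolled sort-based midrank ranker
# instead of rank()/cor(method = "spearman").

# Exact conditional p for a 2x2 table by full enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(a, b, c, d, sided = "two") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  xs <- lo:hi
  pr <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1))
  obs <- pr[xs == a]
  p <- switch(sided,
    two = sum(pr[pr <= obs * (1 + 1e-7)]),
    less = sum(pr[xs <= a]),
    greater = sum(pr[xs >= a]))
  min(1, p)
}

# Cross-ratio odds ratio with Haldane-Anscombe correction on zero cells.
oracle_cross_or <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
}

# Midranks by explicit sorting and tie-group averaging.
naive_midrank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Spearman rho as Pearson on midranks, from explicit sums.
oracle_spearman <- function(x, y) {
  rx <- naive_midrank(x)
  ry <- naive_midrank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Upper-tail hypergeometric probability by summing the pmf with choose().
oracle_hyper_tail <- function(overlap, set_size, draws, universe_size) {
  ks <- overlap:min(set_size, draws)
  sum(choose(set_size, ks) * choose(universe_size - set_size, draws - ks) /
        choose(universe_size, draws))
}

# Small random fold-change profile on a shared gene space.
random_profile <- function(n, id = "p", genes = sprintf("G%04d", seq_len(n))) {
  fc_profile(stats::setNames(2^stats::rnorm(n), genes), contrast_id = id)
}

# Write a small TSV fixture into a temp file.
tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
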