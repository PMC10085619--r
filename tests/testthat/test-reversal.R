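make_sig <- function(up, down) {
  revscreen:::new_gene_signature("s", up, down, signature_config())
}

test_that("signed overlap tables count direction agreement", {
  d <- make_sig(c("X", "Y"), "Z")
  a <- make_sig("Z", c("X", "Y"))
  tab <- signed_overlap_table(d, a)
  expect_equal(unclass(tab)[c("a", "b", "c", "d")],
               list(a = 0L, b = 2L, c = 1L, d = 0L))

  self <- signed_overlap_table(d, d)
  expect_equal(c(self$a, self$b, self$c, self$d), c(2L, 0L, 0L, 1L))

  inv <- signed_overlap_table(d, invert_signature(d))
  expect_equal(c(inv$a, inv$b, inv$c, inv$d), c(0L, 2L, 1L, 0L))

  expect_error(signed_overlap_table(d, make_sig("Q", "R")),
               "no shared signature genes", class = "revscreen_overlap_error")
})

test_that("odds ratio is the cross-ratio with Haldane-Anscombe on zeros", {
  expect_equal(fisher_exact(overlap_table(5, 5, 5, 5))$odds_ratio, 1.0)
  fe <- fisher_exact(overlap_table(1, 9, 9, 1))
  expect_equal(fe$odds_ratio, 1 / 81)
  z <- fisher_exact(overlap_table(0, 10, 10, 0))
  expect_equal(z$odds_ratio, (0.5 * 0.5) / (10.5 * 10.5))
  expect_equal(z$odds_ratio_raw, 0)
  expect_error(overlap_table(-1, 2, 3, 4), class = "revscreen_validation_error")
  expect_error(overlap_table(1.5, 2, 3, 4), class = "revscreen_validation_error")
})

test_that("exact p-values match enumeration over tables with fixed margins", {
  # the spec-level worked case: margins (10, 10, 10, 10)
  expect_equal(fisher_exact(overlap_table(1, 9, 9, 1))$p,
               oracle_fisher_p(1, 9, 9, 1), tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:200) {
    cells <- as.list(stats::rbinom(4, 12, 0.4))
    names(cells) <- c("a", "b", "c", "d")
    if (Reduce(`+`, cells) == 0) next
    tab <- do.call(overlap_table, cells)
    for (sided in c("two", "less", "greater")) {
      expect_equal(fisher_exact(tab, sided)$p,
                   do.call(oracle_fisher_p, c(cells, sided)),
                   tolerance = 1e-12)
    }
  }
})

test_that("inverting the agent inverts the odds ratio", {
  set.seed(4)
  for (rep in 1:50) {
    cells <- 1 + stats::rbinom(4, 10, 0.5)  # no zero cells
    or1 <- fisher_exact(overlap_table(cells[1], cells[2], cells[3], cells[4]))$odds_ratio
    # swapping the agent's directions swaps a<->b and c<->d
    or2 <- fisher_exact(overlap_table(cells[2], cells[1], cells[4], cells[3]))$odds_ratio
    expect_equal(or1 * or2, 1, tolerance = 1e-12)
  }
})

test_that("Spearman rho handles identity, reciprocal, and ties", {
  set.seed(5)
  x <- random_profile(40, "disease")
  expect_equal(spearman_reversal(x, x)$rho, 1.0)
  recip <- fc_profile(1 / x$fc, "recip")
  expect_equal(spearman_reversal(x, recip)$rho, -1.0)
  expect_equal(spearman_reversal(x, recip)$p, 0)

  # a tied 5-gene case against the naive midrank oracle
  g <- paste0("G", 1:5)
  a <- fc_profile(setNames(c(2, 2, 1.2, 0.5, 0.8), g))
  b <- fc_profile(setNames(c(1.5, 0.9, 0.9, 0.7, 2.2), g))
  expect_equal(spearman_reversal(a, b)$rho,
               oracle_spearman(a$fc[g], b$fc[g]), tolerance = 1e-12)
})

test_that("Spearman rho is symmetric and monotone-transform invariant", {
  set.seed(6)
  for (rep in 1:20) {
    x <- random_profile(30)
    y <- random_profile(30, "y")
    r1 <- spearman_reversal(x, y)
    expect_equal(r1$rho, spearman_reversal(y, x)$rho)
    # squaring linear FC is strictly monotone on (0, Inf)
    y2 <- fc_profile(y$fc^2, "y2")
    expect_equal(spearman_reversal(x, y2)$rho, r1$rho)
    expect_equal(r1$n_shared, 30L)
  }
})

test_that("degenerate Spearman inputs raise classed errors", {
  g <- paste0("G", 1:2)
  a <- fc_profile(setNames(c(2, 0.5), g))
  expect_error(spearman_reversal(a, a), "at least 3",
               class = "revscreen_overlap_error")
  g5 <- paste0("G", 1:5)
  const <- fc_profile(setNames(rep(2, 5), g5))
  var5 <- fc_profile(setNames(c(1, 2, 3, 4, 5), g5))
  expect_error(spearman_reversal(const, var5), "constant",
               class = "revscreen_constant_error")
})

test_that("permutation p-values are seeded and reproducible", {
  set.seed(7)
  x <- random_profile(8)
  y <- random_profile(8, "y")
  p1 <- spearman_reversal(x, y, permutation = TRUE, n_perm = 500,
                          perm_seed = 11)
  p2 <- spearman_reversal(x, y, permutation = TRUE, n_perm = 500,
                          perm_seed = 11)
  expect_identical(p1$p, p2$p)
  expect_equal(p1$p_method, "permutation")
  expect_gt(p1$p, 0)
  expect_error(spearman_reversal(x, y, permutation = TRUE),
               "perm_seed", class = "revscreen_validation_error")
})

test_that("treatment contrasts are labeled by reversal direction", {
  set.seed(8)
  d <- random_profile(100, "disease")
  recip <- fc_profile(1 / d$fc, "treatment")
  v <- validate_reversal(recip, d)
  expect_equal(v$rho, -1)
  expect_equal(v$label, "reversal")
  v2 <- validate_reversal(d, d)
  expect_equal(v2$rho, 1)
  expect_equal(v2$label, "concordant")
})
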