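small_matrix <- function(case, control, genes = NULL) {
  m <- cbind(case, control)
  genes <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  dimnames(m) <- list(genes,
                      c(sprintf("case_%d", seq_len(ncol(case))),
                        sprintf("ctrl_%d", seq_len(ncol(control)))))
  expression_matrix(m, c(rep("case", ncol(case)),
                         rep("control", ncol(control))))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("pseudocount fold change follows (mean_case + e)/(mean_control + e)", {
  em <- small_matrix(matrix(c(10, 10), 1), matrix(c(5, 5), 1))
  expect_equal(unname(compute_fc(em, pseudocount = 1)$fc), 11 / 6)
  # identical groups give FC = 1 everywhere
  em2 <- small_matrix(matrix(1:6, 3), matrix(1:6, 3))
  expect_equal(unname(compute_fc(em2)$fc), rep(1, 3))
})

test_that("swapping case and control labels reciprocates the profile", {
  set.seed(21)
  vals <- matrix(rpois(40, 20), 10, 4,
                 dimnames = list(sprintf("G%02d", 1:10), paste0("s", 1:4)))
  fwd <- compute_fc(expression_matrix(vals, c("case", "case", "control", "control")))
  rev <- compute_fc(expression_matrix(vals, c("control", "control", "case", "case")))
  expect_equal(fwd$fc, 1 / rev$fc, tolerance = 1e-12)
})

test_that("library-size normalization absorbs a global scale factor", {
  set.seed(22)
  vals <- matrix(rpois(60, 50) + 1, 15, 4,
                 dimnames = list(sprintf("G%02d", 1:15), paste0("s", 1:4)))
  groups <- c("case", "case", "control", "control")
  base <- compute_fc(expression_matrix(vals, groups),
                     pseudocount = 1e-8, library_size_normalize = TRUE)
  scaled <- compute_fc(expression_matrix(vals * 7, groups),
                       pseudocount = 1e-8, library_size_normalize = TRUE)
  expect_equal(scaled$fc, base$fc, tolerance = 1e-6)
  # ... and per-sample depth differences are corrected
  uneven <- vals
  uneven[, 1] <- uneven[, 1] * 10
  fixed <- compute_fc(expression_matrix(uneven, groups),
                      pseudocount = 1e-8, library_size_normalize = TRUE)
  raw <- compute_fc(expression_matrix(uneven, groups), pseudocount = 1e-8)
  expect_gt(max(abs(log2(raw$fc) - log2(base$fc))),
            max(abs(log2(fixed$fc) - log2(base$fc))))
})

test_that("geometric means are supported and zeros behave as documented", {
  em <- small_matrix(matrix(c(4, 16), 1), matrix(c(2, 8), 1))
  geo <- compute_fc(em, pseudocount = 1, mean_type = "geometric")
  expect_equal(unname(geo$fc), (8 + 1) / (4 + 1))
  em0 <- small_matrix(matrix(c(0, 16), 1), matrix(c(2, 8), 1))
  geo0 <- compute_fc(em0, pseudocount = 1, mean_type = "geometric")
  expect_equal(unname(geo0$fc), 1 / 5)  # geometric mean with a zero is 0
})

test_that("matrix construction enforces groups and value ranges", {
  m <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(expression_matrix(m, c("case", "case")),
               class = "revscreen_validation_error")
  expect_error(expression_matrix(m, c("case", "other")),
               class = "revscreen_validation_error")
  m[1] <- -1
  expect_error(expression_matrix(m, c("case", "control")),
               class = "revscreen_validation_error")
  em <- small_matrix(matrix(1:2, 1), matrix(3:4, 1))
  expect_error(compute_fc(em, pseudocount = 0),
               class = "revscreen_validation_error")
})

test_that("planted effects are recovered and tighten with sample size", {
  errs <- vapply(c(3L, 30L), function(n) {
    cfg <- simulation_config(n_genes = 2000L, n_case = n, n_control = n,
                             de_fraction = 0.1, de_log2fc_mean = 1,
                             de_log2fc_sd = 0, noise_sd = 0.5, seed = 3L)
    sim <- simulate_expression(cfg)
    fc <- compute_fc(sim$matrix, pseudocount = 1e-6)
    up <- sim$truth$gene[sim$truth$log2fc > 0]
    abs(stats::median(log2(fc$fc[up])) - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.1)
  expect_lte(errs[2], errs[1] + 0.02)
  # median linear FC of positively planted genes near 2 at n = 10
  cfg <- simulation_config(n_genes = 2000L, n_case = 10L, n_control = 10L,
                           de_fraction = 0.1, de_log2fc_mean = 1,
                           de_log2fc_sd = 0, noise_sd = 0.5, seed = 3L)
  sim <- simulate_expression(cfg)
  fc <- compute_fc(sim$matrix, pseudocount = 1e-6)
  up <- sim$truth$gene[sim$truth$log2fc > 0]
  expect_gt(stats::median(fc$fc[up]), 1.8)
  expect_lt(stats::median(fc$fc[up]), 2.2)
})

test_that("matrix and design TSVs round-trip", {
  em <- small_matrix(matrix(c(10, 20, 30, 40), 2), matrix(c(1, 2, 3, 4), 2))
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  design_path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE)
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(em$values), group = em$groups),
              design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  em2 <- read_expression_matrix(mat_path, design_path)
  expect_equal(em2$values, em$values)
  expect_equal(em2$groups, em$groups)
})
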