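test_that("the generators are deterministic given a seed", {
  cfg <- simulation_config(n_genes = 200L, n_case = 4L, n_control = 4L,
                           n_agents = 10L, n_reversers = 2L,
                           n_mimickers = 2L, seed = 5L)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  l1 <- simulate_agent_library(s1$truth, cfg)
  l2 <- simulate_agent_library(s2$truth, cfg)
  expect_identical(l1$labels, l2$labels)
  expect_identical(l1$library$agents$agent_003$fc,
                   l2$library$agents$agent_003$fc)
  g1 <- simulate_gene_sets(s1$truth$gene, n_sets = 5L,
                           set_size_range = c(5L, 20L), seed = 5L)
  g2 <- simulate_gene_sets(s1$truth$gene, n_sets = 5L,
                           set_size_range = c(5L, 20L), seed = 5L)
  expect_identical(g1$sets, g2$sets)
})

test_that("a null simulation has no planted signal", {
  cfg <- simulation_config(n_genes = 1000L, de_fraction = 0, seed = 9L)
  sim <- simulate_expression(cfg)
  expect_true(all(sim$truth$log2fc == 0))
  fc <- compute_fc(sim$matrix, pseudocount = 1e-6)
  # estimated fold changes hover around 1 within sampling noise
  expect_lt(stats::median(abs(log2(fc$fc))), 0.2)
  expect_warning(extract_signature(fc, signature_config(4, 0.1)),
                 "empty signature")
})

test_that("planted DE genes are recovered by the signature thresholds", {
  cfg <- simulation_config(n_genes = 5000L, n_case = 10L, n_control = 10L,
                           de_fraction = 0.1, de_log2fc_mean = 1.5,
                           seed = 11L)
  sim <- simulate_expression(cfg)
  sig <- extract_signature(compute_fc(sim$matrix),
                           signature_config(1.50, 0.67))
  de <- sim$truth$gene[sim$truth$is_de]
  recall <- length(intersect(signature_genes(sig), de)) / length(de)
  expect_gte(recall, 0.8)
})

test_that("a noiseless full-strength reverser is the exact reciprocal", {
  cfg <- simulation_config(n_genes = 100L, n_agents = 3L, n_reversers = 1L,
                           n_mimickers = 1L, reversal_strength = 1,
                           agent_noise_sd = 0, seed = 13L)
  sim <- simulate_expression(cfg)
  lib <- simulate_agent_library(sim$truth, cfg)
  rev_id <- lib$labels$agent_id[lib$labels$role == "reverser"]
  truth_fc <- 2^sim$truth$log2fc
  names(truth_fc) <- sim$truth$gene
  expect_equal(lib$library$agents[[rev_id]]$fc, 1 / truth_fc,
               tolerance = 1e-12)
  disease <- fc_profile(truth_fc[sim$truth$is_de], "disease")
  agent <- lib$library$agents[[rev_id]]
  expect_equal(spearman_reversal(disease, agent)$rho, -1)
})

test_that("the designated enriched set dominates the ORA ranking", {
  set.seed(17)
  universe <- sprintf("G%04d", 1:2000)
  degs <- sample(universe, 200)
  first <- vapply(1:100, function(i) {
    coll <- simulate_gene_sets(universe, n_sets = 20L,
                               set_size_range = c(50L, 100L),
                               enriched_in = degs, oversample_rate = 5,
                               seed = 1000L + i)
    res <- ora(degs, coll)
    res$set_name[1] == "enriched_set"
  }, logical(1))
  expect_gte(mean(first), 0.95)
})

test_that("null ORA p-values are approximately uniform", {
  set.seed(19)
  universe <- sprintf("G%05d", 1:20000)
  coll <- simulate_gene_sets(universe, n_sets = 200L,
                             set_size_range = c(500L, 3000L), seed = 23L)
  degs <- sample(universe, 2000)
  res <- ora(degs, coll)
  d <- suppressWarnings(stats::ks.test(res$p, "punif"))$statistic
  # 99th percentile of the one-sample KS statistic at n = 200 is ~0.115
  expect_lt(unname(d), 0.115)
})

test_that("the correlated-pair generator plants the requested Spearman rho", {
  pair <- simulate_reversal_pair(n_genes = 10000L, target_rho = -0.2,
                                 seed = 7L)
  v <- validate_reversal(pair$treatment, pair$disease)
  expect_lt(abs(v$rho - (-0.2)), 0.05)
  expect_equal(v$label, "reversal")
  # symmetric target on the positive side
  pair2 <- simulate_reversal_pair(n_genes = 10000L, target_rho = 0.5,
                                  seed = 7L)
  rho2 <- spearman_reversal(pair2$disease, pair2$treatment)$rho
  expect_lt(abs(rho2 - 0.5), 0.05)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(), class = "revscreen_validation_error")
  expect_error(simulation_config(n_agents = 5L, n_reversers = 4L,
                                 n_mimickers = 3L, seed = 1L),
               class = "revscreen_validation_error")
  expect_error(simulation_config(de_fraction = 1.2, seed = 1L),
               class = "revscreen_validation_error")
  expect_error(simulation_config(reversal_strength = 0, seed = 1L),
               class = "revscreen_validation_error")
  expect_error(simulate_gene_sets(letters, n_sets = 2L,
                                  set_size_range = c(5L, 100L), seed = 1L),
               class = "revscreen_validation_error")
})
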