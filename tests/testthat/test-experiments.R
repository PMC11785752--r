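test_that("Mann-Whitney U and exact p reproduce brute-force rank enumeration", {
  set.seed(42)
  for (n1 in 1:6) for (n2 in 1:6) {
    x <- round(stats::runif(n1), 6)
    y <- round(stats::runif(n2) + 0.1, 6)
    got <- rnmsim:::mann_whitney(x, y)
    want <- brute_force_mw(x, y)
    expect_equal(got$U, want$U, info = sprintf("n1=%d n2=%d", n1, n2))
    expect_equal(got$p, want$p, tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
  # the classic maximal-separation case: U = 0 under the min convention
  got <- rnmsim:::mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)
})

test_that("distribution comparison handles identical, separated and tied samples", {
  b <- matrix(0.1, 50, 1, dimnames = list(NULL, "X"))
  q <- matrix(0.9, 50, 1, dimnames = list(NULL, "X"))
  sep <- compare_distributions(b, q)
  expect_lt(sep$p, 1e-10)
  expect_equal(sep$direction, "up")
  expect_true(sep$significant)

  same <- compare_distributions(b, b)
  expect_equal(same$p, 1)
  expect_equal(same$U, 50 * 50 / 2)
  expect_equal(same$direction, "unchanged")
  expect_false(same$significant)

  # symmetry: swapping samples flips direction, keeps U and p
  swapped <- compare_distributions(q, b)
  expect_equal(swapped$U, sep$U)
  expect_equal(swapped$p, sep$p)
  expect_equal(swapped$direction, "down")
})

test_that("perturbations are paired with the baseline and follow edge signs", {
  cfg <- simulation_config()
  base_pos <- suppressWarnings(
    run_baseline_ensemble(toy("cascade_pos"), cfg, clamps = c(A = 0),
                          n_runs = 20, seed_base = 0))
  up <- run_perturbation(toy("cascade_pos"), cfg, c(A = 1), base_pos)
  expect_true(all(up$steady_states[, "B"] > 0.99))
  cmp <- compare_distributions(base_pos, up)
  expect_equal(cmp$direction[cmp$node == "B"], "up")

  base_neg <- suppressWarnings(
    run_baseline_ensemble(toy("cascade_neg"), cfg, clamps = c(A = 0),
                          n_runs = 20, seed_base = 0))
  down <- run_perturbation(toy("cascade_neg"), cfg, c(A = 1), base_neg)
  expect_true(all(down$steady_states[, "B"] < 0.01))

  # clamping a node at the value it already holds in a fixed-point ensemble
  # leaves every steady state unchanged
  again <- run_perturbation(toy("cascade_pos"), cfg, c(A = 0), base_pos)
  expect_equal(again$steady_states, base_pos$steady_states, tolerance = 1e-6)
  expect_identical(again$seeds, base_pos$seeds)
})

test_that("monotone sanity: clamping a pure activator never lowers its target", {
  cfg <- simulation_config()
  net <- toy("cascade_pos")
  base <- suppressWarnings(
    run_baseline_ensemble(net, cfg, clamps = c(A = 0.4), n_runs = 10,
                          seed_base = 3))
  pert <- run_perturbation(net, cfg, c(A = 1), base)
  expect_true(all(pert$steady_states[, "B"] >=
                    base$steady_states[, "B"] - 1e-8))
  neg <- toy("cascade_neg")
  base2 <- suppressWarnings(
    run_baseline_ensemble(neg, cfg, clamps = c(A = 0.4), n_runs = 10,
                          seed_base = 3))
  pert2 <- run_perturbation(neg, cfg, c(A = 1), base2)
  expect_true(all(pert2$steady_states[, "B"] <=
                    base2$steady_states[, "B"] + 1e-8))
})

test_that("rescue experiments compare degenerate and rescued ensembles", {
  cfg <- simulation_config()
  # driver D activates T; rescue R inhibits T
  net <- regulatory_network(
    c("D", "R", "T"),
    data.frame(source = c("D", "R"), target = "T", effect = c(1L, -1L)))
  base <- suppressWarnings(
    run_baseline_ensemble(net, cfg, clamps = c(D = 0, R = 0), n_runs = 20,
                          seed_base = 1))
  res <- rescue_experiment(net, cfg, degenerate_clamps = c(D = 1),
                           rescue_clamps = c(R = 1), baseline = base)
  expect_gt(stats::median(res$degenerate$steady_states[, "T"]), 0.9)
  expect_lt(stats::median(res$rescued$steady_states[, "T"]), 0.1)
  row_t <- res$comparison[res$comparison$node == "T", ]
  expect_true(row_t$significant)
  expect_equal(row_t$direction, "down")

  # rescue identical to the degenerate clamps changes nothing
  null_res <- rescue_experiment(net, cfg, degenerate_clamps = c(D = 1),
                                rescue_clamps = c(D = 1), baseline = base)
  expect_false(any(null_res$comparison$significant))

  # co-stimulation: several degenerate clamps accepted as one set
  co <- rescue_experiment(net, cfg, degenerate_clamps = c(D = 1, R = 0),
                          rescue_clamps = c(R = 1), baseline = base)
  expect_s3_class(co$comparison, "comparison_result")
})

test_that("phenotype classification contrasts group means with a margin", {
  groups <- list(anabolic = c("ACAN", "COL2A"), catabolic = c("MMP3", "TNF"))
  ss <- c(ACAN = 1, COL2A = 1, MMP3 = 0, TNF = 0)
  expect_equal(classify_phenotype(ss, groups)$call, "pro-anabolic")
  expect_equal(classify_phenotype(1 - ss, groups)$call, "pro-catabolic")
  flat <- c(ACAN = 0.5, COL2A = 0.5, MMP3 = 0.5, TNF = 0.5)
  expect_equal(classify_phenotype(flat, groups, margin = 0.01)$call,
               "balanced")
  expect_error(classify_phenotype(ss, list(anabolic = character(0),
                                           catabolic = "TNF")),
               class = "rnm_config_error")
  expect_error(classify_phenotype(ss[-1], groups),
               class = "rnm_lookup_error")
})
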