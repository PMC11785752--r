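# Independent oracles and shared fixtures for the suite.

# Brute-force two-sided Mann-Whitney: enumerate every assignment of the
# combined ranks to the first sample (no ties assumed) and compute
# P(|U1 - n1 n2 / 2| >= observed) exactly.
brute_force_mw <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u1_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  m <- n1 * n2 / 2
  d_obs <- abs(u1_obs - m)
  subsets <- utils::combn(n1 + n2, n1)
  u1_all <- colSums(matrix(seq_len(n1 + n2)[subsets], nrow = n1)) -
    n1 * (n1 + 1) / 2
  list(U = min(u1_obs, n1 * n2 - u1_obs),
       p = mean(abs(u1_all - m) >= d_obs - 1e-12))
}

# Brute-force cell-means ANOVA sum of squares for one effect of a balanced
# two-level design: group rows by the effect's +/-1 code and accumulate
# n_g (mean_g - grand mean)^2.
brute_force_effect_ss <- function(code, y) {
  grand <- mean(y)
  sum(vapply(split(y, code), function(v) length(v) * (mean(v) - grand)^2, 0))
}

# Effect +/-1 codes of a design, mirroring the modelled effect set.
design_codes <- function(design, order = "main+second") {
  lv <- sort(design$levels)
  coded <- ifelse(design$rows == lv[2], 1, -1)
  cols <- list()
  p <- length(design$factors)
  for (j in seq_len(p)) cols[[design$factors[j]]] <- coded[, j]
  if (order == "main+second" && p >= 2) {
    for (j in seq_len(p - 1)) for (k in seq(j + 1, p)) {
      cols[[paste(design$factors[j], design$factors[k], sep = ":")]] <-
        coded[, j] * coded[, k]
    }
  }
  cols
}

# Shared expensive fixtures, built once per test run.
.shared <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (is.null(.shared$fx)) .shared$fx <- generate_paper_like_fixture(0)
  .shared$fx
}

shared_baseline <- function() {
  if (is.null(.shared$base))
    .shared$base <- run_baseline_ensemble(shared_fixture(),
                                          simulation_config(),
                                          n_runs = 100, seed_base = 0)
  .shared$base
}

toy <- function(name) generate_toy_motifs()[[name]]

quiet_integrate <- function(...) {
  suppressWarnings(integrate_to_steady_state(...))
}
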