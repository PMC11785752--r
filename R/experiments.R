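# In-silico perturbation protocols: sustained activation (clamping) of
# chosen nodes starting from a baseline ensemble's steady states, rescue
# stimulations layered on a degenerate baseline, node-wise Mann-Whitney
# comparison of steady-state distributions, and anabolic/catabolic
# phenotype calls.

#' Define a perturbation protocol
#'
#' @param label human-readable protocol name.
#' @param added_clamps named vector of clamps applied by the perturbation
#'   (values in \[0,1\], typically 1 for sustained stimulation).
#' @param baseline_clamps clamps already active in the baseline (kept during
#'   the perturbation); keys may overlap `added_clamps` only with equal
#'   values.
#' @param start_mode `"from-baseline-SS"` (each baseline run's steady state
#'   is the initial condition; default) or `"from-random"` (fresh random
#'   initial conditions with the baseline's seeds).
#' @return object of class `perturbation_protocol`.
#' @export
perturbation_protocol <- function(label, added_clamps,
                                  baseline_clamps = NULL,
                                  start_mode = c("from-baseline-SS",
                                                 "from-random")) {
  start_mode <- match.arg(start_mode)
  added_clamps <- unlist(added_clamps)
  baseline_clamps <- unlist(baseline_clamps)
  shared <- intersect(names(added_clamps), names(baseline_clamps))
  if (length(shared) &&
      any(added_clamps[shared] != baseline_clamps[shared]))
    config_error("added_clamps conflict with baseline_clamps on shared nodes")
  structure(list(label = label, added_clamps = added_clamps,
                 baseline_clamps = baseline_clamps, start_mode = start_mode),
            class = "perturbation_protocol")
}

#' Run a clamping perturbation against a baseline ensemble
#'
#' For `start_mode = "from-baseline-SS"`, run k of the perturbed ensemble
#' integrates from run k's baseline steady state with the union of baseline
#' and added clamps, so perturbed runs are paired run-by-run with the
#' baseline.  Unconverged baseline runs propagate their flag.
#'
#' @param net a `regulatory_network`.
#' @param cfg a `simulation_config`.
#' @param protocol a `perturbation_protocol` (or named clamp vector, taken
#'   as `added_clamps`).
#' @param baseline an `ensemble_result` computed on the same network/config.
#' @return an `ensemble_result`, paired run-by-run with `baseline`.
#' @export
run_perturbation <- function(net, cfg, protocol, baseline) {
  if (!inherits(protocol, "perturbation_protocol"))
    protocol <- perturbation_protocol("perturbation", protocol)
  clamps <- c(protocol$baseline_clamps,
              protocol$added_clamps[setdiff(names(protocol$added_clamps),
                                            names(protocol$baseline_clamps))])
  m <- compile_model(net, cfg, clamps)
  if (!identical(colnames(baseline$steady_states), m$names))
    validation_error("baseline was computed on a different node set")
  n_runs <- nrow(baseline$steady_states)
  x0 <- if (protocol$start_mode == "from-baseline-SS")
    baseline$steady_states
  else {
    x <- sample_initial_conditions(m$n, n_runs, baseline$seeds[1])
    colnames(x) <- m$names
    x
  }
  ss <- matrix(NA_real_, n_runs, m$n, dimnames = list(NULL, m$names))
  converged <- logical(n_runs)
  for (k in seq_len(n_runs)) {
    res <- steady_state_fast(unname(x0[k, ]), m)
    ss[k, ] <- res$state
    converged[k] <- res$converged
  }
  finalize_ensemble(ss, x0, converged, baseline$seeds, baseline$cluster_tol,
                    net, cfg, clamps)
}

# --- Mann-Whitney U ---------------------------------------------------------

# Exact or approximate two-sided Mann-Whitney U test.
# Convention: U = min(U1, U2); two-sided p = P(|U1 - n1 n2 / 2| >= observed)
# under the null.  Exact null (stats::pwilcox) when min(n1, n2) <= 20 and no
# ties; normal approximation with tie correction otherwise.
mann_whitney <- function(x, y, equal_tol = 0) {
  n1 <- length(x)
  n2 <- length(y)
  if (!n1 || !n2) validation_error("empty sample in Mann-Whitney test")
  # samples whose pooled spread is below equal_tol are identical for all
  # practical purposes (differences at the solver-tolerance scale carry no
  # signal, only integration rounding)
  if (diff(range(c(x, y))) <= equal_tol)
    return(list(U = n1 * n2 / 2, p = 1, u1 = n1 * n2 / 2))
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && min(n1, n2) <= 20L) {
    # P(U1 <= m - d) + P(U1 >= m + d), d = |u1 - m|; capped at 1
    p <- stats::pwilcox(u, n1, n2) +
      stats::pwilcox(n1 * n2 - u - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
         ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1, u1 = u1))
    z <- (u1 - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = u, p = p, u1 = u1)
}

#' Compare two steady-state ensembles node by node
#'
#' Two-sided Mann-Whitney U test per node (convention `U = min(U1, U2)`;
#' exact null when `min(n1, n2) <= 20` and no ties, normal approximation
#' with tie correction otherwise; no multiple-testing correction).
#' Direction is the sign of the median shift (perturbed minus baseline);
#' identical samples give `U = n1 n2 / 2`, `p = 1`, `"unchanged"`.
#'
#' @param baseline,perturbed `ensemble_result` objects on the same node set
#'   (or plain runs x nodes matrices).
#' @param alpha significance level in (0,1), default 0.05.
#' @param equal_tol two samples whose pooled range is narrower than this are
#'   treated as identical (default `1e-5`): shifts at the steady-state
#'   solver-tolerance scale are integration rounding, not signal.
#' @return object of class `comparison_result`: data.frame with `node`, `U`,
#'   `p`, `median_baseline`, `median_perturbed`, `direction`
#'   (up/down/unchanged), `significant`.
#' @export
compare_distributions <- function(baseline, perturbed, alpha = 0.05,
                                  equal_tol = 1e-5) {
  if (alpha <= 0 || alpha >= 1) config_error("alpha must lie in (0,1)")
  b <- ensemble_matrix(baseline)
  q <- ensemble_matrix(perturbed)
  if (!identical(colnames(b), colnames(q)))
    validation_error("ensembles have different node sets")
  rows <- lapply(colnames(b), function(nd) {
    mw <- mann_whitney(b[, nd], q[, nd], equal_tol)
    mb <- stats::median(b[, nd])
    mq <- stats::median(q[, nd])
    shifted <- abs(mq - mb) > equal_tol
    data.frame(node = nd, U = mw$U, p = mw$p,
               median_baseline = mb, median_perturbed = mq,
               direction = if (shifted && mq > mb) "up"
                           else if (shifted && mq < mb) "down"
                           else "unchanged",
               significant = mw$p < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_result", class(out))
  out
}

ensemble_matrix <- function(x) {
  if (inherits(x, "ensemble_result"))
    x$steady_states[x$converged, , drop = FALSE]
  else as.matrix(x)
}

#' Rescue experiment on a degenerate baseline
#'
#' Builds a degenerate ensemble by clamping `degenerate_clamps` (e.g.
#' TNF = 1, or TNF and IL-1β co-stimulation) on top of the healthy baseline,
#' then layers `rescue_clamps` on the degenerate state and compares the two.
#' `mode = "sequential"` (default) equilibrates the degenerate clamp first
#' and starts the rescue from the degenerate steady states;
#' `"simultaneous"` applies both clamp sets together from the healthy
#' baseline steady states.
#'
#' @param net a `regulatory_network`.
#' @param cfg a `simulation_config`.
#' @param degenerate_clamps named clamp set creating the degenerate baseline.
#' @param rescue_clamps named clamp set of the rescue stimulation.
#' @param baseline healthy-baseline `ensemble_result`.
#' @param alpha significance level for the node-wise comparison.
#' @param mode `"sequential"` or `"simultaneous"`.
#' @return list with `degenerate` and `rescued` (`ensemble_result`s) and
#'   `comparison` (degenerate vs rescued `comparison_result`).
#' @export
rescue_experiment <- function(net, cfg, degenerate_clamps, rescue_clamps,
                              baseline, alpha = 0.05,
                              mode = c("sequential", "simultaneous")) {
  mode <- match.arg(mode)
  degenerate_clamps <- unlist(degenerate_clamps)
  rescue_clamps <- unlist(rescue_clamps)
  degen <- run_perturbation(net, cfg,
                            perturbation_protocol("degenerate",
                                                  degenerate_clamps),
                            baseline)
  start <- if (mode == "sequential") degen else baseline
  # the rescue stimulation overrides the degenerate level of any node it
  # re-clamps (e.g. stimulating a factor the degenerate clamp held at 0)
  kept <- degenerate_clamps[setdiff(names(degenerate_clamps),
                                    names(rescue_clamps))]
  rescued <- run_perturbation(net, cfg,
    perturbation_protocol("rescue", rescue_clamps, baseline_clamps = kept),
    start)
  list(degenerate = degen, rescued = rescued,
       comparison = compare_distributions(degen, rescued, alpha))
}

#' Classify a steady state as pro-anabolic or pro-catabolic
#'
#' The anabolic index is the mean activation over the anabolic group
#' (structural proteins and growth factors); the catabolic index over the
#' catabolic group (degrading enzymes and pro-inflammatory cytokines).  The
#' call contrasts the two with a declared margin.
#'
#' @param ss named steady-state vector.
#' @param groups list with character vectors `anabolic` and `catabolic`
#'   (non-empty, nodes present in `ss`).
#' @param margin decision margin (default 0.1): pro-anabolic if
#'   anabolic - catabolic > margin, pro-catabolic if < -margin, else
#'   balanced.
#' @return list of class `phenotype_score`: `anabolic_index`,
#'   `catabolic_index`, `call`.
#' @export
classify_phenotype <- function(ss, groups, margin = 0.1) {
  if (is.null(groups$anabolic) || !length(groups$anabolic) ||
      is.null(groups$catabolic) || !length(groups$catabolic))
    config_error("groups must contain non-empty 'anabolic' and 'catabolic'")
  miss <- setdiff(c(groups$anabolic, groups$catabolic), names(ss))
  if (length(miss))
    lookup_error(sprintf("state lacks node(s): %s",
                         paste(miss, collapse = ", ")))
  a <- mean(ss[groups$anabolic])
  c_ <- mean(ss[groups$catabolic])
  call <- if (a - c_ > margin) "pro-anabolic"
          else if (a - c_ < -margin) "pro-catabolic" else "balanced"
  structure(list(anabolic_index = a, catabolic_index = c_, call = call,
                 margin = margin),
            class = "phenotype_score")
}

#' @export
print.phenotype_score <- function(x, ...) {
  cat(sprintf("<phenotype_score> %s (anabolic %.3f vs catabolic %.3f, margin %g)\n",
              x$call, x$anabolic_index, x$catabolic_index, x$margin))
  invisible(x)
}
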