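# Baseline protocol: integrate the system from many uniform-random initial
# conditions (one Mersenne-Twister stream per run, seeded seed_base + k),
# cluster the resulting steady states (single linkage, Chebyshev distance)
# and report the dominant-attractor fraction and per-node distribution
# summaries.

#' Sample random initial conditions
#'
#' Run `k` (1-based) draws its state from a Mersenne-Twister stream seeded
#' `seed_base + k - 1`, uniform on \[0,1\]^n.  Deterministic given
#' (`seed_base`, `n_runs`, `n_nodes`); the caller's RNG state is left
#' untouched.
#'
#' @param n_nodes number of nodes.
#' @param n_runs number of runs, >= 1.
#' @param seed_base first seed (default 0: seeds 0..n_runs-1).
#' @return matrix `n_runs` x `n_nodes` of initial conditions.
#' @export
sample_initial_conditions <- function(n_nodes, n_runs, seed_base = 0L) {
  if (n_runs < 1L) config_error("n_runs must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  out <- matrix(NA_real_, n_runs, n_nodes)
  for (k in seq_len(n_runs)) {
    set.seed(seed_base + k - 1L, kind = "Mersenne-Twister")
    out[k, ] <- stats::runif(n_nodes)
  }
  out
}

#' Cluster steady states into attractors
#'
#' Single-linkage grouping under the Chebyshev (maximum-coordinate) metric:
#' two states belong to the same attractor cluster iff they are connected by
#' a chain of states at pairwise distance <= `tol`.  Cluster labels are
#' canonicalised by decreasing cluster size, ties broken by smallest row
#' index, so the labelling is independent of input order up to relabelling.
#'
#' @param steady_states matrix (runs x nodes).
#' @param tol distance threshold (default 0.01).
#' @return integer vector of cluster labels, 1 = largest cluster.
#' @export
cluster_attractors <- function(steady_states, tol = 0.01) {
  ss <- as.matrix(steady_states)
  n <- nrow(ss)
  if (n == 0L) validation_error("need at least one steady state")
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(ss, method = "maximum"), method = "single")
  raw <- stats::cutree(hc, h = tol)
  sizes <- table(raw)
  first <- vapply(split(seq_len(n), raw), min, 0L)
  ord <- order(-as.integer(sizes), first)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  relabel[raw]
}

#' Run the random-initial-condition baseline ensemble
#'
#' Integrates `n_runs` random initial conditions to steady state under the
#' given clamps, clusters the converged steady states into attractors, and
#' summarises per-node distributions.  Unconverged runs are never discarded
#' silently: they are flagged, excluded from clustering, and reported.
#'
#' @param net a `regulatory_network`.
#' @param cfg a `simulation_config`.
#' @param clamps optional named clamp set.
#' @param n_runs number of runs (default 100).
#' @param seed_base base seed (default 0).
#' @param cluster_tol Chebyshev tolerance for attractor identity
#'   (default 0.01).
#' @return object of class `ensemble_result`: `steady_states` (runs x nodes),
#'   `initial_states`, `seeds`, `converged`, `clusters` (NA for unconverged
#'   runs), `dominant_fraction` (largest cluster over all runs), `summary`
#'   (see [summarize_baseline()]), plus the network/config used.
#' @export
run_baseline_ensemble <- function(net, cfg = simulation_config(),
                                  clamps = NULL, n_runs = 100L,
                                  seed_base = 0L, cluster_tol = 0.01) {
  m <- compile_model(net, cfg, clamps)
  x0 <- sample_initial_conditions(m$n, n_runs, seed_base)
  colnames(x0) <- m$names
  ss <- matrix(NA_real_, n_runs, m$n, dimnames = list(NULL, m$names))
  converged <- logical(n_runs)
  for (k in seq_len(n_runs)) {
    res <- tryCatch(steady_state_fast(x0[k, ], m), rnm_error = function(e) {
      numerical_error(sprintf("run %d failed: %s", k, conditionMessage(e)))
    })
    ss[k, ] <- res$state
    converged[k] <- res$converged
  }
  finalize_ensemble(ss, x0, converged, seed_base + seq_len(n_runs) - 1L,
                    cluster_tol, net, cfg, clamps)
}

finalize_ensemble <- function(ss, x0, converged, seeds, cluster_tol,
                              net, cfg, clamps) {
  n_runs <- nrow(ss)
  clusters <- rep(NA_integer_, n_runs)
  if (any(converged))
    clusters[converged] <- cluster_attractors(ss[converged, , drop = FALSE],
                                              cluster_tol)
  dominant <- if (any(converged)) max(table(clusters[converged])) / n_runs
              else 0
  out <- structure(
    list(steady_states = ss, initial_states = x0, seeds = seeds,
         converged = converged, clusters = clusters,
         dominant_fraction = dominant, cluster_tol = cluster_tol,
         clamps = clamps, network = net, config = cfg),
    class = "ensemble_result")
  out$summary <- summarize_baseline(out)
  out
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_result> %d runs x %d nodes; %d converged; ",
                     "%d attractor cluster(s); dominant fraction %.2f\n"),
              nrow(x$steady_states), ncol(x$steady_states), sum(x$converged),
              length(unique(stats::na.omit(x$clusters))),
              x$dominant_fraction))
  invisible(x)
}

#' Per-node summary of an ensemble
#'
#' Boxplot-style statistics per node over converged runs: median, quartiles
#' (type-7), 1.5 IQR whiskers clipped to the data, outlier count, and the
#' skewness sign (third central moment) describing whether the distribution
#' is right- or left-skewed.
#'
#' @param result an `ensemble_result`.
#' @return data.frame with one row per node: `node`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `n_outliers`, `skewness`, `skew`.
#' @export
summarize_baseline <- function(result) {
  ss <- result$steady_states[result$converged, , drop = FALSE]
  if (!nrow(ss)) {
    # nothing converged: summarise the final states so the failure is
    # inspectable, and say so
    warning("no converged runs; summarising unconverged final states",
            call. = FALSE)
    ss <- result$steady_states
  }
  stat1 <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    inside <- v >= lo & v <= hi
    m3 <- mean((v - mean(v))^3)
    c(median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = if (any(inside)) min(v[inside]) else q[1],
      whisker_high = if (any(inside)) max(v[inside]) else q[3],
      n_outliers = sum(!inside), skewness = m3)
  }
  stats_mat <- t(apply(ss, 2L, stat1))
  out <- data.frame(node = colnames(ss), stats_mat, row.names = NULL)
  out$skew <- ifelse(abs(out$skewness) < 1e-12, "symmetric",
                     ifelse(out$skewness > 0, "right", "left"))
  out
}
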