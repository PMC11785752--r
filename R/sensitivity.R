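# Full-factorial sensitivity screening: generate all n^p level combinations
# over a factor set, integrate each combination (factors as initial
# conditions, never clamped) to steady state, and rank effects by a
# fixed-effects factorial ANOVA on +/-1-coded contrasts, reported as
# F = (MSB/MSW) x 100 with second-order interactions included.

#' Generate a two-level full factorial design
#'
#' All `n^p` combinations of `p` factors at the given levels, in canonical
#' order (last factor varies fastest), deterministic.
#'
#' @param factors character vector of factor (node) names, no duplicates.
#' @param levels the two treatment values (default `c(0, 1)`).
#' @return object of class `factorial_design`: `factors`, `levels`, `rows`
#'   (matrix `n^p` x `p`).
#' @export
full_factorial <- function(factors, levels = c(0, 1)) {
  if (!length(factors)) config_error("need at least one factor")
  if (anyDuplicated(factors))
    config_error(sprintf("duplicate factor name(s): %s",
      paste(unique(factors[duplicated(factors)]), collapse = ", ")))
  if (length(levels) != 2L || levels[1] == levels[2])
    config_error("need exactly two distinct levels")
  p <- length(factors)
  grid <- do.call(expand.grid, c(rep(list(levels), p),
                                 KEEP.OUT.ATTRS = FALSE))
  # expand.grid varies the first column fastest; canonical order wants the
  # last factor fastest, so reverse the column roles
  rows <- as.matrix(grid[, rev(seq_len(p)), drop = FALSE])
  dimnames(rows) <- list(NULL, factors)
  structure(list(factors = factors, levels = levels, rows = rows),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("<factorial_design> %d factors x 2 levels = %d rows\n",
              length(x$factors), nrow(x$rows)))
  invisible(x)
}

#' Integrate every design row to steady state
#'
#' Each design row sets the factor nodes' initial values to their levels;
#' every other node starts at the background state.  Factors are initial
#' conditions only -- never clamped -- so the system relaxes freely from
#' each combination.  Deterministic.
#'
#' @param net a `regulatory_network`.
#' @param cfg a `simulation_config`.
#' @param design a `factorial_design` whose factors are nodes of `net`.
#' @param background named full state vector for non-factor nodes, or a
#'   single value recycled to all nodes (default 0.5); the per-node medians
#'   of a baseline ensemble are the recommended choice.
#' @param responses character vector of response node names (default: all
#'   nodes).
#' @return matrix rows x responses of steady-state levels, with attribute
#'   `converged` (logical per row).
#' @export
run_design <- function(net, cfg, design, background = 0.5,
                       responses = NULL) {
  m <- compile_model(net, cfg)
  miss <- setdiff(design$factors, m$names)
  if (length(miss))
    lookup_error(sprintf("factor(s) not in network: %s",
                         paste(miss, collapse = ", ")))
  if (is.null(responses)) responses <- m$names
  responses <- canonical_node_name(responses)
  miss <- setdiff(responses, m$names)
  if (length(miss))
    lookup_error(sprintf("response(s) not in network: %s",
                         paste(miss, collapse = ", ")))
  bg <- if (length(background) == 1L && is.null(names(background)))
    rep(as.numeric(background), m$n)
  else as_state(background, m)
  fi <- match(design$factors, m$names)
  ri <- match(responses, m$names)
  nr <- nrow(design$rows)
  out <- matrix(NA_real_, nr, length(responses),
                dimnames = list(NULL, responses))
  converged <- logical(nr)
  for (i in seq_len(nr)) {
    x0 <- bg
    x0[fi] <- design$rows[i, ]
    res <- tryCatch(steady_state_fast(x0, m), rnm_error = function(e)
      numerical_error(sprintf("design row %d failed: %s", i,
                              conditionMessage(e))))
    out[i, ] <- res$state[ri]
    converged[i] <- res$converged
  }
  attr(out, "converged") <- converged
  out
}

# +/-1 coding of a two-level design (low level -> -1, high -> +1).
coded_matrix <- function(design) {
  lv <- sort(design$levels)
  ifelse(design$rows == lv[2], 1, -1)
}

effect_columns <- function(design, order) {
  p <- length(design$factors)
  coded <- coded_matrix(design)
  cols <- list()
  for (j in seq_len(p)) cols[[design$factors[j]]] <- coded[, j]
  if (order == "main+second" && p >= 2L) {
    for (j in seq_len(p - 1L)) for (k in seq(j + 1L, p)) {
      nm <- paste(design$factors[j], design$factors[k], sep = ":")
      cols[[nm]] <- coded[, j] * coded[, k]
    }
  }
  cols
}

#' Factorial ANOVA effect screening
#'
#' Fixed-effects factorial ANOVA of each response on the +/-1-coded main
#' effects (and, by default, all second-order interactions).  Each effect
#' has 1 df: `MSB` is its contrast sum of squares; `MSW` is the residual
#' mean square after removing all modelled effects.  The reported
#' `F = (MSB/MSW) x 100`; the p-value comes from the unscaled ratio on
#' (1, residual df) -- the x100 is presentational scaling of the statistic
#' only.  The `sign` of a main effect (or interaction) is the sign of its
#' contrast coefficient on the response: `+` means the high level raises the
#' response.  A response explained perfectly (`MSW = 0`) is flagged and
#' reported with `F = Inf`, `p = 0`.
#'
#' @param design a `factorial_design`.
#' @param responses matrix rows x response nodes (from [run_design()]), or a
#'   vector for a single response.
#' @param order `"main+second"` (default) or `"main"`.
#' @return data.frame of effect records: `effect`, `response`,
#'   `effect_order` (1 or 2), `MSB`, `MSW`, `F` (scaled x100), `p`, `sign`,
#'   `significant` (p <= 0.05), `perfect_fit`.
#' @export
anova_effects <- function(design, responses,
                          order = c("main+second", "main")) {
  order <- match.arg(order)
  if (is.null(dim(responses)))
    responses <- matrix(responses, ncol = 1L,
                        dimnames = list(NULL, "response"))
  responses <- as.matrix(responses)
  N <- nrow(design$rows)
  if (nrow(responses) != N)
    validation_error("responses do not match the design row count")
  cols <- effect_columns(design, order)
  nE <- length(cols)
  df_res <- N - 1L - nE
  if (df_res < 0L) config_error("more effects than residual degrees of freedom")
  out <- list()
  for (resp in colnames(responses)) {
    y <- responses[, resp]
    tot <- sum((y - mean(y))^2)
    ssE <- vapply(cols, function(cc) sum(cc * y)^2 / N, 0)
    coef_sign <- vapply(cols, function(cc) sign(sum(cc * y)), 0)
    sse <- max(tot - sum(ssE), 0)
    scale_ref <- max(tot, 1e-300)
    perfect <- df_res == 0L | sse <= 1e-10 * scale_ref
    msw <- if (df_res > 0L) sse / df_res else NA_real_
    if (perfect || !is.finite(msw) || msw <= 0) {
      f_raw <- ifelse(ssE > 0, Inf, 0)
      p <- ifelse(ssE > 0, 0, 1)
      perfect_flag <- rep(TRUE, nE)
      msw_rep <- rep(if (df_res > 0L) sse / df_res else 0, nE)
    } else {
      f_raw <- ssE / msw
      p <- stats::pf(f_raw, 1, df_res, lower.tail = FALSE)
      perfect_flag <- rep(FALSE, nE)
      msw_rep <- rep(msw, nE)
    }
    out[[resp]] <- data.frame(
      effect = names(cols), response = resp,
      effect_order = ifelse(grepl(":", names(cols), fixed = TRUE), 2L, 1L),
      MSB = unname(ssE), MSW = msw_rep, F = unname(f_raw) * 100,
      p = unname(p),
      sign = ifelse(coef_sign > 0, "+", ifelse(coef_sign < 0, "-", NA)),
      significant = unname(p) <= 0.05,
      perfect_fit = perfect_flag, row.names = NULL)
  }
  do.call(rbind, out) -> res
  rownames(res) <- NULL
  res
}

#' Aggregate effect records over response groups
#'
#' For each effect and named response group (e.g. structural proteins,
#' degrading enzymes), the effect is significant for the group if it is
#' significant (p <= 0.05) for at least one member response; the group F is
#' the maximum F across the group's responses.  Non-significant effects are
#' retained with a flag, never dropped.
#'
#' @param records effect records from [anova_effects()].
#' @param groups named list of character vectors of response nodes.
#' @return object of class `sensitivity_report`: `effects` (the input
#'   records) and `groups` (data.frame `group`, `effect`, `effect_order`,
#'   `F`, `p_min`, `sign`, `significant`).
#' @export
aggregate_groups <- function(records, groups) {
  if (!length(groups) || is.null(names(groups)))
    config_error("groups must be a named list of response-node vectors")
  rows <- list()
  for (g in names(groups)) {
    sub <- records[records$response %in% groups[[g]], , drop = FALSE]
    if (!nrow(sub)) next
    for (e in unique(sub$effect)) {
      se <- sub[sub$effect == e, , drop = FALSE]
      best <- which.max(se$F)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, effect = e, effect_order = se$effect_order[1],
        F = max(se$F), p_min = min(se$p), sign = se$sign[best],
        significant = any(se$significant))
    }
  }
  structure(list(effects = records,
                 groups = if (length(rows)) do.call(rbind, rows)
                          else data.frame()),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d effect records over %d response(s); %d group rows (%d significant)\n",
              nrow(x$effects), length(unique(x$effects$response)),
              nrow(x$groups), sum(x$groups$significant)))
  invisible(x)
}

#' Pareto table of a sensitivity report
#'
#' Orders effects by descending F (infinite, perfectly-explained effects
#' first; ties broken by effect then group/response name) and attaches
#' log10(F) for log-scale Pareto plotting.  The cytokine-style view
#' restricts to main effects via `effect_order = 1`; the growth-factor view
#' keeps interactions (`effect_order = NULL`).
#'
#' @param report a `sensitivity_report` (grouped rows are used) or a plain
#'   effect-record data.frame.
#' @param effect_order optional filter: keep only effects of this order
#'   (1 = main, 2 = second-order interaction).
#' @param significant_only keep only significant rows (default TRUE, the
#'   plotted set); non-significant rows are flagged, not reordered.
#' @return data.frame sorted by descending F with a `log10_F` column.
#' @export
pareto_table <- function(report, effect_order = NULL,
                         significant_only = TRUE) {
  tab <- if (inherits(report, "sensitivity_report")) report$groups else report
  if (!nrow(tab)) return(tab)
  if (!is.null(effect_order))
    tab <- tab[tab$effect_order %in% effect_order, , drop = FALSE]
  if (significant_only)
    tab <- tab[tab$significant, , drop = FALSE]
  if (!nrow(tab)) return(tab)
  label2 <- if ("group" %in% names(tab)) tab$group else tab$response
  ord <- order(-is.infinite(tab$F), -tab$F, tab$effect, label2)
  tab <- tab[ord, , drop = FALSE]
  tab$log10_F <- log10(tab$F)
  rownames(tab) <- NULL
  tab
}
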