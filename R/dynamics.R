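# The semi-quantitative engine. Each node n carries an activation level
# x_n in [0,1]. Regulated nodes follow
#     dx_n/dt = A(omega_n) - gamma * x_n
# where omega_n in [0,1] is the fuzzy-logic aggregate of the node's
# activators and inhibitors and A is a sigmoid with gain h normalised so
# that A(0)=0, A(0.5)=0.5, A(1)=1. Input nodes (no regulators) hold their
# initial value; clamped nodes hold their clamp value.

#' Simulation configuration
#'
#' Collects every dynamical parameter.  Defaults are the standard choice for
#' this model class: sigmoid gain `h = 10` and decay `gamma = 1` for all
#' nodes, unit activator/inhibitor weights, an integration horizon of 30
#' model time units extended in 30-unit chunks up to 300 when the
#' steady-state criterion (max |dx/dt| below `ss_tol`) is not yet met.
#'
#' @param h sigmoid gain, > 0.
#' @param gamma decay rate per node, > 0.
#' @param alpha activator weight, > 0.
#' @param beta inhibitor weight, > 0.
#' @param t_end integration horizon (model time units).
#' @param t_max extension cap, >= `t_end`.
#' @param ss_tol steady-state threshold on max |dx/dt|.
#' @param rel_tol,abs_tol integrator tolerances.
#' @param method `"ode45"` (adaptive Runge-Kutta 4(5), default) or `"rk4"`
#'   (fixed-step cross-check mode).
#' @param rk4_dt fixed step size for `method = "rk4"`.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(h = 10, gamma = 1, alpha = 1, beta = 1,
                              t_end = 30, t_max = 300, ss_tol = 1e-6,
                              rel_tol = 1e-6, abs_tol = 1e-8,
                              method = c("ode45", "rk4"), rk4_dt = 0.01) {
  method <- match.arg(method)
  if (h <= 0 || gamma <= 0 || alpha <= 0 || beta <= 0)
    config_error("h, gamma, alpha and beta must all be > 0")
  if (t_end <= 0 || t_max < t_end)
    config_error("need 0 < t_end <= t_max")
  if (ss_tol <= 0 || rel_tol <= 0 || abs_tol <= 0 || rk4_dt <= 0)
    config_error("tolerances and step sizes must be > 0")
  structure(list(h = h, gamma = gamma, alpha = alpha, beta = beta,
                 t_end = t_end, t_max = t_max, ss_tol = ss_tol,
                 rel_tol = rel_tol, abs_tol = abs_tol, method = method,
                 rk4_dt = rk4_dt),
            class = "simulation_config")
}

#' Sigmoid activation response
#'
#' The gain-`h` sigmoid mapping aggregate input `omega` to production rate,
#' normalised so that A(0) = 0, A(0.5) = 0.5 and A(1) = 1 exactly:
#' \deqn{A(\omega) = \frac{-e^{0.5h} + e^{-h(\omega-0.5)}}
#'                        {(1-e^{0.5h})\,(1+e^{-h(\omega-0.5)})}}
#' Evaluated in a form that avoids overflow of `exp(0.5 h)` for large gains.
#'
#' @param omega aggregate input in \[0,1\] (vectorised).
#' @param h sigmoid gain, > 0.
#' @return activation in \[0,1\].
#' @export
activation_response <- function(omega, h) {
  if (any(h <= 0)) config_error("h must be > 0")
  # divide numerator and denominator by exp(0.5 h):
  #   A = (exp(-h w) - 1) / ((exp(-0.5 h) - 1) * (1 + exp(-h (w - 0.5))))
  num <- expm1(-h * omega)
  den <- expm1(-0.5 * h) * (1 + exp(-h * (omega - 0.5)))
  a <- num / den
  pmin(pmax(a, 0), 1)
}

# Internal compiled form of (network, config, clamps): adjacency matrices and
# index vectors so the derivative is a handful of vectorised operations.
compile_model <- function(net, cfg, clamps = NULL) {
  validate_network(net)
  nm <- node_names(net)
  n <- length(nm)
  inter <- net$interactions
  Ma <- Mi <- matrix(0, n, n, dimnames = list(nm, nm))
  if (nrow(inter)) {
    si <- match(inter$source, nm)
    ti <- match(inter$target, nm)
    act <- inter$effect == 1L
    Ma[cbind(ti[act], si[act])] <- 1
    Mi[cbind(ti[!act], si[!act])] <- 1
  }
  Wa <- cfg$alpha * rowSums(Ma)
  Wi <- cfg$beta * rowSums(Mi)
  has_a <- Wa > 0
  has_i <- Wi > 0
  input_idx <- which(!has_a & !has_i)

  clamp_idx <- integer(0)
  clamp_val <- numeric(0)
  if (length(clamps)) {
    cn <- canonical_node_name(names(clamps))
    bad <- setdiff(cn, nm)
    if (length(bad))
      lookup_error(sprintf("clamp on unknown node(s): %s",
                           paste(bad, collapse = ", ")))
    v <- as.numeric(clamps)
    if (any(v < 0 | v > 1))
      config_error("clamp values must lie in [0,1]")
    clamp_idx <- match(cn, nm)
    clamp_val <- v
  }
  list(names = nm, n = n, Ma = Ma, Mi = Mi, Wa = Wa, Wi = Wi,
       has_a = has_a, has_i = has_i, input_idx = input_idx,
       clamp_idx = clamp_idx, clamp_val = clamp_val, cfg = cfg)
}

# omega for every node at state x; NA for input nodes.
omega_vector <- function(x, m) {
  sa <- as.vector(m$Ma %*% x) * m$cfg$alpha
  si <- as.vector(m$Mi %*% x) * m$cfg$beta
  fa <- rep(1, m$n)
  fi <- rep(1, m$n)
  fa[m$has_a] <- ((1 + m$Wa[m$has_a]) / m$Wa[m$has_a]) *
    (sa[m$has_a] / (1 + sa[m$has_a]))
  fi[m$has_i] <- 1 - ((1 + m$Wi[m$has_i]) / m$Wi[m$has_i]) *
    (si[m$has_i] / (1 + si[m$has_i]))
  w <- pmin(pmax(fa * fi, 0), 1)
  w[m$input_idx] <- NA_real_
  w
}

derivative_vector <- function(x, m) {
  w <- omega_vector(x, m)
  dx <- numeric(m$n)
  reg <- !is.na(w)
  dx[reg] <- activation_response(w[reg], m$cfg$h) - m$cfg$gamma * x[reg]
  dx[m$input_idx] <- 0
  dx[m$clamp_idx] <- 0
  dx
}

#' Aggregate fuzzy-logic input of a node
#'
#' Computes the sigmoid aggregate omega of a node's regulators at a given
#' state.  With activator sum `s_a` (levels times `alpha`), inhibitor sum
#' `s_i`, and total weights `W_a`, `W_i`: a node with only activators gets
#' `((1+W_a)/W_a) * s_a/(1+s_a)`; only inhibitors,
#' `1 - ((1+W_i)/W_i) * s_i/(1+s_i)`; both, the product of the two factors.
#' The result is clipped to \[0,1\] against rounding.  A node with no
#' regulators is an input node: omega is undefined and `NA_real_` is
#' returned as the sentinel (such nodes hold their initial value during
#' integration).
#'
#' @param node node name.
#' @param state numeric state vector named by node, each entry in \[0,1\].
#' @param net a `regulatory_network`.
#' @param cfg a `simulation_config`.
#' @return scalar omega in \[0,1\], or `NA_real_` for an input node.
#' @export
omega_input <- function(node, state, net, cfg = simulation_config()) {
  m <- compile_model(net, cfg)
  node <- canonical_node_name(node)
  if (!node %in% m$names) lookup_error(sprintf("unknown node '%s'", node))
  x <- as_state(state, m)
  unname(omega_vector(x, m)[match(node, m$names)])
}

#' Time derivative of the full system
#'
#' `dx_n/dt = A(omega_n) - gamma * x_n` for regulated nodes; exactly 0 for
#' clamped nodes and input nodes (no regulators).
#'
#' @param state numeric state vector named by node.
#' @param net a `regulatory_network`.
#' @param cfg a `simulation_config`.
#' @param clamps optional named vector/list of clamp values in \[0,1\].
#' @return named derivative vector.
#' @export
derivative_field <- function(state, net, cfg = simulation_config(),
                             clamps = NULL) {
  m <- compile_model(net, cfg, clamps)
  x <- as_state(state, m)
  stats::setNames(derivative_vector(x, m), m$names)
}

as_state <- function(state, m) {
  state <- unlist(state)
  if (!is.null(names(state))) {
    names(state) <- canonical_node_name(names(state))
    miss <- setdiff(m$names, names(state))
    if (length(miss))
      lookup_error(sprintf("state lacks node(s): %s",
                           paste(miss, collapse = ", ")))
    state <- state[m$names]
  } else if (length(state) != m$n) {
    validation_error(sprintf("state has %d entries, network has %d nodes",
                             length(state), m$n))
  }
  state <- as.numeric(state)
  if (any(!is.finite(state)) || any(state < -1e-9 | state > 1 + 1e-9))
    validation_error("state entries must be finite and lie in [0,1]")
  pmin(pmax(state, 0), 1)
}

apply_clamps <- function(x, m) {
  if (length(m$clamp_idx)) x[m$clamp_idx] <- m$clamp_val
  x
}

#' Integrate a regulatory network to steady state
#'
#' Integrates the system from `x0` with an adaptive Runge-Kutta 4(5) scheme
#' (the `"ode45"` method of \pkg{deSolve}; fixed-step classical RK4 as a
#' cross-check mode).  Clamped coordinates of `x0` are overwritten by the
#' clamp values and their derivatives held at zero; input nodes (no
#' regulators) hold their initial value, with a one-time warning.  If
#' max |dx/dt| at `t_end` exceeds `ss_tol`, the horizon is extended in
#' `t_end`-sized chunks up to `t_max`; the final state is flagged
#' converged/unconverged accordingly and lies in \[0,1\]^n.
#'
#' @param x0 initial state (named, or positional over the node order).
#' @param net a `regulatory_network`.
#' @param cfg a `simulation_config`.
#' @param clamps optional named clamp set, values in \[0,1\].
#' @param trajectory_times optional vector of output times per chunk; by
#'   default ~60 samples per chunk are kept.
#' @param warn_inputs warn once about input nodes (default TRUE).
#' @return list of class `rnm_trajectory`: `times`, `states` (matrix time x
#'   node), `state` (final, named), `converged`, `t_converged`, `residual`
#'   (final max |dx/dt|).
#' @export
integrate_to_steady_state <- function(x0, net, cfg = simulation_config(),
                                      clamps = NULL, trajectory_times = NULL,
                                      warn_inputs = TRUE) {
  m <- compile_model(net, cfg, clamps)
  x <- apply_clamps(as_state(x0, m), m)
  if (warn_inputs && length(m$input_idx))
    warning(sprintf("input node(s) without regulators hold initial values: %s",
                    paste(m$names[m$input_idx], collapse = ", ")),
            call. = FALSE)

  func <- function(t, y, parms) list(derivative_vector(y, m))
  all_times <- numeric(0)
  all_states <- NULL
  t0 <- 0
  converged <- FALSE
  t_converged <- NA_real_
  repeat {
    times <- if (is.null(trajectory_times))
      seq(t0, t0 + cfg$t_end, length.out = 61L)
    else unique(sort(c(t0, t0 + trajectory_times, t0 + cfg$t_end)))
    sol <- if (cfg$method == "ode45") {
      deSolve::ode(y = x, times = times, func = func, parms = NULL,
                   method = "ode45", rtol = cfg$rel_tol, atol = cfg$abs_tol)
    } else {
      ft <- seq(t0, t0 + cfg$t_end, by = cfg$rk4_dt)
      deSolve::ode(y = x, times = ft, func = func, parms = NULL,
                   method = "rk4")
    }
    states <- unname(sol[, -1L, drop = FALSE])
    if (any(!is.finite(states)))
      numerical_error("non-finite state during integration")
    # forward invariance holds analytically; trim solver rounding
    states <- pmin(pmax(states, 0), 1)
    keep <- if (is.null(all_states)) TRUE else -1L
    all_times <- c(all_times, sol[keep, 1L])
    all_states <- rbind(all_states, states[keep, , drop = FALSE])
    x <- states[nrow(states), ]
    t0 <- t0 + cfg$t_end
    res <- max(abs(derivative_vector(x, m)))
    if (res <= cfg$ss_tol) {
      converged <- TRUE
      t_converged <- t0
      break
    }
    if (t0 + cfg$t_end > cfg$t_max + 1e-9) break
  }
  colnames(all_states) <- m$names
  structure(list(times = all_times, states = all_states,
                 state = stats::setNames(x, m$names),
                 converged = converged, t_converged = t_converged,
                 residual = max(abs(derivative_vector(x, m)))),
            class = "rnm_trajectory")
}

#' @export
print.rnm_trajectory <- function(x, ...) {
  cat(sprintf("<rnm_trajectory> %d nodes, t in [0, %g], %s (residual %.3g)\n",
              ncol(x$states), max(x$times),
              if (x$converged) sprintf("converged at t=%g", x$t_converged)
              else "NOT converged", x$residual))
  invisible(x)
}

# Fast path used by ensembles/designs: no trajectory storage.
steady_state_fast <- function(x0, m) {
  x <- apply_clamps(x0, m)
  cfg <- m$cfg
  func <- function(t, y, parms) list(derivative_vector(y, m))
  t0 <- 0
  repeat {
    sol <- if (cfg$method == "ode45") {
      deSolve::ode(y = x, times = c(t0, t0 + cfg$t_end), func = func,
                   parms = NULL, method = "ode45",
                   rtol = cfg$rel_tol, atol = cfg$abs_tol)
    } else {
      deSolve::ode(y = x, times = seq(t0, t0 + cfg$t_end, by = cfg$rk4_dt),
                   func = func, parms = NULL, method = "rk4")
    }
    x <- pmin(pmax(unname(sol[nrow(sol), -1L]), 0), 1)
    if (any(!is.finite(x))) numerical_error("non-finite state during integration")
    t0 <- t0 + cfg$t_end
    res <- max(abs(derivative_vector(x, m)))
    if (res <= cfg$ss_tol) return(list(state = x, converged = TRUE))
    if (t0 + cfg$t_end > cfg$t_max + 1e-9)
      return(list(state = x, converged = FALSE))
  }
}
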