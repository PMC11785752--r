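test_that("aggregate input omega matches the closed-form cases", {
  net1 <- toy("cascade_pos")
  cfg <- simulation_config()
  # one activator at level 1: ((1+1)/1) * (1/2) = 1
  expect_equal(omega_input("B", c(A = 1, B = 0), net1, cfg), 1)
  expect_equal(omega_input("B", c(A = 0, B = 0), net1, cfg), 0)
  # one activator at 0.5: 2 * (0.5/1.5) = 2/3
  expect_equal(omega_input("B", c(A = 0.5, B = 0), net1, cfg), 2 / 3)

  # activator and inhibitor both at 1: product form gives 1 * (1 - 1) = 0
  net2 <- regulatory_network(
    c("A", "I", "B"),
    data.frame(source = c("A", "I"), target = "B", effect = c(1L, -1L)))
  expect_equal(omega_input("B", c(A = 1, I = 1, B = 0), net2, cfg), 0)
  # sole inhibitor at 0.5: 1 - 2*(0.5/1.5) = 1/3
  expect_equal(omega_input("B", c(A = 1, B = 0), toy("cascade_neg"), cfg),
               0)
  expect_equal(omega_input("B", c(A = 0.5, B = 0), toy("cascade_neg"), cfg),
               1 / 3)
  # input node sentinel
  expect_true(is.na(omega_input("A", c(A = 0.3, B = 0), net1, cfg)))
})

test_that("activation response passes through its anchor points for all gains", {
  for (h in c(1, 10, 50)) {
    expect_equal(activation_response(0, h), 0)
    expect_equal(activation_response(1, h), 1)
    expect_equal(activation_response(0.5, h), 0.5)
  }
  # closed-form spot value
  expect_equal(activation_response(0.75, 10), 0.9299, tolerance = 1e-4)
})

test_that("activation response is strictly increasing on [0,1]", {
  grid <- seq(0, 1, by = 0.01)
  for (h in c(0.5, 1, 10, 50)) {
    a <- activation_response(grid, h)
    expect_true(all(diff(a) > 0), info = sprintf("h = %g", h))
    expect_true(all(a >= 0 & a <= 1))
  }
  # very steep gains saturate in floating point but stay monotone and bounded
  a <- activation_response(grid, 200)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("derivative field implements activation minus decay with clamp zeros", {
  cfg <- simulation_config()
  net <- toy("cascade_pos")
  # omega=1 held at x=1 with gamma=1: fixed point
  d <- derivative_field(c(A = 1, B = 1), net, cfg)
  expect_equal(unname(d["B"]), 0)
  # omega=0 at x=0.4: pure decay
  d2 <- derivative_field(c(A = 0, B = 0.4), net, cfg)
  expect_equal(unname(d2["B"]), -0.4)
  # clamped node: derivative exactly zero whatever the state
  d3 <- derivative_field(c(A = 1, B = 0.7), net, cfg, clamps = c(B = 0.2))
  expect_identical(unname(d3["B"]), 0)
  # input node: derivative zero
  expect_identical(unname(d["A"]), 0)
})

test_that("cascades integrate to the forced steady states under clamping", {
  cfg <- simulation_config()
  up <- quiet_integrate(c(A = 0, B = 0), toy("cascade_pos"), cfg,
                        clamps = c(A = 1))
  expect_true(up$converged)
  expect_equal(unname(up$state["B"]), 1, tolerance = 1e-5)
  down <- quiet_integrate(c(A = 0, B = 0.9), toy("cascade_neg"), cfg,
                          clamps = c(A = 1))
  expect_equal(unname(down$state["B"]), 0, tolerance = 1e-5)
  # clamped coordinate equals its clamp at every output time
  expect_true(all(up$states[, "A"] == 1))
  expect_equal(length(up$times), nrow(up$states))
})

test_that("the toggle switch remembers which side started high", {
  cfg <- simulation_config()
  tr <- quiet_integrate(c(A = 0.9, B = 0.1), toy("toggle"), cfg)
  expect_true(tr$converged)
  expect_gt(tr$state["A"], 0.9)
  expect_lt(tr$state["B"], 0.1)
  tr2 <- quiet_integrate(c(A = 0.1, B = 0.9), toy("toggle"), cfg)
  expect_gt(tr2$state["B"], 0.9)
})

test_that("trajectories started in the unit cube stay in the unit cube", {
  cfg <- simulation_config()
  motifs <- generate_toy_motifs()
  set.seed(11)
  for (nm in names(motifs)) {
    n <- nrow(motifs[[nm]]$nodes)
    for (rep in 1:3) {
      x0 <- stats::setNames(stats::runif(n), motifs[[nm]]$nodes$name)
      tr <- quiet_integrate(x0, motifs[[nm]], cfg)
      expect_true(all(tr$states >= 0 & tr$states <= 1),
                  info = sprintf("%s rep %d", nm, rep))
    }
  }
})

test_that("steady states satisfy the fixed-point identity x* = A(omega*)/gamma", {
  cfg <- simulation_config()
  net <- toy("incoherent_ffl")
  tr <- quiet_integrate(c(A = 0.7, B = 0.2, C = 0.9), net, cfg,
                        clamps = c(A = 0.7))
  expect_true(tr$converged)
  for (nd in c("B", "C")) {
    w <- omega_input(nd, tr$state, net, cfg)
    expect_equal(unname(tr$state[nd]),
                 activation_response(w, cfg$h) / cfg$gamma,
                 tolerance = 1e-5)
  }
})

test_that("Boolean stable fixed points persist at high gain", {
  cfg50 <- simulation_config(h = 50)
  # cascade with root on: Boolean fixed point (1, 1)
  tr <- quiet_integrate(c(A = 1, B = 1), toy("cascade_pos"), cfg50,
                        clamps = c(A = 1))
  expect_lt(max(abs(tr$state - c(1, 1))), 0.05)
  # toggle fixed point (1, 0)
  tr2 <- quiet_integrate(c(A = 1, B = 0), toy("toggle"), cfg50)
  expect_lt(max(abs(tr2$state - c(1, 0))), 0.05)
})

test_that("adaptive and fixed-step integrators agree on the toy suite", {
  motifs <- generate_toy_motifs()
  set.seed(5)
  for (nm in c("cascade_pos", "toggle", "incoherent_ffl")) {
    n <- nrow(motifs[[nm]]$nodes)
    x0 <- stats::setNames(round(stats::runif(n), 2), motifs[[nm]]$nodes$name)
    a <- quiet_integrate(x0, motifs[[nm]], simulation_config())
    b <- quiet_integrate(x0, motifs[[nm]],
                         simulation_config(method = "rk4", rk4_dt = 0.01))
    expect_lt(max(abs(a$state - b$state)), 1e-4)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(h = 0), class = "rnm_config_error")
  expect_error(simulation_config(gamma = -1), class = "rnm_config_error")
  expect_error(simulation_config(t_end = 40, t_max = 30),
               class = "rnm_config_error")
  expect_error(
    quiet_integrate(c(A = 0, B = 0), toy("cascade_pos"),
                    clamps = c(Z = 1)),
    class = "rnm_lookup_error")
  expect_error(
    quiet_integrate(c(A = 2, B = 0), toy("cascade_pos")),
    class = "rnm_validation_error")
})
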