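test_that("single-edge propagation follows the closed-form update", {
  toy <- toy_two_node(w = 0)
  p0 <- propagate(toy$network, toy$solution, c(A = 1))
  expect_equal(p0$activity[["B"]], 0)        # zero weight kills the signal

  toy1 <- toy_two_node(w = 1)
  p1 <- propagate(toy1$network, toy1$solution, c(A = 1))
  expect_equal(p1$activity[["B"]], tanh(1), tolerance = 1e-5)
  expect_equal(p1$activity[["A"]], 1)        # clamped node exact
  expect_true(p1$converged)
})

test_that("propagate matches the independent oracle on small networks", {
  for (seed in 1:100) {
    sys <- random_toy_system(seed)
    sol <- model_solution(sys$network, sys$weights)
    got <- propagate(sys$network, sol, sys$stimulus)
    want <- oracle_propagate(sys$network, sys$weights, sys$stimulus)
    expect_equal(unname(got$activity[sys$network$nodes]),
                 unname(want$activity[sys$network$nodes]),
                 tolerance = 1e-9)
    expect_identical(got$converged, want$converged)
  }
})

test_that("activities stay bounded and clamped nodes keep their values", {
  for (seed in 101:115) {
    sys <- random_toy_system(seed, n_max = 6L)
    sol <- model_solution(sys$network, sys$weights)
    p <- propagate(sys$network, sol, sys$stimulus)
    expect_true(all(abs(p$activity) <= 1))
    expect_equal(p$activity[names(sys$stimulus)], sys$stimulus)
  }
})

test_that("zero stimulus is rejected, all-zero profile is its fixed point", {
  toy <- toy_chain()
  expect_error(propagate(toy$network, toy$solution, c(A = 0)), "nonzero")
  # nodes not fed by the (clamped) stimulus stay at zero
  net <- interaction_network(data.frame(source = "A", target = "B"),
                             nodes = c("A", "B", "C"))
  p <- propagate(net, model_solution(net, 0.5), c(A = 1))
  expect_equal(p$activity[["C"]], 0)
})

test_that("propagation is deterministic and damping-invariant on DAGs", {
  sys <- random_toy_system(42)
  sol <- model_solution(sys$network, sys$weights)
  p1 <- propagate(sys$network, sol, sys$stimulus)
  p2 <- propagate(sys$network, sol, sys$stimulus)
  expect_identical(p1, p2)

  # acyclic chain: converged activities agree across damping values
  net <- interaction_network(data.frame(source = c("A", "B", "C"),
                                        target = c("B", "C", "D")))
  sol <- model_solution(net, c(0.8, -0.6, 0.9))
  profs <- lapply(c(0.25, 0.5, 1), function(d) {
    propagate(net, sol, c(A = -1),
              propagation_config(tol = 1e-10, damping = d))
  })
  expect_equal(profs[[1]]$activity, profs[[2]]$activity, tolerance = 1e-7)
  expect_equal(profs[[2]]$activity, profs[[3]]$activity, tolerance = 1e-7)
})

test_that("propagation rejects invalid weights and configs", {
  toy <- toy_two_node()
  expect_error(propagation_config(tol = 0), "positive")
  expect_error(propagation_config(damping = 0), "damping")
  bad <- toy$solution
  bad$weights[1] <- NaN
  expect_error(propagate(toy$network, bad, c(A = 1)), "non-finite")
})

test_that("non-convergence is flagged, not hidden", {
  # high-gain negative feedback loop rotates instead of settling when
  # updates are undamped
  net <- interaction_network(data.frame(source = c("S", "A", "B"),
                                        target = c("A", "B", "A")))
  sol <- model_solution(net, c(0.5, 1, -1))
  p <- propagate(net, sol, c(S = 1),
                 propagation_config(gain = 5, damping = 1, max_iter = 50))
  expect_false(p$converged)
  expect_identical(p$iterations, 50L)
  expect_true(all(abs(p$activity) <= 1))
})

test_that("ensemble activity averages member profiles", {
  toy <- toy_two_node(w = 0.9)
  sol1 <- toy$solution
  sol1$accuracy <- 1
  ens1 <- model_ensemble(list(sol1), accuracy_gate = 0.9)
  ea <- ensemble_activity(ens1, toy$network, c(A = 1))
  single <- propagate(toy$network, toy$solution, c(A = 1))
  expect_equal(ea$mean$activity, single$activity)
  expect_equal(unname(ea$dispersion), c(0, 0))

  # two symmetric solutions cancel at the downstream node
  sol_pos <- model_solution(toy$network, 0.9, accuracy = 1)
  sol_neg <- model_solution(toy$network, -0.9, accuracy = 1)
  ens2 <- model_ensemble(list(sol_pos, sol_neg), accuracy_gate = 0.9)
  ea2 <- ensemble_activity(ens2, toy$network, c(A = 1))
  expect_equal(ea2$mean$activity[["B"]], 0, tolerance = 1e-6)
  expect_gt(ea2$dispersion[["B"]], 0.5)
})

test_that("ensemble mean recovers planted activities at full accuracy", {
  sys <- generate_system(synthetic_spec(n_nodes = 60, mean_degree = 2,
                                        motive_sizes = c(6L, 6L),
                                        n_rules = 12L, seed = 5))
  stim <- stimulus_from_drug(sys$drugs[[1]], sys$network)
  truth <- propagate(sys$network, sys$ground_truth, stim)
  gt <- sys$ground_truth
  gt$accuracy <- evaluate_accuracy(sys$network, gt, sys$training_set)
  expect_equal(gt$accuracy, 1)
  ens <- model_ensemble(list(gt), accuracy_gate = 0.9)
  ea <- ensemble_activity(ens, sys$network, stim)
  expect_equal(ea$mean$activity, truth$activity)
})
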