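test_that("accuracy counts complied expectations with the 0.1 threshold", {
  toy <- toy_two_node(w = 1)
  ts <- training_set(list(training_rule(c(A = 1), c(B = 1))))
  expect_equal(evaluate_accuracy(toy$network, toy$solution, ts), 1)

  # inverted weight drives B the wrong way
  neg <- toy_two_node(w = -1)
  expect_equal(evaluate_accuracy(neg$network, neg$solution, ts), 0)

  # all-zero weights leave activities below threshold
  zero <- toy_two_node(w = 0)
  expect_equal(evaluate_accuracy(zero$network, zero$solution, ts), 0)

  # pooled counting across expectations: one of two complied
  net <- interaction_network(data.frame(source = c("A", "A"),
                                        target = c("B", "C")))
  sol <- model_solution(net, c(1, -1))
  ts2 <- training_set(list(training_rule(c(A = 1), c(B = 1, C = 1))))
  expect_equal(evaluate_accuracy(net, sol, ts2), 0.5)
})

test_that("training set JSON round-trips", {
  ts <- training_set(list(
    training_rule(c(A = -1), c(B = 1, C = -1)),
    training_rule(c(A = 1, B = -0.5), c(C = 1))))
  path <- withr::local_tempfile(fileext = ".json")
  write_training_set(ts, path)
  back <- read_training_set(path)
  expect_equal(back$rules, ts$rules)
})

test_that("rule and config validation fail loudly", {
  expect_error(training_rule(c(A = 1), numeric()), "non-empty")
  expect_error(training_rule(c(A = 0), c(B = 1)), "nonzero")
  expect_error(training_rule(c(A = 1), c(B = 2)), "\\+1/-1")
  expect_error(training_set(list()), "non-empty")
  expect_error(anneal_config(cooling_rate = 1), "cooling_rate")
  expect_error(anneal_config(min_temperature = 2), "min_temperature")
  expect_error(anneal_config(accuracy_gate = 0), "accuracy_gate")
})

test_that("annealing solves the one-edge toy exactly", {
  toy <- toy_two_node()
  ts <- training_set(list(training_rule(c(A = 1), c(B = 1))))
  cfg <- anneal_config(steps_per_temperature = 100L)
  sol <- anneal_solution(toy$network, ts, cfg, seed = 1)
  expect_equal(sol$accuracy, 1)
  expect_equal(evaluate_accuracy(toy$network, sol, ts), 1)
  expect_gt(sol$weights[["A->B"]], 0)
})

test_that("annealing is deterministic given the seed", {
  sys <- generate_system(synthetic_spec(n_nodes = 40, motive_sizes = c(5L),
                                        n_rules = 6L, seed = 9))
  cfg <- anneal_config(steps_per_temperature = 60L,
                       min_temperature = 1e-3)
  s1 <- anneal_solution(sys$network, sys$training_set, cfg, seed = 4)
  s2 <- anneal_solution(sys$network, sys$training_set, cfg, seed = 4)
  expect_identical(s1$weights, s2$weights)
  s3 <- anneal_solution(sys$network, sys$training_set, cfg, seed = 5)
  expect_false(identical(s1$weights, s3$weights))
})

test_that("contradictory rules cap accuracy at one half and fail the gate", {
  toy <- toy_two_node()
  ts <- training_set(list(training_rule(c(A = 1), c(B = 1)),
                          training_rule(c(A = 1), c(B = -1))))
  sol <- anneal_solution(toy$network, ts, anneal_config(), seed = 1)
  expect_lte(sol$accuracy, 0.5)
  cfg <- anneal_config(n_solutions = 2L, retry_factor = 2L,
                       steps_per_temperature = 50L)
  expect_error(train_ensemble(toy$network, ts, cfg), "best accuracy")
})

test_that("trained ensembles respect the gate and sort by accuracy", {
  toy <- toy_chain()
  ts <- training_set(list(training_rule(c(A = 1), c(B = 1, C = 1)),
                          training_rule(c(A = -1), c(B = -1, C = -1))))
  cfg <- anneal_config(n_solutions = 3L, steps_per_temperature = 100L,
                       base_seed = 10L)
  ens <- train_ensemble(toy$network, ts, cfg)
  acc <- vapply(ens$solutions, function(s) s$accuracy, numeric(1))
  expect_length(acc, 3L)
  expect_true(all(acc > cfg$accuracy_gate))
  expect_identical(acc, sort(acc, decreasing = TRUE))
  # ensemble training is reproducible end to end
  ens2 <- train_ensemble(toy$network, ts, cfg)
  expect_identical(lapply(ens$solutions, `[[`, "weights"),
                   lapply(ens2$solutions, `[[`, "weights"))
})

test_that("ensemble archives round-trip through the directory format", {
  toy <- toy_chain()
  sols <- list(model_solution(toy$network, c(0.5, 0.25), accuracy = 0.95,
                              seed = 1L),
               model_solution(toy$network, c(-0.5, 1), accuracy = 0.92,
                              seed = 2L))
  ens <- model_ensemble(sols, accuracy_gate = 0.9)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir, toy$network)
  back <- read_ensemble(dir, toy$network)
  expect_equal(lapply(back$solutions, `[[`, "weights"),
               lapply(ens$solutions, `[[`, "weights"))
  expect_equal(vapply(back$solutions, `[[`, numeric(1), "accuracy"),
               c(0.95, 0.92))
})

test_that("model solutions validate coverage and bounds", {
  toy <- toy_chain()
  expect_error(model_solution(toy$network, 1), "one weight per edge")
  expect_error(model_solution(toy$network, c(2, 0)), "within")
  named <- model_solution(toy$network,
                          c("B->C" = 0.5, "A->B" = -0.5))
  expect_equal(unname(named$weights), c(-0.5, 0.5))  # edge order restored
  expect_error(model_ensemble(list()), "non-empty")
  low <- model_solution(toy$network, c(0, 0), accuracy = 0.5)
  expect_error(model_ensemble(list(low), 0.9), "gate")
})
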