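# Model solutions, ensembles, training rules and the simulated-annealing
# fit. A solution is one weight per network edge (real-valued in
# [-w_max, w_max]: sign and strength in a single parameter); the ensemble
# is the set of solutions whose training accuracy clears the gate.

#' Construct a model solution
#'
#' @param network the `interaction_network` the weights belong to.
#' @param weights numeric vector with one weight per network edge, in edge
#'   order (or named `"src->dst"`); must cover every edge exactly once.
#' @param accuracy optional training accuracy in `[0, 1]` (set after
#'   evaluation).
#' @param seed optional integer seed that produced the solution.
#' @param w_max weight bound; default 1.
#' @return an object of class `model_solution`.
#' @export
model_solution <- function(network, weights, accuracy = NA_real_,
                           seed = NA_integer_, w_max = 1) {
  stopifnot(inherits(network, "interaction_network"))
  edge_names <- paste(network$edges$source, network$edges$target, sep = "->")
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), edge_names)) {
      stop("solution weights do not cover the network's edges")
    }
    weights <- weights[edge_names]
  } else if (length(weights) != nrow(network$edges)) {
    stop("need exactly one weight per edge (", nrow(network$edges), ")")
  } else {
    names(weights) <- edge_names
  }
  if (any(!is.finite(weights)) || any(abs(weights) > w_max + 1e-12)) {
    stop("weights must be finite and within [-w_max, w_max]")
  }
  structure(list(weights = weights, accuracy = accuracy,
                 seed = as.integer(seed), w_max = w_max),
            class = "model_solution")
}

# weights in network edge order, validated
.solution_weights <- function(solution, network) {
  stopifnot(inherits(solution, "model_solution"))
  if (length(solution$weights) != nrow(network$edges)) {
    stop("solution does not cover all network edges")
  }
  unname(solution$weights)
}

#' Draw a random solution (uniform weights)
#' @inheritParams model_solution
#' @param seed integer seed.
#' @return a `model_solution` with weights uniform in `[-w_max, w_max]`.
#' @export
random_solution <- function(network, seed = 1L, w_max = 1) {
  set.seed(seed)
  model_solution(network, runif(nrow(network$edges), -w_max, w_max),
                 seed = seed, w_max = w_max)
}

#' Construct a model ensemble
#'
#' @param solutions non-empty list of `model_solution`s.
#' @param accuracy_gate minimum accuracy every member must exceed.
#' @return an object of class `model_ensemble`.
#' @export
model_ensemble <- function(solutions, accuracy_gate = 0.9) {
  if (length(solutions) == 0L) stop("ensemble must be non-empty")
  acc <- vapply(solutions, function(s) s$accuracy, numeric(1))
  if (any(is.na(acc))) stop("every ensemble member needs an evaluated accuracy")
  if (any(acc <= accuracy_gate)) {
    stop("ensemble member(s) at or below the accuracy gate (",
         accuracy_gate, ")")
  }
  solutions <- solutions[order(acc, decreasing = TRUE)]
  structure(list(solutions = solutions, accuracy_gate = accuracy_gate),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  acc <- vapply(x$solutions, function(s) s$accuracy, numeric(1))
  cat(sprintf(
    "model ensemble: %d solution(s), gate %.2f, mean accuracy %.2f%%\n",
    length(x$solutions), x$accuracy_gate, 100 * mean(acc)))
  invisible(x)
}

#' Mean accuracy of an ensemble
#' @param ensemble a `model_ensemble`.
#' @return mean of the members' training accuracies.
#' @export
ensemble_accuracy <- function(ensemble) {
  mean(vapply(ensemble$solutions, function(s) s$accuracy, numeric(1)))
}

# ---- training rules -----------------------------------------------------

#' Construct a training rule / training set
#'
#' A training rule is one curated stimulus-to-response relationship: a
#' stimulus (clamped inputs, e.g. a drug's targets) and the expected
#' activation signs at a non-empty set of response proteins. A valid model
#' must drive each expected protein to the expected sign with at least the
#' activity threshold in magnitude.
#'
#' @param stimulus named numeric clamp vector.
#' @param expected named numeric vector of expected signs (+1/-1).
#' @return a `training_rule`.
#' @export
training_rule <- function(stimulus, expected) {
  if (length(expected) == 0L || is.null(names(expected))) {
    stop("rule must have a non-empty named 'expected' vector")
  }
  if (!all(expected %in% c(-1, 1))) stop("expected signs must be +1/-1")
  if (length(stimulus) == 0L || all(stimulus == 0)) {
    stop("rule stimulus must have at least one nonzero input")
  }
  names(stimulus) <- normalize_symbol(names(stimulus))
  names(expected) <- normalize_symbol(names(expected))
  structure(list(stimulus = stimulus, expected = expected),
            class = "training_rule")
}

#' @rdname training_rule
#' @param rules non-empty list of `training_rule`s.
#' @export
training_set <- function(rules) {
  if (length(rules) == 0L) stop("training set must be non-empty")
  stopifnot(all(vapply(rules, inherits, logical(1), "training_rule")))
  structure(list(rules = rules), class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  n_exp <- sum(vapply(x$rules, function(r) length(r$expected), integer(1)))
  cat("training set:", length(x$rules), "rule(s),", n_exp,
      "protein expectations\n")
  invisible(x)
}

#' Read / write a training set (JSON)
#'
#' JSON layout: a list of `{"stimulus": {protein: value},
#' "expected": {protein: sign}}` objects.
#'
#' @param path file path.
#' @return a `training_set`.
#' @export
read_training_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  training_set(lapply(obj, function(r) {
    training_rule(unlist(r$stimulus), unlist(r$expected))
  }))
}

#' @rdname read_training_set
#' @param ts a `training_set` to write.
#' @export
write_training_set <- function(ts, path) {
  stopifnot(inherits(ts, "training_set"))
  jsonlite::write_json(lapply(ts$rules, function(r) {
    list(stimulus = as.list(r$stimulus), expected = as.list(r$expected))
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# flatten rules into the 0-based index form the compiled core uses
.pack_rules <- function(ts, network) {
  lapply(ts$rules, function(r) {
    ci <- match(names(r$stimulus), network$nodes) - 1L
    ei <- match(names(r$expected), network$nodes) - 1L
    if (anyNA(ci)) stop("rule stimulates protein(s) absent from network")
    if (anyNA(ei)) stop("rule expects protein(s) absent from network")
    list(clamp_idx = ci, clamp_val = unname(r$stimulus),
         exp_idx = ei, exp_sign = unname(r$expected))
  })
}

# ---- accuracy -----------------------------------------------------------

#' Fraction of training expectations a solution complies with
#'
#' An expectation (protein `p`, sign `s`) of a rule is complied with iff,
#' after propagating the rule's stimulus, `sign(activity_p) == s` and
#' `|activity_p| >= activity_threshold`. Accuracy is complied expectations
#' over total expectations, pooled across rules.
#'
#' @param network an `interaction_network`.
#' @param solution a `model_solution`.
#' @param ts a `training_set`.
#' @param activity_threshold minimum activity magnitude (default 0.1, the
#'   same threshold the analysis layer uses for reversion).
#' @param config a [propagation_config()].
#' @return fraction in `[0, 1]`.
#' @export
evaluate_accuracy <- function(network, solution, ts, activity_threshold = 0.1,
                              config = propagation_config()) {
  stopifnot(inherits(ts, "training_set"))
  w <- .solution_weights(solution, network)
  ei <- .edge_index(network)
  res <- cpp_evaluate_rules(length(network$nodes), ei$src, ei$dst, w,
                            .pack_rules(ts, network), config$gain,
                            config$damping, config$tol, config$max_iter,
                            activity_threshold, 0.3)
  res$accuracy
}

# ---- annealing ----------------------------------------------------------

#' Simulated-annealing configuration
#'
#' Controls the stochastic optimization that fits edge weights to the
#' training set. The annealer minimises
#' `(1 - margin) + lambda * prior_penalty`, where the margin score
#' `mean(max(0, sign * activity))` is a continuous surrogate that gives the
#' search gradient-like guidance, while the discrete per-expectation
#' accuracy remains the reported and gating metric. Sign priors on edges
#' are enforced softly: each edge whose fitted weight opposes its prior
#' contributes `|weight|` to the penalty.
#'
#' @param n_solutions ensemble size to train.
#' @param accuracy_gate minimum accuracy for a solution to be valid
#'   (default 0.90).
#' @param initial_temperature,cooling_rate,steps_per_temperature,min_temperature
#'   geometric cooling schedule (temperature multiplied by `cooling_rate`
#'   after each block of `steps_per_temperature` single-edge proposals).
#' @param proposal_sigma SD of the Gaussian weight perturbation at the
#'   initial temperature; proposals shrink proportionally as the system
#'   cools and are reflected at the weight bound.
#' @param sign_prior_penalty soft sign-prior penalty weight lambda
#'   (default 0.1).
#' @param margin_cap cap of the continuous margin surrogate: each
#'   expectation scores `min(sign * activity, margin_cap) / margin_cap`, so
#'   activity beyond the cap earns nothing more and the annealer spreads
#'   effort over all expectations instead of saturating a few (default
#'   0.3, three times the compliance threshold).
#' @param base_seed first seed; run k of an ensemble uses `base_seed + k - 1`.
#' @param activity_threshold compliance threshold used by the accuracy
#'   metric (default 0.1).
#' @param retry_factor annealing runs allowed per requested solution before
#'   training fails loudly (default 5).
#' @param w_max weight bound (default 1).
#' @param propagation [propagation_config()] used inside training; the
#'   default relaxes `tol` to 1e-4 because compliance only needs signs and
#'   a 0.1 magnitude.
#' @return a list of class `anneal_config`.
#' @export
anneal_config <- function(n_solutions = 5L, accuracy_gate = 0.9,
                          initial_temperature = 0.02, cooling_rate = 0.9,
                          steps_per_temperature = 450L,
                          min_temperature = 1e-5, proposal_sigma = 0.4,
                          sign_prior_penalty = 0.1, margin_cap = 0.3,
                          base_seed = 1L,
                          activity_threshold = 0.1, retry_factor = 5L,
                          w_max = 1,
                          propagation = propagation_config(tol = 1e-3,
                                                           max_iter = 20L)) {
  if (cooling_rate <= 0 || cooling_rate >= 1) {
    stop("cooling_rate must be in (0, 1)")
  }
  if (accuracy_gate <= 0 || accuracy_gate > 1) {
    stop("accuracy_gate must be in (0, 1]")
  }
  if (initial_temperature <= 0 || min_temperature <= 0 ||
      min_temperature >= initial_temperature) {
    stop("need 0 < min_temperature < initial_temperature")
  }
  if (proposal_sigma <= 0) stop("proposal_sigma must be positive")
  if (sign_prior_penalty < 0) stop("sign_prior_penalty must be >= 0")
  structure(list(n_solutions = as.integer(n_solutions),
                 accuracy_gate = accuracy_gate,
                 initial_temperature = initial_temperature,
                 cooling_rate = cooling_rate,
                 steps_per_temperature = as.integer(steps_per_temperature),
                 min_temperature = min_temperature,
                 proposal_sigma = proposal_sigma,
                 sign_prior_penalty = sign_prior_penalty,
                 margin_cap = margin_cap,
                 base_seed = as.integer(base_seed),
                 activity_threshold = activity_threshold,
                 retry_factor = as.integer(retry_factor),
                 w_max = w_max,
                 propagation = propagation),
            class = "anneal_config")
}

#' Fit one weight solution by simulated annealing
#'
#' Weights start uniform in `[-w_max, w_max]`; single-edge Gaussian
#' proposals are accepted by the Metropolis criterion under geometric
#' cooling. The best solution seen (highest accuracy, ties broken by
#' objective) is returned with its accuracy evaluated from a cold start.
#' Deterministic given `seed`.
#'
#' @inheritParams evaluate_accuracy
#' @param config an [anneal_config()].
#' @param seed integer seed for this run.
#' @return a `model_solution` with evaluated accuracy.
#' @export
anneal_solution <- function(network, ts, config = anneal_config(), seed = 1L) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(ts, "training_set"),
            inherits(config, "anneal_config"))
  if (nrow(network$edges) < 1L) stop("network has no edges to fit")
  ei <- .edge_index(network)
  prior <- network$edges$sign_prior
  prior[is.na(prior)] <- 0L
  pc <- config$propagation
  res <- cpp_anneal(length(network$nodes), ei$src, ei$dst, as.numeric(prior),
                    .pack_rules(ts, network), config$w_max,
                    config$initial_temperature, config$cooling_rate,
                    config$steps_per_temperature, config$min_temperature,
                    config$proposal_sigma, config$sign_prior_penalty,
                    pc$gain, pc$damping, pc$tol, pc$max_iter,
                    config$activity_threshold, config$margin_cap,
                    as.integer(seed), TRUE)
  model_solution(network, res$weights, accuracy = res$accuracy,
                 seed = seed, w_max = config$w_max)
}

#' Train an ensemble of valid solutions
#'
#' Runs [anneal_solution()] with seeds `base_seed`, `base_seed + 1`, ...
#' keeping solutions whose accuracy clears the gate, until `n_solutions`
#' members are collected or the retry budget
#' (`retry_factor * n_solutions` runs) is exhausted, in which case training
#' fails with the best accuracy found. Members are sorted by accuracy,
#' descending.
#'
#' @inheritParams anneal_solution
#' @param verbose print per-run progress.
#' @return a `model_ensemble`.
#' @export
train_ensemble <- function(network, ts, config = anneal_config(),
                           verbose = FALSE) {
  stopifnot(config$n_solutions >= 1L)
  budget <- config$retry_factor * config$n_solutions
  kept <- list()
  best_acc <- 0
  run <- 0L
  while (length(kept) < config$n_solutions && run < budget) {
    seed <- config$base_seed + run
    run <- run + 1L
    sol <- anneal_solution(network, ts, config, seed = seed)
    best_acc <- max(best_acc, sol$accuracy)
    if (sol$accuracy > config$accuracy_gate) kept[[length(kept) + 1L]] <- sol
    if (verbose) {
      message(sprintf("  anneal run %d (seed %d): accuracy %.2f%% [%s]",
                      run, seed, 100 * sol$accuracy,
                      if (sol$accuracy > config$accuracy_gate) "kept"
                      else "rejected"))
    }
  }
  if (length(kept) < config$n_solutions) {
    stop(sprintf(paste0("training failed: %d/%d solutions above the %.2f ",
                        "gate within %d runs (best accuracy %.2f%%)"),
                 length(kept), config$n_solutions, config$accuracy_gate,
                 budget, 100 * best_acc))
  }
  ens <- model_ensemble(kept, config$accuracy_gate)
  if (verbose) {
    message(sprintf("ensemble mean accuracy: %.2f%%",
                    100 * ensemble_accuracy(ens)))
  }
  ens
}

# ---- ensemble archive ---------------------------------------------------

#' Write / read an ensemble archive
#'
#' The archive is a directory with one weights TSV per solution
#' (`source  target  weight`) plus a `manifest.json` recording seeds,
#' accuracies and the accuracy gate.
#'
#' @param ensemble a `model_ensemble`.
#' @param dir archive directory (created if needed).
#' @param network the `interaction_network` the solutions cover.
#' @return `dir` (write) or a `model_ensemble` (read).
#' @export
write_ensemble <- function(ensemble, dir, network) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("solution_%03d.tsv", seq_along(ensemble$solutions))
  for (i in seq_along(ensemble$solutions)) {
    df <- data.frame(source = network$edges$source,
                     target = network$edges$target,
                     weight = unname(ensemble$solutions[[i]]$weights))
    .write_tsv(df, file.path(dir, files[i]))
  }
  manifest <- list(
    n_solutions = length(ensemble$solutions),
    accuracy_gate = ensemble$accuracy_gate,
    files = files,
    seeds = vapply(ensemble$solutions, function(s) s$seed, integer(1)),
    accuracies = vapply(ensemble$solutions, function(s) s$accuracy,
                        numeric(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir, network) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sols <- lapply(seq_along(manifest$files), function(i) {
    df <- .read_tsv(file.path(dir, manifest$files[i]))
    model_solution(network,
                   setNames(df$weight, paste(df$source, df$target,
                                             sep = "->")),
                   accuracy = manifest$accuracies[i],
                   seed = manifest$seeds[i])
  })
  model_ensemble(sols, manifest$accuracy_gate)
}
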