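# Variance-based Sobol sensitivity of the propagated output with respect
# to the stimulus inputs. Saltelli-style A/B/AB_i design with Latin
# hypercube base samples; Jansen estimators for the first-order and total
# indices.

#' Sobol sensitivity indices of a function (Saltelli sampling)
#'
#' Estimates first-order and total-order Sobol indices of
#' `f(x_1, ..., x_k)` over a box, from `n_samples * (k + 2)` evaluations:
#' two Latin-hypercube base matrices A and B plus the k column-swapped
#' hybrids AB_i. First-order indices use the Saltelli/Jansen estimator
#' `S_i = mean(yB * (yABi - yA)) / V`; total indices use
#' `T_i = mean((yA - yABi)^2) / (2 V)`.
#'
#' @param f vectorised function taking an `n x k` matrix and returning a
#'   numeric vector of length `n`.
#' @param n_params number of input parameters k (must be >= 2; the
#'   decomposition is degenerate otherwise).
#' @param lower,upper numeric bounds, recycled to length `n_params`.
#' @param n_samples base-sample count N (total evaluations `N * (k + 2)`).
#' @param seed RNG seed.
#' @param param_names optional parameter labels (default `x1..xk`).
#' @return list of class `sensitivity_ranking` with `first_order`,
#'   `total_order` (named numeric), `ranking` (parameter names by
#'   decreasing total index, ties broken lexicographically), and
#'   `variance`.
#' @export
sobol_indices <- function(f, n_params, lower = -1, upper = 1,
                          n_samples = 1024L, seed = 1L,
                          param_names = NULL) {
  if (n_params < 2L) {
    stop("Sobol decomposition needs at least 2 parameters")
  }
  if (n_samples < 8L) stop("n_samples too small")
  if (is.null(param_names)) param_names <- paste0("x", seq_len(n_params))
  lower <- rep_len(lower, n_params)
  upper <- rep_len(upper, n_params)
  set.seed(seed)
  scale01 <- function(U) {
    sweep(sweep(U, 2, upper - lower, "*"), 2, lower, "+")
  }
  A <- scale01(lhs::randomLHS(n_samples, n_params))
  B <- scale01(lhs::randomLHS(n_samples, n_params))
  yA <- f(A)
  yB <- f(B)
  V <- var(c(yA, yB))
  first <- total <- setNames(numeric(n_params), param_names)
  for (i in seq_len(n_params)) {
    ABi <- A
    ABi[, i] <- B[, i]
    yABi <- f(ABi)
    if (V <= .Machine$double.eps) {
      first[i] <- 0; total[i] <- 0
    } else {
      first[i] <- mean(yB * (yABi - yA)) / V
      total[i] <- mean((yA - yABi)^2) / (2 * V)
    }
  }
  ord <- order(-total, param_names)
  structure(list(first_order = first, total_order = total,
                 ranking = param_names[ord], variance = V,
                 n_samples = n_samples),
            class = "sensitivity_ranking")
}

#' @export
print.sensitivity_ranking <- function(x, ...) {
  cat("Sobol sensitivity (", x$n_samples, "base samples ): ranking",
      paste(x$ranking, collapse = " > "), "\n")
  for (p in x$ranking) {
    cat(sprintf("  %-12s S1 = %6.3f   ST = %6.3f\n", p,
                x$first_order[[p]], x$total_order[[p]]))
  }
  invisible(x)
}

#' Sobol sensitivity of the propagated fSignal to the stimulus inputs
#'
#' Treats the clamp values of the stimulated proteins as the uncertain
#' inputs, perturbed uniformly within `+/- delta` of their nominal values
#' (truncated to `[-1, 1]`), and the disease fSignal of the propagated
#' profile as the scalar output. Indices are computed per ensemble
#' solution and averaged, so the ranking reflects the whole ensemble, not
#' one model. Deterministic given `config$seed`.
#'
#' @param network an `interaction_network`.
#' @param ensemble a `model_ensemble`.
#' @param stimulus named numeric clamp vector (>= 2 stimulated proteins).
#' @param chars a `disease_characterization`.
#' @param config an [analysis_config()]; `sobol_samples` and `seed` are
#'   taken from it.
#' @param delta perturbation half-width around each nominal clamp value
#'   (default 0.25).
#' @param propagation a [propagation_config()].
#' @return a `sensitivity_ranking` (indices averaged over the ensemble).
#' @export
sobol_sensitivity <- function(network, ensemble, stimulus, chars,
                              config = analysis_config(), delta = 0.25,
                              propagation = propagation_config()) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  .check_stimulus(stimulus, network)
  k <- length(stimulus)
  if (k < 2L) stop("need at least 2 stimulated proteins")
  if (config$sobol_samples < 64L) stop("sobol_samples must be >= 64")
  asn <- chars$assignments
  if (nrow(asn) == 0L) stop("characterization has no effectors")
  eff_idx <- match(asn$protein, network$nodes)
  if (anyNA(eff_idx)) stop("effector(s) absent from network")
  orient <- if (config$fsignal_orientation == "raw") {
    rep(1, nrow(asn))
  } else -asn$disease_sign

  ei <- .edge_index(network)
  clamp_idx <- match(names(stimulus), network$nodes) - 1L
  lower <- pmax(stimulus - delta, -1)
  upper <- pmin(stimulus + delta, 1)

  per_solution <- lapply(ensemble$solutions, function(sol) {
    w <- .solution_weights(sol, network)
    f <- function(X) {
      acts <- cpp_propagate_batch(length(network$nodes), ei$src, ei$dst, w,
                                  clamp_idx, X, propagation$gain,
                                  propagation$damping, propagation$tol,
                                  propagation$max_iter)
      as.numeric(acts[, eff_idx, drop = FALSE] %*% orient) / nrow(asn)
    }
    sobol_indices(f, k, lower, upper, n_samples = config$sobol_samples,
                  seed = config$seed, param_names = names(stimulus))
  })
  first <- rowMeans(vapply(per_solution, function(s) s$first_order,
                           numeric(k)))
  total <- rowMeans(vapply(per_solution, function(s) s$total_order,
                           numeric(k)))
  ord <- order(-total, names(stimulus))
  structure(list(first_order = first, total_order = total,
                 ranking = names(stimulus)[ord],
                 variance = mean(vapply(per_solution,
                                        function(s) s$variance,
                                        numeric(1))),
                 n_samples = config$sobol_samples,
                 per_solution = per_solution),
            class = "sensitivity_ranking")
}
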