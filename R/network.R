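# Directed protein-interaction network: the substrate of the propagation
# model. Internally nodes are a character vector and edges a data.frame
# (source, target, sign_prior) whose row order defines the weight order of
# every model solution fitted on the network.

#' Build a directed protein-interaction network
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `sign_prior` (+1 known activation, -1 known inhibition, `NA`/0 unknown).
#' @param nodes optional character vector of node ids; defaults to the ids
#'   appearing in `edges`. Every edge endpoint must be a declared node.
#' @param allow_self_loops logical; self-edges are rejected unless enabled.
#' @return an object of class `interaction_network`.
#' @export
#' @examples
#' net <- interaction_network(data.frame(source = c("A", "B"),
#'                                       target = c("B", "C")))
#' net
interaction_network <- function(edges, nodes = NULL, allow_self_loops = FALSE) {
  stopifnot(is.data.frame(edges), all(c("source", "target") %in% names(edges)))
  edges$source <- normalize_symbol(edges$source)
  edges$target <- normalize_symbol(edges$target)
  if (is.null(nodes)) {
    nodes <- unique(c(edges$source, edges$target))
  } else {
    nodes <- normalize_symbol(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node ids")
    dangling <- setdiff(c(edges$source, edges$target), nodes)
    if (length(dangling)) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(head(dangling, 5), collapse = ", "))
    }
  }
  if (!allow_self_loops && any(edges$source == edges$target)) {
    stop("self-loop(s) present and allow_self_loops = FALSE: ",
         paste(head(edges$source[edges$source == edges$target], 5),
               collapse = ", "))
  }
  if (anyDuplicated(paste(edges$source, edges$target))) {
    stop("duplicate edge(s) in edge list")
  }
  if (!"sign_prior" %in% names(edges)) edges$sign_prior <- NA_integer_
  edges$sign_prior <- suppressWarnings(as.integer(edges$sign_prior))
  if (!all(edges$sign_prior %in% c(-1L, 1L) | is.na(edges$sign_prior))) {
    stop("sign priors must be +1, -1 or missing")
  }
  edges <- edges[, c("source", "target", "sign_prior")]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  n_prior <- sum(!is.na(x$edges$sign_prior))
  cat("interaction network:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges (", n_prior, "with sign priors )\n")
  invisible(x)
}

#' Number of edges / nodes
#' @param network an `interaction_network`.
#' @return integer count.
#' @export
n_edges <- function(network) nrow(network$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(network) length(network$nodes)

# 0-based edge endpoint indices for the compiled core
.edge_index <- function(network) {
  list(src = match(network$edges$source, network$nodes) - 1L,
       dst = match(network$edges$target, network$nodes) - 1L)
}

#' Read / write an edge-list TSV
#'
#' Layout: columns `source`, `target`, optional `sign_prior` (+1/-1/blank);
#' `#` starts a comment line.
#'
#' @param path file path.
#' @param allow_self_loops passed to [interaction_network()].
#' @return an `interaction_network`.
#' @export
read_edge_list <- function(path, allow_self_loops = FALSE) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L) stop("edge list is empty: ", path)
  interaction_network(df, allow_self_loops = allow_self_loops)
}

#' @rdname read_edge_list
#' @param network an `interaction_network` to write.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  .write_tsv(network$edges, path)
  invisible(path)
}

#' Convert to an igraph object
#' @param network an `interaction_network`.
#' @return a directed `igraph` graph with `sign_prior` edge attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

# ---- stimuli ------------------------------------------------------------

#' Build a stimulus from a drug profile
#'
#' A stimulus clamps the drug's targets (and pseudotargets, which behave
#' identically at propagation time) at `effect_sign * magnitude`.
#'
#' @param profile a `drug_profile`.
#' @param network the `interaction_network` the stimulus will be applied
#'   to; every target must be a network node.
#' @param magnitude clamp magnitude in (0, 1]; default 1.
#' @return named numeric vector of clamp values (a stimulus).
#' @export
stimulus_from_drug <- function(profile, network, magnitude = 1) {
  stopifnot(inherits(profile, "drug_profile"),
            inherits(network, "interaction_network"))
  if (magnitude <= 0 || magnitude > 1) stop("magnitude must be in (0, 1]")
  clamp <- c(profile$targets, profile$pseudotargets) * magnitude
  missing <- setdiff(names(clamp), network$nodes)
  if (length(missing)) {
    stop("drug target(s) absent from network: ",
         paste(missing, collapse = ", "))
  }
  clamp
}

#' Combine two stimuli
#'
#' Per-protein sum of clamp values, clipped to `[-1, 1]` (the combination
#' model applies both drugs' inputs at once).
#'
#' @param a,b named numeric stimulus vectors.
#' @return combined named numeric stimulus.
#' @export
combine_stimuli <- function(a, b) {
  prot <- union(names(a), names(b))
  va <- setNames(rep(0, length(prot)), prot); va[names(a)] <- a
  vb <- setNames(rep(0, length(prot)), prot); vb[names(b)] <- b
  pmin(pmax(va + vb, -1), 1)
}

.check_stimulus <- function(stimulus, network) {
  if (length(stimulus) == 0L || is.null(names(stimulus))) {
    stop("stimulus must be a non-empty named numeric vector")
  }
  if (all(stimulus == 0)) stop("stimulus must have at least one nonzero input")
  if (any(abs(stimulus) > 1)) stop("clamp values must lie in [-1, 1]")
  missing <- setdiff(names(stimulus), network$nodes)
  if (length(missing)) {
    stop("stimulated protein(s) absent from network: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# ---- propagation --------------------------------------------------------

#' Propagation configuration
#'
#' The propagation scheme is a synchronous damped fixed-point iteration:
#' each non-clamped node moves a fraction `damping` of the way towards
#' `tanh(gain * sum of weighted incoming activities)` per sweep; clamped
#' (stimulated) nodes hold their clamp value throughout. On acyclic
#' networks this reduces to feed-forward evaluation; on cyclic networks it
#' is a well-defined fixed-point search whose non-convergence (oscillation)
#' is reported, not hidden.
#'
#' @param tol convergence tolerance on the max absolute per-sweep change
#'   (must be > 0); default 1e-6.
#' @param max_iter maximum sweeps; default 200.
#' @param damping damping factor in (0, 1]; default 0.5.
#' @param gain sigmoid gain (slope at the origin); default 1.
#' @return a list of class `propagation_config`.
#' @export
propagation_config <- function(tol = 1e-6, max_iter = 200L, damping = 0.5,
                               gain = 1) {
  if (tol <= 0) stop("tol must be positive")
  if (damping <= 0 || damping > 1) stop("damping must be in (0, 1]")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 damping = damping, gain = gain),
            class = "propagation_config")
}

#' Construct an activity profile
#'
#' @param activity named numeric vector in `[-1, 1]` (predicted protein
#'   activity).
#' @param clamped named logical vector marking stimulated nodes.
#' @param converged logical; did the fixed-point iteration converge.
#' @param iterations number of sweeps performed.
#' @return an object of class `activity_profile`.
#' @export
activity_profile <- function(activity, clamped = NULL, converged = TRUE,
                             iterations = 0L) {
  if (is.null(clamped)) {
    clamped <- setNames(rep(FALSE, length(activity)), names(activity))
  }
  if (any(abs(activity) > 1 + 1e-12)) stop("activities must lie in [-1, 1]")
  structure(list(activity = activity, clamped = clamped,
                 converged = isTRUE(converged),
                 iterations = as.integer(iterations)),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("activity profile over", length(x$activity), "proteins;",
      sum(x$clamped), "clamped;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iteration(s)\n")
  invisible(x)
}

#' Propagate a stimulus through one model solution
#'
#' Runs the damped fixed-point iteration of the signal-propagation model:
#' every node integrates the sum of incoming activities weighted by the
#' solution's edge weights, squashed through `tanh` onto `[-1, 1]`.
#' Deterministic given (network, solution, stimulus, config).
#'
#' @param network an `interaction_network`.
#' @param solution a `model_solution` covering every network edge.
#' @param stimulus named numeric clamp vector (see [stimulus_from_drug()]).
#' @param config a [propagation_config()].
#' @return an `activity_profile`; `converged = FALSE` flags that `max_iter`
#'   was reached first (the last iterate is still returned).
#' @export
propagate <- function(network, solution, stimulus,
                      config = propagation_config()) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(config, "propagation_config"))
  w <- .solution_weights(solution, network)
  if (any(!is.finite(w))) stop("non-finite edge weight")
  .check_stimulus(stimulus, network)
  ei <- .edge_index(network)
  clamp_idx <- match(names(stimulus), network$nodes) - 1L
  res <- cpp_propagate(length(network$nodes), ei$src, ei$dst, w,
                       clamp_idx, unname(stimulus), config$gain,
                       config$damping, config$tol, config$max_iter)
  activity <- setNames(res$activity, network$nodes)
  clamped <- setNames(rep(FALSE, length(network$nodes)), network$nodes)
  clamped[names(stimulus)] <- TRUE
  activity_profile(activity, clamped, res$converged, res$iterations)
}

#' Mean activity across an ensemble of solutions
#'
#' Propagates the stimulus through every ensemble member and averages the
#' resulting profiles per protein; the dispersion across solutions (their
#' standard deviation) reflects the spread of equally valid models, the
#' modelling analogue of interpatient variability.
#'
#' @param ensemble a `model_ensemble`.
#' @inheritParams propagate
#' @return list with `mean` (an `activity_profile` whose `converged` flag
#'   is the AND over members), `dispersion` (named numeric SD per protein)
#'   and `profiles` (per-member profiles).
#' @export
ensemble_activity <- function(ensemble, network, stimulus,
                              config = propagation_config()) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (length(ensemble$solutions) == 0L) stop("ensemble is empty")
  profiles <- lapply(ensemble$solutions, function(sol) {
    propagate(network, sol, stimulus, config)
  })
  mat <- do.call(rbind, lapply(profiles, function(p) p$activity))
  mean_act <- colMeans(mat)
  disp <- if (nrow(mat) > 1L) apply(mat, 2, sd) else mean_act * 0
  mean_profile <- activity_profile(
    mean_act, profiles[[1]]$clamped,
    converged = all(vapply(profiles, function(p) p$converged, logical(1))),
    iterations = max(vapply(profiles, function(p) p$iterations, integer(1))))
  list(mean = mean_profile, dispersion = disp, profiles = profiles)
}

# ---- reachability -------------------------------------------------------

#' Fraction of a motive's effectors reachable from a stimulus
#'
#' Graph reachability (ignoring weights) from any stimulated node to each
#' effector of the given motive. Used to justify excluding a motive from
#' modelling when no signal can reach it at all, before any training is
#' attempted.
#'
#' @param network an `interaction_network`.
#' @param stimulus named numeric clamp vector.
#' @param chars a `disease_characterization`.
#' @param motive motive id declared in `chars`.
#' @return fraction in `[0, 1]`.
#' @export
motive_reachability <- function(network, stimulus, chars, motive) {
  stopifnot(inherits(chars, "disease_characterization"))
  if (!motive %in% chars$motives$motive) stop("unknown motive: ", motive)
  effectors <- unique(
    chars$assignments$protein[chars$assignments$motive == motive])
  if (length(effectors) == 0L) return(NA_real_)
  .check_stimulus(stimulus, network)
  g <- as_igraph(network)
  # reachability includes the stimulated nodes themselves: a clamped
  # effector (a drug target that is also an effector) does receive signal
  reached <- unique(unlist(lapply(names(stimulus), function(v) {
    names(igraph::subcomponent(g, v, mode = "out"))
  })))
  mean(effectors %in% reached)
}
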