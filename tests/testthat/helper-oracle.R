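# Independent reference implementation of the propagation update, written
# directly from the update equations with dense matrices and no shared code
# with the package internals. Used to cross-check propagate().
oracle_propagate <- function(network, weights, stimulus,
                             tol = 1e-6, max_iter = 200, damping = 0.5,
                             gain = 1) {
  nodes <- network$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(network$edges))) {
    W[network$edges$source[i], network$edges$target[i]] <- weights[i]
  }
  a <- setNames(rep(0, n), nodes)
  a[names(stimulus)] <- stimulus
  free <- setdiff(nodes, names(stimulus))
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    incoming <- drop(a %*% W)          # sum over u of w_uv * a_u
    new_a <- a
    new_a[free] <- (1 - damping) * a[free] +
      damping * tanh(gain * incoming[free])
    delta <- max(abs(new_a - a))
    a <- new_a
    iters <- it
    if (delta < tol) { converged <- TRUE; break }
  }
  list(activity = a, converged = converged, iterations = iters)
}

# random small network + weights + stimulus for oracle comparisons
random_toy_system <- function(seed, n_max = 6L) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  m <- sample(seq_len(nrow(pairs)), sample(1:min(nrow(pairs), 10), 1))
  edges <- pairs[m, ]
  net <- interaction_network(edges, nodes = nodes)
  w <- runif(nrow(edges), -1, 1)
  n_clamp <- sample(seq_len(n - 1), 1)
  stim <- setNames(runif(n_clamp, -1, 1), sample(nodes, n_clamp))
  stim[abs(stim) < 0.05] <- 0.5   # keep the stimulus clearly nonzero
  list(network = net, weights = w, stimulus = stim)
}
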