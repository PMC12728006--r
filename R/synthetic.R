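# Synthetic benchmark generator: networks, disease characterizations,
# drug profiles, planted ground-truth weight solutions and satisfiable
# training sets with the statistical structure the analysis pipeline
# assumes, so every stage is testable without proprietary data.

#' Synthetic system specification
#'
#' @param n_nodes number of proteins.
#' @param topology `"scale_free"` (preferential attachment, hubs
#'   broadcasting downstream), `"small_world"` (rewired ring lattice with
#'   random edge orientation) or `"dag"` (random acyclic layering).
#' @param mean_degree target mean out-degree.
#' @param motive_sizes per-motive effector counts; the desk-scale default
#'   is `c(12, 6, 10, 14)`, the published disease characterization uses
#'   `c(50, 24, 45, 59)`.
#' @param overlap_fraction fraction of effector slots filled by proteins
#'   already assigned to another motive, in `[0, 1)`; ignored when
#'   `n_unique_effectors` is given.
#' @param n_unique_effectors optional exact number of distinct effector
#'   proteins (the generator distributes shared memberships to hit it
#'   exactly; e.g. 148 at the published scale).
#' @param n_drugs number of drug profiles to plant.
#' @param targets_per_drug targets per drug (clamped at -1: inhibitors).
#' @param n_rules training rules to generate by propagating stimuli
#'   through the ground truth.
#' @param rule_noise fraction of expected signs flipped after generation
#'   (0 keeps the set exactly satisfiable by the ground truth).
#' @param detach_motive optional motive id whose effectors are made
#'   unreachable from every drug target (all their incoming edges are
#'   severed), emulating a pathophysiological process the drugs cannot
#'   touch.
#' @param stimulus_pool_size extra high-reachability nodes (beyond the
#'   drug targets) from which random training stimuli are drawn. Rules
#'   sample a bounded pool because curated input-output compendia probe a
#'   limited target space; it also keeps held-out rules learnable from
#'   training rules.
#' @param seed RNG seed; identical spec + seed reproduces the system
#'   bit for bit.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 120L,
                           topology = c("scale_free", "small_world", "dag"),
                           mean_degree = 3,
                           motive_sizes = c(12L, 6L, 10L, 14L),
                           overlap_fraction = 0.15,
                           n_unique_effectors = NULL,
                           n_drugs = 2L, targets_per_drug = 3L,
                           n_rules = 25L, rule_noise = 0,
                           detach_motive = NULL,
                           stimulus_pool_size = 8L, seed = 1L) {
  topology <- match.arg(topology)
  motive_sizes <- as.integer(motive_sizes)
  if (any(motive_sizes <= 0L)) stop("motive sizes must be positive")
  if (sum(motive_sizes) > 0 && max(motive_sizes) > n_nodes) {
    stop("motive sizes exceed the number of nodes")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  if (rule_noise < 0 || rule_noise > 1) stop("rule_noise must be in [0, 1]")
  if (!is.null(detach_motive) &&
      !detach_motive %in% seq_along(motive_sizes)) {
    stop("detach_motive must index motive_sizes")
  }
  structure(list(n_nodes = as.integer(n_nodes), topology = topology,
                 mean_degree = mean_degree, motive_sizes = motive_sizes,
                 overlap_fraction = overlap_fraction,
                 n_unique_effectors = n_unique_effectors,
                 n_drugs = as.integer(n_drugs),
                 targets_per_drug = as.integer(targets_per_drug),
                 n_rules = as.integer(n_rules), rule_noise = rule_noise,
                 detach_motive = detach_motive,
                 stimulus_pool_size = as.integer(stimulus_pool_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.gen_edges <- function(spec) {
  n <- spec$n_nodes
  if (spec$topology == "scale_free") {
    g <- igraph::sample_pa(n, power = 1,
                           m = max(1L, round(spec$mean_degree)),
                           directed = TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
    # preferential attachment points new -> old; reverse so that hubs
    # broadcast downstream and a stimulus can reach a large set
    el <- el[, c(2, 1), drop = FALSE]
  } else if (spec$topology == "small_world") {
    g <- igraph::sample_smallworld(1, n,
                                   nei = max(1L,
                                             round(spec$mean_degree / 2)),
                                   p = 0.1)
    el <- igraph::as_edgelist(g, names = FALSE)
    flip <- runif(nrow(el)) < 0.5
    el[flip, ] <- el[flip, c(2, 1)]
  } else { # dag: edges only from lower to higher topological rank
    p <- min(1, 2 * spec$mean_degree / max(1, n - 1))
    src <- integer(0); dst <- integer(0)
    for (j in 2:n) {
      par <- which(runif(j - 1) < p)
      src <- c(src, par); dst <- c(dst, rep(j, length(par)))
    }
    el <- cbind(src, dst)
  }
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  el <- unique(el)
  el
}

# split U unique proteins over motives with quotas `sizes`; returns an
# assignment data.frame covering exactly U distinct proteins
.distribute_motives <- function(proteins, sizes, motive_ids) {
  U <- length(proteins); S <- sum(sizes)
  stopifnot(U <= S, max(sizes) <= U)
  # primary memberships: every protein appears somewhere
  quota <- pmax(1L, floor(sizes * U / S))
  while (sum(quota) > U) {
    i <- which.max(quota); quota[i] <- quota[i] - 1L
  }
  while (sum(quota) < U) {
    room <- which(quota < sizes)
    i <- room[which.max(sizes[room] - quota[room])]
    quota[i] <- quota[i] + 1L
  }
  shuffled <- sample(proteins)
  primary <- rep(motive_ids, quota)
  asn <- data.frame(protein = shuffled, motive = primary)
  # duplicate slots: shared memberships in other motives
  for (k in seq_along(sizes)) {
    extra <- sizes[k] - quota[k]
    if (extra > 0L) {
      free <- setdiff(proteins, asn$protein[asn$motive == motive_ids[k]])
      pick <- sample(free, extra)
      asn <- rbind(asn, data.frame(protein = pick,
                                   motive = motive_ids[k]))
    }
  }
  asn
}

.high_reach_nodes <- function(g, n_nodes, exclude = character()) {
  reach <- igraph::ego_size(g, order = n_nodes, mode = "out")
  ord <- order(reach, decreasing = TRUE)
  setdiff(igraph::V(g)$name[ord], exclude)
}

# generate rules by propagating stimuli through the ground truth and
# recording effector signs with |activity| >= 0.1 (so the set is exactly
# satisfiable at zero noise)
.rules_from_ground_truth <- function(network, ground_truth, chars, drugs,
                                     pool, n_rules, rule_noise,
                                     config = propagation_config()) {
  effectors <- unique(chars$assignments$protein)
  rules <- list()
  add_rule <- function(stim) {
    prof <- propagate(network, ground_truth, stim, config)
    a <- prof$activity[effectors]
    keep <- abs(a) >= 0.1
    if (!any(keep)) return(FALSE)
    rules[[length(rules) + 1L]] <<-
      training_rule(stim, sign(a[keep]))
    TRUE
  }
  for (d in drugs) add_rule(stimulus_from_drug(d, network))
  if (length(drugs) >= 2L) {
    combo <- Reduce(combine_stimuli,
                    lapply(drugs, stimulus_from_drug, network = network))
    add_rule(combo)
  }
  attempts <- 0L
  while (length(rules) < n_rules && attempts < 50L * n_rules) {
    attempts <- attempts + 1L
    k <- sample(1:3, 1)
    prot <- sample(pool, min(k, length(pool)))
    add_rule(setNames(sample(c(-1, 1), length(prot), replace = TRUE), prot))
  }
  if (length(rules) < n_rules) {
    stop("could not generate ", n_rules, " satisfiable rules")
  }
  rules <- rules[seq_len(n_rules)]
  if (rule_noise > 0) {
    sizes <- vapply(rules, function(r) length(r$expected), integer(1))
    total <- sum(sizes)
    n_flip <- ceiling(rule_noise * total)
    flip <- sample(total, n_flip)
    offset <- c(0L, cumsum(sizes))
    for (i in seq_along(rules)) {
      local_flip <- flip[flip > offset[i] & flip <= offset[i + 1L]] -
        offset[i]
      rules[[i]]$expected[local_flip] <- -rules[[i]]$expected[local_flip]
    }
  }
  training_set(rules)
}

#' Generate a complete synthetic modelling system
#'
#' Produces a network, a disease characterization, drug profiles, a planted
#' ground-truth weight solution and a training set generated by propagating
#' stimuli through the ground truth (so at `rule_noise = 0` the ground
#' truth satisfies every rule exactly). Drug targets are placed on
#' high-reachability nodes; effectors are drawn from the set reachable
#' from the targets, except for an optional detached motive whose effectors
#' have every incoming edge severed.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_system` with elements `network`,
#'   `chars`, `drugs`, `ground_truth`, `training_set`, `stimulus_pool`,
#'   `spec`.
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nodes <- sprintf("P%04d", seq_len(spec$n_nodes))
  el <- .gen_edges(spec)
  edges <- data.frame(source = nodes[el[, 1]], target = nodes[el[, 2]])

  g0 <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = nodes)
  ranked <- .high_reach_nodes(g0, spec$n_nodes)
  n_targets <- spec$n_drugs * spec$targets_per_drug
  # drug targets live on high-reachability nodes (drugs hit upstream
  # regulators); draws must reach enough of the network to host the
  # effectors, so inadequate draws are resampled (best draw kept as the
  # fallback)
  S_all <- sum(spec$motive_sizes)
  U_bound <- if (is.null(spec$n_unique_effectors)) {
    min(S_all, max(max(spec$motive_sizes),
                   round((1 - spec$overlap_fraction) * S_all)))
  } else spec$n_unique_effectors
  needed <- U_bound + n_targets + 5L
  top <- head(ranked, max(2L * n_targets, ceiling(0.1 * spec$n_nodes)))
  union_reach <- function(targets) {
    unique(unlist(lapply(targets, function(v) {
      names(igraph::subcomponent(g0, v, mode = "out"))
    })))
  }
  target_nodes <- sample(top, n_targets)
  reach <- union_reach(target_nodes)
  for (try in seq_len(19L)) {
    if (length(reach) >= needed) break
    cand <- sample(top, n_targets)
    r <- union_reach(cand)
    if (length(r) > length(reach)) {
      target_nodes <- cand
      reach <- r
    }
  }
  drugs <- lapply(seq_len(spec$n_drugs), function(k) {
    idx <- ((k - 1) * spec$targets_per_drug + 1):(k * spec$targets_per_drug)
    drug_profile(paste0("drug", LETTERS[k]),
                 setNames(rep(-1, length(idx)), target_nodes[idx]))
  })

  sizes <- spec$motive_sizes
  motive_ids <- seq_along(sizes)
  detached <- spec$detach_motive

  detached_set <- character()
  if (!is.null(detached)) {
    off <- setdiff(nodes, c(reach, target_nodes))
    need <- sizes[detached]
    if (length(off) >= need) {
      detached_set <- sample(off, need)
    } else {
      extra <- sample(setdiff(reach, target_nodes), need - length(off))
      detached_set <- c(off, extra)
      # sever every incoming edge so no drug signal can arrive
      keep <- !(edges$target %in% detached_set)
      edges <- edges[keep, , drop = FALSE]
      g0 <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                          vertices = nodes)
      reach <- unique(unlist(lapply(target_nodes, function(v) {
        names(igraph::subcomponent(g0, v, mode = "out"))
      })))
    }
  }

  model_ids <- setdiff(motive_ids, detached)
  model_sizes <- sizes[model_ids]
  U_total <- spec$n_unique_effectors
  if (is.null(U_total)) {
    S <- sum(sizes)
    U_total <- max(max(sizes), round((1 - spec$overlap_fraction) * S))
    U_total <- min(U_total, S)
  }
  U_model <- U_total - length(detached_set)
  if (U_model < max(model_sizes) || U_model > sum(model_sizes)) {
    stop("requested unique effector count infeasible for motive sizes")
  }
  pool_eff <- setdiff(reach, detached_set)
  if (length(pool_eff) < U_model) {
    stop("network too sparse: only ", length(pool_eff),
         " nodes reachable from drug targets, need ", U_model)
  }
  eff <- sample(pool_eff, U_model)
  asn <- .distribute_motives(eff, model_sizes, model_ids)
  if (length(detached_set)) {
    asn <- rbind(asn, data.frame(protein = detached_set,
                                 motive = detached))
  }
  asn$disease_sign <- sample(c(-1L, 1L), nrow(asn), replace = TRUE)
  chars <- disease_characterization(
    asn, motives = data.frame(motive = motive_ids,
                              name = paste0("M", motive_ids)))

  # ground truth: signed weights of useful magnitude; ~half the edges get
  # a sign prior consistent with the ground truth
  m <- nrow(edges)
  w <- sample(c(-1, 1), m, replace = TRUE) * runif(m, 0.4, 1)
  has_prior <- runif(m) < 0.5
  edges$sign_prior <- ifelse(has_prior, as.integer(sign(w)), NA_integer_)
  network <- interaction_network(edges, nodes = nodes)
  ground_truth <- model_solution(network, w, seed = spec$seed)

  pool <- head(setdiff(ranked, target_nodes), spec$stimulus_pool_size)
  ts <- .rules_from_ground_truth(network, ground_truth, chars, drugs,
                                 pool, spec$n_rules, spec$rule_noise)

  structure(list(network = network, chars = chars, drugs = drugs,
                 ground_truth = ground_truth, training_set = ts,
                 stimulus_pool = pool, spec = spec, planted = NULL),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat("synthetic system:", n_nodes(x$network), "nodes,",
      n_edges(x$network), "edges,",
      unique_effector_count(x$chars), "unique effectors,",
      length(x$drugs), "drug(s),",
      length(x$training_set$rules), "training rules\n")
  invisible(x)
}

#' Generate a system with planted two-drug synergy
#'
#' Constructs a network in which drug A and drug B own disjoint downstream
#' mechanisms (each reverting its own exclusive effector block) plus a
#' shared convergent block receiving signal from both, so the intended
#' `exclusive_a` / `exclusive_b` / `convergent` decomposition is known by
#' construction and recoverable by [compare_combination()] on the ground
#' truth. Remaining nodes are random filler that never feeds back into the
#' planted mechanism.
#'
#' @param spec a [synthetic_spec()] with `n_drugs = 2`.
#' @param blocks named integer vector with the planted block sizes
#'   `exclusive_a`, `exclusive_b`, `convergent`.
#' @return a `synthetic_system` whose `planted` element records the
#'   intended protein sets.
#' @export
generate_planted_synergy <- function(spec,
                                     blocks = c(exclusive_a = 5L,
                                                exclusive_b = 4L,
                                                convergent = 3L)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_drugs != 2L) stop("planted synergy needs exactly 2 drugs")
  blocks <- blocks[c("exclusive_a", "exclusive_b", "convergent")]
  if (anyNA(blocks) || any(blocks < 0L)) {
    stop("blocks must give sizes for exclusive_a, exclusive_b, convergent")
  }
  if (sum(blocks) > sum(spec$motive_sizes)) {
    stop("planted block sizes exceed the motive sizes")
  }
  set.seed(spec$seed)
  k <- spec$targets_per_drug
  ta <- sprintf("TA%02d", seq_len(k)); tb <- sprintf("TB%02d", seq_len(k))
  ea <- if (blocks[["exclusive_a"]]) {
    sprintf("EA%02d", seq_len(blocks[["exclusive_a"]]))
  } else character()
  eb <- if (blocks[["exclusive_b"]]) {
    sprintf("EB%02d", seq_len(blocks[["exclusive_b"]]))
  } else character()
  ec <- if (blocks[["convergent"]]) {
    sprintf("EC%02d", seq_len(blocks[["convergent"]]))
  } else character()
  hub <- c("HUBA", "HUBB")
  n_untouched <- max(2L, ceiling(0.3 * sum(blocks)))
  un <- sprintf("UE%02d", seq_len(n_untouched))
  mech <- c(ta, tb, hub, ea, eb, ec, un)
  if (length(mech) > spec$n_nodes) {
    stop("n_nodes too small for the planted mechanism")
  }
  filler <- if (length(mech) < spec$n_nodes) {
    sprintf("F%03d", seq_len(spec$n_nodes - length(mech)))
  } else character()
  nodes <- c(mech, filler)

  edge <- function(s, t, w) data.frame(source = s, target = t, weight = w)
  edges <- rbind(
    edge(ta, "HUBA", 0.9), edge(tb, "HUBB", 0.9),
    if (length(ea)) edge("HUBA", ea, 0.9),
    if (length(eb)) edge("HUBB", eb, 0.9),
    if (length(ec)) edge("HUBA", ec, 0.7),
    if (length(ec)) edge("HUBB", ec, 0.7))
  # filler edges: among filler nodes and from planted effectors outward,
  # never into the mechanism
  if (length(filler) >= 2L) {
    nf <- max(1L, round(spec$mean_degree * length(filler)))
    fs <- sample(c(filler, ea, eb, ec), nf, replace = TRUE)
    ft <- sample(filler, nf, replace = TRUE)
    ok <- fs != ft & !duplicated(paste(fs, ft))
    if (any(ok)) {
      edges <- rbind(edges,
                     edge(fs[ok], ft[ok],
                          sample(c(-1, 1), sum(ok), TRUE) *
                            runif(sum(ok), 0.4, 1)))
    }
  }
  edges <- edges[!duplicated(paste(edges$source, edges$target)), ]
  edges$sign_prior <- NA_integer_
  network <- interaction_network(edges[c("source", "target", "sign_prior")],
                                 nodes = nodes)
  ground_truth <- model_solution(network, edges$weight, seed = spec$seed)

  drugs <- list(drug_profile("drugA", setNames(rep(-1, k), ta)),
                drug_profile("drugB", setNames(rep(-1, k), tb)))

  planted_eff <- c(ea, eb, ec)
  motive_ids <- c(1L, 3L, 4L)
  asn <- data.frame(
    protein = c(planted_eff, un),
    motive = rep_len(motive_ids, length(planted_eff) + length(un)),
    disease_sign = c(rep(1L, length(planted_eff)),
                     sample(c(-1L, 1L), length(un), replace = TRUE)))
  chars <- disease_characterization(
    asn, motives = data.frame(motive = motive_ids,
                              name = paste0("M", motive_ids)))

  ts <- .rules_from_ground_truth(network, ground_truth, chars, drugs,
                                 pool = c(ta, tb), spec$n_rules,
                                 spec$rule_noise)
  structure(list(network = network, chars = chars, drugs = drugs,
                 ground_truth = ground_truth, training_set = ts,
                 stimulus_pool = c(ta, tb), spec = spec,
                 planted = list(exclusive_a = ea, exclusive_b = eb,
                                convergent = ec)),
            class = "synthetic_system")
}
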