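# Mechanism-of-action analytics: fSignal, reverted-effector
# classification, per-motive percentages, combination decomposition,
# bioflag corroboration and mechanism-subnetwork extraction.

#' Analysis configuration
#'
#' @param reversion_threshold minimum activity magnitude for an effector to
#'   count as reverted (default 0.1, inclusive: exactly 0.1 counts).
#' @param fsignal_orientation `"disease_oriented"` (default; the mean of
#'   `-disease_sign * activity`, so positive values mean net reversion of
#'   the disease state) or `"raw"` (the literal mean activity arriving at
#'   the effectors).
#' @param sobol_samples Saltelli base-sample count for sensitivity analysis.
#' @param seed seed for the sensitivity sampler.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(reversion_threshold = 0.1,
                            fsignal_orientation = c("disease_oriented",
                                                    "raw"),
                            sobol_samples = 1024L, seed = 1L) {
  if (reversion_threshold < 0) stop("reversion_threshold must be >= 0")
  structure(list(reversion_threshold = reversion_threshold,
                 fsignal_orientation = match.arg(fsignal_orientation),
                 sobol_samples = as.integer(sobol_samples),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# activity of each protein in a profile, 0 when absent; positional match
# so the same protein listed under several motives gets its value each time
.activity_of <- function(profile, proteins) {
  idx <- match(proteins, names(profile$activity))
  a <- ifelse(is.na(idx), 0, profile$activity[idx])
  names(a) <- proteins
  a
}

.scope_assignments <- function(chars, motive) {
  asn <- chars$assignments
  if (!is.null(motive)) {
    if (!motive %in% chars$motives$motive) stop("unknown motive: ", motive)
    asn <- asn[asn$motive == motive, , drop = FALSE]
    if (nrow(asn) == 0L) stop("motive ", motive, " has no effectors")
  }
  asn
}

#' fSignal: average signal arriving at the disease effectors
#'
#' Averages the predicted protein activity over the effector assignments in
#' scope (all motives, or one motive). In `disease_oriented` mode each
#' term is `-disease_sign * activity`, so a positive fSignal means the
#' treatment pushes effectors against their disease state on average; `raw`
#' mode is the literal mean activity.
#'
#' @param profile an `activity_profile`.
#' @param chars a `disease_characterization`.
#' @param motive optional motive id restricting the scope.
#' @param config an [analysis_config()].
#' @return a single number.
#' @export
fsignal <- function(profile, chars, motive = NULL,
                    config = analysis_config()) {
  stopifnot(inherits(profile, "activity_profile"),
            inherits(chars, "disease_characterization"))
  asn <- .scope_assignments(chars, motive)
  if (nrow(asn) == 0L) stop("characterization has no effectors")
  a <- .activity_of(profile, asn$protein)
  if (config$fsignal_orientation == "raw") mean(a)
  else mean(-asn$disease_sign * a)
}

#' Reverted effectors of a treatment
#'
#' A (protein, motive) assignment is reverted when the treatment drives the
#' protein to the sign opposite its disease sign with at least the
#' reversion threshold in magnitude:
#' `sign(activity) == -disease_sign` and `|activity| >= threshold`.
#'
#' @inheritParams fsignal
#' @return data.frame with columns `protein`, `motive`, `disease_sign`,
#'   `activity`, one row per reverted assignment.
#' @export
reverted_effectors <- function(profile, chars, config = analysis_config()) {
  stopifnot(inherits(profile, "activity_profile"),
            inherits(chars, "disease_characterization"))
  asn <- chars$assignments
  if (nrow(asn) == 0L) {
    return(data.frame(protein = character(), motive = integer(),
                      disease_sign = integer(), activity = numeric()))
  }
  a <- .activity_of(profile, asn$protein)
  rev <- (sign(a) == -asn$disease_sign) &
    (abs(a) >= config$reversion_threshold)
  out <- asn[rev, , drop = FALSE]
  out$activity <- unname(a[rev])
  rownames(out) <- NULL
  out
}

#' Percentage of effectors reverted
#'
#' `100 * |unique reverted proteins in scope| / |unique effector proteins
#' in scope|`. Counting is by unique protein, not by (protein, motive)
#' pair, so a protein reverted in several motives contributes once to the
#' overall percentage.
#'
#' @inheritParams fsignal
#' @return percentage in `[0, 100]`.
#' @export
percent_reversed <- function(profile, chars, motive = NULL,
                             config = analysis_config()) {
  asn <- .scope_assignments(chars, motive)
  denom <- unique(asn$protein)
  if (length(denom) == 0L) stop("no effectors in scope")
  rev <- reverted_effectors(profile, chars, config)
  if (!is.null(motive)) rev <- rev[rev$motive == motive, , drop = FALSE]
  100 * length(unique(rev$protein)) / length(denom)
}

#' Summarise a treatment's mechanism of action
#'
#' Bundles fSignal, the reverted assignments and per-motive reversion
#' percentages for one treatment profile.
#'
#' @inheritParams fsignal
#' @return list of class `moa_result` with elements `fsignal`,
#'   `fsignal_by_motive`, `reverted`, `percent_reversed_overall`,
#'   `percent_reversed_by_motive`, `n_unique_reverted`, `n_unique_effectors`
#'   and `converged`.
#' @export
moa_summary <- function(profile, chars, config = analysis_config()) {
  motives <- chars$motives$motive
  rev <- reverted_effectors(profile, chars, config)
  structure(list(
    fsignal = fsignal(profile, chars, config = config),
    fsignal_by_motive = setNames(
      vapply(motives, function(m) fsignal(profile, chars, m, config),
             numeric(1)), paste0("M", motives)),
    reverted = rev,
    percent_reversed_overall = percent_reversed(profile, chars,
                                                config = config),
    percent_reversed_by_motive = setNames(
      vapply(motives, function(m) percent_reversed(profile, chars, m,
                                                   config), numeric(1)),
      paste0("M", motives)),
    n_unique_reverted = length(unique(rev$protein)),
    n_unique_effectors = unique_effector_count(chars),
    converged = profile$converged),
    class = "moa_result")
}

#' @export
print.moa_result <- function(x, ...) {
  cat(sprintf(
    "MoA summary: fSignal %.3f; %d/%d unique effectors reverted (%.1f%%)\n",
    x$fsignal, x$n_unique_reverted, x$n_unique_effectors,
    x$percent_reversed_overall))
  if (!x$converged) cat("  [warning] propagation did not converge\n")
  invisible(x)
}

# ---- combination decomposition -----------------------------------------

#' Decompose a two-drug combination into convergent and exclusive effects
#'
#' Classifies the unique proteins reverted by the combination treatment:
#' * `convergent` — reverted by drug A alone and drug B alone, and at
#'   least as strongly by the combination
#'   (`|activity_ab| >= max(|activity_a|, |activity_b|)`, the
#'   "greatly reversed" rule);
#' * `exclusive_a` — reverted by A alone and by the combination, but not
#'   by B (a complementary mechanism contributed by A); `exclusive_b`
#'   symmetric;
#' * `emergent` — reverted only under the combination;
#' * `attenuated` — reverted by both single drugs but less strongly under
#'   the combination than under the stronger single drug.
#'
#' The five sets are pairwise disjoint and together partition the
#' combination's unique reverted proteins.
#'
#' @param profile_a,profile_b,profile_ab `activity_profile`s for drug A,
#'   drug B and the combination, over the same protein universe.
#' @param chars a `disease_characterization`.
#' @param config an [analysis_config()].
#' @return list of class `combination_comparison` with the five protein
#'   sets, `per_motive` (data.frame of per-motive tallies),
#'   `complementary_table` (one row per exclusive protein with its
#'   modulation signs), and the per-treatment reverted data.frames.
#' @export
compare_combination <- function(profile_a, profile_b, profile_ab, chars,
                                config = analysis_config()) {
  u <- function(p) sort(unique(names(p$activity)))
  if (!identical(u(profile_a), u(profile_ab)) ||
      !identical(u(profile_b), u(profile_ab))) {
    stop("the three profiles cover different protein universes")
  }
  rev_a <- reverted_effectors(profile_a, chars, config)
  rev_b <- reverted_effectors(profile_b, chars, config)
  rev_ab <- reverted_effectors(profile_ab, chars, config)
  pa <- unique(rev_a$protein); pb <- unique(rev_b$protein)
  pab <- unique(rev_ab$protein)

  both <- intersect(intersect(pa, pb), pab)
  mag_a <- abs(.activity_of(profile_a, both))
  mag_b <- abs(.activity_of(profile_b, both))
  mag_ab <- abs(.activity_of(profile_ab, both))
  great <- mag_ab >= pmax(mag_a, mag_b)
  convergent <- both[great]
  attenuated <- both[!great]
  exclusive_a <- setdiff(intersect(pa, pab), pb)
  exclusive_b <- setdiff(intersect(pb, pab), pa)
  emergent <- setdiff(pab, union(pa, pb))

  motives <- chars$motives$motive
  per_motive <- do.call(rbind, lapply(motives, function(m) {
    in_m <- unique(rev_ab$protein[rev_ab$motive == m])
    data.frame(motive = m,
               convergent = sum(convergent %in% in_m),
               exclusive_a = sum(exclusive_a %in% in_m),
               exclusive_b = sum(exclusive_b %in% in_m),
               emergent = sum(emergent %in% in_m),
               attenuated = sum(attenuated %in% in_m))
  }))

  excl <- c(exclusive_a, exclusive_b)
  complementary_table <- if (length(excl)) {
    asn <- chars$assignments[chars$assignments$protein %in% excl, ,
                             drop = FALSE]
    agg <- split(asn, asn$protein)
    do.call(rbind, lapply(agg, function(d) {
      p <- d$protein[1]
      data.frame(protein = p,
                 motives = paste(d$motive, collapse = ";"),
                 disease_signs = paste(d$disease_sign, collapse = ";"),
                 mod_a = .mod_sign(profile_a, p, config),
                 mod_b = .mod_sign(profile_b, p, config),
                 mod_combo = .mod_sign(profile_ab, p, config),
                 exclusive_to = if (p %in% exclusive_a) "A" else "B")
    }))
  } else data.frame()
  rownames(complementary_table) <- NULL

  structure(list(convergent = convergent,
                 exclusive_a = exclusive_a,
                 exclusive_b = exclusive_b,
                 emergent = emergent,
                 attenuated = attenuated,
                 per_motive = per_motive,
                 complementary_table = complementary_table,
                 reverted_a = rev_a, reverted_b = rev_b,
                 reverted_ab = rev_ab),
            class = "combination_comparison")
}

.mod_sign <- function(profile, protein, config) {
  a <- .activity_of(profile, protein)
  if (abs(a) < config$reversion_threshold) 0L else as.integer(sign(a))
}

#' @export
print.combination_comparison <- function(x, ...) {
  cat(sprintf(paste0("combination decomposition: %d convergent, ",
                     "%d exclusive to A, %d exclusive to B, %d emergent, ",
                     "%d attenuated\n"),
              length(x$convergent), length(x$exclusive_a),
              length(x$exclusive_b), length(x$emergent),
              length(x$attenuated)))
  invisible(x)
}

# ---- bioflag corroboration ---------------------------------------------

#' Corroborate model behaviour against literature bioflags
#'
#' For each bioflag the model is `corroborated` when the predicted activity
#' has the reported sign with at least the threshold magnitude,
#' `below_threshold` when the sign matches (or the activity is zero) but
#' the magnitude falls short, and `antagonised` when the model drives the
#' protein in the opposite direction. Bioflags absent from the profile are
#' reported separately and not counted as evaluated.
#'
#' @param profile an `activity_profile`.
#' @param bioflags a [bioflag_set()].
#' @param config an [analysis_config()] (the reversion threshold doubles as
#'   the bioflag activity threshold).
#' @return list of class `bioflag_report` with counts and a per-protein
#'   status data.frame.
#' @export
corroborate_bioflags <- function(profile, bioflags,
                                 config = analysis_config()) {
  stopifnot(inherits(profile, "activity_profile"))
  if (nrow(bioflags) == 0L) stop("bioflag set is empty")
  present <- bioflags$protein %in% names(profile$activity)
  a <- .activity_of(profile, bioflags$protein)
  status <- rep("absent", nrow(bioflags))
  thr <- config$reversion_threshold
  s <- bioflags$expected_sign
  status[present & sign(a) == s & abs(a) >= thr] <- "corroborated"
  status[present & sign(a) == -s & abs(a) >= thr] <- "antagonised"
  status[present & (abs(a) < thr | sign(a) == 0)] <- "below_threshold"
  per_protein <- data.frame(protein = bioflags$protein,
                            expected_sign = s,
                            activity = unname(a),
                            status = status)
  structure(list(n_evaluated = sum(present),
                 n_corroborated = sum(status == "corroborated"),
                 n_antagonised = sum(status == "antagonised"),
                 n_below_threshold = sum(status == "below_threshold"),
                 n_absent = sum(!present),
                 per_protein = per_protein),
            class = "bioflag_report")
}

#' @export
print.bioflag_report <- function(x, ...) {
  cat(sprintf(paste0("bioflag corroboration: %d/%d corroborated, ",
                     "%d antagonised, %d below threshold, %d absent\n"),
              x$n_corroborated, x$n_evaluated, x$n_antagonised,
              x$n_below_threshold, x$n_absent))
  invisible(x)
}

# ---- mechanism subnetwork ----------------------------------------------

#' Extract the mechanism-of-action subnetwork
#'
#' Builds the subgraph through which the stimulus reaches the reverted
#' effectors: nodes are the stimulated proteins, the reverted effectors and
#' every intermediate lying on a directed path between them whose ensemble
#' mean activity magnitude clears the threshold. Edges are annotated with
#' the sign of (mean weight x mean upstream activity): positive edges carry
#' activation, negative inhibition.
#'
#' @param network an `interaction_network`.
#' @param ensemble a `model_ensemble`.
#' @param stimulus named numeric clamp vector.
#' @param chars a `disease_characterization`.
#' @param config an [analysis_config()].
#' @param convergent optional character vector of convergent effectors to
#'   flag in the export.
#' @return list of class `moa_subnetwork` with `nodes` (protein, role,
#'   activity, convergent) and `edges` (source, target, weight, sign);
#'   empty (with a warning) when nothing is reverted.
#' @export
extract_moa_subnetwork <- function(network, ensemble, stimulus, chars,
                                   config = analysis_config(),
                                   convergent = character()) {
  act <- ensemble_activity(ensemble, network, stimulus)
  profile <- act$mean
  rev <- reverted_effectors(profile, chars, config)
  effectors <- unique(rev$protein)
  stim <- names(stimulus)
  if (length(effectors) == 0L) {
    warning("no reverted effectors; mechanism subnetwork is empty")
    return(structure(list(nodes = data.frame(), edges = data.frame()),
                     class = "moa_subnetwork"))
  }
  g <- as_igraph(network)
  downstream <- unique(unlist(lapply(stim, function(v) {
    names(igraph::subcomponent(g, v, mode = "out"))
  })))
  upstream <- unique(unlist(lapply(effectors, function(v) {
    names(igraph::subcomponent(g, v, mode = "in"))
  })))
  on_path <- intersect(downstream, upstream)
  inter <- setdiff(on_path, c(stim, effectors))
  inter <- inter[abs(profile$activity[inter]) >= config$reversion_threshold]
  keep <- unique(c(stim, effectors, inter))

  W <- rowMeans(vapply(ensemble$solutions, function(s) unname(s$weights),
                       numeric(nrow(network$edges))))
  e <- network$edges
  sel <- e$source %in% keep & e$target %in% keep
  edges <- data.frame(source = e$source[sel], target = e$target[sel],
                      weight = W[sel])
  edges$sign <- as.integer(sign(W[sel] *
                                  profile$activity[edges$source]))
  role <- ifelse(keep %in% stim, "target",
                 ifelse(keep %in% effectors, "effector", "intermediate"))
  nodes <- data.frame(protein = keep, role = role,
                      activity = unname(profile$activity[keep]),
                      convergent = keep %in% convergent)
  structure(list(nodes = nodes, edges = edges), class = "moa_subnetwork")
}

#' Export a mechanism subnetwork as a DOT graph
#'
#' Green edges carry activation, red inhibition, grey silent edges;
#' diamonds mark drug targets and filled circles convergent effectors.
#'
#' @param subnet a `moa_subnetwork`.
#' @param path output `.dot` / `.gv` file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(subnet, path) {
  stopifnot(inherits(subnet, "moa_subnetwork"))
  q <- function(x) paste0('"', gsub('"', "", x), '"')
  lines <- c("digraph moa {", "  rankdir=LR;",
             "  node [style=solid, shape=ellipse];")
  if (nrow(subnet$nodes)) {
    shape <- ifelse(subnet$nodes$role == "target", "diamond",
                    ifelse(subnet$nodes$role == "effector", "circle",
                           "ellipse"))
    style <- ifelse(subnet$nodes$convergent, "filled", "solid")
    lines <- c(lines, sprintf("  %s [shape=%s, style=%s];",
                              q(subnet$nodes$protein), shape, style))
  }
  if (nrow(subnet$edges)) {
    col <- ifelse(subnet$edges$sign > 0, "green",
                  ifelse(subnet$edges$sign < 0, "red", "grey"))
    lines <- c(lines, sprintf("  %s -> %s [color=%s];",
                              q(subnet$edges$source), q(subnet$edges$target),
                              col))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
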