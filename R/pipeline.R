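# End-to-end pipeline: train, per-drug MoA, combination decomposition,
# bioflag corroboration, sensitivity ranking and report/DOT export, plus
# the packaged-table regression replay.

#' Pipeline run configuration
#'
#' Inputs may be given as in-memory objects (as produced by the package's
#' constructors or the synthetic generator) or as file paths in the
#' package's formats; paths are loaded at run start.
#'
#' @param network `interaction_network` or edge-list TSV path.
#' @param chars `disease_characterization` or TSV/JSON path.
#' @param drugs list of `drug_profile`s (or TSV/JSON paths); the first two
#'   are treated as drug A and drug B for the combination analysis.
#' @param training_set `training_set` or JSON path.
#' @param bioflags optional named list of `bioflag_set`s (or TSV paths),
#'   one per drug name, evaluated against that drug's model and the
#'   combination.
#' @param anneal an [anneal_config()].
#' @param analysis an [analysis_config()].
#' @param output_dir directory for the report bundle; created if missing.
#' @param seed base seed stamped into the run; overrides
#'   `anneal$base_seed` and `analysis$seed` so one seed drives all
#'   randomness.
#' @param run_sobol logical; sensitivity analysis can be switched off for
#'   quick runs.
#' @return list of class `run_config`.
#' @export
run_config <- function(network, chars, drugs, training_set,
                       bioflags = NULL, anneal = anneal_config(),
                       analysis = analysis_config(),
                       output_dir = tempfile("moanet_run_"), seed = 1L,
                       run_sobol = TRUE) {
  load_if_path <- function(x, loader) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("input path does not exist: ", x)
      loader(x)
    } else x
  }
  network <- load_if_path(network, read_edge_list)
  chars <- load_if_path(chars, read_characterization)
  drugs <- lapply(drugs, load_if_path, loader = read_drug_profile)
  training_set <- load_if_path(training_set, read_training_set)
  if (!is.null(bioflags)) {
    bioflags <- lapply(bioflags, load_if_path, loader = read_bioflags)
  }
  seed <- as.integer(seed)
  anneal$base_seed <- seed
  analysis$seed <- seed
  structure(list(network = network, chars = chars, drugs = drugs,
                 training_set = training_set, bioflags = bioflags,
                 anneal = anneal, analysis = analysis,
                 output_dir = output_dir, seed = seed,
                 run_sobol = isTRUE(run_sobol)),
            class = "run_config")
}

#' Run the full modelling and mechanism-analysis pipeline
#'
#' Stages: train an ensemble against the training set; propagate each
#' drug's stimulus and the combined stimulus through the ensemble;
#' summarise each treatment's mechanism (fSignal, reverted effectors,
#' per-motive percentages); decompose the combination into convergent and
#' exclusive mechanisms; corroborate bioflags; rank stimulus inputs by
#' Sobol sensitivity; export the mechanism subnetwork (DOT), the ensemble
#' archive and a JSON report. Every artefact is regenerable from the
#' config plus its seed; no timestamps are written, so identical configs
#' give byte-identical reports.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return the report list, invisibly; written to
#'   `file.path(config$output_dir, "report.json")`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %-12s done in %.1fs", name,
        proc.time()[["elapsed"]] - t0)
    out
  }

  net <- config$network; chars <- config$chars
  ensemble <- stage("train", train_ensemble(net, config$training_set,
                                            config$anneal,
                                            verbose = verbose))
  stimuli <- lapply(config$drugs, stimulus_from_drug, network = net)
  names(stimuli) <- vapply(config$drugs, function(d) d$name, character(1))
  combo_stim <- Reduce(combine_stimuli, stimuli)

  acts <- stage("propagate", c(
    lapply(stimuli, function(s) ensemble_activity(ensemble, net, s)),
    list(combination = ensemble_activity(ensemble, net, combo_stim))))

  moa <- stage("moa", lapply(acts, function(a) {
    moa_summary(a$mean, chars, config$analysis)
  }))

  comparison <- NULL
  if (length(stimuli) >= 2L) {
    comparison <- stage("decompose", compare_combination(
      acts[[1]]$mean, acts[[2]]$mean, acts$combination$mean, chars,
      config$analysis))
  }

  bioflag_reports <- NULL
  if (!is.null(config$bioflags)) {
    bioflag_reports <- stage("bioflags", lapply(
      names(config$bioflags), function(drug) {
        bf <- config$bioflags[[drug]]
        prof <- if (drug %in% names(acts)) acts[[drug]]$mean
                else acts$combination$mean
        list(drug = drug,
             single = corroborate_bioflags(prof, bf, config$analysis),
             combination = corroborate_bioflags(acts$combination$mean, bf,
                                                config$analysis))
      }))
  }

  sobol <- NULL
  if (config$run_sobol && length(combo_stim) >= 2L) {
    sobol <- stage("sobol", sobol_sensitivity(net, ensemble, combo_stim,
                                              chars, config$analysis))
  }

  subnet <- stage("subnetwork", extract_moa_subnetwork(
    net, ensemble, combo_stim, chars, config$analysis,
    convergent = if (!is.null(comparison)) comparison$convergent
                 else character()))
  write_dot(subnet, file.path(config$output_dir, "moa_subnetwork.dot"))
  write_ensemble(ensemble, file.path(config$output_dir, "ensemble"), net)
  for (nm in names(acts)) {
    prof <- acts[[nm]]$mean
    .write_tsv(data.frame(protein = names(prof$activity),
                          activity = unname(prof$activity),
                          clamped = unname(prof$clamped)),
               file.path(config$output_dir,
                         paste0("activity_", nm, ".tsv")))
  }

  report <- list(
    seed = config$seed,
    accuracy_gate = config$anneal$accuracy_gate,
    ensemble = list(
      n_solutions = length(ensemble$solutions),
      mean_accuracy = ensemble_accuracy(ensemble),
      mean_accuracy_label = sprintf("%.2f%%",
                                    100 * ensemble_accuracy(ensemble)),
      accuracies = vapply(ensemble$solutions, function(s) s$accuracy,
                          numeric(1))),
    treatments = lapply(moa, function(m) list(
      fsignal = m$fsignal,
      fsignal_by_motive = as.list(m$fsignal_by_motive),
      percent_reversed_overall = m$percent_reversed_overall,
      percent_reversed_by_motive = as.list(m$percent_reversed_by_motive),
      n_unique_reverted = m$n_unique_reverted,
      n_unique_effectors = m$n_unique_effectors,
      converged = m$converged)),
    combination_decomposition = if (!is.null(comparison)) list(
      convergent = as.list(comparison$convergent),
      exclusive_a = as.list(comparison$exclusive_a),
      exclusive_b = as.list(comparison$exclusive_b),
      emergent = as.list(comparison$emergent),
      attenuated = as.list(comparison$attenuated),
      per_motive = comparison$per_motive),
    bioflags = if (!is.null(bioflag_reports)) lapply(
      bioflag_reports, function(b) list(
        drug = b$drug,
        single = b$single[c("n_evaluated", "n_corroborated",
                            "n_antagonised", "n_below_threshold")],
        combination = b$combination[c("n_evaluated", "n_corroborated",
                                      "n_antagonised",
                                      "n_below_threshold")])),
    sobol = if (!is.null(sobol)) list(
      first_order = as.list(sobol$first_order),
      total_order = as.list(sobol$total_order),
      ranking = sobol$ranking))
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report written to %s", file.path(config$output_dir, "report.json"))
  invisible(report)
}

#' Replay the packaged mechanism tables as a regression report
#'
#' Recomputes, through the package's own classification logic, the counts
#' published for the vedolizumab (VDZ) + JAK-inhibitor (JAKi) combination
#' in Crohn's disease: 13 effectors reverted exclusively by VDZ (6 of them
#' in motive M1), 11 exclusively by JAKi (7 in M4), 10 convergent
#' effectors, and 20 of 21 evaluated VDZ bioflags corroborated under the
#' combined treatment. Any mismatch is reported with the offending
#' proteins.
#'
#' @param magnitude symbol-to-activity replay magnitude (default 0.5; the
#'   counts depend only on signs and the 0.1 threshold).
#' @return data.frame with columns `check`, `expected`, `actual`, `pass`,
#'   `mismatch` (offending proteins, if any), with attribute `comparison`
#'   holding the full `combination_comparison`.
#' @export
replay_tables <- function(magnitude = 0.5) {
  tbl <- rbind(read_mechanism_table(moanet_fixture("complementary")),
               read_mechanism_table(moanet_fixture("convergent")))
  rep_ <- mechanism_table_profiles(tbl, magnitude)
  cmp <- compare_combination(rep_$a, rep_$b, rep_$ab, rep_$chars)

  bft <- read_bioflag_table(moanet_fixture("vdz_bioflags"))
  bf_profile <- .bioflag_profile_from_statuses(bft, "status_combo",
                                               magnitude)
  bf <- corroborate_bioflags(bf_profile,
                             bioflag_set(bft$protein, bft$bioflag_sign,
                                         bft$uniprot))

  in_motive <- function(set, m) {
    rev <- cmp$reverted_ab
    intersect(set, unique(rev$protein[rev$motive == m]))
  }
  checks <- list(
    list("vdz_exclusive", 13L, cmp$exclusive_a),
    list("vdz_exclusive_m1", 6L, in_motive(cmp$exclusive_a, 1L)),
    list("jaki_exclusive", 11L, cmp$exclusive_b),
    list("jaki_exclusive_m4", 7L, in_motive(cmp$exclusive_b, 4L)),
    list("convergent", 10L, cmp$convergent),
    list("bioflags_corroborated", 20L,
         bf$per_protein$protein[bf$per_protein$status == "corroborated"]))
  out <- do.call(rbind, lapply(checks, function(ch) {
    data.frame(check = ch[[1]], expected = ch[[2]],
               actual = length(ch[[3]]),
               pass = length(ch[[3]]) == ch[[2]],
               mismatch = if (length(ch[[3]]) == ch[[2]]) "" else
                 paste(ch[[3]], collapse = ","))
  }))
  attr(out, "comparison") <- cmp
  attr(out, "bioflag_report") <- bf
  out
}

# map recorded corroboration statuses back to synthetic activities so the
# classifier can be exercised on the published table
.bioflag_profile_from_statuses <- function(bft, column, magnitude = 0.5) {
  status <- bft[[column]]
  keep <- status != "blank"
  act <- numeric(sum(keep))
  s <- bft$bioflag_sign[keep]
  st <- status[keep]
  act[st == "corroborated"] <- s[st == "corroborated"] * magnitude
  act[st == "antagonised"] <- -s[st == "antagonised"] * magnitude
  act[st == "below_threshold"] <- s[st == "below_threshold"] * 0.05
  activity_profile(setNames(act, bft$protein[keep]))
}
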