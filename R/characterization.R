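#' @useDynLib moanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd var setNames
#' @importFrom utils read.delim write.table head
NULL

# ---- symbols and signs -------------------------------------------------

.symbol_aliases <- c(
  "MADCAM-1" = "MADCAM1",
  "MADCAM_1" = "MADCAM1",
  "CADH1"    = "CDH1"
)

#' Normalize a gene symbol
#'
#' Gene symbols are the canonical protein key throughout the package; UniProt
#' accessions are optional metadata. Normalization upper-cases, strips
#' hyphens/whitespace and resolves a small alias table (e.g. the
#' "MAdCAM-1" spelling becomes `MADCAM1`).
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbol(c("MAdCAM-1", "nfkb2"))
normalize_symbol <- function(x) {
  y <- toupper(trimws(as.character(x)))
  y <- gsub("[-‐‑]", "", y)
  hit <- y %in% names(.symbol_aliases)
  y[hit] <- .symbol_aliases[y[hit]]
  y
}

#' Parse activation/inhibition signs
#'
#' Maps the sign alphabets used across inputs onto integers:
#' `"up"`/`"↑"`/`"▲"`/`+1` to `+1`, `"down"`/`"↓"`/`"▼"`/`-1`
#' to `-1`, and (where allowed) `"none"`/`"▬"` to `0` for
#' no-modulation entries of treatment columns.
#'
#' @param x vector of sign tokens (character or numeric).
#' @param allow_zero logical; permit the no-modulation token. Disease signs
#'   must be strictly `+1`/`-1`, so loaders pass `FALSE` there.
#' @return integer vector of signs.
#' @export
parse_sign <- function(x, allow_zero = FALSE) {
  tok <- tolower(trimws(as.character(x)))
  map <- c("up" = 1, "down" = -1, "none" = 0,
           "+1" = 1, "1" = 1, "-1" = -1, "0" = 0,
           "↑" = 1, "↓" = -1,
           "▲" = 1, "▼" = -1, "▬" = 0)
  out <- unname(map[tok])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unparseable sign token(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  if (!allow_zero && any(out == 0)) {
    stop("sign 0 (no modulation) not allowed here; row value(s): ",
         paste(unique(x[out == 0]), collapse = ", "), call. = FALSE)
  }
  as.integer(out)
}

# ---- disease characterization ------------------------------------------

#' Construct a disease characterization
#'
#' A disease characterization is the response side of the model: a set of
#' effector proteins, each assigned to one or more pathophysiological
#' processes ("motives") with a disease activation sign (+1 hyperactive,
#' -1 hypoactive in disease). The same protein may carry different signs in
#' different motives.
#'
#' @param assignments data.frame with columns `protein`, `motive`
#'   (positive integer), `disease_sign` (+1/-1); one row per
#'   (protein, motive) pair.
#' @param motives optional data.frame with columns `motive`, `name`
#'   declaring motive labels; defaults to the motives present.
#' @return an object of class `disease_characterization`.
#' @export
disease_characterization <- function(assignments, motives = NULL) {
  if (is.null(assignments) || nrow(assignments) == 0L) {
    assignments <- data.frame(protein = character(), motive = integer(),
                              disease_sign = integer())
  }
  stopifnot(all(c("protein", "motive", "disease_sign") %in% names(assignments)))
  assignments$protein <- normalize_symbol(assignments$protein)
  assignments$motive <- as.integer(assignments$motive)
  assignments$disease_sign <- as.integer(assignments$disease_sign)
  if (any(assignments$motive <= 0L, na.rm = TRUE)) {
    stop("motive ids must be positive integers")
  }
  if (!all(assignments$disease_sign %in% c(-1L, 1L))) {
    stop("disease signs must be +1 or -1")
  }
  key <- paste(assignments$protein, assignments$motive)
  if (anyDuplicated(key)) {
    stop("duplicate (protein, motive) assignment(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (is.null(motives)) {
    ids <- sort(unique(assignments$motive))
    motives <- data.frame(motive = ids,
                          name = if (length(ids)) paste0("M", ids)
                                 else character())
  } else {
    stopifnot(all(c("motive", "name") %in% names(motives)))
    motives$motive <- as.integer(motives$motive)
    if (anyDuplicated(motives$motive)) stop("duplicate motive ids declared")
    if (!all(assignments$motive %in% motives$motive)) {
      stop("assignment references an undeclared motive")
    }
  }
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, motives = motives),
            class = "disease_characterization")
}

#' @export
print.disease_characterization <- function(x, ...) {
  cat("disease characterization:",
      unique_effector_count(x), "unique effectors,",
      nrow(x$assignments), "assignments across motives {",
      paste(x$motives$motive, collapse = ","), "}\n")
  invisible(x)
}

#' Number of distinct effector proteins in a characterization
#'
#' A protein assigned to several motives is counted once, so the result is
#' at most the sum of per-motive sizes, with equality iff motives are
#' disjoint.
#'
#' @param chars a `disease_characterization`.
#' @return non-negative integer count.
#' @export
unique_effector_count <- function(chars) {
  stopifnot(inherits(chars, "disease_characterization"))
  length(unique(chars$assignments$protein))
}

#' Read a disease characterization from TSV or JSON
#'
#' TSV layout: columns `protein`, `motive`, `disease_sign`, one row per
#' (protein, motive) assignment. Signs may use any supported alphabet
#' (`up`/`down`, arrows, +1/-1). JSON layout mirrors the object returned by
#' [write_characterization()].
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @return a `disease_characterization`.
#' @export
read_characterization <- function(path, format = c("auto", "tsv", "json")) {
  format <- .resolve_format(match.arg(format), path)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(disease_characterization(as.data.frame(obj$assignments),
                                    as.data.frame(obj$motives)))
  }
  df <- .read_tsv(path)
  if (nrow(df) == 0L || ncol(df) == 0L) return(disease_characterization(NULL))
  stopifnot(all(c("protein", "motive", "disease_sign") %in% names(df)))
  df$disease_sign <- parse_sign(df$disease_sign, allow_zero = FALSE)
  disease_characterization(df)
}

#' Write a disease characterization
#' @param chars a `disease_characterization`.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_characterization <- function(chars, path,
                                   format = c("auto", "tsv", "json")) {
  stopifnot(inherits(chars, "disease_characterization"))
  format <- .resolve_format(match.arg(format), path)
  if (format == "json") {
    jsonlite::write_json(list(assignments = chars$assignments,
                              motives = chars$motives),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    .write_tsv(chars$assignments, path)
  }
  invisible(path)
}

# ---- drug profiles -----------------------------------------------------

#' Construct a drug target profile
#'
#' Targets map proteins to the direction the drug drives them (+1
#' activation, -1 inhibition). Pseudotargets are proteins not physically
#' bound by the drug but clamped in the model to represent a blocked
#' interaction (MAdCAM-1 for vedolizumab); at propagation time they behave
#' exactly like targets, their special status is metadata only.
#'
#' @param name drug name.
#' @param targets named numeric vector of effect signs (+1/-1), names are
#'   gene symbols; must be non-empty.
#' @param pseudotargets optional named numeric vector, disjoint from
#'   `targets`.
#' @return an object of class `drug_profile`.
#' @export
drug_profile <- function(name, targets, pseudotargets = numeric()) {
  if (length(targets) == 0L) stop("drug profile must have at least one target")
  names(targets) <- normalize_symbol(names(targets))
  if (length(pseudotargets)) {
    names(pseudotargets) <- normalize_symbol(names(pseudotargets))
  }
  if (!all(c(targets, pseudotargets) %in% c(-1, 1))) {
    stop("target effect signs must be +1 or -1")
  }
  if (anyDuplicated(names(targets)) || anyDuplicated(names(pseudotargets))) {
    stop("duplicate target protein in drug profile")
  }
  if (any(names(pseudotargets) %in% names(targets))) {
    stop("pseudotargets must be disjoint from targets")
  }
  structure(list(name = as.character(name),
                 targets = targets,
                 pseudotargets = pseudotargets),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("drug profile '", x$name, "': ", length(x$targets), " target(s)",
      if (length(x$pseudotargets)) paste0(" + ", length(x$pseudotargets),
                                          " pseudotarget(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Read a drug profile from TSV or JSON
#'
#' TSV layout: columns `protein`, `effect_sign`, `is_pseudotarget`.
#'
#' @param path file path.
#' @param name drug name; defaults to the file stem.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @return a `drug_profile`.
#' @export
read_drug_profile <- function(path, name = NULL,
                              format = c("auto", "tsv", "json")) {
  format <- .resolve_format(match.arg(format), path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(drug_profile(obj$name, unlist(obj$targets),
                        if (length(obj$pseudotargets)) unlist(obj$pseudotargets)
                        else numeric()))
  }
  df <- .read_tsv(path)
  if (nrow(df) == 0L) stop("drug profile file has no target rows: ", path)
  stopifnot(all(c("protein", "effect_sign") %in% names(df)))
  df$effect_sign <- parse_sign(df$effect_sign, allow_zero = FALSE)
  pseudo <- if ("is_pseudotarget" %in% names(df)) {
    as.logical(df$is_pseudotarget)
  } else rep(FALSE, nrow(df))
  drug_profile(name,
               targets = setNames(df$effect_sign[!pseudo], df$protein[!pseudo]),
               pseudotargets = setNames(df$effect_sign[pseudo],
                                        df$protein[pseudo]))
}

#' Write a drug profile
#' @param profile a `drug_profile`.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_drug_profile <- function(profile, path,
                               format = c("auto", "tsv", "json")) {
  stopifnot(inherits(profile, "drug_profile"))
  format <- .resolve_format(match.arg(format), path)
  if (format == "json") {
    jsonlite::write_json(list(name = profile$name,
                              targets = as.list(profile$targets),
                              pseudotargets = as.list(profile$pseudotargets)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(
      protein = c(names(profile$targets), names(profile$pseudotargets)),
      effect_sign = c(unname(profile$targets), unname(profile$pseudotargets)),
      is_pseudotarget = c(rep(FALSE, length(profile$targets)),
                          rep(TRUE, length(profile$pseudotargets))))
    .write_tsv(df, path)
  }
  invisible(path)
}

# ---- bioflags -----------------------------------------------------------

#' Construct a bioflag set
#'
#' Bioflags are proteins reported in the literature to be altered downstream
#' of a drug's targets; the model is corroborated by checking it drives them
#' in the reported direction.
#'
#' @param protein character vector of gene symbols.
#' @param expected_sign numeric vector of +1/-1, the reported direction.
#' @param uniprot optional character vector of UniProt accessions.
#' @return data.frame of class `bioflag_set`.
#' @export
bioflag_set <- function(protein, expected_sign, uniprot = NA_character_) {
  protein <- normalize_symbol(protein)
  if (anyDuplicated(protein)) stop("one bioflag entry per protein")
  if (!all(expected_sign %in% c(-1, 1))) stop("bioflag signs must be +1/-1")
  structure(data.frame(protein = protein,
                       expected_sign = as.integer(expected_sign),
                       uniprot = uniprot),
            class = c("bioflag_set", "data.frame"))
}

#' Read bioflags from a TSV file
#'
#' Expected columns: `protein`, `bioflag_sign` (or `expected_sign`);
#' optional `uniprot`.
#'
#' @param path file path.
#' @return a `bioflag_set`.
#' @export
read_bioflags <- function(path) {
  df <- .read_tsv(path)
  sign_col <- intersect(c("bioflag_sign", "expected_sign"), names(df))[1]
  if (is.na(sign_col)) stop("no bioflag sign column in ", path)
  bioflag_set(df$protein, parse_sign(df[[sign_col]]),
              uniprot = if ("uniprot" %in% names(df)) df$uniprot
                        else NA_character_)
}

# ---- packaged fixtures --------------------------------------------------

#' Path to a packaged fixture file
#'
#' The package ships small plain-text transcriptions of published
#' mechanism tables for the vedolizumab (VDZ) plus JAK-inhibitor (JAKi)
#' combination in Crohn's disease: `"complementary"` (24 effectors reverted
#' exclusively by one drug and maintained in the combination),
#' `"convergent"` (10 effectors reverted by both drugs), `"vdz_bioflags"`
#' (22 VDZ bioflags with their corroboration status), and the VDZ / JAKi
#' target profiles.
#'
#' @param name one of `"complementary"`, `"convergent"`, `"vdz_bioflags"`,
#'   `"vdz_profile"`, `"jaki_profile"`.
#' @return file path inside the installed package.
#' @export
moanet_fixture <- function(name = c("complementary", "convergent",
                                    "vdz_bioflags", "vdz_profile",
                                    "jaki_profile")) {
  name <- match.arg(name)
  file <- c(complementary = "table_complementary.tsv",
            convergent = "table_convergent.tsv",
            vdz_bioflags = "table_vdz_bioflags.tsv",
            vdz_profile = "vdz_profile.tsv",
            jaki_profile = "jaki_profile.tsv")[[name]]
  path <- system.file("extdata", file, package = "moanet")
  if (!nzchar(path)) stop("fixture not found: ", name)
  path
}

#' Read a complementary/convergent mechanism table
#'
#' Parses the table dialect used by the packaged mechanism fixtures:
#' columns `protein`, `motives` (semicolon list), `disease_signs`
#' (semicolon list, one per motive), `mod_a`, `mod_b`, `mod_combo`
#' (modulation under drug A, drug B and the combination; `up`/`down`/`none`
#' or the triangle/hyphen symbols).
#'
#' @param path TSV file path.
#' @return data.frame with list-columns `motives` and `disease_signs` and
#'   integer modulation columns, class `mechanism_table`.
#' @export
read_mechanism_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("protein", "motives", "disease_signs", "mod_a", "mod_b",
            "mod_combo")
  stopifnot(all(need %in% names(df)))
  motives <- lapply(strsplit(as.character(df$motives), ";"),
                    function(x) as.integer(trimws(x)))
  signs <- lapply(strsplit(as.character(df$disease_signs), ";"),
                  function(x) parse_sign(trimws(x)))
  if (any(lengths(motives) != lengths(signs))) {
    stop("per-row motive and disease-sign lists differ in length")
  }
  out <- data.frame(protein = normalize_symbol(df$protein))
  out$motives <- motives
  out$disease_signs <- signs
  out$mod_a <- parse_sign(df$mod_a, allow_zero = TRUE)
  out$mod_b <- parse_sign(df$mod_b, allow_zero = TRUE)
  out$mod_combo <- parse_sign(df$mod_combo, allow_zero = TRUE)
  if (anyDuplicated(out$protein)) stop("duplicate protein in mechanism table")
  class(out) <- c("mechanism_table", "data.frame")
  out
}

#' Replay a mechanism table as characterization plus activity profiles
#'
#' Converts a mechanism table into the inputs of the analysis layer: a
#' disease characterization built from its (protein, motive, disease sign)
#' triples and three synthetic activity profiles (drug A, drug B,
#' combination) obtained by mapping each modulation symbol to a signed
#' activity (`down` -> -magnitude, `up` -> +magnitude, `none` -> 0). The
#' mapping is a replay convention, not a model claim: reverted/convergent
#' classification depends only on signs and the 0.1 activity threshold.
#'
#' @param tbl a `mechanism_table` (or several, row-bound).
#' @param magnitude absolute activity assigned to modulated proteins
#'   (default 0.5).
#' @return list with `chars` and activity profiles `a`, `b`, `ab`.
#' @export
mechanism_table_profiles <- function(tbl, magnitude = 0.5) {
  stopifnot(inherits(tbl, "mechanism_table") || is.data.frame(tbl))
  assignments <- do.call(rbind, lapply(seq_len(nrow(tbl)), function(i) {
    data.frame(protein = tbl$protein[i],
               motive = tbl$motives[[i]],
               disease_sign = tbl$disease_signs[[i]])
  }))
  chars <- disease_characterization(assignments)
  mk <- function(col) {
    activity_profile(setNames(tbl[[col]] * magnitude, tbl$protein),
                     clamped = setNames(rep(FALSE, nrow(tbl)), tbl$protein),
                     converged = TRUE, iterations = 0L)
  }
  list(chars = chars, a = mk("mod_a"), b = mk("mod_b"), ab = mk("mod_combo"))
}

#' Read a bioflag corroboration table
#'
#' Parses the bioflag fixture dialect: columns `uniprot`, `protein`,
#' `bioflag_sign`, `status_single`, `status_combo` with status values in
#' `corroborated`, `antagonised`, `below_threshold`, `blank` (blank = the
#' protein was not included in the published models).
#'
#' @param path TSV file path.
#' @return data.frame with parsed sign column.
#' @export
read_bioflag_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("uniprot", "protein", "bioflag_sign", "status_single",
            "status_combo")
  stopifnot(all(need %in% names(df)))
  df$protein <- normalize_symbol(df$protein)
  df$bioflag_sign <- parse_sign(df$bioflag_sign)
  ok <- c("corroborated", "antagonised", "below_threshold", "blank")
  if (!all(df$status_single %in% ok) || !all(df$status_combo %in% ok)) {
    stop("unknown corroboration status value")
  }
  df
}

# ---- shared I/O helpers -------------------------------------------------

.resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) return(data.frame())
  tryCatch(
    read.delim(text = lines, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
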