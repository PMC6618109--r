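## Reference-sequence registry, named-variant catalogue, species association
## and the local persistence layer.

#' Create a reference-sequence registry
#'
#' @param catalogue optional data.frame with columns `name`, `sequence` and
#'   optionally `clade` / `accession`: the catalogue of canonical named ITS2
#'   variants. Sequences registered later that match a catalogue entry
#'   exactly (full length) inherit its name. `NULL` loads the bundled
#'   synthetic stand-in catalogue; pass `FALSE`-like empty data.frame to
#'   start nameless.
#' @return a [DivRegistry-class].
#' @examples
#' reg <- newDivRegistry(catalogue = data.frame(name = "C3",
#'   sequence = "ACGTACGT", clade = "C"))
#' uid <- registerSequence(reg, "ACGTACGT", "C")
#' nameOf(reg, uid)
#' @export
newDivRegistry <- function(catalogue = NULL) {
  if (is.null(catalogue)) catalogue <- bundledCatalogue()
  env <- new.env(parent = emptyenv())
  env$uid <- integer(0)
  env$sequence <- character(0)
  env$clade <- character(0)
  env$name <- character(0)
  env$accession <- character(0)
  env$by_seq <- new.env(parent = emptyenv())
  env$next_uid <- 1L
  env$clade_cache <- new.env(parent = emptyenv())
  env$cat_name <- setNames(as.character(catalogue$name),
                           as.character(catalogue$sequence))
  env$cat_accession <- if ("accession" %in% names(catalogue))
    setNames(as.character(catalogue$accession),
             as.character(catalogue$sequence)) else character(0)
  new("DivRegistry", env = env)
}

#' Bundled synthetic named-variant catalogue
#'
#' The original named-variant sequences are not published in text form, so
#' the package bundles a synthetic stand-in catalogue (see
#' `inst/extdata/variant_catalogue_synthetic.tsv`): canonical variant names
#' attached to synthetic sequences derived from the bundled synthetic clade
#' references. It exists so that naming, species association and the full
#' pipeline are exercisable end to end.
#'
#' @return data.frame with columns `name`, `sequence`, `clade`.
#' @export
bundledCatalogue <- function() {
  path <- system.file("extdata", "variant_catalogue_synthetic.tsv",
                      package = "divProfiler")
  if (!nzchar(path)) return(data.frame(name = character(0),
                                       sequence = character(0),
                                       clade = character(0)))
  read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled synthetic clade reference sequences
#'
#' One representative sequence per clade A--I, used by the clade screen.
#' Synthetic stand-ins (the published reference FASTA is not reproduced).
#'
#' @return named character vector (names A--I).
#' @export
bundledCladeRefs <- function() {
  path <- system.file("extdata", "clade_refs_synthetic.fasta",
                      package = "divProfiler")
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Bundled species-association rules
#'
#' Species descriptions tied to the canonical ITS2 sequences that
#' characterise them (for example Durusdinium trenchii is characterised by
#' the D1 and D4 sequences). A species is associated with a type profile
#' when all of its required sequence names occur among the profile's DIVs.
#'
#' @return data.frame with columns `species_name`, `required_names`
#'   (comma-separated canonical names).
#' @export
bundledSpeciesRules <- function() {
  path <- system.file("extdata", "species_rules.tsv", package = "divProfiler")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Register a sequence
#'
#' Registration is idempotent: an identical sequence always maps to the same
#' UID. New sequences receive a fresh monotonically increasing UID and, when
#' present in the catalogue, their canonical name. Re-registering a sequence
#' under a different clade is a conflict error (the clade of a reference
#' sequence is immutable).
#'
#' @param registry a [DivRegistry-class].
#' @param sequence uppercase A/C/G/T string.
#' @param clade clade label A--I.
#' @return the integer UID (invisibly identical on re-registration).
#' @export
registerSequence <- function(registry, sequence, clade) {
  stopifnot(is(registry, "DivRegistry"), length(sequence) == 1L)
  .stopifnot_dna(sequence)
  if (!clade %in% LETTERS[1:9]) stop("clade must be one of A-I")
  env <- registry@env
  hit <- env$by_seq[[sequence]]
  if (!is.null(hit)) {
    if (env$clade[hit] != clade)
      stop(sprintf(
        "clade conflict: sequence already registered under clade %s (uid %d)",
        env$clade[hit], env$uid[hit]))
    return(env$uid[hit])
  }
  uid <- env$next_uid
  env$next_uid <- uid + 1L
  i <- length(env$uid) + 1L
  env$uid[i] <- uid
  env$sequence[i] <- sequence
  env$clade[i] <- clade
  nm <- env$cat_name[sequence]
  env$name[i] <- if (!is.na(nm)) unname(nm) else NA_character_
  ac <- if (length(env$cat_accession)) env$cat_accession[sequence] else NA
  env$accession[i] <- if (!is.na(ac)) unname(ac) else NA_character_
  env$by_seq[[sequence]] <- i
  uid
}

#' @describeIn registerSequence number of registered sequences.
#' @export
registrySize <- function(registry) length(registry@env$uid)

#' @describeIn registerSequence nucleotide sequence(s) for UID(s).
#' @param uid integer UID vector.
#' @export
sequenceOf <- function(registry, uid) {
  env <- registry@env
  env$sequence[match(uid, env$uid)]
}

#' @describeIn registerSequence canonical name for UID(s); the UID rendered
#'   as character where unnamed.
#' @export
nameOf <- function(registry, uid) {
  env <- registry@env
  i <- match(uid, env$uid)
  nm <- env$name[i]
  ifelse(is.na(nm), as.character(uid), nm)
}

#' @describeIn registerSequence clade label for UID(s).
#' @export
cladeOf <- function(registry, uid) {
  env <- registry@env
  env$clade[match(uid, env$uid)]
}

#' @describeIn registerSequence UID for exact sequence(s), NA if absent.
#' @export
uidOf <- function(registry, sequence) {
  env <- registry@env
  vapply(sequence, function(s) {
    i <- env$by_seq[[s]]
    if (is.null(i)) NA_integer_ else env$uid[i]
  }, integer(1), USE.NAMES = FALSE)
}

#' @describeIn registerSequence registry contents as a data.frame
#'   (uid, sequence, clade, name, accession).
#' @export
registryTable <- function(registry) {
  env <- registry@env
  data.frame(uid = env$uid, sequence = env$sequence, clade = env$clade,
             name = env$name, accession = env$accession,
             stringsAsFactors = FALSE)
}

setMethod("show", "DivRegistry", function(object) {
  env <- object@env
  cat(sprintf("DivRegistry: %d sequences (%d named), clades: %s\n",
              length(env$uid), sum(!is.na(env$name)),
              paste(sort(unique(env$clade)), collapse = ",")))
})

#' Associate species descriptions with a type profile
#'
#' A species rule matches when every canonical sequence name it requires is
#' found among the profile's (named) DIVs. Unnamed DIVs never match. The
#' association is monotone: adding DIVs to a profile can only add species.
#'
#' @param profile a [TypeProfile-class].
#' @param rules data.frame of rules as from [bundledSpeciesRules()].
#' @param registry the registry used to resolve DIV names.
#' @return character vector of matching species names, in rule order.
#' @export
associateSpecies <- function(profile, rules = bundledSpeciesRules(),
                             registry) {
  div_names <- nameOf(registry, profile@divs)
  keep <- vapply(seq_len(nrow(rules)), function(i) {
    req <- trimws(strsplit(rules$required_names[i], ",", fixed = TRUE)[[1]])
    if (!length(req)) return(FALSE)
    all(req %in% div_names)
  }, logical(1))
  rules$species_name[keep]
}

## ---- local persistence -----------------------------------------------------

.STORE_VERSION <- 1L

#' Persist / load an analysis state
#'
#' A local single-file snapshot standing in for the framework's hosted
#' database: the registry table, clade collections, discovered profiles and
#' assignments are written as one versioned file. The round trip is
#' lossless; a corrupt or version-mismatched store raises an explicit load
#' error and produces no partial state.
#'
#' @param state list with any of `registry` ([DivRegistry-class]),
#'   `collections` (list of [CladeCollection-class]), `profiles` (list of
#'   [TypeProfile-class]), `assignments` (data.frame), `qc` (data.frame),
#'   `analysis_uid` (integer).
#' @param path file path of the store.
#' @return `persistRun` returns `path` invisibly; `loadRun` returns the
#'   state list with the registry reconstructed.
#' @export
persistRun <- function(state, path) {
  reg_tab <- if (!is.null(state$registry)) {
    env <- state$registry@env
    list(table = registryTable(state$registry), next_uid = env$next_uid,
         cat_name = env$cat_name, cat_accession = env$cat_accession)
  }
  payload <- list(
    magic = "divProfiler-store", version = .STORE_VERSION,
    registry = reg_tab,
    collections = state$collections,
    profiles = state$profiles,
    assignments = state$assignments,
    qc = state$qc,
    analysis_uid = state$analysis_uid
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname persistRun
#' @export
loadRun <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt store file: ", conditionMessage(e), call. = FALSE))
  if (!is.list(payload) || !identical(payload$magic, "divProfiler-store"))
    stop("not a divProfiler store file")
  if (!identical(payload$version, .STORE_VERSION))
    stop("store version mismatch: found ", payload$version,
         ", expected ", .STORE_VERSION)
  registry <- NULL
  if (!is.null(payload$registry)) {
    registry <- newDivRegistry(catalogue = data.frame(
      name = character(0), sequence = character(0)))
    env <- registry@env
    tab <- payload$registry$table
    env$uid <- tab$uid
    env$sequence <- tab$sequence
    env$clade <- tab$clade
    env$name <- tab$name
    env$accession <- tab$accession
    env$next_uid <- payload$registry$next_uid
    env$cat_name <- payload$registry$cat_name
    env$cat_accession <- payload$registry$cat_accession
    for (i in seq_along(tab$sequence)) env$by_seq[[tab$sequence[i]]] <- i
  }
  list(registry = registry, collections = payload$collections,
       profiles = payload$profiles, assignments = payload$assignments,
       qc = payload$qc, analysis_uid = payload$analysis_uid)
}
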