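## Central S4 containers.

#' Analysis configuration
#'
#' Holds every numeric threshold of the pipeline. Defaults are the published
#' quality-control parameters (maximum ambiguous bases 0, maximum homopolymer
#' 5, abundance cutoff "> 2", two primer mismatches allowed on either end,
#' 184--310 bp length window, 200-sequence minimum for a searchable clade
#' collection, 3% OTU dissimilarity cutoff) plus the package's own documented
#' choices where the method leaves a value open (minimum profile support 3,
#' footprint relative-abundance cutoff 0.01, column-entropy threshold 0.10
#' bits, 30 bp minimum read-pair overlap, 80% identity/coverage for the clade
#' screen).
#'
#' @slot maxambig maximum ambiguous (non-ACGT) bases tolerated per contig.
#' @slot maxhomop maximum homopolymer run length tolerated.
#' @slot abund_cutoff sequences kept only when per-sample abundance is
#'   strictly greater than this.
#' @slot pdiffs,rdiffs mismatches allowed in the forward / reverse primer.
#' @slot minlength,maxlength inclusive length window after primer trimming.
#' @slot min_collection_size a clade collection is searchable only when its
#'   total abundance is strictly greater than this.
#' @slot footprint_rel_cutoff minimum within-collection relative abundance
#'   for a sequence to enter the collection's footprint.
#' @slot min_support minimum number of supporting collections for a
#'   discovered profile.
#' @slot range_tolerance fractional widening applied to characterised DIV
#'   abundance ranges.
#' @slot otu_cutoff OTU clustering dissimilarity cutoff.
#' @slot entropy_threshold column entropy (bits) above which decomposition
#'   keeps splitting.
#' @slot min_overlap minimum read-pair overlap (bp).
#' @slot id_min,cov_min identity and query-coverage thresholds of the clade
#'   screen.
#' @slot fwd_primer,rev_primer amplicon primers, 5'->3', IUPAC codes allowed.
#' @slot bootstrap_reps bootstrap replicates for consensus trees.
#' @slot rng_seed seed used by stochastic steps.
#' @export
setClass("DivConfig", representation(
  maxambig = "integer", maxhomop = "integer", abund_cutoff = "integer",
  pdiffs = "integer", rdiffs = "integer",
  minlength = "integer", maxlength = "integer",
  min_collection_size = "integer",
  footprint_rel_cutoff = "numeric", min_support = "integer",
  range_tolerance = "numeric", otu_cutoff = "numeric",
  entropy_threshold = "numeric", min_overlap = "integer",
  id_min = "numeric", cov_min = "numeric",
  fwd_primer = "character", rev_primer = "character",
  bootstrap_reps = "integer", rng_seed = "integer"
))

setValidity("DivConfig", function(object) {
  msg <- character(0)
  fr <- c(footprint_rel_cutoff = object@footprint_rel_cutoff,
          range_tolerance = object@range_tolerance,
          otu_cutoff = object@otu_cutoff,
          id_min = object@id_min, cov_min = object@cov_min)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "all fractional thresholds must lie in [0, 1]")
  if (object@minlength > object@maxlength)
    msg <- c(msg, "minlength must be <= maxlength")
  if (length(msg)) msg else TRUE
})

#' Create an analysis configuration
#'
#' @param ... named overrides for any [DivConfig-class] slot.
#' @return a validated `DivConfig`.
#' @examples
#' cfg <- divConfig(min_support = 4L)
#' cfg@min_support
#' @export
divConfig <- function(...) {
  defaults <- list(
    maxambig = 0L, maxhomop = 5L, abund_cutoff = 2L,
    pdiffs = 2L, rdiffs = 2L, minlength = 184L, maxlength = 310L,
    min_collection_size = 200L, footprint_rel_cutoff = 0.01,
    min_support = 3L, range_tolerance = 0, otu_cutoff = 0.03,
    entropy_threshold = 0.10, min_overlap = 30L,
    id_min = 0.8, cov_min = 0.8,
    fwd_primer = "GAATTGCAGAACTCCGTGAACC",
    rev_primer = "CGGGTTCWCTTGTYTGACTTCATGC",
    bootstrap_reps = 100L, rng_seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  defaults[names(dots)] <- dots
  int_slots <- c("maxambig", "maxhomop", "abund_cutoff", "pdiffs", "rdiffs",
                 "minlength", "maxlength", "min_collection_size",
                 "min_support", "min_overlap", "bootstrap_reps", "rng_seed")
  for (s in int_slots) defaults[[s]] <- as.integer(defaults[[s]])
  do.call(new, c("DivConfig", defaults))
}

#' Reference-sequence registry
#'
#' A registry of unique post-QC nucleotide sequences. Each distinct sequence
#' receives a stable integer UID at first registration; a sequence carries an
#' immutable clade label (A--I) and, when it matches the bundled catalogue of
#' named variants exactly, its canonical name (for example "C3"). The
#' registry has reference semantics (it wraps an environment) because it is
#' shared and appended to throughout a pipeline run.
#'
#' @slot env environment holding the registry tables.
#' @seealso [newDivRegistry()], [registerSequence()]
#' @export
setClass("DivRegistry", representation(env = "environment"))

#' Per-sample, per-clade collection of post-QC sequences
#'
#' The searchable unit of the analysis: all of one sample's post-QC sequences
#' belonging to one clade, stored as counts per registry UID. A collection is
#' searchable only when its total abundance strictly exceeds the configured
#' minimum (200 by default), which guards the profile search against
#' sequencing-depth artefacts.
#'
#' @slot sample_id sample identifier.
#' @slot clade clade label, one of A--I.
#' @slot abundances integer counts named by registry UID.
#' @slot total sum of the counts.
#' @slot searchable whether `total` exceeds the configured minimum.
#' @export
setClass("CladeCollection", representation(
  sample_id = "character", clade = "character",
  abundances = "numeric", total = "numeric", searchable = "logical"
))

setValidity("CladeCollection", function(object) {
  msg <- character(0)
  if (!object@clade %in% LETTERS[1:9])
    msg <- c(msg, "clade must be one of A-I")
  if (is.null(names(object@abundances)) ||
      anyDuplicated(names(object@abundances)))
    msg <- c(msg, "abundances must be uniquely named by UID")
  if (length(object@abundances) && any(object@abundances <= 0))
    msg <- c(msg, "abundances must be positive")
  if (!isTRUE(all.equal(object@total, sum(object@abundances))))
    msg <- c(msg, "total must equal the sum of abundances")
  if (length(msg)) msg else TRUE
})

#' Construct a clade collection
#'
#' @param sample_id sample identifier.
#' @param clade clade label (A--I).
#' @param abundances positive counts named by registry UID.
#' @param min_collection_size searchability threshold (strict: searchable iff
#'   total is greater than this).
#' @return a [CladeCollection-class].
#' @export
cladeCollection <- function(sample_id, clade, abundances,
                            min_collection_size = 200L) {
  total <- sum(abundances)
  new("CladeCollection", sample_id = sample_id, clade = clade,
      abundances = abundances, total = total,
      searchable = total > min_collection_size)
}

#' @describeIn cladeCollection collection identifier (`sample|clade`).
#' @param cc a `CladeCollection`.
#' @export
ccId <- function(cc) paste(cc@sample_id, cc@clade, sep = "|")

setMethod("show", "CladeCollection", function(object) {
  cat(sprintf("CladeCollection %s: clade %s, %d sequences, total %d (%s)\n",
              object@sample_id, object@clade, length(object@abundances),
              as.integer(object@total),
              if (object@searchable) "searchable" else "not searchable"))
})

#' ITS2 type profile
#'
#' The taxonomic unit: an ordered set of defining intragenomic variants
#' (DIVs) together with the relative-abundance range each DIV occupied in the
#' samples supporting the profile. `majority_set` records which DIVs were the
#' most abundant sequence in at least one supporting sample (a profile whose
#' supporters disagree on the most abundant DIV is a "comajority" profile,
#' written with "/" in its name).
#'
#' @slot uid integer profile identifier.
#' @slot clade clade label.
#' @slot divs DIV UIDs in decreasing order of mean relative abundance.
#' @slot means mean relative abundance per DIV (same order as `divs`).
#' @slot ranges 2 x n matrix (rows `min`, `max`) of relative-abundance
#'   ranges; columns named by DIV UID.
#' @slot majority_set UIDs observed as the most abundant DIV in at least one
#'   supporter.
#' @slot support identifiers of the supporting clade collections.
#' @slot name profile name in the DIV naming grammar.
#' @slot fallback TRUE for single-DIV profiles created when no discovered
#'   profile matched a sample.
#' @export
setClass("TypeProfile", representation(
  uid = "integer", clade = "character", divs = "integer", means = "numeric",
  ranges = "matrix", majority_set = "integer", support = "character",
  name = "character", fallback = "logical"
))

setValidity("TypeProfile", function(object) {
  msg <- character(0)
  if (!all(object@majority_set %in% object@divs))
    msg <- c(msg, "majority_set must be a subset of divs")
  if (length(object@divs)) {
    rg <- object@ranges
    if (!identical(rownames(rg), c("min", "max")) ||
        ncol(rg) != length(object@divs))
      msg <- c(msg, "ranges must be a 2 x n_div matrix with rows min/max")
    else if (any(rg < 0) || any(rg > 1) || any(rg["min", ] > rg["max", ]))
      msg <- c(msg, "ranges must satisfy 0 <= min <= max <= 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TypeProfile", function(object) {
  cat(sprintf("TypeProfile %d [%s] clade %s: %d DIV(s), %d supporter(s)%s\n",
              object@uid, object@name, object@clade, length(object@divs),
              length(object@support),
              if (object@fallback) " (fallback)" else ""))
})

#' Synthetic Symbiodiniaceae genotype
#'
#' A simulated genome's ITS2 complement: a small set of intragenomic variant
#' sequences (a base sequence plus variants within a few substitutions of it)
#' and the fixed proportion at which each variant occurs among the genome's
#' rDNA copies.
#'
#' @slot name genotype label.
#' @slot clade clade label.
#' @slot variants variant sequences (unique).
#' @slot proportions per-variant proportions, summing to 1.
#' @export
setClass("SyntheticGenotype", representation(
  name = "character", clade = "character",
  variants = "character", proportions = "numeric"
))

setValidity("SyntheticGenotype", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@variants)) msg <- c(msg, "variants must be unique")
  if (length(object@variants) != length(object@proportions))
    msg <- c(msg, "one proportion per variant required")
  if (!isTRUE(all.equal(sum(object@proportions), 1)))
    msg <- c(msg, "proportions must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticGenotype", function(object) {
  cat(sprintf("SyntheticGenotype %s (clade %s): %d variants, proportions %s\n",
              object@name, object@clade, length(object@variants),
              paste(signif(object@proportions, 3), collapse = "/")))
})
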