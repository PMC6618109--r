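## Profile engine: footprint extraction, discovery of re-occurring DIV sets,
## multimodal splitting, profile characterisation, assignment, naming and
## genus re-merging.

#' Extract a clade collection's footprint
#'
#' The footprint is the subset of a searchable collection's sequences whose
#' within-collection relative abundance reaches `footprint_rel_cutoff`; it
#' is the unit searched for re-occurring DIV sets.
#'
#' @param cc a searchable [CladeCollection-class].
#' @param footprint_rel_cutoff relative-abundance cutoff.
#' @return list of class `Footprint` with `clade`, `members` (integer UIDs,
#'   sorted), `rel` (relative abundances named by UID over all members of
#'   the collection) and `source` (collection id).
#' @export
extractFootprint <- function(cc, footprint_rel_cutoff = 0.01) {
  if (!cc@searchable)
    stop("collection ", ccId(cc), " is not searchable (total <= minimum)")
  rel <- cc@abundances / cc@total
  members <- sort(as.integer(names(rel)[rel >= footprint_rel_cutoff]))
  structure(list(clade = cc@clade, members = members, rel = rel,
                 source = ccId(cc)), class = "Footprint")
}

# set key helpers -------------------------------------------------------------
.set_key <- function(uids) paste(sort(uids), collapse = ",")
.key_set <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

# Intersection closure of a list of integer sets. Any maximal set supported
# by a group of footprints is the intersection of their member sets, so the
# closure contains every candidate the exhaustive search could return.
.intersection_closure <- function(sets, max_sets = 5000L) {
  keys <- new.env(parent = emptyenv())
  pool <- list()
  add <- function(s) {
    if (!length(s)) return(FALSE)
    k <- .set_key(s)
    if (!is.null(keys[[k]])) return(FALSE)
    keys[[k]] <- TRUE
    pool[[length(pool) + 1L]] <<- sort(s)
    TRUE
  }
  for (s in sets) add(s)
  frontier <- seq_along(pool)
  while (length(frontier) && length(pool) < max_sets) {
    new_frontier <- integer(0)
    n_before <- length(pool)
    for (i in frontier) {
      for (j in seq_len(length(pool))) {
        if (j == i) next
        inter <- intersect(pool[[i]], pool[[j]])
        if (add(inter)) new_frontier <- c(new_frontier, length(pool))
        if (length(pool) >= max_sets) break
      }
      if (length(pool) >= max_sets) break
    }
    frontier <- new_frontier[new_frontier > n_before]
  }
  pool
}

#' Discover candidate profiles from footprints
#'
#' Greedy largest-first search for re-occurring sequence sets: repeatedly
#' select the largest member set that is contained in the footprints of at
#' least `min_support` not-yet-explained collections, mark those collections
#' explained, and continue until no further supported set exists. Ties are
#' broken deterministically: larger cardinality, then more supporters, then
#' higher summed member abundance across supporters, then lexicographically
#' smaller sorted UID list. Candidate member sets are drawn from the
#' intersection closure of the footprints, which contains every set the
#' exhaustive subset enumeration could select.
#'
#' @param footprints list of footprints (all one clade), from
#'   [extractFootprint()].
#' @param min_support minimum number of supporting collections.
#' @return list of candidates, each a list with `members` (sorted UIDs),
#'   `supporting` (collection ids explained by this candidate), and
#'   `abundance` (supporters x members relative-abundance matrix).
#' @export
discoverCandidateProfiles <- function(footprints, min_support = 3L) {
  if (!length(footprints)) return(list())
  if (length(unique(vapply(footprints, `[[`, character(1), "clade"))) != 1L)
    stop("footprints must all belong to one clade")
  pool <- .intersection_closure(lapply(footprints, `[[`, "members"))
  unexplained <- rep(TRUE, length(footprints))
  fp_members <- lapply(footprints, `[[`, "members")
  candidates <- list()
  repeat {
    best <- NULL
    for (s in pool) {
      sup <- which(unexplained & vapply(fp_members, function(m)
        all(s %in% m), logical(1)))
      if (length(sup) < min_support) next
      ab_sum <- sum(vapply(sup, function(i)
        sum(footprints[[i]]$rel[as.character(s)]), numeric(1)))
      cand <- list(members = s, sup = sup, n = length(sup), ab = ab_sum)
      if (is.null(best)) { best <- cand; next }
      better <- FALSE
      if (length(s) != length(best$members)) {
        better <- length(s) > length(best$members)
      } else if (cand$n != best$n) {
        better <- cand$n > best$n
      } else if (!isTRUE(all.equal(cand$ab, best$ab))) {
        better <- cand$ab > best$ab
      } else {
        better <- .lex_cmp(s, best$members) < 0
      }
      if (better) best <- cand
    }
    if (is.null(best)) break
    A <- do.call(rbind, lapply(best$sup, function(i)
      footprints[[i]]$rel[as.character(best$members)]))
    rownames(A) <- vapply(footprints[best$sup], `[[`, character(1), "source")
    colnames(A) <- as.character(best$members)
    candidates[[length(candidates) + 1L]] <- list(
      members = best$members,
      supporting = rownames(A),
      abundance = A)
    unexplained[best$sup] <- FALSE
  }
  candidates
}

# Kernel-density multimodality check on a vector of relative abundances.
# Returns NULL (unimodal) or the x-positions of the two dominant modes.
.find_modes <- function(x, valley_frac = 0.85, min_separation = 0.05) {
  if (length(x) < 4L || diff(range(x)) < min_separation) return(NULL)
  d <- tryCatch(stats::density(x, bw = "nrd0"), error = function(e) NULL)
  if (is.null(d)) return(NULL)
  y <- d$y
  n <- length(y)
  is_max <- c(y[1] > y[2], y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], y[n] > y[n - 1])
  peaks <- which(is_max)
  if (length(peaks) < 2L) return(NULL)
  top <- peaks[order(-y[peaks])][1:2]
  top <- sort(top)
  if (abs(d$x[top[2]] - d$x[top[1]]) < min_separation) return(NULL)
  valley <- min(y[top[1]:top[2]])
  if (valley < valley_frac * min(y[top])) d$x[top] else NULL
}

#' Split a candidate on multimodal DIV abundances
#'
#' Each member's relative-abundance distribution across supporters is tested
#' for multimodality (Gaussian kernel density, Silverman bandwidth; two or
#' more local maxima whose deepest intervening valley is below 85% of the
#' lower maximum). Modes closer together than `min_separation` (relative
#' abundance) are not treated as distinct: the method looks for "distinctly
#' different" abundances, and sequencing-depth noise alone can produce
#' narrowly separated density maxima. On a detection, supporters are
#' partitioned by nearest
#' mode and each part re-tested recursively until every member is unimodal.
#' A split any of whose children would fall below `min_support` supporters
#' is not retained. Distinct children keep identical member sets, so
#' profiles sharing DIVs but differing in abundance are realisable.
#'
#' @param candidate a candidate from [discoverCandidateProfiles()].
#' @param min_support minimum supporters per retained child.
#' @param min_separation minimum distance between modes (relative
#'   abundance) for a split.
#' @return list of candidates (length 1 when no split is retained).
#' @export
splitMultimodal <- function(candidate, min_support = 3L,
                            min_separation = 0.05) {
  A <- candidate$abundance
  for (j in seq_len(ncol(A))) {
    modes <- .find_modes(A[, j], min_separation = min_separation)
    if (is.null(modes)) next
    part <- abs(A[, j] - modes[1]) <= abs(A[, j] - modes[2])
    if (sum(part) < min_support || sum(!part) < min_support) next
    children <- lapply(list(which(part), which(!part)), function(rows) {
      list(members = candidate$members,
           supporting = candidate$supporting[rows],
           abundance = A[rows, , drop = FALSE])
    })
    return(c(splitMultimodal(children[[1]], min_support, min_separation),
             splitMultimodal(children[[2]], min_support, min_separation)))
  }
  list(candidate)
}

#' Characterise a candidate as a type profile
#'
#' DIVs are ordered by decreasing mean relative abundance across supporters
#' (ties by lower UID); each DIV's range is its observed minimum/maximum,
#' widened by `range_tolerance` and clamped to [0, 1]; the majority set
#' collects the DIVs observed as the most abundant member in at least one
#' supporter.
#'
#' @param candidate candidate with an `abundance` matrix.
#' @param clade clade label.
#' @param uid profile UID to assign.
#' @param registry registry for naming.
#' @param range_tolerance fractional widening of the ranges.
#' @param fallback flag the profile as a fallback profile.
#' @return a [TypeProfile-class].
#' @export
characterizeProfile <- function(candidate, clade, uid, registry,
                                range_tolerance = 0, fallback = FALSE) {
  A <- candidate$abundance
  uids <- as.integer(colnames(A))
  means <- colMeans(A)
  ord <- order(-means, uids)
  uids <- uids[ord]; means <- means[ord]
  A <- A[, ord, drop = FALSE]
  rg <- rbind(min = pmax(0, apply(A, 2L, min) - range_tolerance),
              max = pmin(1, apply(A, 2L, max) + range_tolerance))
  colnames(rg) <- as.character(uids)
  maj <- sort(unique(uids[apply(A, 1L, which.max)]))
  p <- new("TypeProfile", uid = as.integer(uid), clade = clade,
           divs = uids, means = unname(means), ranges = rg,
           majority_set = maj, support = candidate$supporting,
           name = "", fallback = fallback)
  p@name <- nameProfile(p, registry)
  p
}

#' Name a type profile
#'
#' Majority-set DIVs come first, joined by "/" (comajority), remaining DIVs
#' follow joined by "-"; within each block DIVs appear in decreasing mean
#' abundance. Unnamed DIVs are rendered as their UID.
#'
#' @param profile a [TypeProfile-class].
#' @param registry registry resolving DIV names.
#' @return the profile name string.
#' @export
nameProfile <- function(profile, registry) {
  labs <- nameOf(registry, profile@divs)
  in_maj <- profile@divs %in% profile@majority_set
  maj <- paste(labs[in_maj], collapse = "/")
  rest <- labs[!in_maj]
  if (length(rest)) paste(c(maj, rest), collapse = "-") else maj
}

#' @describeIn nameProfile parse a profile name back into its ordered DIV
#'   names and majority set.
#' @param name profile name string.
#' @export
parseProfileName <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  maj <- strsplit(parts[1], "/", fixed = TRUE)[[1]]
  list(divs = c(maj, parts[-1]), majority = maj)
}

#' Match discovered profiles against a clade collection
#'
#' A profile matches when every DIV is present in the collection and each
#' DIV's relative abundance lies within the profile's characterised range.
#' Overlapping matches (shared DIVs) are resolved to a single profile per
#' overlap component by [resolveOverlaps()]. Multiple disjoint same-clade
#' profiles are retained only when each has been found as the sole profile
#' in another sample (`standalone_uids`); when none of the disjoint matches
#' is standalone-validated the strongest match by summed DIV abundance is
#' kept conservatively.
#'
#' @param cc a [CladeCollection-class].
#' @param profiles list of [TypeProfile-class] of the same clade.
#' @param standalone_uids UIDs validated as sole profile of some sample;
#'   NULL treats every profile as validated.
#' @return data.frame with columns `profile_uid` and `rel_abundance` (sum of
#'   DIV counts divided by the collection total).
#' @export
assignProfiles <- function(cc, profiles, standalone_uids = NULL) {
  rel <- cc@abundances / cc@total
  matches <- Filter(function(p) {
    if (p@clade != cc@clade) return(FALSE)
    ids <- as.character(p@divs)
    if (!all(ids %in% names(rel))) return(FALSE)
    all(rel[ids] >= p@ranges["min", ids] - 1e-12 &
          rel[ids] <= p@ranges["max", ids] + 1e-12)
  }, profiles)
  if (!length(matches))
    return(data.frame(profile_uid = integer(0), rel_abundance = numeric(0)))
  # resolve overlap components to single winners
  n <- length(matches)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- i != j &&
      length(intersect(matches[[i]]@divs, matches[[j]]@divs)) > 0
  comp <- .components(adj | diag(TRUE, n))
  winners <- lapply(unique(comp), function(k)
    resolveOverlaps(matches[comp == k], cc))
  if (length(winners) > 1L && !is.null(standalone_uids)) {
    ok <- vapply(winners, function(p) p@uid %in% standalone_uids, logical(1))
    # several disjoint profiles stand only if each is standalone-validated;
    # otherwise assign the single strongest match conservatively
    if (!all(ok)) winners <- list(resolveOverlaps(winners, cc))
  }
  data.frame(
    profile_uid = vapply(winners, slot, integer(1), "uid"),
    rel_abundance = vapply(winners, function(p)
      sum(cc@abundances[as.character(p@divs)]) / cc@total, numeric(1)))
}

#' Resolve overlapping profile matches
#'
#' Among matching profiles that share DIVs, the profile containing the
#' greatest summed DIV relative abundance in the sample wins; ties prefer
#' more DIVs, then the lower profile UID.
#'
#' @param profiles list of matching [TypeProfile-class].
#' @param cc the [CladeCollection-class] being assigned.
#' @return the single chosen profile.
#' @export
resolveOverlaps <- function(profiles, cc) {
  rel <- cc@abundances / cc@total
  score <- vapply(profiles, function(p)
    sum(rel[as.character(p@divs)], na.rm = TRUE), numeric(1))
  ndiv <- vapply(profiles, function(p) length(p@divs), numeric(1))
  uid <- vapply(profiles, slot, integer(1), "uid")
  profiles[[order(-score, -ndiv, uid)[1L]]]
}

#' Fallback assignment by most abundant sequence
#'
#' When no discovered profile matches a searchable collection, the
#' collection is conservatively assigned a profile defined simply by its
#' most abundant sequence (ties broken by lower UID). An existing fallback
#' profile for that sequence is reused; otherwise one is created with the
#' permissive range [0, 1].
#'
#' @param cc the unmatched [CladeCollection-class].
#' @param profiles existing profiles (searched for a reusable fallback).
#' @param registry registry for naming.
#' @param next_uid UID for a newly created profile.
#' @return the (possibly new) fallback [TypeProfile-class].
#' @export
fallbackAssign <- function(cc, profiles, registry, next_uid) {
  ab <- cc@abundances
  uids <- as.integer(names(ab))
  top <- uids[order(-ab, uids)][1L]
  for (p in profiles) {
    if (p@fallback && p@clade == cc@clade && identical(p@divs, top)) {
      p@support <- union(p@support, ccId(cc))
      return(p)
    }
  }
  rg <- matrix(c(0, 1), nrow = 2, dimnames = list(c("min", "max"),
                                                  as.character(top)))
  p <- new("TypeProfile", uid = as.integer(next_uid), clade = cc@clade,
           divs = top, means = unname(ab[as.character(top)] / cc@total),
           ranges = rg, majority_set = top, support = ccId(cc),
           name = "", fallback = TRUE)
  p@name <- nameProfile(p, registry)
  p
}

#' Flag putative super types
#'
#' An artefactual profile merging two co-occurring taxa's sequence
#' radiations betrays itself by a disconnected DIV similarity graph: DIVs
#' are joined when their sequences are within `max_nt` edits, and a profile
#' whose graph has two or more connected components is flagged (a warning,
#' never an automatic split).
#'
#' @param profile a [TypeProfile-class] with at least 2 DIVs.
#' @param registry registry resolving DIV sequences.
#' @param max_nt edit-distance threshold for graph edges.
#' @return list with `pass` (logical) and `components` (component index per
#'   DIV); emits a warning when `pass` is FALSE.
#' @export
flagSuperTypes <- function(profile, registry, max_nt = 3L) {
  if (length(profile@divs) < 2L)
    return(list(pass = TRUE, components = rep(1L, length(profile@divs))))
  seqs <- sequenceOf(registry, profile@divs)
  d <- adist(seqs)
  adj <- d <= max_nt
  comp <- .components(adj)
  pass <- max(comp) == 1L
  if (!pass)
    warning(sprintf(
      "profile %s: DIVs form %d disconnected radiations (possible super type)",
      profile@name, max(comp)), call. = FALSE)
  list(pass = pass, components = comp)
}

#' Re-merge genus-separated assignments for a sample
#'
#' Within-clade profile abundances are adjusted relative to the sample's
#' pre-separation clade proportions. With `normalise = TRUE` (default) each
#' clade's assignment abundances are first rescaled to sum to one, so that a
#' fully assigned sample's merged abundances sum to exactly 1; with
#' `normalise = FALSE` the raw within-clade abundances are scaled by the
#' clade fraction directly (sums are then <= 1).
#'
#' @param assignments_by_clade named list (by clade) of data.frames with
#'   `profile_uid`, `rel_abundance`.
#' @param clade_totals named numeric of per-clade read totals.
#' @param sample_total total reads of the sample across clades.
#' @param normalise rescale within-clade abundances to sum to 1 first.
#' @return data.frame with `profile_uid`, `rel_abundance` (fractions of the
#'   whole sample).
#' @export
mergeGenusOutputs <- function(assignments_by_clade, clade_totals,
                              sample_total = sum(clade_totals),
                              normalise = TRUE) {
  if (sum(clade_totals) > sample_total + 1e-9)
    stop("clade totals exceed the sample total")
  out <- list()
  for (cl in names(assignments_by_clade)) {
    a <- assignments_by_clade[[cl]]
    if (!nrow(a)) next
    w <- a$rel_abundance
    if (normalise && sum(w) > 0) w <- w / sum(w)
    out[[cl]] <- data.frame(profile_uid = a$profile_uid,
                            rel_abundance = w * clade_totals[[cl]] /
                              sample_total)
  }
  if (!length(out))
    return(data.frame(profile_uid = integer(0), rel_abundance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run a full profile analysis
#'
#' Orchestrates the profile engine over a set of clade collections:
#' footprint extraction per clade, greedy discovery of re-occurring DIV
#' sets (profiles carried over from `prior_profiles` are retained as
#' candidate sets and re-supported), supporter expansion to every collection
#' whose footprint contains the member set, multimodal splitting, profile
#' characterisation, range-checked assignment with standalone validation of
#' multi-profile samples, fallback assignment for unmatched collections,
#' and genus re-merging of the per-sample output abundances.
#'
#' @param collections list of [CladeCollection-class] (all samples).
#' @param registry a [DivRegistry-class].
#' @param config a [DivConfig-class].
#' @param prior_profiles profiles from an earlier analysis to retain.
#' @return list with `profiles` (list of [TypeProfile-class]),
#'   `assignments` (data.frame: sample_id, clade, profile_uid, profile_name,
#'   within-clade and merged relative abundance), `within_clade` (the
#'   pre-merge assignment tables) and `footprints`.
#' @export
runAnalysis <- function(collections, registry, config = divConfig(),
                        prior_profiles = list()) {
  searchable <- Filter(function(cc) cc@searchable, collections)
  clades <- sort(unique(vapply(searchable, slot, character(1), "clade")))
  profiles <- list()
  next_uid <- if (length(prior_profiles))
    max(vapply(prior_profiles, slot, integer(1), "uid")) + 1L else 1L

  footprints_all <- list()
  for (cl in clades) {
    ccs <- Filter(function(cc) cc@clade == cl, searchable)
    fps <- lapply(ccs, extractFootprint, config@footprint_rel_cutoff)
    footprints_all[[cl]] <- fps
    cands <- discoverCandidateProfiles(fps, config@min_support)
    member_sets <- lapply(cands, `[[`, "members")
    # retain prior profiles of this clade as candidate sets
    for (p in prior_profiles) {
      if (p@clade != cl || p@fallback) next
      if (!any(vapply(member_sets, function(m)
        identical(m, sort(p@divs)), logical(1))))
        member_sets <- c(member_sets, list(sort(p@divs)))
    }
    # expand supporters to every collection containing the member set
    expanded <- list()
    for (m in member_sets) {
      sup <- which(vapply(fps, function(fp) all(m %in% fp$members),
                          logical(1)))
      if (!length(sup)) next
      A <- do.call(rbind, lapply(sup, function(i)
        fps[[i]]$rel[as.character(m)]))
      rownames(A) <- vapply(fps[sup], `[[`, character(1), "source")
      colnames(A) <- as.character(m)
      expanded[[.set_key(m)]] <- list(members = m,
                                      supporting = rownames(A),
                                      abundance = A)
    }
    # multimodal splitting, then characterisation
    for (cand in expanded) {
      for (child in splitMultimodal(cand, config@min_support)) {
        p <- characterizeProfile(child, cl, next_uid, registry,
                                 config@range_tolerance)
        next_uid <- next_uid + 1L
        profiles[[length(profiles) + 1L]] <- p
      }
    }
  }

  # assignment: first pass to find standalone-validated profiles
  first_pass <- lapply(searchable, function(cc)
    assignProfiles(cc, profiles, standalone_uids = NULL))
  standalone <- unique(unlist(lapply(first_pass, function(a)
    if (nrow(a) == 1L) a$profile_uid)))

  within <- list()
  for (k in seq_along(searchable)) {
    cc <- searchable[[k]]
    a <- assignProfiles(cc, profiles, standalone_uids = standalone)
    if (!nrow(a)) {
      fb <- fallbackAssign(cc, profiles, registry, next_uid)
      if (!any(vapply(profiles, function(p) p@uid == fb@uid, logical(1)))) {
        next_uid <- next_uid + 1L
        profiles[[length(profiles) + 1L]] <- fb
      } else {
        profiles[[which(vapply(profiles, function(p) p@uid == fb@uid,
                               logical(1)))]] <- fb
      }
      a <- data.frame(profile_uid = fb@uid,
                      rel_abundance = sum(cc@abundances[
                        as.character(fb@divs)]) / cc@total)
    }
    within[[ccId(cc)]] <- cbind(sample_id = cc@sample_id, clade = cc@clade,
                                a)
  }

  # merge per sample across clades (unsearchable collections contribute to
  # the clade totals but receive no profile)
  sample_ids <- unique(vapply(collections, slot, character(1), "sample_id"))
  rows <- list()
  for (sid in sample_ids) {
    ccs <- Filter(function(cc) cc@sample_id == sid, collections)
    totals <- vapply(ccs, slot, numeric(1), "total")
    names(totals) <- vapply(ccs, slot, character(1), "clade")
    by_clade <- list()
    for (cc in ccs) {
      w <- within[[ccId(cc)]]
      if (!is.null(w))
        by_clade[[cc@clade]] <- w[, c("profile_uid", "rel_abundance")]
    }
    if (!length(by_clade)) next
    merged <- mergeGenusOutputs(by_clade, totals[names(by_clade)],
                                sum(totals))
    if (!nrow(merged)) next
    cl_of <- setNames(
      rep(names(by_clade), vapply(by_clade, nrow, integer(1))), NULL)
    rows[[sid]] <- data.frame(sample_id = sid, clade = cl_of,
                              profile_uid = merged$profile_uid,
                              rel_abundance = merged$rel_abundance)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), clade = character(0),
               profile_uid = integer(0), rel_abundance = numeric(0))
  rownames(assignments) <- NULL
  uid_map <- vapply(profiles, slot, integer(1), "uid")
  assignments$profile_name <- vapply(assignments$profile_uid, function(u)
    profiles[[match(u, uid_map)]]@name, character(1))
  names(profiles) <- as.character(uid_map)
  list(profiles = profiles, assignments = assignments,
       within_clade = within, footprints = footprints_all)
}
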