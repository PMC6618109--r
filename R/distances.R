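## Alignment, p-distances, NJ/bootstrap/consensus trees, Bray-Curtis and
## weighted UniFrac distances, and principal coordinate analysis.

#' Multiple sequence alignment (center-star)
#'
#' Internal aligner for within-clade ITS2 sequences: every sequence is
#' globally aligned (match +1, mismatch -1, gap -2) to the first sequence
#' (callers pass sequences in decreasing abundance order, so the center is
#' the most abundant), and the pairwise alignments are merged by the
#' center-star construction ("once a gap, always a gap"). Ungapping any row
#' recovers the corresponding input exactly.
#'
#' @param sequences character vector (>= 1), same clade.
#' @return named character vector of aligned rows (equal lengths); names are
#'   the input names, or the sequences themselves when unnamed.
#' @export
alignSequences <- function(sequences) {
  if (!length(sequences)) stop("no sequences to align")
  nm <- if (is.null(names(sequences))) sequences else names(sequences)
  if (length(sequences) == 1L) return(setNames(sequences, nm))
  center <- sequences[[1L]]
  n <- nchar(center)
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  aligned_center <- vector("list", length(sequences))
  aligned_row <- vector("list", length(sequences))
  ins <- matrix(0L, nrow = length(sequences), ncol = n + 1L)
  for (i in seq_along(sequences)[-1L]) {
    if (sequences[[i]] == center) {
      aligned_center[[i]] <- center; aligned_row[[i]] <- center
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      sequences[[i]], center, type = "global",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
    ac <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ar <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    aligned_center[[i]] <- ac; aligned_row[[i]] <- ar
    pos <- 0L
    for (k in seq_along(ac)) {
      if (ac[k] == "-") ins[i, pos + 1L] <- ins[i, pos + 1L] + 1L
      else pos <- pos + 1L
    }
  }
  master <- apply(ins, 2L, max)
  build_row <- function(ac, ar) {
    # walk the pairwise alignment, padding up to the master gap profile
    out <- character(0)
    pos <- 0L; k <- 1L; pending <- 0L
    flush <- function(out, pending, pos) {
      c(out, rep("-", master[pos + 1L] - pending))
    }
    while (k <= length(ac)) {
      if (ac[k] == "-") {
        out <- c(out, ar[k]); pending <- pending + 1L
      } else {
        out <- flush(out, pending, pos)
        pending <- 0L
        out <- c(out, ar[k])
        pos <- pos + 1L
      }
      k <- k + 1L
    }
    out <- flush(out, pending, pos)
    paste(out, collapse = "")
  }
  rows <- character(length(sequences))
  center_chars <- strsplit(center, "")[[1]]
  rows[1L] <- build_row(center_chars, center_chars)
  for (i in seq_along(sequences)[-1L]) {
    ac <- aligned_center[[i]]; ar <- aligned_row[[i]]
    if (is.character(ac) && length(ac) == 1L) {  # identical to center
      ac <- strsplit(ac, "")[[1]]; ar <- strsplit(ar, "")[[1]]
    }
    rows[i] <- build_row(ac, ar)
  }
  setNames(rows, nm)
}

#' Pairwise p-distances from an alignment
#'
#' Uncorrected proportion of differing positions per pair. With
#' `ignore_terminal_gaps` (the `countends = F` behaviour), positions falling
#' in either sequence's terminal gap runs are excluded from numerator and
#' denominator. Positions where both sequences have a gap are never
#' compared; an internal gap opposite a base counts as a difference.
#'
#' @param alignment named character vector of aligned rows.
#' @param ignore_terminal_gaps exclude terminal gap runs.
#' @return symmetric distance matrix with the alignment names as labels.
#' @export
pairwiseDistances <- function(alignment, ignore_terminal_gaps = TRUE) {
  M <- .char_matrix(unname(alignment))
  n <- nrow(M); L <- ncol(M)
  lead <- integer(n); trail <- integer(n)
  for (i in seq_len(n)) {
    nongap <- which(M[i, ] != "-")
    lead[i] <- if (length(nongap)) nongap[1L] else L + 1L
    trail[i] <- if (length(nongap)) nongap[length(nongap)] else 0L
  }
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    cols <- seq_len(L)
    if (ignore_terminal_gaps)
      cols <- cols[cols >= max(lead[i], lead[j]) &
                     cols <= min(trail[i], trail[j])]
    a <- M[i, cols]; b <- M[j, cols]
    comparable <- !(a == "-" & b == "-")
    if (!any(comparable))
      stop(sprintf("no comparable columns between rows %d and %d", i, j))
    d <- sum(a[comparable] != b[comparable]) / sum(comparable)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree
#'
#' Standard NJ agglomeration (via ape) on a distance matrix. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sibling
#' edge. The two-leaf case returns a tree whose single path has length
#' d(1,2).
#'
#' @param dm symmetric distance matrix with labels.
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(dm) {
  labs <- rownames(dm)
  if (is.null(labs)) labs <- colnames(dm)
  n <- length(labs)
  if (n < 2L) stop("need at least 2 leaves")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = rep(dm[1, 2] / 2, 2L),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(dm))
  # clamp negative edges, moving the deficit to the sibling edge
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- which(tr$edge[, 1L] == parent & seq_len(nrow(tr$edge)) != e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib)) tr$edge.length[sib[1L]] <-
        max(0, tr$edge.length[sib[1L]] + deficit)
  }
  tr
}

#' Bootstrapped 50% majority-rule consensus tree
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance
#' matrix and NJ tree per replicate, and returns the majority-rule consensus
#' (bipartitions present in more than half the replicates). Seeded, so the
#' same seed reproduces the same consensus.
#'
#' @param alignment named character vector of aligned rows.
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @param p consensus threshold (0.5 = majority rule).
#' @return an [ape::phylo] consensus tree (no branch lengths).
#' @export
bootstrapConsensus <- function(alignment, reps = 100L, seed = 1L, p = 0.5) {
  M <- .char_matrix(unname(alignment))
  L <- ncol(M)
  trees <- .with_seed(seed, {
    lapply(seq_len(reps), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      rows <- apply(M[, cols, drop = FALSE], 1L, paste, collapse = "")
      names(rows) <- names(alignment)
      njTree(pairwiseDistances(rows))
    })
  })
  ape::consensus(trees, p = p)
}

#' Weighted (normalised) UniFrac distance
#'
#' For each branch of the tree, the difference between the fractions of the
#' two communities' abundance descending through that branch is weighted by
#' the branch length; the sum is normalised by the abundance-weighted
#' leaf depths so the distance lies in [0, 1]. Zero iff the normalised
#' abundance vectors are identical; symmetric.
#'
#' @param tree an [ape::phylo] with branch lengths; leaves must cover the
#'   abundance names.
#' @param a,b abundances named by tip label (need not be normalised).
#' @return the distance (numeric scalar).
#' @export
weightedUnifrac <- function(tree, a, b) {
  if (!length(a) || sum(a) == 0 || !length(b) || sum(b) == 0)
    stop("empty abundance map")
  if (!all(names(a) %in% tree$tip.label) ||
      !all(names(b) %in% tree$tip.label))
    stop("abundance names must be tree tips")
  pa <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
  pb <- pa
  pa[names(a)] <- a / sum(a)
  pb[names(b)] <- b / sum(b)
  ntip <- length(tree$tip.label)
  # accumulate the tip mass below every edge (postorder)
  edge <- tree$edge
  below_a <- numeric(ntip + tree$Nnode)
  below_b <- numeric(ntip + tree$Nnode)
  below_a[seq_len(ntip)] <- pa
  below_b[seq_len(ntip)] <- pb
  ord <- ape::postorder(tree)
  for (e in ord) {
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    below_a[parent] <- below_a[parent] + below_a[child]
    below_b[parent] <- below_b[parent] + below_b[child]
  }
  wa <- below_a[edge[, 2L]]
  wb <- below_b[edge[, 2L]]
  len <- tree$edge.length
  num <- sum(len * abs(wa - wb))
  den <- sum(len * (wa + wb))
  if (den == 0) return(0)
  num / den
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(a_i, b_i)) / (sum(a) + sum(b))` over the union of the
#' two named count vectors; bounded in [0, 1].
#'
#' @param a,b non-negative counts named by feature.
#' @return the dissimilarity (numeric scalar).
#' @export
brayCurtis <- function(a, b) {
  if ((!length(a) || sum(a) == 0) && (!length(b) || sum(b) == 0))
    stop("both abundance maps are empty")
  keys <- union(names(a), names(b))
  av <- setNames(numeric(length(keys)), keys)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  1 - 2 * sum(pmin(av, bv)) / (sum(av) + sum(bv))
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: the doubly centred matrix of squared distances
#' is eigendecomposed; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues are reported
#' but their axes dropped.
#'
#' @param dm symmetric distance matrix with labels.
#' @return list of class `PCoAResult`: `points` (labels x axes),
#'   `eigenvalues` (all, decreasing), `prop_explained` (per retained axis).
#' @export
pcoaOrdination <- function(dm) {
  n <- nrow(dm)
  if (is.null(n) || n < 2L) stop("need at least 2 objects")
  # cmdscale warns when fewer than k eigenvalues are positive; axes with
  # non-positive eigenvalues are dropped below by design
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = n - 1L, eig = TRUE))
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- which(sc$eig[seq_len(ncol(sc$points))] > 1e-12 * max(abs(sc$eig)))
  pts <- sc$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  rownames(pts) <- rownames(dm)
  prop <- eig[eig > 0] / sum(eig[eig > 0])
  structure(list(points = pts, eigenvalues = eig,
                 prop_explained = prop[seq_len(ncol(pts))]),
            class = "PCoAResult")
}

#' @export
print.PCoAResult <- function(x, ...) {
  cat(sprintf("PCoAResult: %d objects, %d axes (%.1f%% on PC1)\n",
              nrow(x$points), ncol(x$points), 100 * x$prop_explained[1]))
  invisible(x)
}

## ---- sample- and profile-level distance matrices ---------------------------

# Per-sample abundance vectors (named by uid) for one clade.
.clade_vectors <- function(collections, clade) {
  ccs <- Filter(function(cc) cc@clade == clade, collections)
  setNames(lapply(ccs, function(cc) cc@abundances),
           vapply(ccs, slot, character(1), "sample_id"))
}

# NJ tree over the unique sequences appearing in a set of abundance vectors.
.uid_tree <- function(uids, registry) {
  seqs <- sequenceOf(registry, uids)
  aln <- alignSequences(setNames(seqs, as.character(uids)))
  njTree(pairwiseDistances(aln))
}

#' Between-sample distance matrix for one clade
#'
#' Bray-Curtis or weighted UniFrac distances between the samples' full
#' post-QC sequence complements of one clade. The UniFrac tree is the NJ
#' tree over all of the clade's sequences.
#'
#' @param collections list of [CladeCollection-class].
#' @param clade clade label.
#' @param metric "braycurtis" or "unifrac".
#' @param registry registry (required for "unifrac").
#' @return symmetric distance matrix labelled by sample id.
#' @export
sampleDistances <- function(collections, clade,
                            metric = c("braycurtis", "unifrac"),
                            registry = NULL) {
  metric <- match.arg(metric)
  vecs <- .clade_vectors(collections, clade)
  if (length(vecs) < 2L) stop("need at least 2 samples of clade ", clade)
  tree <- NULL
  if (metric == "unifrac") {
    uids <- sort(unique(as.integer(unlist(lapply(vecs, names)))))
    if (length(uids) < 2L) stop("need at least 2 sequences for UniFrac")
    tree <- .uid_tree(uids, registry)
  }
  n <- length(vecs)
  D <- matrix(0, n, n, dimnames = list(names(vecs), names(vecs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- if (metric == "braycurtis")
      brayCurtis(vecs[[i]], vecs[[j]])
    else weightedUnifrac(tree, vecs[[i]], vecs[[j]])
  }
  D
}

#' Between-profile distance matrix for one clade
#'
#' Profiles are represented by their DIV abundance-range midpoints.
#'
#' @param profiles list of [TypeProfile-class].
#' @param clade clade label.
#' @param metric "braycurtis" or "unifrac".
#' @param registry registry (required for "unifrac").
#' @return symmetric distance matrix labelled by profile name.
#' @export
profileDistances <- function(profiles, clade,
                             metric = c("braycurtis", "unifrac"),
                             registry = NULL) {
  metric <- match.arg(metric)
  ps <- Filter(function(p) p@clade == clade, profiles)
  if (length(ps) < 2L) stop("need at least 2 profiles of clade ", clade)
  vecs <- lapply(ps, function(p)
    setNames(colMeans(p@ranges), colnames(p@ranges)))
  names(vecs) <- vapply(ps, slot, character(1), "name")
  tree <- NULL
  if (metric == "unifrac") {
    uids <- sort(unique(as.integer(unlist(lapply(vecs, names)))))
    tree <- .uid_tree(uids, registry)
  }
  n <- length(vecs)
  D <- matrix(0, n, n, dimnames = list(names(vecs), names(vecs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- if (metric == "braycurtis")
      brayCurtis(vecs[[i]], vecs[[j]])
    else weightedUnifrac(tree, vecs[[i]], vecs[[j]])
  }
  D
}
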