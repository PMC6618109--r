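# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (enumeration / closed forms / textbook algorithms) and
# never call the code paths they are checking.

# Needleman-Wunsch global alignment, match +1 / mismatch -1 / gap -2.
nw_align <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(A[i] == B[j], 1, -1),
                           S[i, j + 1] - 2, S[i + 1, j] - 2)
  }
  # traceback
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(A[i] == B[j], 1, -1)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1, m + 1])
}

# Exhaustive re-occurring-set search: enumerate every subset of the observed
# sequence universe, then apply the same greedy selection and tie rules as
# the discovery contract. Feasible for <= 8 sequences x <= 10 collections.
enumerate_profiles <- function(footprints, min_support) {
  universe <- sort(unique(unlist(lapply(footprints, `[[`, "members"))))
  stopifnot(length(universe) <= 12)
  subsets <- list()
  for (mask in seq_len(2^length(universe) - 1)) {
    s <- universe[bitwAnd(mask, 2^(seq_along(universe) - 1)) > 0]
    subsets[[length(subsets) + 1]] <- s
  }
  lex_less <- function(a, b) {
    k <- min(length(a), length(b))
    if (k > 0) {
      d <- a[seq_len(k)] - b[seq_len(k)]
      nz <- which(d != 0)
      if (length(nz)) return(d[nz[1]] < 0)
    }
    length(a) < length(b)
  }
  unexplained <- rep(TRUE, length(footprints))
  out <- list()
  repeat {
    best <- NULL
    for (s in subsets) {
      sup <- which(unexplained & vapply(footprints, function(fp)
        all(s %in% fp$members), logical(1)))
      if (length(sup) < min_support) next
      ab <- sum(vapply(sup, function(i)
        sum(footprints[[i]]$rel[as.character(s)]), numeric(1)))
      cand <- list(members = s, sup = sup, ab = ab)
      if (is.null(best)) { best <- cand; next }
      pick <- FALSE
      if (length(s) != length(best$members))
        pick <- length(s) > length(best$members)
      else if (length(sup) != length(best$sup))
        pick <- length(sup) > length(best$sup)
      else if (!isTRUE(all.equal(ab, best$ab))) pick <- ab > best$ab
      else pick <- lex_less(s, best$members)
      if (pick) best <- cand
    }
    if (is.null(best)) break
    out[[length(out) + 1]] <- list(members = best$members,
                                   n_sup = length(best$sup))
    unexplained[best$sup] <- FALSE
  }
  out
}

# Count-weighted average linkage via hclust on the read-expanded matrix:
# every read is its own point (zero distance to copies of its sequence).
brute_average_linkage <- function(dm, counts, cutoff) {
  labs <- rownames(dm)
  expanded <- rep(labs, counts[labs])
  n <- length(expanded)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- dm[expanded[i], expanded[j]]
  if (length(unique(expanded)) == 1)
    return(list(sort(unique(expanded))))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  grp <- stats::cutree(hc, h = cutoff)
  unname(lapply(split(expanded, grp), function(x) sort(unique(x))))
}

# Closed-form three-point branch lengths for a 3-leaf star.
three_point <- function(d12, d13, d23) {
  c(l1 = (d12 + d13 - d23) / 2,
    l2 = (d12 + d23 - d13) / 2,
    l3 = (d13 + d23 - d12) / 2)
}

# Random additive distance matrix from a random topology with known
# branch lengths (via ape); returns the tree and its cophenetic matrix.
random_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 0.5))
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# Direct weighted-normalised UniFrac on a tiny explicitly rooted tree,
# summing over edges by brute-force tip enumeration.
unifrac_oracle <- function(tree, a, b) {
  a <- a / sum(a); b <- b / sum(b)
  tips <- tree$tip.label
  below <- function(node) {
    if (node <= length(tips)) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tl <- below(tree$edge[e, 2])
    pa <- sum(a[intersect(names(a), tl)])
    pb <- sum(b[intersect(names(b), tl)])
    num <- num + tree$edge.length[e] * abs(pa - pb)
    den <- den + tree$edge.length[e] * (pa + pb)
  }
  num / den
}
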