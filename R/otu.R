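## 97%-similarity OTU clustering baseline (count-weighted average linkage).

#' Average-neighbour OTU clustering
#'
#' Agglomerative average-linkage clustering in which every redundant read
#' contributes to the linkage (count-weighted: the distance between two
#' clusters is the count-weighted mean of their members' pairwise
#' distances). Clusters merge while the minimum inter-cluster distance does
#' not exceed `cutoff` (3% dissimilarity by default); ties are broken by
#' label order. Merge heights are recorded.
#'
#' @param dm symmetric distance matrix over unique sequences (labels).
#' @param counts read counts named by label.
#' @param cutoff dissimilarity cutoff.
#' @return list of clusters, each with `members` (named counts),
#'   `representative` (most abundant member; ties to the lexicographically
#'   smaller label) and `merge_height` (dissimilarity at which the cluster
#'   last merged; 0 for singletons).
#' @export
clusterAverageNeighbour <- function(dm, counts, cutoff = 0.03) {
  labs <- rownames(dm)
  stopifnot(!is.null(labs), all(labs %in% names(counts)))
  n <- length(labs)
  clusters <- lapply(labs, function(l) setNames(counts[l], l))
  sizes <- as.numeric(counts[labs])
  heights <- numeric(n)
  D <- dm
  active <- rep(TRUE, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    best <- NULL
    for (ii in seq_along(idx)) for (jj in seq_along(idx)) {
      if (jj <= ii) next
      i <- idx[ii]; j <- idx[jj]
      if (is.null(best) || D[i, j] < best$d) best <- list(i = i, j = j,
                                                          d = D[i, j])
    }
    if (best$d > cutoff) break
    i <- best$i; j <- best$j
    # count-weighted average linkage update
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- (sizes[i] * D[i, k] + sizes[j] * D[j, k]) /
        (sizes[i] + sizes[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- best$d
    active[j] <- FALSE
  }
  lapply(which(active), function(i) {
    mem <- clusters[[i]]
    rep_lab <- names(mem)[order(-mem, names(mem))][1L]
    list(members = mem, representative = rep_lab,
         merge_height = heights[i])
  })
}

#' OTU representatives
#'
#' @param clusters list from [clusterAverageNeighbour()].
#' @return character vector of representative labels, named `OTU1..OTUn`.
#' @export
otuRepresentatives <- function(clusters) {
  stopifnot(length(clusters) > 0L)
  setNames(vapply(clusters, `[[`, character(1), "representative"),
           paste0("OTU", seq_along(clusters)))
}

#' Run the OTU comparison pipeline
#'
#' Clusters post-QC sequences at the configured dissimilarity cutoff either
#' pooled across samples ("across", the classical approach) or sample by
#' sample ("within"). Distances are p-distances on the internal alignment
#' with terminal gaps ignored.
#'
#' @param samples named list (by sample id) of per-sample read counts named
#'   by sequence.
#' @param mode "across" or "within".
#' @param cutoff dissimilarity cutoff.
#' @return data.frame: one row per OTU with `representative`,
#'   `merge_height` and one count column per sample.
#' @export
runOtuPipeline <- function(samples, mode = c("across", "within"),
                           cutoff = 0.03) {
  mode <- match.arg(mode)
  sample_ids <- names(samples)
  cluster_sets <- function(counts) {
    if (length(counts) == 1L)
      return(list(list(members = counts, representative = names(counts),
                       merge_height = 0)))
    ord <- order(-counts, names(counts))
    aln <- alignSequences(setNames(names(counts)[ord], names(counts)[ord]))
    dm <- pairwiseDistances(aln, ignore_terminal_gaps = TRUE)
    clusterAverageNeighbour(dm, counts, cutoff)
  }
  otu_rows <- list()
  add_row <- function(cl, per_sample) {
    key <- cl$representative
    if (is.null(otu_rows[[key]])) {
      otu_rows[[key]] <<- c(list(representative = key,
                                 merge_height = cl$merge_height),
                            as.list(setNames(numeric(length(sample_ids)),
                                             sample_ids)))
    }
    for (sid in names(per_sample))
      otu_rows[[key]][[sid]] <<- otu_rows[[key]][[sid]] + per_sample[[sid]]
    otu_rows[[key]]$merge_height <<- max(otu_rows[[key]]$merge_height,
                                         cl$merge_height)
  }
  if (mode == "across") {
    pooled <- tapply(
      unlist(unname(samples)),
      unlist(lapply(samples, names)), sum)
    pooled <- setNames(as.numeric(pooled), names(pooled))
    for (cl in cluster_sets(pooled)) {
      per_sample <- lapply(samples, function(s) {
        sum(s[intersect(names(s), names(cl$members))])
      })
      add_row(cl, per_sample)
    }
  } else {
    for (sid in sample_ids) {
      for (cl in cluster_sets(samples[[sid]])) {
        add_row(cl, setNames(list(sum(cl$members)), sid))
      }
    }
  }
  out <- do.call(rbind, lapply(otu_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
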