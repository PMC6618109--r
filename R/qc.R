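## Quality-control chain: read-pair merging, ambiguity/homopolymer screen,
## clade separation, dereplication, abundance filter, primer trimming,
## length screen and entropy-based decomposition.

#' Merge one read pair into a contig
#'
#' Finds the highest-scoring ungapped overlap (score = matches - mismatches)
#' between the forward read and the reverse complement of the reverse read,
#' over all overlap lengths of at least `min_overlap`. At overlap mismatches
#' the base with the higher Phred quality is kept (ties keep the forward
#' base). The pair is rejected when no overlap scores at least 80% of its
#' length, i.e. when no near-identical overlap exists.
#'
#' @param fwd,rev read sequences as sequenced (the reverse read is on the
#'   reverse-complement strand).
#' @param fwd_qual,rev_qual Phred+33 quality strings.
#' @param min_overlap minimum overlap length in bp.
#' @return list with `contig` (character or NA), `status` ("merged" or
#'   "rejected"), `overlap`, `mismatches`.
#' @export
mergeReadPair <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                          min_overlap = 30L) {
  if (is.null(fwd_qual)) fwd_qual <- strrep("I", nchar(fwd))
  if (is.null(rev_qual)) rev_qual <- strrep("I", nchar(rev))
  rc <- .revcomp(rev)
  rcq <- paste(rev(strsplit(rev_qual, "")[[1]]), collapse = "")
  f <- strsplit(fwd, "")[[1]]; r <- strsplit(rc, "")[[1]]
  fq <- utf8ToInt(fwd_qual) - 33L
  rq <- utf8ToInt(rcq) - 33L
  nf <- length(f); nr <- length(r)
  if (min(nf, nr) < min_overlap)
    return(list(contig = NA_character_, status = "rejected",
                overlap = NA_integer_, mismatches = NA_integer_))
  best <- list(score = -Inf, v = NA_integer_, mm = NA_integer_)
  for (v in seq(min(nf, nr), min_overlap)) {
    if (v <= best$score) break  # no smaller overlap can beat the best score
    a <- f[(nf - v + 1L):nf]; b <- r[seq_len(v)]
    mm <- sum(a != b)
    score <- v - 2L * mm
    if (score > best$score) best <- list(score = score, v = v, mm = mm)
  }
  if (!is.finite(best$score) || best$score < 0.8 * best$v)
    return(list(contig = NA_character_, status = "rejected",
                overlap = NA_integer_, mismatches = NA_integer_))
  v <- best$v
  ov_f <- f[(nf - v + 1L):nf]; ov_r <- r[seq_len(v)]
  qf <- fq[(nf - v + 1L):nf]; qr <- rq[seq_len(v)]
  cons <- ifelse(ov_f == ov_r | qf >= qr, ov_f, ov_r)
  contig <- paste(c(if (nf > v) f[seq_len(nf - v)], cons,
                    if (nr > v) r[(v + 1L):nr]), collapse = "")
  list(contig = contig, status = "merged", overlap = v, mismatches = best$mm)
}

# Vectorised merging for whole samples where all forward reads share one
# length and all reverse reads share one length (the common Illumina case).
# Falls back to mergeReadPair() otherwise. Returns a character vector with
# NA for rejected pairs.
.merge_pairs_fast <- function(fwd, rev, fwd_qual, rev_qual,
                              min_overlap = 30L) {
  n <- length(fwd)
  if (n == 0L) return(character(0))
  if (length(unique(nchar(fwd))) != 1L || length(unique(nchar(rev))) != 1L) {
    return(vapply(seq_len(n), function(i)
      mergeReadPair(fwd[i], rev[i], fwd_qual[i], rev_qual[i],
                    min_overlap)$contig, character(1)))
  }
  rc <- .revcomp(rev)
  rcq <- vapply(strsplit(rev_qual, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  Fm <- .char_matrix(fwd); Rm <- .char_matrix(rc)
  FQ <- .qual_matrix(fwd_qual); RQ <- .qual_matrix(rcq)
  nf <- ncol(Fm); nr <- ncol(Rm)
  if (min(nf, nr) < min_overlap) return(rep(NA_character_, n))
  best_score <- rep(-Inf, n); best_v <- rep(NA_integer_, n)
  for (v in seq(min(nf, nr), min_overlap)) {
    if (v <= min(best_score)) break
    mm <- rowSums(Fm[, (nf - v + 1L):nf, drop = FALSE] !=
                    Rm[, seq_len(v), drop = FALSE])
    sc <- v - 2 * mm
    upd <- sc > best_score
    best_score[upd] <- sc[upd]; best_v[upd] <- v
  }
  ok <- is.finite(best_score) & best_score >= 0.8 * best_v
  out <- rep(NA_character_, n)
  for (v in unique(best_v[ok])) {
    idx <- which(ok & best_v == v)
    fcols <- (nf - v + 1L):nf; rcols <- seq_len(v)
    A <- Fm[idx, fcols, drop = FALSE]; B <- Rm[idx, rcols, drop = FALSE]
    keepf <- A == B | FQ[idx, fcols, drop = FALSE] >=
      RQ[idx, rcols, drop = FALSE]
    cons <- ifelse(keepf, A, B)
    pre <- if (nf > v) substr(fwd[idx], 1L, nf - v) else ""
    post <- if (nr > v) substr(rc[idx], v + 1L, nr) else ""
    mid <- apply(cons, 1L, paste, collapse = "")
    out[idx] <- paste0(pre, mid, post)
  }
  out
}

#' Ambiguity and homopolymer screen
#'
#' Discards contigs carrying more than `maxambig` ambiguous (non-ACGT) bases
#' or a homopolymer run longer than `maxhomop`; both filters target reads
#' putatively generated from sequencing errors.
#'
#' @param contigs character vector of contigs.
#' @param maxambig maximum ambiguous bases tolerated.
#' @param maxhomop maximum homopolymer run length tolerated.
#' @return logical vector, TRUE = keep.
#' @export
screenQuality <- function(contigs, maxambig = 0L, maxhomop = 5L) {
  ambig <- nchar(gsub("[ACGT]", "", contigs))
  run <- grepl(sprintf("([ACGTN])\\1{%d,}", maxhomop), contigs)
  ambig <= maxambig & !run
}

#' Dereplicate sequences
#'
#' @param contigs character vector (redundant sequences).
#' @return integer counts named by unique sequence, in decreasing count
#'   order (ties broken alphabetically) so results are independent of input
#'   order.
#' @export
dereplicate <- function(contigs) {
  if (!length(contigs)) return(setNames(integer(0), character(0)))
  tab <- table(contigs)
  counts <- setNames(as.integer(tab), names(tab))
  counts[order(-counts, names(counts))]
}

# Shared k-mer counts against reference k-mer sets; used to shortlist the
# candidate reference/orientation before alignment-based verification.
.kmer_set <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

.clade_ref_index <- function(refs, k = 8L) {
  idx <- list()
  for (cl in names(refs)) {
    idx[[paste0(cl, "+")]] <- .kmer_set(refs[[cl]], k)
    idx[[paste0(cl, "-")]] <- .kmer_set(.revcomp(refs[[cl]]), k)
  }
  idx
}

#' Assign a sequence to a clade
#'
#' Screens a sequence against the nine clade reference sequences (both
#' orientations) and returns the clade of the best local alignment, provided
#' alignment identity and query coverage meet the configured thresholds
#' (80% each by default); otherwise `NA`. A shared 8-mer prescreen
#' shortlists the two most promising reference/orientation candidates, which
#' are then verified by Smith-Waterman alignment (match +1, mismatch -1,
#' gap -2).
#'
#' @param sequences character vector of query sequences.
#' @param refs named character vector of clade references (names A--I), as
#'   from [bundledCladeRefs()].
#' @param config a [DivConfig-class] (thresholds `id_min`, `cov_min`).
#' @param cache optional environment memoising sequence -> clade.
#' @return character vector of clade labels, NA where unassignable.
#' @export
assignClade <- function(sequences, refs = bundledCladeRefs(),
                        config = divConfig(), cache = NULL) {
  out <- rep(NA_character_, length(sequences))
  todo <- seq_along(sequences)
  if (!is.null(cache)) {
    hit <- vapply(sequences, function(s) {
      h <- cache[[s]]
      if (is.null(h)) "?" else if (is.na(h)) "NA" else h
    }, character(1), USE.NAMES = FALSE)
    out[hit != "?"] <- ifelse(hit[hit != "?"] == "NA", NA_character_,
                              hit[hit != "?"])
    todo <- which(hit == "?")
  }
  if (!length(todo)) return(out)
  idx <- .clade_ref_index(refs)
  # IUPAC-aware matrix: queries may carry ambiguity codes when the op is
  # called outside the pipeline order (scores equal baseOnly on A/C/G/T)
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
  # shortlist the two best reference/orientation candidates per query
  cand <- t(vapply(sequences[todo], function(s) {
    km <- .kmer_set(s)
    shared <- vapply(idx, function(ref_k) sum(km %in% ref_k), numeric(1))
    names(sort(shared, decreasing = TRUE))[1:2]
  }, character(2), USE.NAMES = FALSE))
  best_score <- rep(-Inf, length(todo))
  best_clade <- rep(NA_character_, length(todo))
  for (col in 1:2) {
    for (cd in unique(cand[, col])) {
      sel <- which(cand[, col] == cd)
      cl <- substr(cd, 1L, 1L); ori <- substr(cd, 2L, 2L)
      q <- sequences[todo[sel]]
      if (ori == "-") q <- .revcomp(q)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(q), refs[[cl]], type = "local",
        substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
      ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      cov <- Biostrings::width(Biostrings::pattern(pa)) / nchar(q)
      sc <- Biostrings::score(pa)
      ok <- ident >= config@id_min & cov >= config@cov_min &
        sc > best_score[sel]
      best_score[sel[ok]] <- sc[ok]
      best_clade[sel[ok]] <- cl
    }
  }
  out[todo] <- best_clade
  if (!is.null(cache)) for (k in seq_along(todo))
    cache[[sequences[todo[k]]]] <- best_clade[k]
  out
}

#' Abundance filter
#'
#' Retains sequences found at an abundance strictly greater than `cutoff`
#' (the published rule is "> 2"), discarding likely error sequences.
#'
#' @param counts named counts (sequence -> count).
#' @param cutoff non-negative integer.
#' @return the filtered named counts.
#' @export
filterLowAbundance <- function(counts, cutoff = 2L) {
  stopifnot(cutoff >= 0)
  counts[counts > cutoff]
}

# Primer match helper: minimum mismatches of `primer` (IUPAC allowed)
# against `seq` starting at 1-based offset `at`; Inf if out of range.
.primer_mismatches <- function(seq_chars, primer_sets, at) {
  L <- length(primer_sets)
  if (at < 1L || at + L - 1L > length(seq_chars)) return(Inf)
  mm <- 0L
  for (j in seq_len(L)) {
    if (!(seq_chars[at + j - 1L] %in% primer_sets[[j]])) mm <- mm + 1L
  }
  mm
}

#' Trim amplicon primers
#'
#' Locates the forward primer at the 5' end (within `pdiffs` mismatches) and
#' the reverse complement of the reverse primer at the 3' end (within
#' `rdiffs` mismatches), trying start offsets within 3 positions of the
#' respective sequence end, and returns the interior. IUPAC degeneracies in
#' the primers match their base sets; mismatch counting is indel-free.
#' Sequences in which either primer cannot be found are discarded (NA).
#'
#' @param sequences character vector.
#' @param fwd_primer,rev_primer primers 5'->3'.
#' @param pdiffs,rdiffs mismatch allowances.
#' @return character vector of trimmed interiors, NA where discarded.
#' @export
trimPrimers <- function(sequences, fwd_primer, rev_primer,
                        pdiffs = 2L, rdiffs = 2L) {
  fp <- .IUPAC[strsplit(fwd_primer, "")[[1]]]
  rp <- .IUPAC[strsplit(.revcomp(rev_primer), "")[[1]]]
  lf <- length(fp); lr <- length(rp)
  vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    f_at <- NA_integer_; f_mm <- Inf
    for (at in 1:4) {
      mm <- .primer_mismatches(ch, fp, at)
      if (mm < f_mm) { f_mm <- mm; f_at <- at }
    }
    if (f_mm > pdiffs) return(NA_character_)
    r_at <- NA_integer_; r_mm <- Inf
    for (at in (n - lr + 1L):(n - lr - 2L)) {
      mm <- .primer_mismatches(ch, rp, at)
      if (mm < r_mm) { r_mm <- mm; r_at <- at }
    }
    if (r_mm > rdiffs) return(NA_character_)
    start <- f_at + lf
    end <- r_at - 1L
    if (start > end) return(NA_character_)
    substr(s, start, end)
  }, character(1), USE.NAMES = FALSE)
}

#' Length screen
#'
#' @param sequences character vector.
#' @param minlength,maxlength inclusive window; the published screen removes
#'   sequences shorter than 184 bp or longer than 310 bp.
#' @return logical vector, TRUE = keep.
#' @export
screenLength <- function(sequences, minlength = 184L, maxlength = 310L) {
  stopifnot(minlength <= maxlength)
  n <- nchar(sequences)
  n >= minlength & n <= maxlength
}

#' Entropy-based decomposition of unique sequences
#'
#' A deliberately simplified minimum-entropy decomposition: unique sequences
#' of one clade are multiple-aligned, the Shannon entropy (bits, base
#' frequencies over non-gap characters, weighted by read counts) of every
#' alignment column is computed, and the sequence set is split recursively
#' on the highest-entropy column while that entropy exceeds
#' `entropy_threshold`. Child nodes whose total abundance falls below
#' `max(min_node_abund, node_frac * parent)` are merged into the nearest
#' surviving child by edit distance between representatives. Each node is
#' reported by its most abundant member sequence; read counts are conserved.
#'
#' @param counts read counts named by unique sequence.
#' @param entropy_threshold entropy (bits) above which a column triggers a
#'   split.
#' @param min_node_abund absolute minimum node abundance (reads).
#' @param node_frac minimum node abundance as a fraction of the parent.
#' @return counts named by node-representative sequence.
#' @export
entropyDecompose <- function(counts, entropy_threshold = 0.10,
                             min_node_abund = 10L, node_frac = 0.01) {
  if (length(counts) <= 1L) return(counts)
  seqs <- names(counts)
  aln <- alignSequences(seqs[order(-counts, seqs)])
  aln <- aln[seqs]  # restore input order
  M <- .char_matrix(unname(aln))
  w <- as.numeric(counts)

  col_entropy <- function(rows) {
    apply(M[rows, , drop = FALSE], 2L, function(col) {
      keep <- col != "-"
      if (!any(keep)) return(0)
      .shannon(tapply(w[rows][keep], col[keep], sum))
    })
  }

  decompose <- function(rows) {
    if (length(rows) == 1L) return(list(rows))
    H <- col_entropy(rows)
    j <- which.max(H)
    if (H[j] <= entropy_threshold) return(list(rows))
    groups <- split(rows, M[rows, j])
    if (length(groups) <= 1L) return(list(rows))
    totals <- vapply(groups, function(g) sum(w[g]), numeric(1))
    min_ab <- max(min_node_abund, node_frac * sum(w[rows]))
    ok <- totals >= min_ab
    if (sum(ok) <= 1L) return(list(rows))  # cannot split into >=2 real nodes
    keep <- groups[ok]
    reps <- vapply(keep, function(g) seqs[g[which.max(w[g])]], character(1))
    for (g in groups[!ok]) {
      gr <- seqs[g[which.max(w[g])]]
      d <- as.numeric(adist(gr, reps))
      tgt <- which.min(d)
      keep[[tgt]] <- c(keep[[tgt]], g)
    }
    unlist(lapply(keep, decompose), recursive = FALSE)
  }

  nodes <- decompose(seq_along(seqs))
  reps <- vapply(nodes, function(g) {
    cand <- seqs[g]
    cand[order(-w[g], cand)][1L]
  }, character(1))
  totals <- vapply(nodes, function(g) sum(counts[g]), numeric(1))
  out <- tapply(totals, reps, sum)
  res <- setNames(as.integer(out), names(out))
  res[order(-res, names(res))]
}

#' Build per-sample clade collections
#'
#' One collection per (sample, clade); a collection is flagged searchable
#' only when its total abundance strictly exceeds `min_collection_size`
#' (the "more than 200 sequences" rule).
#'
#' @param node_counts named counts (sequence -> count) after decomposition.
#' @param clades clade label per sequence (parallel to `node_counts`).
#' @param sample_id sample identifier.
#' @param registry a [DivRegistry-class]; sequences are registered and
#'   abundances keyed by UID.
#' @param min_collection_size searchability threshold.
#' @return list of [CladeCollection-class], ordered by clade label.
#' @export
buildCladeCollections <- function(node_counts, clades, sample_id, registry,
                                  min_collection_size = 200L) {
  stopifnot(length(node_counts) == length(clades), !anyNA(clades))
  out <- list()
  for (cl in sort(unique(clades))) {
    sel <- clades == cl
    uids <- vapply(names(node_counts)[sel], function(s)
      registerSequence(registry, s, cl), integer(1))
    ab <- setNames(as.numeric(node_counts[sel]), as.character(uids))
    out[[cl]] <- cladeCollection(sample_id, cl, ab, min_collection_size)
  }
  unname(out)
}

#' Run the full QC chain on one sample
#'
#' Applies, in order: read-pair merging, ambiguity/homopolymer screening,
#' clade assignment, dereplication, the "> cutoff" abundance filter, primer
#' trimming, the length screen and the per-clade entropy decomposition, then
#' builds the sample's clade collections. The returned QC report gives the
#' surviving read count after every stage (plus the node count after
#' decomposition, which is a unique-sequence figure, not a read count).
#'
#' @param fwd,rev,fwd_qual,rev_qual read data as from [readFastqPair()].
#' @param sample_id sample identifier.
#' @param registry a [DivRegistry-class].
#' @param refs clade reference sequences.
#' @param config a [DivConfig-class].
#' @return list with `collections`, `qc` (named numeric of stage counts) and
#'   `node_counts` (named counts with a `clades` attribute).
#' @export
runSampleQC <- function(fwd, rev, fwd_qual, rev_qual, sample_id,
                        registry, refs = bundledCladeRefs(),
                        config = divConfig()) {
  qc <- c(reads_in = length(fwd))
  contigs <- .merge_pairs_fast(fwd, rev, fwd_qual, rev_qual,
                               config@min_overlap)
  contigs <- contigs[!is.na(contigs)]
  qc["contigs"] <- length(contigs)

  keep <- screenQuality(contigs, config@maxambig, config@maxhomop)
  contigs <- contigs[keep]
  qc["quality_screen"] <- length(contigs)

  counts <- dereplicate(contigs)
  clades <- assignClade(names(counts), refs, config,
                        cache = registry@env$clade_cache)
  counts <- counts[!is.na(clades)]
  clades <- clades[!is.na(clades)]
  qc["clade_assigned"] <- sum(counts)

  keep <- counts > config@abund_cutoff
  counts <- counts[keep]; clades <- clades[keep]
  qc["abundance_filter"] <- sum(counts)

  trimmed <- trimPrimers(names(counts), config@fwd_primer, config@rev_primer,
                         config@pdiffs, config@rdiffs)
  ok <- !is.na(trimmed)
  counts <- counts[ok]; clades <- clades[ok]; trimmed <- trimmed[ok]
  # trimming can merge formerly distinct sequences
  agg <- tapply(as.numeric(counts), trimmed, sum)
  cl_by_seq <- tapply(clades, trimmed, function(x) x[[1L]])
  counts <- setNames(as.integer(agg), names(agg))
  clades <- as.character(cl_by_seq[names(counts)])
  qc["primer_trim"] <- sum(counts)

  keep <- screenLength(names(counts), config@minlength, config@maxlength)
  counts <- counts[keep]; clades <- clades[keep]
  qc["length_screen"] <- sum(counts)

  node_counts <- integer(0); node_clades <- character(0)
  for (cl in sort(unique(clades))) {
    nodes <- entropyDecompose(counts[clades == cl],
                              config@entropy_threshold)
    node_counts <- c(node_counts, nodes)
    node_clades <- c(node_clades, rep(cl, length(nodes)))
  }
  qc["post_decomposition"] <- sum(node_counts)
  qc["nodes"] <- length(node_counts)

  collections <- buildCladeCollections(node_counts, node_clades, sample_id,
                                       registry, config@min_collection_size)
  attr(node_counts, "clades") <- node_clades
  list(collections = collections, qc = qc, node_counts = node_counts)
}

#' Load a dataset of paired FASTQ samples
#'
#' Runs [runSampleQC()] over every row of a sample sheet.
#'
#' @param sample_sheet data.frame with columns `sample_id`, `fwd`, `rev`
#'   (file paths), or a path to such a TSV (paths resolved relative to the
#'   sheet's directory).
#' @param registry a [DivRegistry-class].
#' @param refs clade reference sequences.
#' @param config a [DivConfig-class].
#' @return list with `collections` (flat list across samples), `qc`
#'   (data.frame, one row per sample) and `sample_ids`.
#' @export
loadDataset <- function(sample_sheet, registry = newDivRegistry(),
                        refs = bundledCladeRefs(), config = divConfig()) {
  if (is.character(sample_sheet)) sample_sheet <- readSampleSheet(sample_sheet)
  collections <- list()
  qc_rows <- list()
  for (i in seq_len(nrow(sample_sheet))) {
    pair <- readFastqPair(sample_sheet$fwd[i], sample_sheet$rev[i])
    res <- runSampleQC(pair$fwd, pair$rev, pair$fwd_qual, pair$rev_qual,
                       sample_sheet$sample_id[i], registry, refs, config)
    collections <- c(collections, res$collections)
    qc_rows[[i]] <- res$qc
  }
  qc <- as.data.frame(do.call(rbind, qc_rows))
  qc <- cbind(sample_id = sample_sheet$sample_id, qc)
  list(collections = collections, qc = qc, registry = registry,
       sample_ids = sample_sheet$sample_id)
}
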