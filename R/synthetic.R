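## Synthetic Symbiodiniaceae community simulator with ground truth.

# Fixed instantiation of IUPAC degeneracies used when synthesising concrete
# amplicon molecules (trimming still matches the degenerate primer).
.concrete <- function(primer) {
  sets <- .IUPAC[strsplit(primer, "")[[1]]]
  paste(vapply(sets, `[[`, character(1), 1L), collapse = "")
}

#' Create a synthetic genotype
#'
#' A genotype is a base ITS2 sequence plus derived intragenomic variants,
#' each within `divergence` substitutions of the base, occurring at fixed
#' proportions among the genome's rDNA copies. Deterministic for a fixed
#' seed.
#'
#' @param clade clade label.
#' @param n_variants number of variant sequences (>= 1).
#' @param proportions per-variant proportions (sum 1); default is a
#'   geometric decay (ratio 0.55) normalised to 1, mimicking the strongly
#'   skewed variant abundances of real rDNA arrays.
#' @param divergence maximum substitutions between base and variant (>= 1
#'   when `n_variants` > 1).
#' @param seed RNG seed.
#' @param base_seq base sequence; defaults to a uniformly random 260-mer.
#' @param name genotype label.
#' @return a [SyntheticGenotype-class].
#' @export
makeGenotype <- function(clade, n_variants, proportions = NULL,
                         divergence = 3L, seed = 1L, base_seq = NULL,
                         name = sprintf("%s-gt%d", clade, seed)) {
  stopifnot(n_variants >= 1L)
  if (n_variants > 1L && divergence < 1L)
    stop("cannot derive distinct variants with divergence 0")
  if (is.null(proportions)) {
    proportions <- 0.55^(seq_len(n_variants) - 1L)
    proportions <- proportions / sum(proportions)
  }
  stopifnot(length(proportions) == n_variants,
            isTRUE(all.equal(sum(proportions), 1)))
  .with_seed(seed, {
    if (is.null(base_seq)) base_seq <- .random_dna(1L, 260L)
    variants <- base_seq
    bases <- c("A", "C", "G", "T")
    while (length(variants) < n_variants) {
      nedit <- sample.int(divergence, 1L)
      ch <- strsplit(base_seq, "")[[1]]
      pos <- sample.int(length(ch), nedit)
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      cand <- paste(ch, collapse = "")
      if (!cand %in% variants) variants <- c(variants, cand)
    }
    new("SyntheticGenotype", name = name, clade = clade,
        variants = variants, proportions = proportions)
  })
}

#' Simulate one sample's paired FASTQ reads
#'
#' Reads are drawn multinomially from the variant proportions scaled by the
#' genotype mixture weights. Each amplicon molecule is the forward primer,
#' the variant sequence and the reverse complement of the reverse primer;
#' forward/reverse reads are the first `read_length` bases of each strand,
#' so pairs overlap and exercise merging. Substitution errors occur per base
#' at `error_rate`; qualities are uniformly high ("I") except at simulated
#' error positions ("#"), so merge conflicts resolve deterministically in
#' favour of the error-free strand.
#'
#' @param genotypes list of [SyntheticGenotype-class].
#' @param weights mixture weights (sum 1).
#' @param depth number of read pairs.
#' @param error_rate per-base substitution probability in [0, 1).
#' @param read_length read length (bp).
#' @param seed RNG seed.
#' @param fwd_file,rev_file optional FASTQ(.gz) output paths.
#' @param config a [DivConfig-class] supplying the primers.
#' @param sample_id used in read identifiers.
#' @return invisible list with `fwd`, `rev`, `fwd_qual`, `rev_qual`, `ids`
#'   and `truth` (reads drawn per genotype/variant).
#' @export
simulateSampleReads <- function(genotypes, weights = NULL, depth = 2000L,
                                error_rate = 0.001, read_length = 250L,
                                seed = 1L, fwd_file = NULL, rev_file = NULL,
                                config = divConfig(),
                                sample_id = "sample") {
  stopifnot(depth >= 1L, error_rate >= 0, error_rate < 1)
  if (is.null(weights)) weights <- rep(1 / length(genotypes),
                                       length(genotypes))
  stopifnot(length(weights) == length(genotypes),
            isTRUE(all.equal(sum(weights), 1)))
  fwdp <- .concrete(config@fwd_primer)
  revp_rc <- .revcomp(.concrete(config@rev_primer))
  pool_seq <- character(0); pool_p <- numeric(0); pool_lab <- character(0)
  for (g in seq_along(genotypes)) {
    gt <- genotypes[[g]]
    pool_seq <- c(pool_seq, gt@variants)
    pool_p <- c(pool_p, gt@proportions * weights[g])
    pool_lab <- c(pool_lab, paste(gt@name, seq_along(gt@variants),
                                  sep = ":"))
  }
  .with_seed(seed, {
    draws <- as.integer(rmultinom(1L, depth, pool_p))
    amplicons <- paste0(fwdp, pool_seq, revp_rc)
    fwd_full <- rep(substr(amplicons, 1L, read_length), draws)
    rc_amp <- .revcomp(amplicons)
    rev_full <- rep(substr(rc_amp, 1L, read_length), draws)
    n <- length(fwd_full)
    perm <- sample.int(n)
    fwd_full <- fwd_full[perm]; rev_full <- rev_full[perm]
    add_errors <- function(reads) {
      L <- read_length
      qual <- rep(strrep("I", L), length(reads))
      nerr <- rbinom(1L, length(reads) * L, error_rate)
      if (nerr > 0L) {
        pos <- sample.int(length(reads) * L, nerr)
        ri <- (pos - 1L) %/% L + 1L
        ci <- (pos - 1L) %% L + 1L
        for (k in seq_len(nerr)) {
          old <- substr(reads[ri[k]], ci[k], ci[k])
          new_base <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          substr(reads[ri[k]], ci[k], ci[k]) <- new_base
          substr(qual[ri[k]], ci[k], ci[k]) <- "#"
        }
      }
      list(reads = reads, qual = qual)
    }
    fe <- add_errors(fwd_full)
    re <- add_errors(rev_full)
    ids <- sprintf("read_%s_%06d", sample_id, seq_len(n))
    if (!is.null(fwd_file)) writeFastq(ids, fe$reads, fe$qual, fwd_file)
    if (!is.null(rev_file)) writeFastq(ids, re$reads, re$qual, rev_file)
    invisible(list(fwd = fe$reads, rev = re$reads, fwd_qual = fe$qual,
                   rev_qual = re$qual, ids = ids,
                   truth = setNames(draws, pool_lab)))
  })
}

#' Generate a ground-truthed synthetic study
#'
#' Emits a ready-to-run input directory: K same-clade genotypes derived from
#' the bundled clade reference, `n_per_genotype` standalone samples per
#' genotype, optional extra samples mixing two same-clade genotypes
#' (50/50), and optional extra samples mixing a genotype with a second-clade
#' genotype (50/50, the second-clade genotype also represented standalone so
#' profile discovery can validate it). All reads are written as paired
#' FASTQ(.gz) with a sample sheet and a ground-truth table.
#'
#' @param K number of same-clade genotypes.
#' @param n_per_genotype standalone samples per genotype.
#' @param mixed_fraction extra same-clade two-genotype samples as a fraction
#'   of the standalone sample count.
#' @param cross_clade_fraction extra cross-clade samples as a fraction of
#'   the standalone sample count.
#' @param depth read pairs per sample.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed (drives genotypes and every sample).
#' @param out_dir output directory.
#' @param clade primary clade label.
#' @param second_clade clade of the cross-clade genotype.
#' @param n_variants variant counts per genotype, recycled over genotypes.
#' @param read_length read length.
#' @param config a [DivConfig-class] supplying primers and thresholds.
#' @param gzip write gzipped FASTQ.
#' @return list with `sheet` (sample-sheet path), `truth` (data.frame),
#'   `genotypes` (list incl. any second-clade genotype) and `dir`.
#' @export
generateStudy <- function(K = 3L, n_per_genotype = 10L, mixed_fraction = 0,
                          cross_clade_fraction = 0, depth = 2000L,
                          error_rate = 0.001, seed = 1L,
                          out_dir = tempfile("study"), clade = "C",
                          second_clade = "A", n_variants = c(4L, 3L, 6L, 5L),
                          read_length = 250L, config = divConfig(),
                          gzip = TRUE) {
  stopifnot(K >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- bundledCladeRefs()
  nv <- rep_len(n_variants, K)
  # genotype bases: clade reference with genotype-specific substitutions in
  # disjoint position blocks, so DIV sets are distinct and clade-assignable
  mutate_block <- function(base, block, nmut, seed) {
    .with_seed(seed, {
      ch <- strsplit(base, "")[[1]]
      pos <- block[sample.int(length(block), nmut)]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]),
                                     1L)
      paste(ch, collapse = "")
    })
  }
  # genotype bases derive from the reference's interior (primers are added
  # back by the read simulator)
  interior <- function(cl) {
    x <- trimPrimers(refs[[cl]], config@fwd_primer, config@rev_primer,
                     config@pdiffs, config@rdiffs)
    if (is.na(x)) refs[[cl]] else x
  }
  ref_int <- interior(clade)
  base_len <- nchar(ref_int)
  blocks <- split(seq_len(base_len),
                  cut(seq_len(base_len), K + 1L, labels = FALSE))
  genotypes <- lapply(seq_len(K), function(k) {
    base <- mutate_block(ref_int, blocks[[k]], 8L, seed + k)
    makeGenotype(clade, nv[k], divergence = 3L, seed = seed + 100L + k,
                 base_seq = base, name = sprintf("%s%d", clade, k))
  })
  cross_gt <- NULL
  n_base <- K * n_per_genotype
  n_mixed <- round(mixed_fraction * n_base)
  n_cross <- round(cross_clade_fraction * n_base)
  if (n_cross > 0L) {
    cross_gt <- makeGenotype(second_clade, 3L, divergence = 3L,
                             seed = seed + 999L,
                             base_seq = interior(second_clade),
                             name = paste0(second_clade, "1"))
  }
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  rows <- list(); truth <- list()
  add_sample <- function(sid, gts, wts, sseed) {
    fwd <- file.path(out_dir, paste0(sid, "_R1", ext))
    rev <- file.path(out_dir, paste0(sid, "_R2", ext))
    simulateSampleReads(gts, wts, depth, error_rate, read_length,
                        seed = sseed, fwd_file = fwd, rev_file = rev,
                        config = config, sample_id = sid)
    rows[[sid]] <<- data.frame(sample_id = sid, fwd = basename(fwd),
                               rev = basename(rev))
    truth[[sid]] <<- data.frame(
      sample_id = sid,
      genotypes = paste(vapply(gts, slot, character(1), "name"),
                        collapse = ";"),
      weights = paste(wts, collapse = ";"))
  }
  s <- 0L
  for (k in seq_len(K)) for (r in seq_len(n_per_genotype)) {
    s <- s + 1L
    add_sample(sprintf("S%03d", s), genotypes[k], 1, seed * 1000L + s)
  }
  if (n_mixed > 0L) {
    pairs <- utils::combn(K, 2L)
    for (m in seq_len(n_mixed)) {
      s <- s + 1L
      pr <- pairs[, (m - 1L) %% ncol(pairs) + 1L]
      add_sample(sprintf("S%03d", s), genotypes[pr], c(0.5, 0.5),
                 seed * 1000L + s)
    }
  }
  if (n_cross > 0L) {
    for (m in seq_len(n_cross)) {
      s <- s + 1L
      k <- (m - 1L) %% K + 1L
      add_sample(sprintf("S%03d", s), list(genotypes[[k]], cross_gt),
                 c(0.5, 0.5), seed * 1000L + s)
    }
    for (m in seq_len(3L)) {  # standalone support for the cross-clade taxon
      s <- s + 1L
      add_sample(sprintf("S%03d", s), list(cross_gt), 1, seed * 1000L + s)
    }
  }
  sheet <- do.call(rbind, rows)
  sheet_path <- file.path(out_dir, "samples.tsv")
  write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  write.table(truth_df, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(sheet = sheet_path, truth = truth_df,
       genotypes = c(genotypes, if (!is.null(cross_gt)) list(cross_gt)),
       dir = out_dir)
}
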