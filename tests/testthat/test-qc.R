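set.seed(301)
toy_insert <- paste(sample(c("A", "C", "G", "T"), 120, TRUE,
                           prob = c(.3, .25, .25, .2)), collapse = "")

test_that("read pairs merge on exact overlaps and reject without one", {
  # fwd = 5' half, rev = reverse complement of the 3' half, 30 bp overlap
  fwd <- substr(toy_insert, 1, 75)
  rev3 <- rc_chr(substr(toy_insert, 46, 120))
  m <- mergeReadPair(fwd, rev3, min_overlap = 30L)
  expect_identical(m$status, "merged")
  expect_identical(m$contig, toy_insert)
  expect_identical(m$overlap, 30L)
  # unrelated reads: no acceptable overlap
  other <- paste(rep(c("A", "C"), 40), collapse = "")
  expect_identical(mergeReadPair(fwd, other, min_overlap = 30L)$status,
                   "rejected")
  # reads shorter than min_overlap can never merge
  expect_identical(mergeReadPair("ACGTACGT", "ACGTACGT")$status, "rejected")
})

test_that("overlap mismatches resolve to the higher-quality base, either order", {
  fwd <- substr(toy_insert, 1, 75)
  tail_rc <- rc_chr(substr(toy_insert, 46, 120))
  # introduce a disagreement at overlap position 60 of the contig
  true_base <- substr(toy_insert, 60, 60)
  wrong <- setdiff(c("A", "C", "G", "T"), true_base)[1]
  fwd_bad <- fwd
  substr(fwd_bad, 60, 60) <- wrong
  ql <- function(n, at = NULL, q = "I") {
    s <- strrep("I", n); if (!is.null(at)) substr(s, at, at) <- q; s
  }
  # forward carries the error at low quality -> reverse base wins
  m1 <- mergeReadPair(fwd_bad, tail_rc, ql(75, 60, "#"), ql(75), 30L)
  expect_identical(m1$contig, toy_insert)
  expect_identical(m1$mismatches, 1L)
  # reverse strand carries low quality at that position -> forward base wins
  rev_pos <- 75 - (60 - 46)  # contig pos 60 within the reversed read
  m2 <- mergeReadPair(fwd_bad, tail_rc, ql(75), ql(75, rev_pos, "#"), 30L)
  expect_identical(substr(m2$contig, 60, 60), wrong)
})

test_that("vectorised merging agrees with the single-pair contract", {
  set.seed(77)
  amps <- replicate(20, paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                              collapse = ""))
  fwd <- substr(amps, 1, 100)
  rev <- substr(vapply(amps, rc_chr, character(1)), 1, 100)
  fq <- rep(strrep("I", 100), 20); rq <- fq
  fast <- divProfiler:::.merge_pairs_fast(fwd, rev, fq, rq, 30L)
  slow <- vapply(seq_along(fwd), function(i)
    mergeReadPair(fwd[i], rev[i], fq[i], rq[i], 30L)$contig, character(1))
  expect_identical(fast, slow)
  expect_identical(fast, unname(amps))
})

test_that("ambiguity and homopolymer screens apply the published thresholds", {
  base <- substr(toy_insert, 1, 40)
  with_n <- paste0(substr(base, 1, 20), "N", substr(base, 22, 40))
  with_run6 <- paste0(substr(base, 1, 20), "AAAAAA", substr(base, 27, 40))
  with_run5 <- paste0(substr(base, 1, 20), "AAAAA", "C", substr(base, 27, 40))
  keep <- screenQuality(c(base, with_n, with_run6, with_run5),
                        maxambig = 0L, maxhomop = 5L)
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("dereplication conserves reads and ignores input order", {
  x <- c("AAA", "CCC", "AAA", "GGG", "AAA", "CCC")
  d <- dereplicate(x)
  expect_identical(d, c(AAA = 3L, CCC = 2L, GGG = 1L))
  expect_identical(dereplicate(rev(x)), d)
  expect_identical(sum(d), length(x))
  expect_identical(dereplicate(character(0)),
                   setNames(integer(0), character(0)))
  expect_identical(dereplicate(rep("T", 1000)), c(T = 1000L))
})

test_that("clade screening finds the best reference and rejects noise", {
  cfg <- fix_config
  expect_identical(assignClade(fix_refs[["C"]], fix_refs, cfg), "C")
  expect_identical(assignClade(fix_refs[["D"]], fix_refs, cfg), "D")
  # catalogue (interior) sequences map to their clades
  expect_identical(assignClade(cat_seq("C3"), fix_refs, cfg), "C")
  expect_identical(assignClade(cat_seq("D1"), fix_refs, cfg), "D")
  # orientation is resolved
  expect_identical(assignClade(rc_chr(cat_seq("C3")), fix_refs, cfg), "C")
  # composition-preserving shuffle scores below the identity threshold
  set.seed(5)
  shuf <- paste(sample(strsplit(fix_refs[["C"]], "")[[1]]), collapse = "")
  expect_true(is.na(assignClade(shuf, fix_refs, cfg)))
  # three substitutions stay well above threshold
  ch <- strsplit(fix_refs[["C"]], "")[[1]]
  for (p in c(30L, 150L, 250L))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  expect_identical(assignClade(paste(ch, collapse = ""), fix_refs, cfg), "C")
})

test_that("abundance filtering keeps strictly greater-than-cutoff counts", {
  counts <- c(S = 3L, T = 2L, U = 1L)
  expect_identical(filterLowAbundance(counts, 2L), c(S = 3L))
  expect_identical(filterLowAbundance(counts, 0L), counts)
  expect_identical(filterLowAbundance(setNames(integer(0), character(0)), 2L),
                   setNames(integer(0), character(0)))
})

test_that("primer trimming allows up to the configured mismatches", {
  insert <- substr(toy_insert, 1, 100)
  amp <- make_amplicon(insert)
  cfg <- fix_config
  expect_identical(
    trimPrimers(amp, cfg@fwd_primer, cfg@rev_primer), insert)
  # two mismatches in the forward primer: still trimmed
  amp2 <- amp
  substr(amp2, 3, 3) <- "T"; substr(amp2, 7, 7) <- "A"
  expect_identical(trimPrimers(amp2, cfg@fwd_primer, cfg@rev_primer), insert)
  # three mismatches: discarded; the Hamming oracle confirms no offset works
  amp3 <- amp2
  substr(amp3, 11, 11) <- "C"
  fp <- concrete_fwd
  mm_at <- vapply(1:6, function(at) {
    sum(strsplit(substr(amp3, at, at + nchar(fp) - 1), "")[[1]] !=
          strsplit(fp, "")[[1]])
  }, numeric(1))
  expect_true(all(mm_at > 2))
  expect_true(is.na(trimPrimers(amp3, cfg@fwd_primer, cfg@rev_primer)))
  # IUPAC degeneracy in the reverse primer matches its base set
  expect_identical(trimPrimers(amp, cfg@fwd_primer,
                               "CGGGTTCWCTTGTYTGACTTCATGC"), insert)
})

test_that("length screen bounds are inclusive at 184 and 310", {
  mk <- function(n) strrep("A", n)
  expect_identical(screenLength(vapply(c(183, 184, 250, 310, 311), mk,
                                       character(1))),
                   c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("entropy decomposition splits real variation and absorbs noise", {
  s1 <- substr(toy_insert, 1, 60)
  s2 <- s1; substr(s2, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                          substr(s1, 30, 30))[1]
  # all identical -> a single node with the total count
  expect_identical(entropyDecompose(setNames(500L, s1)),
                   setNames(500L, s1))
  # two equal variants at one position: column entropy is 1 bit -> two nodes
  nodes <- entropyDecompose(setNames(c(50L, 50L), c(s1, s2)))
  expect_identical(sort(names(nodes)), sort(c(s1, s2)))
  expect_identical(unname(nodes), c(50L, 50L))
  # a singleton 1-bp variant of a dominant sequence is absorbed:
  # column entropy of (1000, 1) is far below the threshold
  p <- c(1000, 1) / 1001
  expect_lt(-sum(p * log2(p)), 0.10)
  nodes2 <- entropyDecompose(setNames(c(1000L, 1L), c(s1, s2)))
  expect_identical(nodes2, setNames(1001L, s1))
  # a 30-read variant exceeds the entropy threshold and the node minimum
  nodes3 <- entropyDecompose(setNames(c(1000L, 30L), c(s1, s2)))
  expect_identical(nodes3, setNames(c(1000L, 30L), c(s1, s2)))
  # counts are always conserved
  expect_identical(sum(nodes3), 1030L)
})

test_that("clade collections obey the strict >200 searchability rule", {
  reg <- newDivRegistry()
  s1 <- substr(toy_insert, 1, 50); s2 <- substr(toy_insert, 51, 100)
  ccs <- buildCladeCollections(setNames(c(201L, 200L), c(s1, s2)),
                               c("C", "C"), "s1", reg)
  expect_length(ccs, 1L)
  expect_true(ccs[[1]]@searchable)  # total 401 > 200
  ccs2 <- buildCladeCollections(setNames(201L, s1), "C", "s2", reg)
  expect_true(ccs2[[1]]@searchable)
  ccs3 <- buildCladeCollections(setNames(200L, s1), "C", "s3", reg)
  expect_false(ccs3[[1]]@searchable)
  # two clades give two collections
  s3 <- rc_chr(substr(toy_insert, 1, 50))
  ccs4 <- buildCladeCollections(setNames(c(300L, 250L), c(s1, s3)),
                                c("C", "A"), "s4", reg)
  expect_identical(vapply(ccs4, function(cc) cc@clade, character(1)),
                   c("A", "C"))
})

test_that("the QC chain is deterministic and conserves reads stage to stage", {
  gt <- makeGenotype("C", 3, seed = 9, base_seq = cat_seq("C3"))
  sim <- simulateSampleReads(list(gt), 1, depth = 400, error_rate = 0.002,
                             seed = 4, config = fix_config)
  run <- function() {
    reg <- newDivRegistry()
    runSampleQC(sim$fwd, sim$rev, sim$fwd_qual, sim$rev_qual, "s1",
                reg, fix_refs, fix_config)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$qc, r2$qc)
  expect_identical(r1$node_counts, r2$node_counts)
  qc <- r1$qc
  stages <- c("reads_in", "contigs", "quality_screen", "clade_assigned",
              "abundance_filter", "primer_trim", "length_screen",
              "post_decomposition")
  expect_true(all(diff(qc[stages]) <= 0))
  expect_identical(unname(qc["post_decomposition"]),
                   unname(qc["length_screen"]))
})
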