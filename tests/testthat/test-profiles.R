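make_rel <- function(uids, vals) setNames(vals, as.character(uids))

test_that("footprints collect sequences at or above the relative cutoff", {
  cc <- make_cc("s1", "C", make_rel(1:4, c(600, 300, 50, 5)))  # total 955
  fp <- extractFootprint(cc, 0.01)
  expect_identical(fp$members, c(1L, 2L, 3L))  # 5/955 < 1%
  expect_identical(fp$source, "s1|C")
  # cutoff 0 keeps everything
  expect_identical(extractFootprint(cc, 0)$members, 1:4)
  # only the majority above the cutoff -> singleton footprint
  cc2 <- make_cc("s2", "C", make_rel(1:3, c(980, 6, 5)))
  expect_identical(extractFootprint(cc2, 0.05)$members, 1L)
  # unsearchable collections are a caller error
  cc3 <- make_cc("s3", "C", make_rel(1, 150))
  expect_error(extractFootprint(cc3), "not searchable")
})

test_that("discovery finds the documented maximal supported sets", {
  # 3 identical footprints {1,2}, min_support 2 -> one candidate
  fps <- lapply(1:3, function(i)
    make_footprint(c(1, 2), make_rel(1:2, c(.6, .3)), paste0("s", i, "|C")))
  cands <- discoverCandidateProfiles(fps, 2L)
  expect_length(cands, 1L)
  expect_identical(cands[[1]]$members, c(1L, 2L))
  expect_length(cands[[1]]$supporting, 3L)

  # 4 x {1,2,3} and 3 x {1,2}: both sets emerge with their own supporters
  fps2 <- c(
    lapply(1:4, function(i)
      make_footprint(1:3, make_rel(1:3, c(.5, .3, .1)), paste0("a", i, "|C"))),
    lapply(1:3, function(i)
      make_footprint(1:2, make_rel(1:2, c(.6, .3)), paste0("b", i, "|C"))))
  cands2 <- discoverCandidateProfiles(fps2, 3L)
  expect_length(cands2, 2L)
  expect_identical(cands2[[1]]$members, 1:3)
  expect_length(cands2[[1]]$supporting, 4L)
  expect_identical(cands2[[2]]$members, c(1L, 2L))
  expect_length(cands2[[2]]$supporting, 3L)

  # a single sample cannot support anything at the default threshold
  expect_length(discoverCandidateProfiles(fps[1], 3L), 0L)
})

test_that("discovery equals exhaustive subset enumeration on random instances", {
  set.seed(202)
  for (rep in 1:12) {
    n_seq <- sample(4:8, 1)
    n_cc <- sample(4:10, 1)
    fps <- lapply(seq_len(n_cc), function(i) {
      k <- sample(2:n_seq, 1)
      members <- sort(sample(n_seq, k))
      rel <- make_rel(members, round(runif(k, .05, .9), 3))
      make_footprint(members, rel, paste0("s", i, "|C"))
    })
    ms <- sample(2:3, 1)
    got <- discoverCandidateProfiles(fps, ms)
    want <- enumerate_profiles(fps, ms)
    expect_identical(length(got), length(want))
    for (k in seq_along(got)) {
      expect_identical(got[[k]]$members, as.integer(want[[k]]$members))
      expect_identical(length(got[[k]]$supporting), want[[k]]$n_sup)
    }
  }
})

test_that("multimodal abundance distributions split; unimodal ones do not", {
  mk_cand <- function(vals2) {
    A <- cbind(rep(0.5, length(vals2)), vals2)
    colnames(A) <- c("1", "2")
    rownames(A) <- paste0("s", seq_along(vals2), "|C")
    list(members = 1:2, supporting = rownames(A), abundance = A)
  }
  # all ~0.30: unimodal
  set.seed(5)
  uni <- mk_cand(0.30 + runif(12, -0.01, 0.01))
  expect_length(splitMultimodal(uni, 3L), 1L)
  # 6 samples near 0.05 and 6 near 0.40: two clear modes
  bim_vals <- c(0.05, 0.052, 0.048, 0.051, 0.05, 0.049,
                0.40, 0.41, 0.39, 0.402, 0.398, 0.40)
  bim <- mk_cand(bim_vals)
  parts <- splitMultimodal(bim, 3L)
  expect_length(parts, 2L)
  expect_identical(vapply(parts, function(p) nrow(p$abundance), integer(1)),
                   c(6L, 6L))
  expect_identical(parts[[1]]$members, parts[[2]]$members)
  # a mode with only 2 supporters dissolves back: no split retained
  few <- mk_cand(c(0.05, 0.052, 0.40, 0.41, 0.39, 0.402, 0.398, 0.40))
  expect_length(splitMultimodal(few, 3L), 1L)
})

test_that("characterisation orders DIVs, records ranges and the majority set", {
  reg <- toy_registry(c("C3", "C3c", "C3gulf"))
  uids <- reg$uids
  A <- rbind(c(0.5, 0.30, 0.10),
             c(0.6, 0.35, 0.12),
             c(0.55, 0.32, 0.11))
  colnames(A) <- as.character(uids)
  rownames(A) <- paste0("s", 1:3, "|C")
  cand <- list(members = sort(uids), supporting = rownames(A), abundance = A)
  p <- characterizeProfile(cand, "C", 1L, reg$registry)
  expect_identical(p@divs, unname(uids))
  expect_identical(unname(p@ranges["min", ]), c(0.5, 0.30, 0.10))
  expect_identical(unname(p@ranges["max", ]), c(0.6, 0.35, 0.12))
  expect_identical(p@majority_set, unname(uids["C3"]))
  expect_identical(p@name, "C3-C3c-C3gulf")
  # tolerance widens and clamps
  p2 <- characterizeProfile(cand, "C", 2L, reg$registry,
                            range_tolerance = 0.2)
  expect_identical(unname(p2@ranges["min", 1]), 0.3)
  expect_identical(unname(p2@ranges["max", 1]), 0.8)
  # supporters split between two top DIVs -> comajority
  A2 <- A; A2[2, ] <- c(0.30, 0.5, 0.12)
  cand2 <- list(members = sort(uids), supporting = rownames(A2),
                abundance = A2)
  p3 <- characterizeProfile(cand2, "C", 3L, reg$registry)
  expect_setequal(p3@majority_set, unname(uids[c("C3", "C3c")]))
  expect_match(p3@name, "^C3/C3c")
})

test_that("profile naming follows the DIV grammar and parses back", {
  reg <- toy_registry(c("C3", "C3gulf", "C3c", "C3aq"))
  uids <- reg$uids
  p1 <- make_profile(1, uids, rep(.1, 4), c(.6, .5, .4, .3),
                     majority = uids["C3"])
  p1@means <- c(.6, .5, .4, .3)
  expect_identical(nameProfile(p1, reg$registry), "C3-C3gulf-C3c-C3aq")
  # comajority: majority block first, "/"-joined
  p2 <- make_profile(2, uids[c("C3", "C3c", "C3gulf")], rep(.1, 3),
                     c(.6, .5, .4), majority = uids[c("C3", "C3c")])
  expect_identical(nameProfile(p2, reg$registry), "C3/C3c-C3gulf")
  # single DIV
  p3 <- make_profile(3, uids["C3"], .5, .9)
  expect_identical(nameProfile(p3, reg$registry), "C3")
  # unnamed DIVs render as UID
  reg2 <- newDivRegistry(catalogue = data.frame(name = character(0),
                                                sequence = character(0)))
  u <- registerSequence(reg2, "ACGTACGTACGT", "C")
  p4 <- make_profile(4, u, .1, .9)
  expect_identical(nameProfile(p4, reg2), as.character(u))
  # round trip
  for (p in list(p1, p2, p3)) {
    parsed <- parseProfileName(nameProfile(p, reg$registry))
    expect_identical(parsed$divs,
                     unname(nameOf(reg$registry, p@divs)))
    expect_identical(parsed$majority,
                     unname(nameOf(reg$registry, p@majority_set)))
  }
})

test_that("assignment requires presence and in-range abundance of every DIV", {
  reg <- toy_registry(c("C3", "C3gulf", "C3c", "C3aq"))
  uids <- reg$uids
  prof <- make_profile(1, uids, c(.30, .15, .10, .05),
                       c(.60, .35, .25, .15))
  # all DIVs in range -> assigned
  cc <- make_cc("s1", "C",
                make_rel(uids, c(500, 250, 150, 80)))  # rel ~.51/.26/.15/.08
  a <- assignProfiles(cc, list(prof))
  expect_identical(a$profile_uid, 1L)
  expect_equal(a$rel_abundance, 1.0)
  # C3aq present but below its range minimum -> not assigned
  cc2 <- make_cc("s2", "C", make_rel(uids, c(540, 260, 160, 20)))
  expect_identical(nrow(assignProfiles(cc2, list(prof))), 0L)
  # a missing DIV also blocks assignment
  cc3 <- make_cc("s3", "C", make_rel(uids[1:3], c(540, 260, 160)))
  expect_identical(nrow(assignProfiles(cc3, list(prof))), 0L)
})

test_that("two disjoint standalone-validated profiles co-assign; overlaps resolve", {
  reg <- toy_registry(c("C3", "C3a", "C3ab", "C15", "C15x"))
  uids <- reg$uids
  pA <- make_profile(1, uids[c("C3", "C3a", "C3ab")], rep(.01, 3),
                     rep(.9, 3))
  pB <- make_profile(2, uids[c("C15", "C15x")], rep(.01, 2), rep(.9, 2))
  cc <- make_cc("mix", "C", make_rel(uids, c(300, 100, 50, 250, 80)))
  both <- assignProfiles(cc, list(pA, pB), standalone_uids = c(1L, 2L))
  expect_setequal(both$profile_uid, c(1L, 2L))
  expect_equal(sum(both$rel_abundance), 1.0)
  # without standalone validation of one, only the strongest is kept
  one <- assignProfiles(cc, list(pA, pB), standalone_uids = 1L)
  expect_identical(one$profile_uid, 1L)
  # overlapping profiles resolve to the greatest summed DIV abundance
  pC <- make_profile(3, uids[c("C3", "C3a")], rep(.01, 2), rep(.9, 2))
  res <- assignProfiles(cc, list(pA, pC), standalone_uids = c(1L, 3L))
  expect_identical(res$profile_uid, 1L)  # superset has the higher DIV sum
})

test_that("overlap resolution breaks ties by DIV count then UID", {
  reg <- toy_registry(c("C3", "C3a", "C3ab", "C3c"))
  uids <- reg$uids
  cc <- make_cc("s", "C", make_rel(uids, c(250, 250, 250, 250)))
  p4 <- make_profile(7, uids, rep(0, 4), rep(1, 4))
  p3 <- make_profile(8, uids[1:3], rep(0, 3), rep(1, 3))
  expect_identical(resolveOverlaps(list(p3, p4), cc)@uid, 7L)  # higher sum
  pX <- make_profile(9, uids[1:2], rep(0, 2), rep(1, 2))
  pY <- make_profile(10, uids[3:4], rep(0, 2), rep(1, 2))
  # equal sums, equal DIV counts -> lower uid
  expect_identical(resolveOverlaps(list(pY, pX), cc)@uid, 9L)
  # equal sums, different DIV counts -> more DIVs
  pZ <- make_profile(11, uids[1:3], rep(0, 3), rep(1, 3))
  ccw <- make_cc("s2", "C", make_rel(uids, c(300, 150, 150, 600)))
  # pZ sum = .5, pW sum = .5 with 1 DIV
  pW <- make_profile(12, uids[4], 0, 1)
  expect_identical(resolveOverlaps(list(pW, pZ), ccw)@uid, 11L)
})

test_that("fallback assigns the most abundant sequence and reuses profiles", {
  reg <- toy_registry(c("C3", "C3c"))
  uids <- reg$uids
  cc <- make_cc("s1", "C", make_rel(uids, c(700, 300)))
  fb <- fallbackAssign(cc, list(), reg$registry, 50L)
  expect_true(fb@fallback)
  expect_identical(fb@divs, unname(uids["C3"]))
  expect_identical(fb@name, "C3")
  # reuse: same top sequence in another sample extends support
  cc2 <- make_cc("s2", "C", make_rel(uids, c(800, 250)))
  fb2 <- fallbackAssign(cc2, list(fb), reg$registry, 51L)
  expect_identical(fb2@uid, fb@uid)
  expect_setequal(fb2@support, c("s1|C", "s2|C"))
  # abundance tie -> lower uid wins
  cc3 <- make_cc("s3", "C", make_rel(uids, c(500, 500)))
  fb3 <- fallbackAssign(cc3, list(), reg$registry, 60L)
  expect_identical(fb3@divs, unname(min(uids)))
})

test_that("genus re-merging scales by clade proportions", {
  a_C <- data.frame(profile_uid = 1L, rel_abundance = 1.0)
  a_A <- data.frame(profile_uid = 2L, rel_abundance = 1.0)
  m <- mergeGenusOutputs(list(C = a_C, A = a_A),
                         c(C = 150, A = 50), 200)
  expect_equal(m$rel_abundance[m$profile_uid == 1L], 0.75)
  expect_equal(m$rel_abundance[m$profile_uid == 2L], 0.25)
  # single clade: unchanged
  m1 <- mergeGenusOutputs(list(C = a_C), c(C = 300), 300)
  expect_equal(m1$rel_abundance, 1.0)
  # raw (non-normalised) arithmetic: 0.8 of a clade holding 50% -> 0.40
  m2 <- mergeGenusOutputs(
    list(C = data.frame(profile_uid = 1L, rel_abundance = 0.8)),
    c(C = 100), 200, normalise = FALSE)
  expect_equal(m2$rel_abundance, 0.40)
  # inconsistent totals error
  expect_error(mergeGenusOutputs(list(C = a_C), c(C = 300), 200),
               "exceed")
})

test_that("super-type flagging detects disconnected DIV radiations", {
  # one radiation: sequences within 2 edits of a base
  reg <- newDivRegistry(catalogue = data.frame(name = character(0),
                                               sequence = character(0)))
  set.seed(31)
  base1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  v1 <- base1; substr(v1, 10, 10) <- "A"; substr(v1, 20, 20) <- "C"
  base2 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  v2 <- base2; substr(v2, 30, 30) <- "G"
  u <- c(registerSequence(reg, base1, "C"), registerSequence(reg, v1, "C"),
         registerSequence(reg, base2, "C"), registerSequence(reg, v2, "C"))
  # distances verified by the dynamic-programming oracle (utils::adist)
  expect_lte(utils::adist(base1, v1)[1, 1], 3)
  expect_gt(utils::adist(base1, base2)[1, 1], 3)
  one <- make_profile(1, u[1:2], rep(0, 2), rep(1, 2))
  expect_true(flagSuperTypes(one, reg)$pass)
  mixed <- make_profile(2, u, rep(0, 4), rep(1, 4))
  expect_warning(res <- flagSuperTypes(mixed, reg), "super type")
  expect_false(res$pass)
  expect_identical(max(res$components), 2L)
  single <- make_profile(3, u[1], 0, 1)
  expect_true(flagSuperTypes(single, reg)$pass)
})

test_that("a full analysis is deterministic and covers every searchable collection", {
  reg <- toy_registry(c("C3", "C3gulf", "C3c", "C15", "C15x", "D1"))
  uids <- reg$uids
  mk <- function(sid, vals, clade = "C", ids = uids[1:3])
    make_cc(sid, clade, make_rel(ids, vals))
  ccs <- c(
    lapply(1:4, function(i) mk(paste0("a", i), c(600, 300, 90) + i)),
    lapply(1:4, function(i) mk(paste0("b", i), c(700, 260) + i,
                               ids = uids[c("C15", "C15x")])),
    list(mk("lone", c(900, 80), ids = uids[c("C3", "C3gulf")])))
  res <- runAnalysis(ccs, reg$registry)
  res2 <- runAnalysis(ccs, reg$registry)
  expect_identical(res$assignments, res2$assignments)
  # every searchable collection is assigned at least one profile
  expect_setequal(unique(res$assignments$sample_id),
                  vapply(ccs, function(cc) cc@sample_id, character(1)))
  # assignments never reference sequences absent from the sample
  for (i in seq_len(nrow(res$assignments))) {
    sid <- res$assignments$sample_id[i]
    p <- res$profiles[[as.character(res$assignments$profile_uid[i])]]
    cc <- Filter(function(x) x@sample_id == sid && x@clade == p@clade,
                 ccs)[[1]]
    expect_true(all(as.character(p@divs) %in% names(cc@abundances)))
  }
  # profiles from a prior run are retained and re-supported
  res3 <- runAnalysis(ccs, reg$registry, prior_profiles = res$profiles)
  prior_sets <- lapply(Filter(function(p) !p@fallback, res$profiles),
                       function(p) sort(p@divs))
  new_sets <- lapply(Filter(function(p) !p@fallback, res3$profiles),
                     function(p) sort(p@divs))
  for (s in prior_sets)
    expect_true(any(vapply(new_sets, identical, logical(1), s)))
})
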