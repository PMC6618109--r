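# Shared fixture builders (all data generated in code).

fix_config <- divProfiler::divConfig()
fix_refs <- divProfiler::bundledCladeRefs()
fix_catalogue <- divProfiler::bundledCatalogue()

cat_seq <- function(name) {
  fix_catalogue$sequence[match(name, fix_catalogue$name)]
}

# registry preloaded with a few catalogue sequences; returns registry and
# the uids of the requested names
toy_registry <- function(names = c("C3", "C3gulf", "C3c", "C3aq")) {
  reg <- divProfiler::newDivRegistry()
  uids <- vapply(names, function(nm)
    divProfiler::registerSequence(
      reg, cat_seq(nm), fix_catalogue$clade[match(nm, fix_catalogue$name)]),
    integer(1))
  list(registry = reg, uids = uids)
}

make_cc <- function(sample_id, clade, abundances,
                    min_collection_size = 200L) {
  divProfiler::cladeCollection(sample_id, clade, abundances,
                               min_collection_size)
}

make_footprint <- function(members, rel, source = "s|C", clade = "C") {
  structure(list(clade = clade, members = sort(as.integer(members)),
                 rel = rel, source = source), class = "Footprint")
}

make_profile <- function(uid, divs, mins, maxs, clade = "C",
                         majority = divs[1], name = paste0("P", uid),
                         fallback = FALSE,
                         support = c("a|C", "b|C", "c|C")) {
  rg <- rbind(min = mins, max = maxs)
  colnames(rg) <- as.character(divs)
  methods::new("TypeProfile", uid = as.integer(uid), clade = clade,
               divs = as.integer(divs),
               means = (mins + maxs) / 2, ranges = rg,
               majority_set = as.integer(majority), support = support,
               name = name, fallback = fallback)
}

# concrete primers as the simulator instantiates them
concrete_fwd <- "GAATTGCAGAACTCCGTGAACC"
concrete_rev <- "CGGGTTCACTTGTCTGACTTCATGC"
rc_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

make_amplicon <- function(insert) {
  paste0(concrete_fwd, insert, rc_chr(concrete_rev))
}

# perfect-quality read pair covering an amplicon with a given read length
perfect_pair <- function(amplicon, read_length = 200L) {
  fwd <- substr(amplicon, 1L, read_length)
  rev <- substr(rc_chr(amplicon), 1L, read_length)
  list(fwd = fwd, rev = rev,
       fq = strrep("I", read_length), rq = strrep("I", read_length))
}

write_fastq_pair <- function(pairs, dir = tempfile("fq")) {
  dir.create(dir, showWarnings = FALSE)
  ids <- sprintf("r%04d", seq_along(pairs$fwd))
  fwd <- file.path(dir, "s_R1.fastq")
  rev <- file.path(dir, "s_R2.fastq")
  divProfiler::writeFastq(ids, pairs$fwd, pairs$fq, fwd)
  divProfiler::writeFastq(ids, pairs$rev, pairs$rq, rev)
  list(fwd = fwd, rev = rev, dir = dir)
}
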