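## Standard-format IO: FASTQ pairs, sample sheets, count tables, FASTA,
## distance matrices and PCoA coordinates.

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `fwd`, `rev`; file paths are
#'   resolved relative to the sheet's directory when not absolute.
#' @return data.frame with absolute paths.
#' @export
readSampleSheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fwd", "rev")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                            file.path(base, p))
  sheet$fwd <- fix(sheet$fwd)
  sheet$rev <- fix(sheet$rev)
  sheet
}

#' Read one demultiplexed FASTQ pair
#'
#' Accepts plain or gzipped four-line FASTQ. Read identifiers (first
#' whitespace-delimited token) must pair up one-to-one between the files;
#' mismatched pairing raises an error listing the offending ids.
#'
#' @param fwd_file,rev_file forward / reverse FASTQ(.gz) paths.
#' @return list with `ids`, `fwd`, `rev` (character vectors) and
#'   `fwd_qual`, `rev_qual` (Phred+33 strings).
#' @export
readFastqPair <- function(fwd_file, rev_file) {
  # Biostrings warns when converting a QualityScaledDNAStringSet back to
  # plain character vectors (metadata columns dropped); that conversion is
  # exactly what we want here
  rd <- function(f) suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(f)
    list(ids = sub("\\s.*$", "", names(x)),
         seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
  })
  f <- rd(fwd_file); r <- rd(rev_file)
  if (length(f$ids) != length(r$ids))
    stop(sprintf("unequal read counts: %d forward vs %d reverse",
                 length(f$ids), length(r$ids)))
  if (!identical(f$ids, r$ids)) {
    bad <- union(setdiff(f$ids, r$ids), setdiff(r$ids, f$ids))
    if (!length(bad)) bad <- f$ids[f$ids != r$ids]
    stop("read pairing mismatch for ids: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  list(ids = f$ids, fwd = unname(f$seq), rev = unname(r$seq),
       fwd_qual = unname(f$qual), rev_qual = unname(r$qual))
}

#' Write a FASTQ file
#'
#' @param ids read identifiers.
#' @param seqs sequences.
#' @param quals Phred+33 quality strings.
#' @param path output path; a `.gz` suffix triggers compression.
#' @export
writeFastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(quals))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write the sequence count tables and FASTA
#'
#' Writes `<prefix>.seqs.absolute.tsv`, `<prefix>.seqs.relative.tsv` and
#' `<prefix>.seqs.fasta`. Rows are sequences in decreasing order of total
#' abundance across all samples; the first columns carry the sequence UID,
#' canonical name (UID where unnamed), clade and accession, followed by one
#' column per sample in sheet order. The relative table divides each sample
#' column by that sample's total. A `<prefix>.qc.tsv` with the per-sample
#' QC-retention counts accompanies the tables when `qc` is given.
#'
#' @param collections list of [CladeCollection-class] across samples.
#' @param registry a [DivRegistry-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param sample_ids column order; defaults to order of appearance.
#' @param qc optional per-sample QC data.frame.
#' @return invisible character vector of the written paths.
#' @export
writeSequenceCountTable <- function(collections, registry, dir,
                                    prefix = "output", sample_ids = NULL,
                                    qc = NULL) {
  if (is.null(sample_ids))
    sample_ids <- unique(vapply(collections, slot, character(1),
                                "sample_id"))
  uids <- sort(unique(as.integer(unlist(lapply(collections, function(cc)
    names(cc@abundances))))))
  abs_m <- matrix(0, length(uids), length(sample_ids),
                  dimnames = list(as.character(uids), sample_ids))
  for (cc in collections)
    abs_m[names(cc@abundances), cc@sample_id] <-
      abs_m[names(cc@abundances), cc@sample_id] + cc@abundances
  ord <- order(-rowSums(abs_m), as.integer(rownames(abs_m)))
  abs_m <- abs_m[ord, , drop = FALSE]
  uids <- uids[ord]
  meta <- data.frame(uid = uids, name = nameOf(registry, uids),
                     clade = cladeOf(registry, uids),
                     accession = registryTable(registry)$accession[
                       match(uids, registryTable(registry)$uid)],
                     stringsAsFactors = FALSE)
  totals <- colSums(abs_m)
  rel_m <- sweep(abs_m, 2L, pmax(totals, 1), "/")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_abs <- file.path(dir, paste0(prefix, ".seqs.absolute.tsv"))
  p_rel <- file.path(dir, paste0(prefix, ".seqs.relative.tsv"))
  p_fa <- file.path(dir, paste0(prefix, ".seqs.fasta"))
  write.table(cbind(meta, as.data.frame(abs_m, check.names = FALSE)),
              p_abs, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(meta, as.data.frame(rel_m, check.names = FALSE)),
              p_rel, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- Biostrings::DNAStringSet(sequenceOf(registry, uids))
  names(fa) <- meta$name
  Biostrings::writeXStringSet(fa, p_fa)
  paths <- c(p_abs, p_rel, p_fa)
  if (!is.null(qc)) {
    p_qc <- file.path(dir, paste0(prefix, ".qc.tsv"))
    write.table(qc, p_qc, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p_qc)
  }
  invisible(paths)
}

#' Write the profile count tables
#'
#' Writes `<prefix>.profiles.absolute.tsv` and
#' `<prefix>.profiles.relative.tsv`. One row per profile, in decreasing
#' order of the number of output samples the profile was found in, with the
#' profile UID, clade, majority sequence(s), associated species, local
#' abundance (samples in this output), database abundance (samples in the
#' whole store), profile name and DIV accession/UID list, followed by one
#' column per sample (absolute: summed DIV read counts; relative: fraction
#' of the sample as merged). The analysis UID is recorded in a `#` header
#' line.
#'
#' @param result a [runAnalysis()] result.
#' @param collections the analysed collections.
#' @param registry a [DivRegistry-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param analysis_uid analysis identifier written to the header.
#' @param store_assignments optional assignments data.frame from the whole
#'   store for the database-abundance column (defaults to this output).
#' @param species_rules species-association rules.
#' @return invisible character vector of written paths.
#' @export
writeProfileCountTable <- function(result, collections, registry, dir,
                                   prefix = "output", analysis_uid = 1L,
                                   store_assignments = NULL,
                                   species_rules = bundledSpeciesRules()) {
  asn <- result$assignments
  if (is.null(store_assignments)) store_assignments <- asn
  sample_ids <- unique(vapply(collections, slot, character(1), "sample_id"))
  profs <- result$profiles
  local_n <- vapply(profs, function(p)
    sum(asn$profile_uid == p@uid), integer(1))
  db_n <- vapply(profs, function(p)
    length(unique(store_assignments$sample_id[
      store_assignments$profile_uid == p@uid])), integer(1))
  ord <- order(-local_n, vapply(profs, slot, integer(1), "uid"))
  profs <- profs[ord]; local_n <- local_n[ord]; db_n <- db_n[ord]
  reg_tab <- registryTable(registry)
  div_list <- vapply(profs, function(p) {
    acc <- reg_tab$accession[match(p@divs, reg_tab$uid)]
    paste(ifelse(is.na(acc), as.character(p@divs), acc), collapse = ",")
  }, character(1))
  maj <- vapply(profs, function(p)
    paste(nameOf(registry, p@majority_set), collapse = "/"), character(1))
  species <- vapply(profs, function(p)
    paste(associateSpecies(p, species_rules, registry), collapse = ";"),
    character(1))
  meta <- data.frame(
    profile_uid = vapply(profs, slot, integer(1), "uid"),
    clade = vapply(profs, slot, character(1), "clade"),
    majority_its2_sequence = maj,
    associated_species = species,
    abundance_local = local_n,
    abundance_db = db_n,
    profile_name = vapply(profs, slot, character(1), "name"),
    div_accessions = div_list,
    stringsAsFactors = FALSE)
  cc_by <- split(collections, vapply(collections, slot, character(1),
                                     "sample_id"))
  abs_m <- matrix(0, length(profs), length(sample_ids),
                  dimnames = list(meta$profile_name, sample_ids))
  rel_m <- abs_m
  for (i in seq_along(profs)) {
    p <- profs[[i]]
    rows <- asn[asn$profile_uid == p@uid, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      sid <- rows$sample_id[k]
      rel_m[i, sid] <- rows$rel_abundance[k]
      for (cc in cc_by[[sid]]) {
        if (cc@clade != p@clade) next
        ids <- intersect(as.character(p@divs), names(cc@abundances))
        abs_m[i, sid] <- abs_m[i, sid] + sum(cc@abundances[ids])
      }
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_abs <- file.path(dir, paste0(prefix, ".profiles.absolute.tsv"))
  p_rel <- file.path(dir, paste0(prefix, ".profiles.relative.tsv"))
  hdr <- sprintf("# analysis_uid: %d", as.integer(analysis_uid))
  for (pp in list(list(p_abs, abs_m), list(p_rel, rel_m))) {
    con <- file(pp[[1]], "w")
    writeLines(hdr, con)
    write.table(cbind(meta, as.data.frame(pp[[2]], check.names = FALSE)),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(c(p_abs, p_rel))
}

#' Read back a count table written by this package
#'
#' @param path TSV path (a leading `#` header line is skipped).
#' @return data.frame.
#' @export
readCountTable <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write / read a distance matrix
#'
#' Square tab-delimited matrix with a label column and header.
#'
#' @param dm labelled symmetric matrix.
#' @param path TSV path.
#' @export
writeDistanceMatrix <- function(dm, path) {
  df <- data.frame(label = rownames(dm), dm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  m
}

#' Write distance and ordination outputs for analysed clades
#'
#' One matrix file and one PCoA coordinate file per clade, metric and
#' comparison level; file names encode all three
#' (`<level>_<metric>_<clade>.dist.tsv` / `.pcoa.tsv`). The PCoA file holds
#' one row per label plus a trailing eigenvalue row.
#'
#' @param collections analysed collections.
#' @param result [runAnalysis()] result (profile-level outputs).
#' @param registry registry.
#' @param dir output directory.
#' @param metrics metrics to compute.
#' @param levels comparison levels.
#' @return invisible character vector of written paths.
#' @export
writeDistanceOutputs <- function(collections, result, registry, dir,
                                 metrics = c("braycurtis", "unifrac"),
                                 levels = c("samples", "profiles")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clades <- sort(unique(vapply(collections, slot, character(1), "clade")))
  paths <- character(0)
  for (cl in clades) for (metric in metrics) for (level in levels) {
    dm <- tryCatch({
      if (level == "samples")
        sampleDistances(collections, cl, metric, registry)
      else profileDistances(result$profiles, cl, metric, registry)
    }, error = function(e) NULL)
    if (is.null(dm)) next
    stem <- file.path(dir, sprintf("%s_%s_%s", level, metric, cl))
    writeDistanceMatrix(dm, paste0(stem, ".dist.tsv"))
    pc <- pcoaOrdination(dm)
    coord <- data.frame(label = rownames(pc$points), pc$points,
                        check.names = FALSE)
    eig_row <- c("eigenvalues",
                 as.list(pc$eigenvalues[seq_len(ncol(pc$points))]))
    names(eig_row) <- names(coord)
    coord <- rbind(coord, as.data.frame(eig_row, check.names = FALSE))
    write.table(coord, paste0(stem, ".pcoa.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, paste0(stem, ".dist.tsv"), paste0(stem, ".pcoa.tsv"))
  }
  invisible(paths)
}
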