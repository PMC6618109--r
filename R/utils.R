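## Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats density rbinom rmultinom runif setNames
#' @importFrom utils adist head read.delim write.table
NULL

# IUPAC nucleotide codes -> base sets (used for primer matching).
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Reverse complement of plain character vectors, preserving IUPAC codes.
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split equal-length strings into a character matrix (one row per string).
.char_matrix <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(character(0), nrow = 0L))
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("strings must have equal length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = w, byrow = TRUE)
}

# Phred qualities (offset 33) as an integer matrix for equal-length strings.
.qual_matrix <- function(x) {
  n <- length(x)
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("quality strings must have equal length")
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = n, ncol = w,
         byrow = TRUE) - 33L
}

# Shannon entropy (bits) of a frequency/count vector.
.shannon <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1L) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Run a block with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic lexicographic comparison of two integer vectors.
# Returns -1, 0 or 1.
.lex_cmp <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) {
    d <- a[seq_len(k)] - b[seq_len(k)]
    nz <- which(d != 0)
    if (length(nz)) return(sign(d[nz[1L]]))
  }
  sign(length(a) - length(b))
}

# Connected components of an undirected graph given a logical adjacency matrix.
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      queue <- c(queue, nb)
    }
  }
  comp
}

# Uniformly random DNA string(s).
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

.stopifnot_dna <- function(x) {
  if (any(!grepl("^[ACGT]+$", x)))
    stop("sequences must be non-empty uppercase A/C/G/T strings")
  invisible(x)
}
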