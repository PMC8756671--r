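# Independent brute-force oracles used to cross-check the alignment-backed
# implementation. Pure-R dynamic programming; O(n*m), only for small inputs.

# Gotoh affine-gap alignment with free end gaps in both sequences.
# A gap of length L costs open + ext * L. Returns the optimal score.
oracle_overlap_score <- function(a, b, submat, open, ext) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in aligned pair
  X <- matrix(NEG, n + 1L, m + 1L)  # ends in gap consuming A (gap in B)
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends in gap consuming B (gap in A)
  M[1L, 1L] <- 0
  X[, 1L] <- 0  # free leading overhang of A
  Y[1L, ] <- 0  # free leading overhang of B
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- submat[A[i - 1L], B[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext,
                     Y[i - 1L, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext,
                     X[i, j - 1L] - open - ext)
    }
  }
  # free trailing overhangs: alignment may stop at the end of either sequence
  max(M[n + 1L, ], M[, m + 1L], X[n + 1L, ], X[, m + 1L],
      Y[n + 1L, ], Y[, m + 1L])
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Hamming identity for equal-length, gap-free pairs: the exact percent
# identity when the only differences are substitutions.
oracle_hamming_identity <- function(a, b) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  stopifnot(length(A) == length(B))
  100 * mean(A == B)
}

# Exhaustive reciprocal-best-hit matching on a Hamming identity matrix.
oracle_rbh <- function(dna, rna, threshold) {
  idm <- outer(seq_len(nrow(dna)), seq_len(nrow(rna)),
               Vectorize(function(i, j) {
                 oracle_hamming_identity(dna$sequence[i], rna$sequence[j])
               }))
  pairs <- list()
  for (i in seq_len(nrow(dna))) {
    j <- which.max(idm[i, ])
    if (which.max(idm[, j]) == i && idm[i, j] >= threshold) {
      pairs[[length(pairs) + 1L]] <- c(dna$gene_id[i], rna$gene_id[j])
    }
  }
  if (!length(pairs)) {
    return(tibble::tibble(dna_gene_id = character(), rna_gene_id = character()))
  }
  out <- do.call(rbind, pairs)
  tibble::tibble(dna_gene_id = out[, 1L], rna_gene_id = out[, 2L])
}

# random protein / dna helpers with local RNG use
rand_protein <- function(n, seed) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  withr::with_seed(seed, paste(sample(aa, n, TRUE), collapse = ""))
}

rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

# mutate a protein at given positions to fixed residues
with_residue <- function(protein, pos, res) {
  for (k in seq_along(pos)) substr(protein, pos[k], pos[k]) <- res[k]
  protein
}
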