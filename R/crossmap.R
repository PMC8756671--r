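#' Percent identity between two sequences
#'
#' Global alignment (match +2, mismatch -3, gap open 5, extend 2 for
#' nucleotides; BLOSUM62 with open 10 / extend 1 for proteins); identity
#' = 100 x identical columns / aligned columns, where terminal gap columns
#' (unmatched sequence ends) are excluded from both counts. The end-gap
#' exclusion lives in the identity metric rather than the alignment scoring:
#' a fully free-end-gap alignment of two unrelated sequences degenerates to a
#' few perfectly matching terminal residues and would report 100% identity.
#'
#' @param a,b Sequences (character scalars), same molecule type.
#' @param moltype `"nt"` (default) or `"aa"`.
#' @return A list with `percent_identity` and `aligned_columns`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")$percent_identity # 100
#' @export
pairwise_identity <- function(a, b, moltype = c("nt", "aa")) {
  moltype <- match.arg(moltype)
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  if (moltype == "nt") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
    pwa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  } else {
    pwa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
  }
  identity_from_alignment(as.character(Biostrings::alignedPattern(pwa)),
                          as.character(Biostrings::alignedSubject(pwa)))
}

# identity over the alignment core: terminal gap runs (unmatched ends) are
# dropped, internal gap columns count against identity
identity_from_alignment <- function(pat, sub) {
  p <- strsplit(pat, "")[[1L]]
  s <- strsplit(sub, "")[[1L]]
  core <- which(p != "-" & s != "-")
  if (length(core) == 0L) return(list(percent_identity = 0, aligned_columns = 0L))
  keep <- seq(core[1L], core[length(core)])
  cols <- length(keep)
  matches <- sum(p[keep] == s[keep] & p[keep] != "-")
  list(percent_identity = 100 * matches / cols, aligned_columns = cols)
}

#' Reciprocal-best-hit matching of two gene sets at an identity threshold
#'
#' Matches every metagenome (DNA) gene against every metatranscriptome (RNA)
#' gene by pairwise identity, keeps for each gene its best hit (ties broken by
#' higher identity, then more aligned columns, then lexicographic id), and
#' retains the pairs that are mutual best hits with identity at or above the
#' threshold — so DNA- and RNA-level abundances can be compared gene by gene.
#'
#' @param dna,rna Data frames with `gene_id` and `sequence` (same moltype),
#'   or named character vectors of sequences.
#' @param threshold Minimum percent identity to retain a pair (default 95).
#' @param moltype `"nt"` or `"aa"`.
#' @return Tibble `dna_gene_id`, `rna_gene_id`, `percent_identity`,
#'   `aligned_columns`, `reciprocal_best` (all TRUE in the retained set).
#' @export
reciprocal_match <- function(dna, rna, threshold = 95, moltype = c("nt", "aa")) {
  moltype <- match.arg(moltype)
  dna <- as_seq_tbl(dna)
  rna <- as_seq_tbl(rna)
  if (nrow(dna) == 0L || nrow(rna) == 0L) abort("both gene sets must be non-empty")
  if (moltype == "nt") {
    patterns <- Biostrings::DNAStringSet(setNames(dna$sequence, dna$gene_id))
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                       baseOnly = FALSE)
    go <- 5; ge <- 2
  } else {
    patterns <- Biostrings::AAStringSet(setNames(dna$sequence, dna$gene_id))
    submat <- "BLOSUM62"
    go <- 10; ge <- 1
  }
  hits <- purrr::map_dfr(seq_len(nrow(rna)), function(j) {
    subj <- if (moltype == "nt") Biostrings::DNAString(rna$sequence[j])
            else Biostrings::AAString(rna$sequence[j])
    pwa <- Biostrings::pairwiseAlignment(patterns, subj, type = "global",
                                         substitutionMatrix = submat,
                                         gapOpening = go, gapExtension = ge)
    pats <- as.character(Biostrings::alignedPattern(pwa))
    subs <- as.character(Biostrings::alignedSubject(pwa))
    ids <- purrr::map2(pats, subs, identity_from_alignment)
    tibble(dna_gene_id = dna$gene_id,
           rna_gene_id = rna$gene_id[j],
           percent_identity = vapply(ids, `[[`, numeric(1), "percent_identity"),
           aligned_columns = vapply(ids, `[[`, numeric(1), "aligned_columns"))
  })
  best_by <- function(df, keycol, othercol) {
    df |>
      arrange(.data[[keycol]], dplyr::desc(.data$percent_identity),
              dplyr::desc(.data$aligned_columns), .data[[othercol]]) |>
      dplyr::distinct(.data[[keycol]], .keep_all = TRUE)
  }
  best_d <- best_by(hits, "dna_gene_id", "rna_gene_id")
  best_r <- best_by(hits, "rna_gene_id", "dna_gene_id")
  out <- inner_join(
    best_d |> select("dna_gene_id", "rna_gene_id", "percent_identity", "aligned_columns"),
    best_r |> select("dna_gene_id", "rna_gene_id"),
    by = c("dna_gene_id", "rna_gene_id")
  ) |>
    filter(.data$percent_identity >= threshold) |>
    mutate(reciprocal_best = TRUE) |>
    arrange(.data$dna_gene_id)
  out
}

as_seq_tbl <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) abort("sequence vectors must be named by gene id")
    return(tibble(gene_id = names(x), sequence = unname(x)))
  }
  as_tibble(x)[, c("gene_id", "sequence")]
}
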