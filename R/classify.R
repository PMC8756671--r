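#' Alignment and quality-gate parameters for tolerance classification
#'
#' @param gap_opening,gap_extension Affine gap costs (positive penalties) for
#'   the end-gap-free global protein alignment.
#' @param substitution_matrix Name of the scoring matrix (passed to
#'   [Biostrings::pairwiseAlignment()]).
#' @param min_identity Minimum fraction of identical aligned columns for a
#'   confident residue read; alignments below are flagged low-confidence and
#'   the gene is called `indeterminate`.
#' @param min_columns Minimum number of aligned columns for a confident read.
#' @param min_orf_aa Minimum length (aa) of a stop-free translated segment to
#'   be considered a candidate open reading frame.
#'
#' @return A list of class `bglccr_aln_params`.
#' @export
alignment_params <- function(gap_opening = 10, gap_extension = 1,
                             substitution_matrix = "BLOSUM62",
                             min_identity = 0.30, min_columns = 150,
                             min_orf_aa = 100) {
  structure(list(gap_opening = gap_opening, gap_extension = gap_extension,
                 substitution_matrix = substitution_matrix,
                 min_identity = min_identity, min_columns = min_columns,
                 min_orf_aa = min_orf_aa),
            class = "bglccr_aln_params")
}

#' Six-frame translation candidates of a nucleotide sequence
#'
#' Translates all six reading frames, splits each translation at stop codons
#' and keeps the stop-free segments long enough to be plausible GH1 fragments.
#' Codons containing ambiguity letters translate to `X`.
#'
#' @param sequence Nucleotide sequence (character scalar).
#' @param min_orf_aa Minimum segment length in amino acids (default 100; use 1
#'   to keep every segment).
#'
#' @return A tibble with columns `frame` (`"+1"`..`"-3"`) and `protein`,
#'   one row per retained stop-free segment.
#' @examples
#' translate_candidates("ATGTGGAAA", min_orf_aa = 1)
#' @export
translate_candidates <- function(sequence, min_orf_aa = 100) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single nucleotide string")
  }
  if (nchar(sequence) < 3L) {
    abort("sequence shorter than one codon cannot be translated")
  }
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  fuzzy <- grepl("[^ACGT]", toupper(sequence))
  frames <- character(6L)
  names(frames) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (off in 1:3) {
    frames[[paste0("+", off)]] <- frame_translation(fwd, off, fuzzy)
    frames[[paste0("-", off)]] <- frame_translation(rev, off, fuzzy)
  }
  segments <- lapply(frames, strsplit, split = "*", fixed = TRUE)
  out <- tibble(
    frame = rep(names(frames), lengths(purrr::map(segments, ~ .x[[1L]]))),
    protein = unlist(lapply(segments, `[[`, 1L), use.names = FALSE)
  )
  filter(out, nchar(.data$protein) >= min_orf_aa)
}

frame_translation <- function(dna, offset, fuzzy = FALSE) {
  len <- length(dna) - offset + 1L
  if (len < 3L) return("")
  sub <- Biostrings::subseq(dna, start = offset,
                            width = len - (len %% 3L))
  if (fuzzy) {
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
  } else {
    as.character(Biostrings::translate(sub))
  }
}

#' Anchor a protein candidate set to the reference by pairwise alignment
#'
#' Aligns every candidate protein against the reference with an end-gap-free
#' (overlap) global alignment and keeps the highest-scoring candidate. The
#' aligned columns give a map from reference positions to query residues, so
#' residues can be read off at the discriminating positions.
#'
#' @param candidates Tibble with columns `frame`, `protein` (see
#'   [translate_candidates()]); for protein input use a single row with
#'   `frame = "aa"`.
#' @param reference A [gh1_reference()] object.
#' @param params An [alignment_params()] object.
#'
#' @return A list of class `bglccr_anchor` with elements `frame`, `score`,
#'   `identity` (fraction), `columns`, `passes_gates` (logical) and
#'   `residue_at(pos)` lookups materialised in `residues` (named character,
#'   one entry per reference position covered; `NA` means uncovered).
#' @export
anchor_to_reference <- function(candidates, reference, params = alignment_params()) {
  stopifnot(inherits(reference, "gh1_reference"))
  candidates <- candidates[nchar(candidates$protein) > 0L, , drop = FALSE]
  if (nrow(candidates) == 0L) {
    abort("no candidate protein to anchor (all frames empty after stop-codon splitting)",
          class = "bglccr_no_candidate")
  }
  ref_aa <- Biostrings::AAString(reference$ref_protein)
  alns <- purrr::map(candidates$protein, function(p) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(p), subject = ref_aa, type = "overlap",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_opening, gapExtension = params$gap_extension
    )
  })
  scores <- vapply(alns, Biostrings::score, numeric(1))
  best <- which.max(scores)
  pwa <- alns[[best]]
  cols <- Biostrings::nchar(pwa)
  identity <- if (cols > 0) Biostrings::nmatch(pwa) / cols else 0
  res_map <- reference_residue_map(pwa, nchar(reference$ref_protein))
  structure(
    list(frame = candidates$frame[best],
         query_protein = candidates$protein[best],
         score = scores[best],
         identity = identity,
         columns = cols,
         passes_gates = identity >= params$min_identity && cols >= params$min_columns,
         residues = res_map),
    class = "bglccr_anchor"
  )
}

# Walk aligned columns: reference position -> query residue ("-" for a gap
# column, NA outside the aligned region).
reference_residue_map <- function(pwa, ref_len) {
  ap <- strsplit(as.character(Biostrings::alignedPattern(pwa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pwa)), "")[[1L]]
  res <- rep(NA_character_, ref_len)
  pos <- Biostrings::start(Biostrings::subject(pwa)) - 1L
  for (k in seq_along(as_)) {
    if (as_[k] != "-") {
      pos <- pos + 1L
      res[pos] <- ap[k]
    }
  }
  res
}

#' Call glucose tolerance from anchored residues
#'
#' A gene is `glucose_tolerant` when every discriminating position carries its
#' required residue (by default Trp at 168 and Leu at 173), `non_tolerant`
#' when all positions are covered by non-gap, unambiguous residues but at
#' least one differs, and `indeterminate` when the alignment failed the
#' quality gates or any position is uncovered, gapped or ambiguous
#' (`X`/`B`/`Z`/`J`).
#'
#' @param anchored A `bglccr_anchor` object (or `NULL` for a gene with no
#'   usable frame, which yields `indeterminate`).
#' @param reference A [gh1_reference()] object.
#'
#' @return A one-row tibble: `frame`, one `residue_<pos>` column per
#'   discriminating position, `call`, `identity`, `score`.
#' @export
call_tolerance <- function(anchored, reference) {
  pos <- as.integer(names(reference$positions))
  req <- unname(reference$positions)
  res_cols <- setNames(rep("-", length(pos)), paste0("residue_", pos))
  if (is.null(anchored)) {
    return(tibble(frame = NA_character_, !!!as.list(res_cols),
                  call = "indeterminate", identity = NA_real_, score = NA_real_))
  }
  res <- anchored$residues[pos]
  res[is.na(res)] <- "-"
  res_cols[] <- res
  ambiguous <- res %in% c("X", "B", "Z", "J", "*")
  if (!anchored$passes_gates || any(res == "-") || any(ambiguous)) {
    call <- "indeterminate"
  } else if (all(res == req)) {
    call <- "glucose_tolerant"
  } else {
    call <- "non_tolerant"
  }
  tibble(frame = anchored$frame, !!!as.list(res_cols), call = call,
         identity = anchored$identity, score = anchored$score)
}

#' Classify genes as glucose tolerant or not from their sequences
#'
#' End-to-end residue-based classification: nucleotide records are translated
#' in six frames, split at stop codons, anchored to the reference by pairwise
#' alignment, and the residues aligned to the discriminating positions decide
#' the call. Protein records skip translation.
#'
#' @param genes A data frame with columns `gene_id`, `sequence` and optionally
#'   `moltype` (`"nt"` or `"aa"`; guessed from the alphabet when absent) and
#'   `taxon`.
#' @param reference A [gh1_reference()] object.
#' @param params An [alignment_params()] object.
#'
#' @return A tibble with one row per input gene, in input order: `gene_id`,
#'   `moltype`, `frame`, `residue_<pos>` columns, `call`, `identity`, `score`
#'   (plus `taxon` when supplied).
#' @examples
#' ref <- gh1_reference()
#' genes <- tibble::tibble(gene_id = "ref", sequence = ref$ref_protein, moltype = "aa")
#' classify_genes(genes, ref)$call # "glucose_tolerant"
#' @export
classify_genes <- function(genes, reference = gh1_reference(),
                           params = alignment_params()) {
  genes <- as_tibble(genes)
  if (!all(c("gene_id", "sequence") %in% names(genes))) {
    abort("`genes` needs columns `gene_id` and `sequence`")
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    abort(paste0("duplicate gene_id in input: ", paste(dup, collapse = ", ")))
  }
  if (!"moltype" %in% names(genes)) {
    genes$moltype <- vapply(genes$sequence, guess_moltype, character(1))
  }
  if (nrow(genes) == 0L) {
    pos <- as.integer(names(reference$positions))
    empty <- tibble(gene_id = character(), moltype = character(),
                    frame = character())
    for (p in pos) empty[[paste0("residue_", p)]] <- character()
    empty$call <- character()
    empty$identity <- numeric()
    empty$score <- numeric()
    return(empty)
  }
  calls <- purrr::map2_dfr(genes$sequence, genes$moltype, function(s, mt) {
    cand <- if (identical(mt, "aa")) {
      tibble(frame = "aa", protein = toupper(s))
    } else {
      translate_candidates(s, min_orf_aa = params$min_orf_aa)
    }
    anchored <- tryCatch(
      anchor_to_reference(cand, reference, params),
      bglccr_no_candidate = function(e) NULL
    )
    call_tolerance(anchored, reference)
  })
  out <- bind_rows(calls)
  out <- tibble(gene_id = genes$gene_id, moltype = genes$moltype, out)
  if ("taxon" %in% names(genes)) out$taxon <- genes$taxon
  out
}

guess_moltype <- function(s) {
  letters_used <- unique(strsplit(toupper(s), "")[[1L]])
  if (all(letters_used %in% c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W",
                              "K", "M", "B", "D", "H", "V", "-"))) "nt" else "aa"
}

#' Classify a FASTA file of beta-glucosidase genes
#'
#' Reads nucleotide or protein FASTA (taxon lineage may follow a `|` in the
#' header as semicolon-separated ranks) and runs [classify_genes()].
#'
#' @param path FASTA path.
#' @param reference,params See [classify_genes()].
#' @param moltype `"auto"` (default), `"nt"` or `"aa"`.
#'
#' @return The [classify_genes()] tibble; `summary(attr(x, "counts"))` — the
#'   tibble carries a `counts` attribute with per-call totals.
#' @export
classify_fasta <- function(path, reference = gh1_reference(),
                           params = alignment_params(), moltype = "auto") {
  genes <- read_gene_fasta(path, moltype = moltype)
  out <- classify_genes(genes, reference, params)
  attr(out, "counts") <- dplyr::count(out, .data$call, name = "n_genes")
  out
}

#' Read a gene FASTA into a tibble
#'
#' @param path FASTA path.
#' @param moltype `"auto"`, `"nt"` or `"aa"`.
#' @return Tibble with `gene_id`, `sequence`, `moltype` and `taxon` (NA when
#'   the header carries no `|`-separated lineage).
#' @export
read_gene_fasta <- function(path, moltype = "auto") {
  set <- tryCatch(
    if (identical(moltype, "aa")) Biostrings::readAAStringSet(path)
    else Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("cannot read FASTA ", path, ": ", conditionMessage(e)))
  )
  if (length(set) == 0L) {
    return(tibble(gene_id = character(), sequence = character(),
                  moltype = character(), taxon = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", sub("\\|.*$", "", headers))
  taxon <- ifelse(grepl("|", headers, fixed = TRUE),
                  trimws(sub("^[^|]*\\|", "", headers)), NA_character_)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record id in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as.character(set)
  mt <- if (identical(moltype, "auto")) {
    vapply(seqs, guess_moltype, character(1), USE.NAMES = FALSE)
  } else rep(moltype, length(seqs))
  tibble(gene_id = ids, sequence = unname(seqs), moltype = mt, taxon = taxon)
}

#' Write tolerance calls to TSV
#'
#' @param calls Tibble from [classify_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}
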