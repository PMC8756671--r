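#' Simulate GH1 beta-glucosidase gene sequences with planted tolerance labels
#'
#' Builds genes from the reference protein: random substitutions at
#' non-discriminating positions at the configured per-site rate, with
#' glucose-tolerant genes keeping Trp168/Leu173 and non-tolerant genes having
#' one or both residues ablated to a random non-required amino acid. Each
#' protein is reverse-translated with uniform codon choice (emulating the
#' ~1100-1200 bp amplicons of a functional-gene clone library) and placed on a
#' random strand. The planted labels are returned as ground truth.
#'
#' @param n_genes Number of genes (default 100).
#' @param fraction_gt Fraction of glucose-tolerant genes (default 0.5).
#' @param mutation_rate Per-site substitution probability at
#'   non-discriminating positions (default 0.05). Rates >= 0.5 are refused:
#'   they destroy the homology the classifier's identity gate requires.
#' @param reference A [gh1_reference()] object.
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG stream
#'   (single-stream Monte-Carlo designs).
#' @return List with `genes` (tibble `gene_id`, `sequence`, `moltype`) and
#'   `truth` (tibble `gene_id`, `label`, `strand`, `n_substitutions`), plus
#'   `params`.
#' @examples
#' sim <- sim_sequences(n_genes = 4, seed = 1)
#' sim$truth
#' @export
sim_sequences <- function(n_genes = 100, fraction_gt = 0.5, mutation_rate = 0.05,
                          reference = gh1_reference(), seed = 1) {
  if (fraction_gt < 0 || fraction_gt > 1) abort("fraction_gt must be in [0, 1]")
  if (mutation_rate >= 0.5) {
    abort("mutation_rate >= 0.5 refused: simulated genes would no longer be recognisable homologs")
  }
  ref_chars <- strsplit(reference$ref_protein, "")[[1L]]
  disc_pos <- as.integer(names(reference$positions))
  req <- unname(reference$positions)
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  n_gt <- round(n_genes * fraction_gt)
  withr_seed(seed, {
    labels <- sample(rep(c("glucose_tolerant", "non_tolerant"),
                         c(n_gt, n_genes - n_gt)))
    ids <- sprintf("gene_%03d", seq_len(n_genes))
    recs <- purrr::map(seq_len(n_genes), function(i) {
      p <- ref_chars
      mutable <- setdiff(seq_along(p), disc_pos)
      hit <- mutable[stats::runif(length(mutable)) < mutation_rate]
      for (k in hit) p[k] <- sample(setdiff(aa20, p[k]), 1L)
      if (labels[i] == "non_tolerant") {
        which_ablate <- sample(c("first", "second", "both"), 1L)
        abl <- switch(which_ablate, first = 1L, second = 2L, both = 1:2)
        for (k in abl) p[disc_pos[k]] <- sample(setdiff(aa20, req[k]), 1L)
      } else {
        p[disc_pos] <- req
      }
      dna <- reverse_translate(p)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
      }
      list(sequence = dna, protein = paste(p, collapse = ""),
           strand = strand, n_sub = length(hit))
    })
    list(
      genes = tibble(gene_id = ids,
                     sequence = purrr::map_chr(recs, "sequence"),
                     moltype = "nt"),
      truth = tibble(gene_id = ids, label = labels,
                     protein = purrr::map_chr(recs, "protein"),
                     strand = purrr::map_chr(recs, "strand"),
                     n_substitutions = purrr::map_int(recs, "n_sub")),
      params = list(n_genes = n_genes, fraction_gt = fraction_gt,
                    mutation_rate = mutation_rate, seed = seed)
    )
  })
}

reverse_translate <- function(protein_chars) {
  codons <- codon_choices()
  paste(vapply(protein_chars, function(a) {
    opts <- codons[[a]]
    if (is.null(opts)) abort(paste0("no codon for residue ", a))
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

codon_choices <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Simulate paired DNA and RNA abundance tables with planted TE effects
#'
#' Each gene gets a lognormal DNA baseline and a lognormal base transcription
#' efficiency. Expected RNA abundance is `DNA x baseTE x effect(gene,
#' treatment)` where the effect multiplier is `f_up` for glucose-tolerant
#' genes under high-glucose treatments (transcriptional up-regulation under
#' carbon catabolite repression), `f_down` for non-tolerant genes there
#' (repression of the ordinary hydrolytic enzymes), and 1 elsewhere. Observed
#' values multiply the expectation by mean-one lognormal noise per replicate.
#' With `depth` set, each sample is scaled to that total and rounded to
#' counts, emulating compositional sequencing read abundances; left `NULL`
#' the tables behave like absolute copy numbers (the qPCR situation).
#'
#' @param truth Tibble with `gene_id` and `label` (from [sim_sequences()], or
#'   any planted labelling).
#' @param treatments Treatment design tibble; default [treatment_design()].
#' @param f_up TE multiplier for glucose-tolerant genes under high glucose
#'   (default 2).
#' @param f_down TE multiplier for non-tolerant genes under high glucose
#'   (default 0.5).
#' @param base_te_meanlog,base_te_sdlog Lognormal parameters of per-gene base
#'   TE (default meanlog 0, sdlog 0.5).
#' @param dna_meanlog,dna_sdlog Lognormal parameters of per-gene DNA baseline
#'   (default meanlog log(100), sdlog 1).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   observation noise (default 0.2; 0 = noiseless).
#' @param n_replicates Replicates per treatment (default 1; use 3 for
#'   qPCR-style tables).
#' @param depth Target sample total for count scaling, or `NULL` (default)
#'   for absolute values.
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG stream
#'   (single-stream Monte-Carlo designs).
#' @return List of class `bglccr_sim`: `dna`, `rna` (long tibbles `sample`,
#'   `treatment`, `gene_id`, `abundance`, `level`), `truth` (input truth plus
#'   `base_te`), `effects` (tibble `gene_id`, `treatment`, `effect`), `params`.
#' @export
sim_abundance <- function(truth, treatments = treatment_design(),
                          f_up = 2, f_down = 0.5,
                          base_te_meanlog = 0, base_te_sdlog = 0.5,
                          dna_meanlog = log(100), dna_sdlog = 1,
                          noise_cv = 0.2, n_replicates = 1, depth = NULL,
                          seed = 1) {
  if (!(f_up >= 1 && 1 >= f_down && f_down > 0)) {
    abort("effect multipliers must satisfy f_up >= 1 >= f_down > 0")
  }
  genes <- truth$gene_id
  n_g <- length(genes)
  sdlog_noise <- sqrt(log(1 + noise_cv^2))
  withr_seed(seed, {
    base_dna <- rlnorm(n_g, dna_meanlog, dna_sdlog)
    base_te <- rlnorm(n_g, base_te_meanlog, base_te_sdlog)
    effects <- tidyr::expand_grid(gene_id = genes,
                                  treatment = treatments$treatment) |>
      left_join(truth[, c("gene_id", "label")], by = "gene_id") |>
      left_join(treatments[, c("treatment", "is_high_glucose")], by = "treatment") |>
      mutate(effect = dplyr::case_when(
        .data$is_high_glucose & .data$label == "glucose_tolerant" ~ f_up,
        .data$is_high_glucose & .data$label == "non_tolerant" ~ f_down,
        TRUE ~ 1
      )) |>
      select("gene_id", "treatment", "effect")
    grid <- tidyr::expand_grid(treatment = treatments$treatment,
                               replicate = seq_len(n_replicates),
                               gene_id = genes) |>
      mutate(sample = if (n_replicates > 1L) {
        paste0(.data$treatment, "_r", .data$replicate)
      } else .data$treatment) |>
      left_join(effects, by = c("gene_id", "treatment")) |>
      left_join(tibble(gene_id = genes, .dna0 = base_dna, .te0 = base_te),
                by = "gene_id")
    noise <- function(n) {
      if (noise_cv == 0) rep(1, n) else rlnorm(n, -sdlog_noise^2 / 2, sdlog_noise)
    }
    dna <- grid |>
      mutate(abundance = .data$.dna0 * noise(dplyr::n()), level = "DNA") |>
      select("sample", "treatment", "gene_id", "abundance", "level")
    rna <- grid |>
      mutate(abundance = .data$.dna0 * .data$.te0 * .data$effect * noise(dplyr::n()),
             level = "RNA") |>
      select("sample", "treatment", "gene_id", "abundance", "level")
    if (!is.null(depth)) {
      rescale <- function(df) {
        df |>
          group_by(.data$sample) |>
          mutate(abundance = round(.data$abundance / sum(.data$abundance) * depth)) |>
          ungroup()
      }
      dna <- rescale(dna)
      rna <- rescale(rna)
    }
    structure(
      list(dna = dna, rna = rna,
           truth = truth |> mutate(base_te = base_te, base_dna = base_dna),
           effects = effects,
           params = list(f_up = f_up, f_down = f_down, noise_cv = noise_cv,
                         n_replicates = n_replicates, depth = depth,
                         seed = seed)),
      class = "bglccr_sim"
    )
  })
}

#' Simulate triplicate qPCR copy-number tables
#'
#' Convenience wrapper around [sim_abundance()]: absolute copy numbers (no
#' depth scaling), three replicates per treatment with multiplicative
#' lognormal replicate noise — the layout of gene-specific qPCR assays run on
#' DNA and cDNA templates in triplicate.
#'
#' @inheritParams sim_abundance
#' @param n_replicates Default 3.
#' @return See [sim_abundance()].
#' @export
sim_qpcr <- function(truth, treatments = treatment_design(), f_up = 2,
                     f_down = 0.5, noise_cv = 0.2, n_replicates = 3, seed = 1,
                     ...) {
  sim_abundance(truth, treatments = treatments, f_up = f_up, f_down = f_down,
                noise_cv = noise_cv, n_replicates = n_replicates, depth = NULL,
                seed = seed, ...)
}

#' Simulate taxon abundance profiles with a planted block correlation structure
#'
#' Samples share a latent environmental factor; taxa in odd blocks follow it
#' and taxa in even blocks oppose it, plus independent Gaussian noise. Taxa
#' within a block are therefore positively correlated, and across adjacent
#' blocks negatively — the ground truth for co-occurrence network recovery.
#'
#' @param n_blocks Number of blocks (default 2).
#' @param taxa_per_block Taxa per block (default 5).
#' @param n_samples Number of samples (default 20).
#' @param noise_sd SD of the additive noise (default 0.1; latent factor has
#'   SD 1).
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG stream
#'   (single-stream Monte-Carlo designs).
#' @return List: `profiles` (taxa x samples matrix), `truth` (tibble `taxon`,
#'   `block`), `params`.
#' @export
sim_block_profiles <- function(n_blocks = 2, taxa_per_block = 5,
                               n_samples = 20, noise_sd = 0.1, seed = 1) {
  withr_seed(seed, {
    z <- rnorm(n_samples)
    taxa <- sprintf("taxon_%02d", seq_len(n_blocks * taxa_per_block))
    block <- rep(seq_len(n_blocks), each = taxa_per_block)
    sign <- ifelse(block %% 2L == 1L, 1, -1)
    profiles <- t(vapply(seq_along(taxa), function(i) {
      sign[i] * z + rnorm(n_samples, sd = noise_sd)
    }, numeric(n_samples)))
    rownames(profiles) <- taxa
    colnames(profiles) <- sprintf("sample_%02d", seq_len(n_samples))
    list(profiles = profiles,
         truth = tibble(taxon = taxa, block = block),
         params = list(n_blocks = n_blocks, taxa_per_block = taxa_per_block,
                       n_samples = n_samples, noise_sd = noise_sd, seed = seed))
  })
}

#' Make mutated copies of genes at exact target identities
#'
#' For cross-mapping experiments: each selected gene is copied with exactly
#' `round((1 - identity) * length)` substitutions at distinct positions, so
#' the nucleotide identity of the copy to its source is known by construction.
#'
#' @param genes Tibble with `gene_id`, `sequence` (nucleotide).
#' @param identities Numeric vector in (0, 1\]; recycled over `genes` rows
#'   selected by `which`.
#' @param which Row indices of genes to copy (default all).
#' @param suffix Appended to the copied gene ids (default "_rna").
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG stream
#'   (single-stream Monte-Carlo designs).
#' @return Tibble `gene_id`, `sequence`, `source_id`, `target_identity`.
#' @export
sim_mutated_copies <- function(genes, identities, which = seq_len(nrow(genes)),
                               suffix = "_rna", seed = 1) {
  stopifnot(length(identities) == length(which))
  bases <- c("A", "C", "G", "T")
  withr_seed(seed, {
    purrr::map2_dfr(which, identities, function(i, ident) {
      s <- strsplit(genes$sequence[i], "")[[1L]]
      k <- round((1 - ident) * length(s))
      pos <- sample(seq_along(s), k)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
      tibble(gene_id = paste0(genes$gene_id[i], suffix),
             sequence = paste(s, collapse = ""),
             source_id = genes$gene_id[i],
             target_identity = 100 * (1 - k / length(s)))
    })
  })
}

#' Write simulated genes to FASTA
#'
#' @param genes Tibble with `gene_id`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  set <- Biostrings::BStringSet(setNames(genes$sequence, genes$gene_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a long abundance tibble as a samples-by-genes TSV
#'
#' Inverse of [read_abundance_tsv()].
#'
#' @param df Long tibble (`sample`, `gene_id`, `abundance`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(df, path) {
  wide <- df |>
    select("sample", "gene_id", "abundance") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "abundance")
  readr::write_tsv(wide, path)
  invisible(path)
}
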