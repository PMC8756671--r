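ref <- gh1_reference()

test_that("six-frame translation finds the expected peptides", {
  cand <- translate_candidates("ATGTGG", min_orf_aa = 1)
  expect_true("MW" %in% cand$protein[cand$frame == "+1"])

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGTGG")))
  cand_rc <- translate_candidates(rc, min_orf_aa = 1)
  expect_true("MW" %in% cand_rc$protein[startsWith(cand_rc$frame, "-")])

  expect_error(translate_candidates("AT"), "codon")
})

test_that("stop codons split translations into segments", {
  # M W * M W -> two 2-aa segments in frame +1
  cand <- translate_candidates("ATGTGGTAAATGTGG", min_orf_aa = 1)
  plus1 <- cand$protein[cand$frame == "+1"]
  expect_equal(sort(plus1), c("MW", "MW"))
  expect_false(any(grepl("\\*", cand$protein)))
})

test_that("the reference anchors to itself with a perfect position map", {
  anchored <- anchor_to_reference(
    tibble::tibble(frame = "aa", protein = ref$ref_protein), ref)
  expect_identical(anchored$residues,
                   strsplit(ref$ref_protein, "")[[1]])
  expect_equal(anchored$identity, 1)
  call <- call_tolerance(anchored, ref)
  expect_equal(call$call, "glucose_tolerant")
  expect_equal(call$residue_168, "W")
  expect_equal(call$residue_173, "L")
})

test_that("N-terminal truncation shifts positions through gap columns", {
  trunc <- substr(ref$ref_protein, 6, nchar(ref$ref_protein))
  anchored <- anchor_to_reference(tibble::tibble(frame = "aa", protein = trunc), ref)
  expect_equal(anchored$residues[168], "W")
  expect_equal(anchored$residues[173], "L")
  expect_true(all(is.na(anchored$residues[1:5])))
  # selected score matches the independent DP aligner on this pair
  expect_equal(anchored$score,
               oracle_overlap_score(trunc, ref$ref_protein, blosum62, 10, 1))
  expect_equal(call_tolerance(anchored, ref)$call, "glucose_tolerant")
})

test_that("residue rule distinguishes tolerant, non-tolerant and gapped genes", {
  w168a <- with_residue(ref$ref_protein, 168, "A")
  expect_equal(classify_genes(
    tibble::tibble(gene_id = "m", sequence = w168a, moltype = "aa"), ref)$call,
    "non_tolerant")

  l173p <- with_residue(ref$ref_protein, 173, "P")
  expect_equal(classify_genes(
    tibble::tibble(gene_id = "m", sequence = l173p, moltype = "aa"), ref)$call,
    "non_tolerant")

  # deletion spanning position 173 -> gap column -> indeterminate
  gapped <- paste0(substr(ref$ref_protein, 1, 169),
                   substr(ref$ref_protein, 178, nchar(ref$ref_protein)))
  res <- classify_genes(
    tibble::tibble(gene_id = "d", sequence = gapped, moltype = "aa"), ref)
  expect_equal(res$call, "indeterminate")

  # ambiguity character at a discriminating position -> indeterminate
  amb <- with_residue(ref$ref_protein, 168, "X")
  expect_equal(classify_genes(
    tibble::tibble(gene_id = "x", sequence = amb, moltype = "aa"), ref)$call,
    "indeterminate")
})

test_that("unrelated sequences fail the identity gate", {
  rnd <- rand_protein(nchar(ref$ref_protein), seed = 99)
  res <- classify_genes(
    tibble::tibble(gene_id = "rnd", sequence = rnd, moltype = "aa"), ref)
  expect_equal(res$call, "indeterminate")
  expect_lt(res$identity, 0.30)
})

test_that("selected alignment score equals the brute-force DP optimum", {
  short_ref <- gh1_reference(positions = c("168" = "W", "173" = "L"))
  short_ref$ref_protein <- substr(short_ref$ref_protein, 1, 250)
  cases <- list(
    substr(short_ref$ref_protein, 10, 240),
    with_residue(substr(short_ref$ref_protein, 1, 250), c(20, 60, 110), c("A", "G", "K")),
    paste0(substr(short_ref$ref_protein, 1, 100), substr(short_ref$ref_protein, 121, 250)),
    rand_protein(200, seed = 3)
  )
  for (q in cases) {
    anchored <- anchor_to_reference(tibble::tibble(frame = "aa", protein = q),
                                    short_ref)
    expect_equal(anchored$score,
                 oracle_overlap_score(q, short_ref$ref_protein, blosum62, 10, 1))
  }
})

test_that("classification of simulated genes recovers every planted label", {
  sim <- sim_sequences(n_genes = 100, fraction_gt = 0.5, seed = 11)
  calls <- classify_genes(sim$genes, ref)
  expect_equal(calls$gene_id, sim$truth$gene_id)
  expect_equal(calls$call, sim$truth$label)
  expect_equal(sum(calls$call == "glucose_tolerant"), 50)
})

test_that("reverse-complementing a gene never changes its call", {
  sim <- sim_sequences(n_genes = 12, seed = 21)
  calls <- classify_genes(sim$genes, ref)
  rc <- sim$genes
  rc$sequence <- vapply(rc$sequence, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  expect_equal(classify_genes(rc, ref)$call, calls$call)
})

test_that("protein records give the same calls as their nucleotide genes", {
  sim <- sim_sequences(n_genes = 10, seed = 31)
  nt_calls <- classify_genes(sim$genes, ref)
  aa_calls <- classify_genes(
    tibble::tibble(gene_id = sim$truth$gene_id, sequence = sim$truth$protein,
                   moltype = "aa"), ref)
  expect_equal(aa_calls$call, nt_calls$call)
})

test_that("classification is deterministic", {
  sim <- sim_sequences(n_genes = 8, seed = 41)
  expect_identical(classify_genes(sim$genes, ref), classify_genes(sim$genes, ref))
})

test_that("classify_fasta round-trips files and rejects bad input", {
  sim <- sim_sequences(n_genes = 10, seed = 51)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gene_fasta(sim$genes, fa)
  out <- classify_fasta(fa, ref)
  expect_equal(out$gene_id, sim$genes$gene_id)
  expect_equal(out$call, sim$truth$label)
  counts <- attr(out, "counts")
  expect_equal(sum(counts$n_genes), 10)

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_equal(nrow(classify_fasta(empty, ref)), 0)

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "ATG", ">g1", "ATG"), dup)
  expect_error(classify_fasta(dup, ref), "duplicate")
})

test_that("taxon lineages are parsed from FASTA headers", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1|Actinobacteria;Micrococcales", "ATGTGGAAA",
               ">g2", "ATGTGGAAA"), fa)
  genes <- read_gene_fasta(fa)
  expect_equal(genes$taxon, c("Actinobacteria;Micrococcales", NA))
})
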