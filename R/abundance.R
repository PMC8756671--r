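#' Read a samples-by-genes abundance TSV into a long tibble
#'
#' Expected layout: first column the sample/treatment id, remaining columns one
#' per gene, header row with gene ids.
#'
#' @param path TSV path.
#' @param level `"DNA"` or `"RNA"` tag carried along in the output.
#' @return Long tibble: `sample`, `gene_id`, `abundance`, `level`.
#' @export
read_abundance_tsv <- function(path, level = c("DNA", "RNA")) {
  level <- match.arg(level)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  names(wide)[1L] <- "sample"
  out <- tidyr::pivot_longer(wide, -"sample", names_to = "gene_id",
                             values_to = "abundance")
  out$level <- level
  validate_abundance(out)
  out
}

validate_abundance <- function(df, value_col = "abundance") {
  v <- df[[value_col]]
  if (any(!is.na(v) & v < 0)) abort("abundance table contains negative entries")
  invisible(df)
}

#' Per-sample relative abundance over a gene universe
#'
#' Divides each gene's abundance by its sample's total over the universe of
#' classifiable genes (the genes whose sequence carries a readable
#' glucose-tolerance motif region), so each sample's relative abundances sum
#' to 1 over that universe. Genes outside the universe are dropped.
#'
#' @param df Long abundance tibble (`sample`, `gene_id`, `abundance`, ...).
#' @param gene_universe Character vector of gene ids to normalise over;
#'   default all genes present.
#' @return The tibble restricted to the universe with an added
#'   `rel_abundance` column.
#' @examples
#' df <- tibble::tibble(sample = "s1", gene_id = c("g1", "g2", "g3"),
#'                      abundance = c(10, 30, 60))
#' relative_abundance(df)$rel_abundance # 0.1 0.3 0.6
#' @export
relative_abundance <- function(df, gene_universe = NULL) {
  df <- as_tibble(df)
  gene_universe <- gene_universe %||% unique(df$gene_id)
  missing <- setdiff(gene_universe, df$gene_id)
  if (length(missing)) {
    abort(paste0("gene_universe names genes absent from the table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  key <- if ("sample" %in% names(df)) "sample" else "treatment"
  out <- df |>
    filter(.data$gene_id %in% gene_universe) |>
    group_by(.data[[key]]) |>
    mutate(.total = sum(.data$abundance)) |>
    ungroup()
  bad <- unique(out[[key]][out$.total <= 0])
  if (length(bad)) {
    abort(paste0("sample(s) with zero total abundance over the gene universe: ",
                 paste(bad, collapse = ", ")))
  }
  out |> mutate(rel_abundance = .data$abundance / .data$.total) |>
    select(-".total")
}

#' Average qPCR replicates into one value per treatment
#'
#' Arithmetic mean of the replicate copy numbers per (gene, treatment), with
#' the per-gene coefficient of variation reported alongside (NA when the mean
#' is zero).
#'
#' @param df Long tibble with columns `sample`, `gene_id`, `abundance` and a
#'   `treatment` column mapping each replicate sample to its treatment.
#' @return Tibble `treatment`, `gene_id`, `abundance` (mean), `cv`,
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(df) {
  if (!"treatment" %in% names(df)) {
    abort("`df` needs a `treatment` column mapping replicates to treatments")
  }
  df |>
    group_by(.data$treatment, .data$gene_id) |>
    summarise(
      cv = ifelse(mean(.data$abundance) > 0,
                  sd(.data$abundance) / mean(.data$abundance), NA_real_),
      n_replicates = dplyr::n(),
      abundance = mean(.data$abundance),
      .groups = "drop"
    ) |>
    select("treatment", "gene_id", "abundance", "cv", "n_replicates")
}

#' Per-gene transcription efficiency (RNA/DNA)
#'
#' Transcription efficiency is the ratio of a gene's RNA-level value to its
#' DNA-level value in the same treatment: transcripts per gene copy when both
#' are relative abundances or qPCR copy numbers. The ratio direction is
#' configurable; the default RNA/DNA makes larger TE mean higher expression.
#' TE is undefined (NA) where the denominator is zero.
#'
#' @param dna,rna Long tibbles with a shared key column (`treatment` or
#'   `sample`), `gene_id` and the value column.
#' @param value_col Column holding the values (default `"rel_abundance"`,
#'   falls back to `"abundance"` when absent).
#' @param direction `"rna_dna"` (default) or `"dna_rna"`.
#' @param key Grouping key column name, default `"treatment"` if present else
#'   `"sample"`.
#' @return Tibble `treatment` (or `sample`), `gene_id`, `te`.
#' @export
transcription_efficiency <- function(dna, rna, value_col = NULL,
                                     direction = c("rna_dna", "dna_rna"),
                                     key = NULL) {
  direction <- match.arg(direction)
  key <- key %||% (if ("treatment" %in% names(dna)) "treatment" else "sample")
  value_col <- value_col %||%
    (if ("rel_abundance" %in% names(dna)) "rel_abundance" else "abundance")
  d <- dna |> select(all_of(c(key, "gene_id", value_col))) |>
    rename(.dna = all_of(value_col))
  r <- rna |> select(all_of(c(key, "gene_id", value_col))) |>
    rename(.rna = all_of(value_col))
  only_d <- setdiff(unique(d$gene_id), unique(r$gene_id))
  only_r <- setdiff(unique(r$gene_id), unique(d$gene_id))
  if (length(only_d) || length(only_r)) {
    abort(paste0("gene sets differ between DNA and RNA tables; DNA-only: ",
                 paste(head(only_d, 5), collapse = ", "), "; RNA-only: ",
                 paste(head(only_r, 5), collapse = ", ")))
  }
  out <- inner_join(d, r, by = c(key, "gene_id"))
  num <- if (direction == "rna_dna") out$.rna else out$.dna
  den <- if (direction == "rna_dna") out$.dna else out$.rna
  out$te <- ifelse(den > 0, num / den, NA_real_)
  out |> select(all_of(c(key, "gene_id", "te")))
}

#' Relative transcription efficiency against the control treatment
#'
#' For each gene and non-control treatment,
#' `rel_te = (TE_treatment - TE_ck) / TE_ck`: the fractional change in
#' transcription efficiency relative to the untreated control. Genes whose
#' control TE is zero or undefined cannot be expressed on this scale and are
#' excluded (ids recorded in the `excluded` attribute and reported via a
#' message).
#'
#' @param te Tibble from [transcription_efficiency()].
#' @param ck Name of the control treatment (default `"CK"`).
#' @param keep_ck Keep the control rows (identically 0) in the output;
#'   default TRUE.
#' @return Tibble `treatment`, `gene_id`, `rel_te`, with attribute
#'   `excluded` (character vector of dropped gene ids).
#' @examples
#' te <- tibble::tibble(treatment = c("CK", "T"), gene_id = "g", te = c(1, 2))
#' relative_te(te)$rel_te # 0 1
#' @export
relative_te <- function(te, ck = "CK", keep_ck = TRUE) {
  key <- if ("treatment" %in% names(te)) "treatment" else "sample"
  if (!ck %in% te[[key]]) {
    abort(paste0("control treatment '", ck, "' absent from the TE table"))
  }
  ck_te <- te |> filter(.data[[key]] == ck) |>
    select("gene_id", te_ck = "te")
  excluded <- ck_te$gene_id[is.na(ck_te$te_ck) | ck_te$te_ck <= 0]
  if (length(excluded)) {
    inform(paste0(length(excluded),
                  " gene(s) excluded from relative TE (control TE zero or undefined): ",
                  paste(head(excluded, 5), collapse = ", ")))
  }
  out <- te |>
    inner_join(ck_te, by = "gene_id") |>
    filter(!.data$gene_id %in% excluded) |>
    mutate(rel_te = (.data$te - .data$te_ck) / .data$te_ck) |>
    select(all_of(c(key, "gene_id", "rel_te")))
  if (!keep_ck) out <- out |> filter(.data[[key]] != ck)
  attr(out, "excluded") <- excluded
  out
}

#' Group-average (relative) transcription efficiency per treatment
#'
#' Summarises a per-gene TE or relative-TE table by treatment and tolerance
#' group: unweighted mean (each gene one vote), SD and gene count, plus the
#' signed difference mean(glucose_tolerant) - mean(non_tolerant) per
#' treatment. Genes with an `indeterminate` call are excluded.
#'
#' @param values Tibble with `treatment` (or `sample`), `gene_id` and a value
#'   column (`rel_te` or `te`).
#' @param calls Tolerance-call tibble (`gene_id`, `call`) from
#'   [classify_genes()] or a planted-truth table.
#' @param value_col Which column to average; default `"rel_te"` if present,
#'   else `"te"`.
#' @return A tibble of class `bglccr_groups`: `treatment`, `group`, `n_genes`,
#'   `mean`, `sd`, `gt_minus_nongt`.
#' @export
group_summary <- function(values, calls, value_col = NULL) {
  key <- if ("treatment" %in% names(values)) "treatment" else "sample"
  value_col <- value_col %||% (if ("rel_te" %in% names(values)) "rel_te" else "te")
  calls <- calls |> filter(.data$call != "indeterminate") |>
    select("gene_id", group = "call")
  merged <- values |> inner_join(calls, by = "gene_id") |>
    filter(!is.na(.data[[value_col]]))
  grid <- tidyr::expand_grid(!!key := unique(values[[key]]),
                             group = c("glucose_tolerant", "non_tolerant"))
  out <- merged |>
    group_by(.data[[key]], .data$group) |>
    summarise(n_genes = dplyr::n(),
              mean = mean(.data[[value_col]]),
              sd = sd(.data[[value_col]]),
              .groups = "drop") |>
    dplyr::right_join(grid, by = c(key, "group")) |>
    mutate(n_genes = tidyr::replace_na(.data$n_genes, 0L)) |>
    arrange(.data[[key]], .data$group)
  diffs <- out |>
    tidyr::pivot_wider(id_cols = all_of(key), names_from = "group",
                       values_from = "mean") |>
    mutate(gt_minus_nongt = .data$glucose_tolerant - .data$non_tolerant) |>
    select(all_of(key), "gt_minus_nongt")
  out <- out |> left_join(diffs, by = key)
  class(out) <- c("bglccr_groups", class(out))
  attr(out, "value_col") <- value_col
  out
}

#' Fraction of glucose-tolerant genes
#'
#' Unweighted: the number of glucose-tolerant calls over all decided
#' (non-indeterminate) calls. Weighted (e.g. by expression abundance): the
#' summed weight of glucose-tolerant genes over the summed weight of decided
#' genes.
#'
#' @param calls Tibble with `gene_id` and `call`.
#' @param weights Optional named numeric vector (names = gene ids) of
#'   non-negative weights, e.g. RNA relative abundances.
#' @return A single fraction in \[0, 1\].
#' @examples
#' calls <- tibble::tibble(gene_id = paste0("g", 1:31),
#'                         call = rep(c("glucose_tolerant", "non_tolerant"), c(17, 14)))
#' tolerant_ratio(calls) # 17/31
#' @export
tolerant_ratio <- function(calls, weights = NULL) {
  decided <- calls |> filter(.data$call %in% c("glucose_tolerant", "non_tolerant"))
  if (nrow(decided) == 0L) abort("no decided (non-indeterminate) calls")
  if (is.null(weights)) {
    return(sum(decided$call == "glucose_tolerant") / nrow(decided))
  }
  if (any(weights < 0)) abort("weights must be non-negative")
  w <- weights[decided$gene_id]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) abort("weights sum to zero over the decided genes")
  sum(w[decided$call == "glucose_tolerant"]) / sum(w)
}

#' Relative enzyme activity under added glucose
#'
#' Percentage of the glucose-free activity retained at each glucose
#' concentration. When a concentration gradient is supplied the expected
#' behaviour is monotone decreasing activity; a violation raises a warning
#' flag (attribute `non_monotone`), not an error.
#'
#' @param activity_with Numeric vector of activities under added glucose
#'   (ordered by increasing concentration when `conc` is not given).
#' @param activity_without Positive baseline activity without glucose.
#' @param conc Optional glucose concentrations (mmol/L) for labelling.
#' @return Tibble `conc` (NA if unspecified), `relative_activity_pct`, with
#'   attribute `non_monotone`.
#' @examples
#' relative_activity(c(80, 60, 45), 100, conc = c(50, 100, 200))
#' @export
relative_activity <- function(activity_with, activity_without, conc = NULL) {
  if (!is.numeric(activity_without) || length(activity_without) != 1L ||
      activity_without <= 0) {
    abort("baseline activity must be a single positive number")
  }
  pct <- 100 * activity_with / activity_without
  non_mono <- length(pct) > 1L && any(diff(pct) > 0)
  if (non_mono) {
    warn("relative activity is not monotone decreasing along the glucose gradient")
  }
  out <- tibble(conc = if (is.null(conc)) rep(NA_real_, length(pct)) else conc,
                relative_activity_pct = pct)
  attr(out, "non_monotone") <- non_mono
  out
}
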