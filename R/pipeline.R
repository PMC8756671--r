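#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file of one) with at least
#' `fasta` (gene sequences), `dna_tsv` and `rna_tsv` (samples-by-genes
#' abundance tables), `ck` (control treatment name) and `out_dir`. Optional:
#' `reference` (protein FASTA path), `positions` (e.g. `"168:W,173:L"`),
#' `te_direction` (`"rna_dna"`/`"dna_rna"`), `treatments` (metadata TSV with a
#' `treatment` column), `seed`, and nested `crossmap` (`dna_fasta`,
#' `rna_fasta`, `min_identity`) and `network` (`table`, `method`, `r_min`,
#' `alpha`, `n_perm`) blocks.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list (class `bglccr_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  required <- c("fasta", "dna_tsv", "rna_tsv", "ck", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(paste0("config is missing required field(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (f in c("fasta", "dna_tsv", "rna_tsv", "reference", "treatments")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      abort(paste0("config field '", f, "' points to a missing file: ",
                   config[[f]]))
    }
  }
  config$te_direction <- config$te_direction %||% "rna_dna"
  config$seed <- as.integer(config$seed %||% 1L)
  dna_head <- readr::read_tsv(config$dna_tsv, n_max = 0, show_col_types = FALSE)
  samples <- readr::read_tsv(config$dna_tsv, col_select = 1,
                             show_col_types = FALSE)[[1L]]
  if (!any(startsWith(as.character(samples), config$ck))) {
    abort(paste0("control treatment '", config$ck,
                 "' not found among the samples of ", config$dna_tsv))
  }
  rm(dna_head)
  structure(config, class = c("bglccr_config", "list"))
}

#' Run the classification -> TE -> relative-TE pipeline end to end
#'
#' Stages: (1) classify the FASTA genes as glucose tolerant / non-tolerant /
#' indeterminate; (2) read DNA and RNA abundance tables, average replicates if
#' sample ids extend treatment names, and normalise to relative abundances
#' over the decided genes; (3) compute transcription efficiency and the
#' relative TE against the control; (4) summarise by tolerance group and
#' compute tolerant-gene ratios (unweighted and RNA-abundance-weighted).
#' All tables are written as TSV under `out_dir` together with a
#' machine-readable JSON report.
#'
#' @param config See [validate_config()].
#' @return The report list, invisibly; written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S"), " [bglccr] ", ...)

  log_msg("stage classify: ", config$fasta)
  reference <- if (is.null(config$reference) && is.null(config$positions)) {
    gh1_reference()
  } else {
    gh1_reference(path = config$reference,
                  positions = parse_positions(config$positions))
  }
  calls <- classify_fasta(config$fasta, reference)
  write_calls_tsv(calls, file.path(config$out_dir, "tolerance_calls.tsv"))
  decided <- calls$gene_id[calls$call != "indeterminate"]
  if (length(decided) == 0L) abort("stage classify: no gene received a decided call")

  log_msg("stage abundance: ", config$dna_tsv, " + ", config$rna_tsv)
  dna <- read_abundance_tsv(config$dna_tsv, level = "DNA")
  rna <- read_abundance_tsv(config$rna_tsv, level = "RNA")
  dna <- attach_treatment(dna)
  rna <- attach_treatment(rna)
  has_reps <- any(dna$sample != dna$treatment)
  if (has_reps) {
    dna <- aggregate_replicates(dna)
    rna <- aggregate_replicates(rna)
  }
  universe <- intersect(decided, intersect(unique(dna$gene_id),
                                           unique(rna$gene_id)))
  dna_rel <- relative_abundance(dna, universe)
  rna_rel <- relative_abundance(rna, universe)

  log_msg("stage TE: direction ", config$te_direction, ", control ", config$ck)
  te <- transcription_efficiency(dna_rel, rna_rel,
                                 direction = config$te_direction,
                                 key = "treatment")
  rel <- relative_te(te, ck = config$ck)
  readr::write_tsv(te, file.path(config$out_dir, "te.tsv"))
  readr::write_tsv(rel, file.path(config$out_dir, "relative_te.tsv"))

  log_msg("stage summaries")
  groups <- group_summary(rel, calls)
  readr::write_tsv(groups, file.path(config$out_dir, "group_summary.tsv"))
  rna_w <- rna_rel |>
    group_by(.data$gene_id) |>
    summarise(w = mean(.data$rel_abundance), .groups = "drop")
  ratios <- tibble(
    ratio = c("unweighted", "rna_weighted"),
    value = c(tolerant_ratio(calls),
              tolerant_ratio(calls, setNames(rna_w$w, rna_w$gene_id)))
  )
  per_treatment_w <- rna_rel |>
    group_by(.data$treatment) |>
    dplyr::group_modify(function(d, key) {
      tibble(value = tolerant_ratio(calls,
                                    setNames(d$rel_abundance, d$gene_id)))
    }) |>
    ungroup() |>
    mutate(ratio = paste0("rna_weighted_", .data$treatment)) |>
    select("ratio", "value")
  ratios <- bind_rows(ratios, per_treatment_w)
  readr::write_tsv(ratios, file.path(config$out_dir, "tolerant_ratios.tsv"))

  report <- list(
    package_version = as.character(utils::packageVersion("bglccr")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_genes = nrow(calls),
    calls = as.list(table(calls$call)),
    excluded_from_rel_te = attr(rel, "excluded"),
    tolerant_ratios = setNames(as.list(ratios$value), ratios$ratio),
    group_summary = groups
  )

  if (!is.null(config$crossmap)) {
    log_msg("stage crossmap")
    cm <- reciprocal_match(read_gene_fasta(config$crossmap$dna_fasta),
                           read_gene_fasta(config$crossmap$rna_fasta),
                           threshold = config$crossmap$min_identity %||% 95)
    readr::write_tsv(cm, file.path(config$out_dir, "crossmap.tsv"))
    report$crossmap_pairs <- nrow(cm)
  }
  if (!is.null(config$network)) {
    log_msg("stage network")
    tab <- readr::read_tsv(config$network$table, show_col_types = FALSE)
    m <- as.matrix(tab[, -1L])
    rownames(m) <- tab[[1L]]
    net <- build_network(m,
                         method = config$network$method %||% "spearman",
                         r_min = config$network$r_min %||% 0.8,
                         alpha = config$network$alpha %||% 0.05,
                         n_perm = config$network$n_perm %||% 1000,
                         seed = config$seed)
    readr::write_tsv(tidy(net), file.path(config$out_dir, "network_edges.tsv"))
    readr::write_tsv(glance(net), file.path(config$out_dir, "network_stats.tsv"))
    write_network_graphml(net, file.path(config$out_dir, "network.graphml"))
    report$network <- as.list(glance(net))
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done: ", config$out_dir)
  invisible(report)
}

# sample ids like "CK_r1" map to treatment "CK"; plain treatment ids map to
# themselves
attach_treatment <- function(df) {
  df$treatment <- sub("_r[0-9]+$", "", df$sample)
  df
}

parse_positions <- function(spec) {
  if (is.null(spec)) return(c("168" = "W", "173" = "L"))
  parts <- strsplit(strsplit(spec, ",")[[1L]], ":")
  setNames(vapply(parts, `[[`, character(1), 2L),
           vapply(parts, `[[`, character(1), 1L))
}
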