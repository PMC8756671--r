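#' Built-in glucose-tolerant GH1 reference profile
#'
#' Loads the reference protein whose residue numbering anchors the two
#' glucose-tolerance-discriminating positions of GH1 family beta-glucosidases:
#' a tryptophan at position 168 and a leucine at position 173. The bundled
#' default is a synthetic GH1-like protein (447 aa) carrying the canonical
#' acid/base (TFNEP) and nucleophile (ITENG) motif context; it exists so the
#' residue rule is testable without an external database, and both the
#' reference sequence and the discriminating positions can be replaced by the
#' caller for use with a curated protein.
#'
#' @param path Path to a single-record protein FASTA. Default: the bundled
#'   synthetic reference.
#' @param positions Named character vector of required residues, names are
#'   1-based positions on the ungapped reference protein. Default
#'   `c("168" = "W", "173" = "L")`.
#'
#' @return A list of class `gh1_reference` with elements `ref_id`,
#'   `ref_protein` (character scalar) and `positions` (named character vector).
#' @examples
#' ref <- gh1_reference()
#' substr(ref$ref_protein, 168, 168) # "W"
#' @export
gh1_reference <- function(path = NULL, positions = c("168" = "W", "173" = "L")) {
  path <- path %||% system.file("extdata", "gh1_reference_synthetic.faa",
                                package = "bglccr", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) != 1L) {
    abort("reference FASTA must contain exactly one protein record")
  }
  prot <- as.character(aa[[1L]])
  pos <- as.integer(names(positions))
  if (anyNA(pos) || any(pos < 1L) || any(pos > nchar(prot))) {
    abort("discriminating positions must be 1-based positions on the reference protein")
  }
  have <- vapply(pos, function(p) substr(prot, p, p), character(1))
  if (!all(have == unname(positions))) {
    abort(paste0(
      "reference protein does not carry its own required residues: expected ",
      paste0(positions, unname(pos), collapse = "/"), ", found ",
      paste0(have, pos, collapse = "/")
    ))
  }
  structure(
    list(ref_id = sub("\\s.*$", "", names(aa)[1L]),
         ref_protein = prot,
         positions = positions),
    class = "gh1_reference"
  )
}

#' @export
print.gh1_reference <- function(x, ...) {
  cat("<gh1_reference> ", x$ref_id, " (", nchar(x$ref_protein), " aa)\n", sep = "")
  cat("  discriminating residues: ",
      paste0(x$positions, names(x$positions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Incubation design of the seven composting treatments
#'
#' The additive concentrations defining each treatment: three high-glucose
#' treatments (200 mmol/L glucose) with low/high cellobiose and optionally
#' D-glucono-1,5-lactone, three glucose-free counterparts, and the untreated
#' control CK. `is_high_glucose` marks the treatments where carbon catabolite
#' repression is expected.
#'
#' @return A tibble with columns `treatment`, `glucose_mM`, `cellobiose_mM`,
#'   `gluconolactone_mM`, `is_high_glucose`.
#' @examples
#' treatment_design()
#' @export
treatment_design <- function() {
  tibble(
    treatment = c("G_H_C_L", "G_H_C_H", "G_H_C_H_D", "C_L", "C_H", "C_H_D", "CK"),
    glucose_mM = c(200, 200, 200, 0, 0, 0, 0),
    cellobiose_mM = c(0.8, 8, 8, 0.8, 8, 8, 0),
    gluconolactone_mM = c(0, 0, 20, 0, 0, 20, 0),
    is_high_glucose = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}
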