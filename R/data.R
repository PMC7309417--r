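#' Bundled glial miRNA screen tables
#'
#' Small plain-text tables from a published pan-glial miRNA overexpression
#' lifespan screen in adult *Drosophila*, shipped as package fixtures:
#' per-miRNA average strengths, the TargetScan family grouping, per-line
#' RNAi validation results and per-gene normalised prediction scores for the
#' 51 genes predicted by all four databases ("common") and the 14 genes
#' predicted by only some ("differential").
#'
#' `glia_mirna_strengths()` returns `mirna`, `av_chi2` (44 rows);
#' `glia_mirna_families()` returns `family`, `member`;
#' `glia_rnai_lines()` returns per-line `gene_id`, `line_id`, `median`,
#' `chi2`, `p_value` (numeric; values below the display threshold parsed as
#' half the bound), `direction`;
#' `glia_prediction_scores()` returns per-gene normalised scores with `NA`
#' where a database does not predict the gene (the common group also has a
#' `pooled` column).
#'
#' @param group `"common"` or `"differential"`.
#' @return A tibble (see above).
#' @name glia-screen-data
NULL

glia_extdata <- function(name) {
  system.file("extdata", name, package = "miRTargetRank", mustWork = TRUE)
}

#' @rdname glia-screen-data
#' @export
glia_mirna_strengths <- function() {
  readr::read_tsv(glia_extdata("mirna_strengths.tsv"),
                  show_col_types = FALSE)
}

#' @rdname glia-screen-data
#' @export
glia_mirna_families <- function() {
  readr::read_tsv(glia_extdata("mirna_families.tsv"), show_col_types = FALSE)
}

#' @rdname glia-screen-data
#' @export
glia_rnai_lines <- function(group = c("common", "differential")) {
  group <- match.arg(group)
  read_rnai_tsv(glia_extdata(paste0("rnai_lines_", group, ".tsv")))
}

#' @rdname glia-screen-data
#' @export
glia_prediction_scores <- function(group = c("common", "differential")) {
  group <- match.arg(group)
  readr::read_tsv(glia_extdata(paste0("prediction_scores_", group, ".tsv")),
                  show_col_types = FALSE, na = "NA")
}
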