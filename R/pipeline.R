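#' Run the full ranking stage
#'
#' Orchestrates the per-database ranking: ingest every prediction table
#' named by the manifest, collapse transcripts, weight by miRNA strength,
#' sum per gene, normalise by the top gene and by miRNA coverage, pool
#' across databases, and census the cross-database overlap. Writes the
#' pooled ranking TSV, the Venn region counts JSON and a provenance block.
#'
#' @param manifest Path to the prediction manifest JSON (database ->
#'   TSV path; see [read_prediction_manifest()]).
#' @param strengths Strength table (columns `mirna_or_family`, `av_chi2`) or
#'   the path of a per-line TSV readable by [read_strength_lines_tsv()].
#' @param families Optional family table (columns `family`, `member`) or TSV
#'   path; family strengths are appended for the TargetScan join.
#' @param n_screened Total miRNAs in the screen (default 44).
#' @param collapse Transcript collapse rule, `"sum"` or `"max"`.
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return Invisibly, a list with `rankings` (per-database tibbles),
#'   `pooled`, `venn`, and `coverage` (miRNAs present per database).
#' @export
run_rank <- function(manifest, strengths, families = NULL, n_screened = 44,
                     collapse = c("sum", "max"), out_dir = NULL) {
  collapse <- match.arg(collapse)
  if (is.character(strengths)) {
    lines <- read_strength_lines_tsv(strengths)
    strengths <- line_strengths(lines, label = "mirna_or_gene")
  }
  if (is.character(families)) {
    families <- readr::read_tsv(families, show_col_types = FALSE)
  }
  if (!is.null(families) && nrow(families) > 0L) {
    # only derive strengths for families not already present
    new_fams <- families[!families$family %in% strengths$mirna_or_family, ,
                         drop = FALSE]
    if (nrow(new_fams) > 0L) {
      strengths <- dplyr::bind_rows(
        strengths,
        family_strengths(strengths, new_fams)
      )
    }
  }
  preds <- read_prediction_manifest(manifest)
  if (sum(vapply(preds, nrow, 1L)) == 0L) {
    stop("empty prediction set", call. = FALSE)
  }
  rankings <- list()
  coverage <- integer()
  for (db in names(preds)) {
    gene_level <- collapse_transcripts(preds[[db]], rule = collapse)
    s1 <- step1_weighted(gene_level, strengths)
    n_present <- dplyr::n_distinct(s1$mirna)
    coverage[[db]] <- n_present
    message(sprintf("database %s: %d/%d screened miRNA units present",
                    db, n_present, n_screened))
    rankings[[db]] <- normalise_ranking(step2_gene_sum(s1), n_present,
                                        n_screened)
  }
  pooled <- pool_databases(rankings)
  venn <- common_targets(lapply(rankings, function(x) x$gene_id))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ranking_tsv(pooled, file.path(out_dir, "ranking_pooled.tsv"))
    for (db in names(rankings)) {
      write_ranking_tsv(rankings[[db]],
                        file.path(out_dir, paste0("ranking_", db, ".tsv")))
    }
    jsonlite::write_json(
      list(intersection_size = length(venn$intersection),
           regions = venn$regions),
      file.path(out_dir, "venn_regions.json"), auto_unbox = TRUE
    )
    write_provenance(out_dir, list(
      stage = "rank", manifest = manifest, n_screened = n_screened,
      collapse = collapse, coverage = as.list(coverage)
    ), input_files = manifest)
  }
  invisible(list(rankings = rankings, pooled = pooled, venn = venn,
                 coverage = coverage))
}

#' Run the RNAi validation stage
#'
#' Scores an RNAi validation screen against a pooled ranking: per-gene
#' Av(chi-square)IR, the 2-RNAi-lines category, combined scores (pooled and
#' per-database), and per-key predicting power. Genes not present in any
#' ranking are listed in a skipped-genes report rather than failing the run.
#'
#' @param rnai Per-line RNAi table (columns `gene_id`, `chi2`, `direction`)
#'   or path of a TSV readable by [read_rnai_tsv()].
#' @param ranking Result of [run_rank()] (its `pooled` element is used) or a
#'   per-gene score table with a `gene_id` column and one numeric column per
#'   key.
#' @param group Label for the gene group being validated.
#' @param out_dir Output directory; `NULL` skips writing.
#' @return Invisibly, a list with `validation` (per-gene tibble), `power`
#'   (per-key predicting power) and `skipped` (gene ids without
#'   predictions).
#' @export
run_validate <- function(rnai, ranking, group = "tested", out_dir = NULL) {
  if (is.character(rnai)) rnai <- read_rnai_tsv(rnai)
  if (nrow(rnai) == 0L) {
    warning("empty RNAi table; nothing to validate", call. = FALSE)
    return(invisible(list(validation = tibble::tibble(),
                          power = tibble::tibble(), skipped = character())))
  }
  score_tbl <- if (is.list(ranking) && !is.data.frame(ranking) &&
                     !is.null(ranking$pooled)) {
    p <- ranking$pooled
    keep <- c("gene_id", "pooled", grep("^norm_", names(p), value = TRUE))
    out <- p[, keep]
    names(out) <- sub("^norm_", "", names(out))
    out
  } else {
    ranking
  }
  validation <- validate_rnai(rnai, score_tbl)
  keys <- sub("^combined_", "",
              grep("^combined_", names(validation), value = TRUE))
  power <- purrr::map_dfr(keys, function(k) {
    if (all(is.na(validation[[paste0("combined_", k)]]))) return(NULL)
    predicting_power(validation, k, group = group)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- validation
    out$av_chi2_ir <- round_half_up(out$av_chi2_ir, 4)
    readr::write_tsv(out, file.path(out_dir, "validation.tsv"), na = "")
    jsonlite::write_json(power, file.path(out_dir, "predicting_power.json"),
                         auto_unbox = TRUE, digits = NA)
    skipped <- attr(validation, "skipped")
    writeLines(skipped %||% character(),
               file.path(out_dir, "skipped_genes.txt"))
    write_provenance(out_dir, list(stage = "validate", group = group))
  }
  invisible(list(validation = validation, power = power,
                 skipped = attr(validation, "skipped")))
}

# machine-readable provenance: config echo, md5 of inputs, session versions
write_provenance <- function(out_dir, config, input_files = character()) {
  input_files <- input_files[file.exists(input_files)]
  jsonlite::write_json(
    list(
      config = config,
      inputs = as.list(tools::md5sum(input_files)),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("miRTargetRank")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE
  )
  invisible(NULL)
}
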