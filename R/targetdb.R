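DATABASES <- c("microcosm", "pictar", "mirnaorg", "targetscan")

# TargetScan point scheme: site type x conservation class
TS_POINTS <- c(
  "8mer|conserved" = 10, "7mer-m8|conserved" = 6, "7mer-1A|conserved" = 4,
  "8mer|poorly_conserved" = 8, "7mer-m8|poorly_conserved" = 4,
  "7mer-1A|poorly_conserved" = 2
)

#' Point value of a TargetScan target site
#'
#' TargetScan reports the seed-match sites a miRNA has on a transcript rather
#' than a numeric score; each site is converted to points favouring longer
#' seed matches and conserved sites: conserved 8mer = 10, conserved 7mer-m8
#' = 6, conserved 7mer-1A = 4, poorly conserved 8mer = 8, poorly conserved
#' 7mer-m8 = 4, poorly conserved 7mer-1A = 2.
#'
#' @param site_type Character vector in `c("8mer", "7mer-m8", "7mer-1A")`.
#' @param conservation Character vector in
#'   `c("conserved", "poorly_conserved")`.
#' @return Numeric vector of points.
#' @examples
#' targetscan_site_points("8mer", "conserved")  # 10
#' @export
targetscan_site_points <- function(site_type, conservation) {
  key <- paste(site_type, conservation, sep = "|")
  pts <- TS_POINTS[key]
  if (any(is.na(pts))) {
    stop("unknown TargetScan site: ",
         paste(unique(key[is.na(pts)]), collapse = ", "), call. = FALSE)
  }
  unname(pts)
}

#' TargetScan raw score from a list of sites
#'
#' Sums the point values of all sites a miRNA (or family) has on a target.
#' An empty site list scores 0.
#'
#' @param sites Data frame with columns `site_type`, `conservation` and an
#'   optional integer `count` (default 1 per row).
#' @return A single non-negative score.
#' @export
targetscan_score <- function(sites) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0L) return(0)
  count <- if ("count" %in% names(sites)) sites$count else rep(1L, nrow(sites))
  stopifnot(all(count >= 0))
  sum(targetscan_site_points(sites$site_type, sites$conservation) * count)
}

#' Database-specific score transform
#'
#' MicroCosm, PicTar and TargetScan scores are used as provided. microRNA.org
#' scores are negative (mirSVR-style, more negative = stronger) and are
#' squared to obtain a positive magnitude; a positive microRNA.org raw score
#' has unexpected polarity and triggers a warning but is still squared.
#'
#' @param database One of `"microcosm"`, `"pictar"`, `"mirnaorg"`,
#'   `"targetscan"`.
#' @param raw_score Finite numeric vector.
#' @return Non-negative transformed scores (for `mirnaorg`) or `raw_score`
#'   unchanged.
#' @export
transform_score <- function(database, raw_score) {
  database <- match.arg(database, DATABASES)
  stopifnot(is.numeric(raw_score), all(is.finite(raw_score)))
  if (database == "mirnaorg") {
    if (any(raw_score > 0)) {
      warning("positive microRNA.org raw score(s): unexpected polarity, ",
              "squared anyway", call. = FALSE)
    }
    raw_score^2
  } else {
    raw_score
  }
}

#' Collapse transcript-level predictions to gene level
#'
#' Predictions listing several transcripts of the same gene are grouped under
#' the gene: scores for the same (miRNA, gene) pair are summed by default
#' (`rule = "sum"`); `rule = "max"` keeps the best transcript instead, for
#' sensitivity analysis.
#'
#' @param records Prediction records from a single database: columns `mirna`,
#'   `gene_id`, `score`, optionally `gene_name` and `transcript_id`.
#' @param rule `"sum"` (default) or `"max"`.
#' @return One record per (mirna, gene_id), transcript column dropped.
#' @export
collapse_transcripts <- function(records, rule = c("sum", "max")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(records),
            all(c("mirna", "gene_id", "score") %in% names(records)))
  if ("gene_name" %in% names(records)) {
    names_per_gene <- dplyr::summarise(
      dplyr::group_by(records, .data$gene_id),
      n_names = dplyr::n_distinct(.data$gene_name[!is.na(.data$gene_name)]),
      .groups = "drop"
    )
    conflicted <- names_per_gene$gene_id[names_per_gene$n_names > 1L]
    if (length(conflicted) > 0L) {
      stop("conflicting gene_name for gene_id: ",
           paste(conflicted, collapse = ", "), call. = FALSE)
    }
  }
  agg <- if (rule == "sum") sum else max
  if (!"raw_score" %in% names(records)) records$raw_score <- records$score
  if (!"gene_name" %in% names(records)) records$gene_name <- NA_character_
  grouped <- dplyr::group_by(records, .data$mirna, .data$gene_id)
  dplyr::summarise(
    grouped,
    gene_name = dplyr::first(.data$gene_name[!is.na(.data$gene_name)],
                             default = NA_character_),
    raw_score = agg(.data$raw_score),
    score = agg(.data$score),
    .groups = "drop"
  )
}

#' Read a miRNA target prediction table
#'
#' Two tab-separated dialects are supported. The `"score"` dialect
#' (MicroCosm, PicTar, microRNA.org) has header
#' `mirna gene_id gene_name transcript_id raw_score`; the database transform
#' ([transform_score()]) is applied on ingest. The `"targetscan"` dialect has
#' header `mirna_or_family gene_id gene_name site_type conservation count`;
#' site rows for the same (miRNA/family, gene) are converted to points and
#' summed. Zero-score records are dropped: a zero carries no prediction.
#'
#' @param path TSV file path.
#' @param database Database name; fixes the dialect (`targetscan` uses the
#'   site-list dialect) and the score transform.
#' @return A tibble of transcript-level (score dialect) or gene-level
#'   (targetscan dialect) prediction records with columns `database`,
#'   `mirna`, `gene_id`, `gene_name`, (`transcript_id`,) `raw_score`,
#'   `score`.
#' @export
read_prediction_tsv <- function(path, database) {
  database <- match.arg(database, DATABASES)
  if (database == "targetscan") {
    x <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           mirna_or_family = readr::col_character(),
                           gene_id = readr::col_character(),
                           gene_name = readr::col_character(),
                           site_type = readr::col_character(),
                           conservation = readr::col_character(),
                           count = readr::col_integer()
                         ))
    x$points <- targetscan_site_points(x$site_type, x$conservation) * x$count
    out <- dplyr::summarise(
      dplyr::group_by(x, mirna = .data$mirna_or_family, .data$gene_id),
      gene_name = dplyr::first(.data$gene_name),
      raw_score = sum(.data$points),
      .groups = "drop"
    )
    out$score <- out$raw_score
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             mirna = readr::col_character(),
                             gene_id = readr::col_character(),
                             gene_name = readr::col_character(),
                             transcript_id = readr::col_character(),
                             raw_score = readr::col_double()
                           ))
    out$score <- transform_score(database, out$raw_score)
  }
  out <- out[out$score != 0, , drop = FALSE]
  tibble::as_tibble(cbind(database = database, out))
}

#' Read a manifest of prediction databases
#'
#' The manifest is a JSON object mapping database name to a TSV path,
#' e.g. `{"microcosm": "microcosm.tsv", ...}`. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest JSON path.
#' @return Named list of prediction record tibbles, one per database.
#' @export
read_prediction_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(length(man) > 0L, !is.null(names(man)))
  base <- dirname(path)
  out <- lapply(names(man), function(db) {
    f <- man[[db]]
    if (!file.exists(f)) f <- file.path(base, man[[db]])
    if (!file.exists(f)) {
      stop("prediction file not found for database '", db, "': ",
           man[[db]], call. = FALSE)
    }
    read_prediction_tsv(f, db)
  })
  names(out) <- names(man)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
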