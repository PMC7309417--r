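VALIDATION_CATEGORIES <- c("confirmed_2x", "contradicted_2x",
                           "partial_confirmed", "partial_contradicted",
                           "no_effect")

#' Categorise a gene's RNAi outcome under the 2-RNAi-lines criterion
#'
#' The community gold standard for trusting an RNAi knockdown is two
#' independent lines with the same phenotype. Categories:
#' \describe{
#'   \item{confirmed_2x}{at least two significant lifespan-shortening lines
#'     and no significant extender;}
#'   \item{contradicted_2x}{the symmetric case for extension;}
#'   \item{partial_confirmed}{a single significant shortening line (others
#'     without effect, or no second line tested);}
#'   \item{partial_contradicted}{the symmetric case for extension;}
#'   \item{no_effect}{no significant line.}
#' }
#' A gene with significant lines in both directions is assigned the partial
#' category of the dominant direction (largest absolute signed chi-square),
#' with a warning.
#'
#' @param chi2 Per-line log-rank chi-squares.
#' @param direction Per-line directions (`"shorten"`, `"extend"`, `"none"`);
#'   `"none"` marks non-significant lines.
#' @return One category string.
#' @export
categorize_lines <- function(chi2, direction) {
  stopifnot(length(chi2) >= 1L, length(chi2) == length(direction))
  sh <- chi2[direction == "shorten"]
  ex <- chi2[direction == "extend"]
  if (length(sh) > 0L && length(ex) > 0L) {
    warning("significant lines in both directions; using dominant |chi2|",
            call. = FALSE)
    return(if (max(sh) >= max(ex)) "partial_confirmed"
           else "partial_contradicted")
  }
  if (length(sh) >= 2L) return("confirmed_2x")
  if (length(ex) >= 2L) return("contradicted_2x")
  if (length(sh) == 1L) return("partial_confirmed")
  if (length(ex) == 1L) return("partial_contradicted")
  "no_effect"
}

#' Validate one predicted target gene against its RNAi lines
#'
#' Averages the gene's signed per-line chi-squares with the same rules used
#' for miRNA strengths (single lines halved, extenders negative) into
#' Av(chi-square)IR, then multiplies it by each available prediction score
#' (pooled and/or per-database) into the combined scores that rank validated
#' targets.
#'
#' @param gene_id Gene label.
#' @param lines Data frame of the gene's RNAi lines: columns `chi2`,
#'   `direction`, optionally `line_id`.
#' @param scores Named numeric vector of the gene's prediction scores, e.g.
#'   `c(pooled = 31.366, targetscan = 19.5843)`; `NA` marks a database that
#'   does not predict the gene.
#' @return One-row tibble: `gene_id`, `av_chi2_ir`, `n_lines`, `category`,
#'   and one `combined_<key>` column per score key.
#' @export
validate_gene <- function(gene_id, lines, scores) {
  stopifnot(is.data.frame(lines), nrow(lines) >= 1L,
            is.numeric(scores), !is.null(names(scores)))
  if (all(is.na(scores))) {
    stop("not a predicted target: ", gene_id, call. = FALSE)
  }
  signed <- signed_chi2(lines$chi2, lines$direction)
  av <- average_strength(signed)
  out <- tibble::tibble(
    gene_id = gene_id,
    av_chi2_ir = av,
    n_lines = nrow(lines),
    category = categorize_lines(lines$chi2, lines$direction)
  )
  for (k in names(scores)) out[[paste0("combined_", k)]] <- scores[[k]] * av
  out
}

#' Validate an RNAi screen against prediction rankings
#'
#' @param rnai_lines Per-line RNAi results: columns `gene_id`, `chi2`,
#'   `direction`, optionally `line_id`.
#' @param score_tbl Per-gene prediction scores: column `gene_id` plus one
#'   numeric column per score key (`pooled`, database names); `NA` where a
#'   database does not predict the gene.
#' @return Tibble with one row per gene (see [validate_gene()]). Genes
#'   absent from `score_tbl` are skipped with a warning and listed in the
#'   `"skipped"` attribute.
#' @export
validate_rnai <- function(rnai_lines, score_tbl) {
  stopifnot(all(c("gene_id", "chi2", "direction") %in% names(rnai_lines)),
            "gene_id" %in% names(score_tbl))
  keys <- setdiff(names(score_tbl), "gene_id")
  genes <- unique(rnai_lines$gene_id)
  # absent from the table, or present with no score under any key, means
  # the gene was never predicted as a target
  in_tbl <- intersect(genes, score_tbl$gene_id)
  all_na <- in_tbl[vapply(in_tbl, function(g) {
    all(is.na(unlist(score_tbl[match(g, score_tbl$gene_id), keys])))
  }, logical(1))]
  skipped <- c(setdiff(genes, score_tbl$gene_id), all_na)
  if (length(skipped) > 0L) {
    warning("gene(s) not in any ranking, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map_dfr(setdiff(genes, skipped), function(g) {
    sc <- unlist(score_tbl[match(g, score_tbl$gene_id), keys])
    validate_gene(g, rnai_lines[rnai_lines$gene_id == g, , drop = FALSE], sc)
  })
  attr(out, "skipped") <- skipped
  out
}

#' Predicting power of a database (or of the pooled ranking)
#'
#' Sums the combined scores (prediction score x Av(chi-square)IR) over all
#' tested genes the key predicts. Genes whose RNAi effect opposed the
#' prediction carry negative Av(chi-square)IR and subtract from the total,
#' penalising false positives.
#'
#' @param validation Tibble from [validate_rnai()].
#' @param key Score key: `"pooled"` or a database name.
#' @param group Optional label carried into the result.
#' @return One-row tibble: `database_or_pooled`, `group`, `power`,
#'   `n_tested` (genes carrying the key).
#' @export
predicting_power <- function(validation, key, group = NA_character_) {
  col <- paste0("combined_", key)
  if (!col %in% names(validation)) {
    stop("no combined scores for key '", key, "'", call. = FALSE)
  }
  v <- validation[[col]]
  if (all(is.na(v))) stop("no record carries key '", key, "'", call. = FALSE)
  tibble::tibble(
    database_or_pooled = key,
    group = group,
    power = sum(v, na.rm = TRUE),
    n_tested = sum(!is.na(v))
  )
}

#' Predicting efficiency
#'
#' Normalises a database's predicting power by the total number of target
#' genes it predicted for the whole screen, measuring how much validated
#' signal each predicted target carries on average. The denominator is the
#' database-wide predicted-target count, not the number of tested genes, and
#' must be supplied by the caller.
#'
#' @param power One-row tibble from [predicting_power()] (or a bare number).
#' @param n_predicted Total predicted targets for the database; must be > 0.
#' @return Efficiency = power / n_predicted.
#' @export
predicting_efficiency <- function(power, n_predicted) {
  if (!is.numeric(n_predicted) || length(n_predicted) != 1L ||
      n_predicted <= 0) {
    stop("n_predicted must be a positive count", call. = FALSE)
  }
  p <- if (is.data.frame(power)) power$power else power
  stopifnot(is.numeric(p), length(p) == 1L)
  p / n_predicted
}

#' Read an RNAi validation table
#'
#' Expects header `gene_id line_id median chi2 p_value direction` (the
#' format written by the simulator and used for the bundled screen tables).
#' P-values below the four-decimal display threshold may be written
#' `<0.0001` and are parsed as half the bound.
#'
#' @param path TSV path.
#' @return Tibble of per-line RNAi results with numeric `p_value`.
#' @export
read_rnai_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         gene_id = readr::col_character(),
                         line_id = readr::col_character(),
                         median = readr::col_double(),
                         chi2 = readr::col_double(),
                         p_value = readr::col_character(),
                         direction = readr::col_character()
                       ))
  x$p_value <- parse_p_display(x$p_value)
  x
}

parse_p_display <- function(p) {
  below <- startsWith(p, "<")
  out <- suppressWarnings(as.numeric(sub("^<", "", p)))
  out[below] <- out[below] / 2
  out
}
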