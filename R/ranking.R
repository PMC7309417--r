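#' Step 1: weight prediction scores by miRNA strength
#'
#' Multiplies every gene-level prediction score by the average strength
#' Av(chi-square) of the predicting miRNA (or miRNA family) measured in the
#' lifespan screen. Predictions for miRNAs that were never screened carry no
#' strength and are skipped with a warning.
#'
#' @param predictions Gene-level prediction records for one database
#'   (columns `mirna`, `gene_id`, `score`, optionally `gene_name`).
#' @param strengths Strength table with columns `mirna_or_family`, `av_chi2`.
#' @return Tibble `mirna`, `gene_id`, `gene_name`, `weighted`
#'   (= score x av_chi2).
#' @export
step1_weighted <- function(predictions, strengths) {
  stopifnot(all(c("mirna", "gene_id", "score") %in% names(predictions)),
            all(c("mirna_or_family", "av_chi2") %in% names(strengths)))
  miss <- setdiff(unique(predictions$mirna), strengths$mirna_or_family)
  if (length(miss) > 0L) {
    warning("skipping predictions for unscreened miRNA(s): ",
            paste(miss, collapse = ", "), call. = FALSE)
    predictions <- predictions[!predictions$mirna %in% miss, , drop = FALSE]
  }
  if (!"gene_name" %in% names(predictions)) {
    predictions$gene_name <- NA_character_
  }
  joined <- dplyr::inner_join(
    predictions,
    strengths[, c("mirna_or_family", "av_chi2")],
    by = c(mirna = "mirna_or_family"),
    relationship = "many-to-one"
  )
  tibble::tibble(
    mirna = joined$mirna,
    gene_id = joined$gene_id,
    gene_name = joined$gene_name,
    weighted = joined$score * joined$av_chi2
  )
}

#' Step 2: sum weighted scores per gene
#'
#' All weighted values from all miRNAs predicted to target the same gene
#' (keyed by its CG number / accession) are summed into the per-database
#' ranking value Sigma; descending Sigma defines the within-database rank.
#'
#' @param step1 Output of [step1_weighted()].
#' @return Tibble `gene_id`, `gene_name`, `sigma`, sorted by descending
#'   `sigma` (ties by `gene_id`).
#' @export
step2_gene_sum <- function(step1) {
  out <- dplyr::summarise(
    dplyr::group_by(step1, .data$gene_id),
    gene_name = dplyr::first(.data$gene_name[!is.na(.data$gene_name)],
                             default = NA_character_),
    sigma = sum(.data$weighted),
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$sigma), .data$gene_id)
}

#' Normalise a per-database ranking and weight by miRNA coverage
#'
#' Scales a database's Sigma values so its top gene scores 100, then
#' multiplies by the fraction of screened miRNAs the database covers, so
#' that databases with more information relevant to the screen weigh more in
#' the pooled ranking. Negative Sigma values (possible through
#' lifespan-extending family strengths) are scaled by the same positive
#' maximum, preserving order.
#'
#' @param sigma_tbl Tibble from [step2_gene_sum()].
#' @param n_mirnas_present Number of screened miRNAs (families counted as
#'   one unit for TargetScan) present in the database.
#' @param n_screened Total number of miRNAs in the screen (default 44).
#' @return `sigma_tbl` with an added `normalised` column.
#' @export
normalise_ranking <- function(sigma_tbl, n_mirnas_present, n_screened = 44) {
  stopifnot(n_mirnas_present > 0, n_mirnas_present <= n_screened)
  m <- max(sigma_tbl$sigma)
  if (!is.finite(m) || m <= 0) stop("degenerate ranking", call. = FALSE)
  sigma_tbl$normalised <-
    sigma_tbl$sigma / m * 100 * (n_mirnas_present / n_screened)
  sigma_tbl
}

#' Rank target genes within one database
#'
#' Convenience chain: [step1_weighted()], [step2_gene_sum()],
#' [normalise_ranking()]. Coverage defaults to the number of distinct
#' strength labels (miRNAs or families) with at least one prediction in the
#' database.
#'
#' @inheritParams step1_weighted
#' @inheritParams normalise_ranking
#' @return Tibble `gene_id`, `gene_name`, `sigma`, `normalised`.
#' @export
rank_database <- function(predictions, strengths, n_screened = 44,
                          n_mirnas_present = NULL) {
  s1 <- step1_weighted(predictions, strengths)
  if (is.null(n_mirnas_present)) {
    n_mirnas_present <- dplyr::n_distinct(s1$mirna)
  }
  normalise_ranking(step2_gene_sum(s1), n_mirnas_present, n_screened)
}

#' Pool normalised rankings across databases
#'
#' For each gene the normalised values from all databases holding it are
#' summed into the final pooled ranking number; a database that does not
#' predict the gene contributes 0. Ranks are dense, descending by pooled
#' value, with ties broken lexicographically by `gene_id`.
#'
#' @param normalised_list Named list of per-database tibbles from
#'   [rank_database()] / [normalise_ranking()].
#' @return Tibble with `gene_id`, `gene_name`, `sigma_<db>` and `norm_<db>`
#'   columns per database, `pooled`, `rank`, and `in_all` (`TRUE` when every
#'   database predicts the gene).
#' @export
pool_databases <- function(normalised_list) {
  stopifnot(length(normalised_list) >= 1L, !is.null(names(normalised_list)))
  dbs <- names(normalised_list)
  wide <- NULL
  for (db in dbs) {
    x <- normalised_list[[db]]
    x <- tibble::tibble(
      gene_id = x$gene_id, gene_name = x$gene_name,
      sigma = x$sigma, norm = x$normalised
    )
    names(x)[3:4] <- paste0(c("sigma_", "norm_"), db)
    wide <- if (is.null(wide)) x else
      dplyr::full_join(wide, x, by = "gene_id", suffix = c("", paste0(".", db)))
  }
  # reconcile gene_name columns produced by successive joins
  name_cols <- grep("^gene_name", names(wide), value = TRUE)
  wide$gene_name <- apply(wide[, name_cols, drop = FALSE], 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_character_ else v[[1L]]
  })
  wide <- wide[, c("gene_id", "gene_name",
                   paste0("sigma_", dbs), paste0("norm_", dbs))]
  norm_mat <- as.matrix(wide[, paste0("norm_", dbs), drop = FALSE])
  wide$pooled <- rowSums(norm_mat, na.rm = TRUE)
  wide$in_all <- rowSums(!is.na(norm_mat)) == length(dbs)
  wide <- dplyr::arrange(wide, dplyr::desc(.data$pooled), .data$gene_id)
  wide$rank <- cumsum(!duplicated(wide$pooled))
  wide
}

#' Intersection and Venn region census of per-database gene sets
#'
#' @param sets Named list (>= 2 entries) of character vectors of gene ids.
#' @return A list with `intersection` (genes present in every set) and
#'   `regions`, a tibble with one row per non-empty membership pattern
#'   (2^k - 1 rows for k sets): logical columns per set plus `count`.
#' @export
common_targets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(memb, 1L, function(row) all(row == p)))
  })
  regions <- tibble::as_tibble(patterns)
  regions$count <- as.integer(counts)
  list(
    intersection = sort(universe[rowSums(memb) == length(sets)]),
    regions = regions
  )
}

#' Write a pooled ranking to TSV
#'
#' @param pooled Tibble from [pool_databases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(pooled, path) {
  utils::write.table(pooled, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
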