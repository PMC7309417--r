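#' Configuration for a synthetic miRNA lifespan screen
#'
#' Bundles every knob of the simulator. The defaults emulate the real study
#' design: 44 screened miRNAs, a ~10^4-gene universe, four prediction
#' databases covering 31/44, 28/44, 43/44 and 40/44 of the screened miRNAs,
#' a ~5.6% four-way overlap of predicted targets, 60 flies per genotype and
#' a 90-day study at a baseline hazard giving a ~31-day median control
#' lifespan (exponential survival, rate = log(2)/31 per day).
#'
#' @param n_mirnas Number of screened miRNAs.
#' @param n_genes Size of the gene universe.
#' @param n_essential_genes Number of planted essential genes whose
#'   knockdown (and targeting-miRNA overexpression) shortens lifespan.
#' @param db_coverage Named fractions of screened miRNAs present per
#'   database.
#' @param overlap_target Target fraction of predicted genes common to all
#'   four databases (achieved in expectation via independent per-database
#'   gene inclusion at rate `overlap_target^(1/n_db)`).
#' @param baseline_hazard Control death rate per day.
#' @param hazard_ratio_range Range of hazard ratios assigned to screened
#'   miRNA lines (log-uniform).
#' @param rnai_hazard_ratio Hazard ratio used for RNAi lines against planted
#'   genes.
#' @param n_flies_per_group Flies per genotype.
#' @param study_days End-of-study (right-censoring) day.
#' @param weibull_shape Shape parameter of the survival distribution
#'   (1 = exponential).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_mirnas = 44,
                              n_genes = 10000,
                              n_essential_genes = 20,
                              db_coverage = c(microcosm = 31 / 44,
                                              pictar = 28 / 44,
                                              mirnaorg = 43 / 44,
                                              targetscan = 40 / 44),
                              overlap_target = 0.056,
                              baseline_hazard = log(2) / 31,
                              hazard_ratio_range = c(1.5, 6),
                              rnai_hazard_ratio = 4,
                              n_flies_per_group = 60,
                              study_days = 90,
                              weibull_shape = 1,
                              seed = 1L) {
  stopifnot(
    n_mirnas >= 1, n_genes >= 10, n_essential_genes >= 0,
    n_essential_genes <= n_genes,
    all(db_coverage > 0), all(db_coverage <= 1),
    overlap_target > 0, overlap_target <= 1,
    baseline_hazard > 0, all(hazard_ratio_range > 0),
    length(hazard_ratio_range) == 2L,
    hazard_ratio_range[1] <= hazard_ratio_range[2],
    rnai_hazard_ratio > 0, n_flies_per_group >= 2, study_days > 0,
    weibull_shape > 0
  )
  structure(
    list(n_mirnas = n_mirnas, n_genes = n_genes,
         n_essential_genes = n_essential_genes, db_coverage = db_coverage,
         overlap_target = overlap_target, baseline_hazard = baseline_hazard,
         hazard_ratio_range = hazard_ratio_range,
         rnai_hazard_ratio = rnai_hazard_ratio,
         n_flies_per_group = n_flies_per_group, study_days = study_days,
         weibull_shape = weibull_shape, seed = as.integer(seed)),
    class = "screen_sim_config"
  )
}

# one global seed drives independent per-stage streams
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Simulate survival records for a set of genotypes
#'
#' Draws per-fly death times from a Weibull (default exponential)
#' distribution whose scale is set by `baseline_hazard` times the genotype's
#' hazard ratio, and right-censors flies alive at `study_days`.
#'
#' @param config A [screen_sim_config()].
#' @param hazard_ratios Named numeric vector: genotype label -> hazard ratio
#'   (control = 1 should be included by the caller).
#' @return Tibble of survival records: `subject_id`, `genotype`, `time`,
#'   `event`.
#' @export
simulate_survival <- function(config, hazard_ratios) {
  stopifnot(inherits(config, "screen_sim_config"),
            is.numeric(hazard_ratios), !is.null(names(hazard_ratios)),
            all(hazard_ratios > 0))
  withr::local_seed(stream_seed(config$seed, "survival"))
  n <- config$n_flies_per_group
  k <- config$weibull_shape
  out <- purrr::map_dfr(names(hazard_ratios), function(g) {
    rate <- config$baseline_hazard * hazard_ratios[[g]]
    # proportional hazards: S(t) = exp(-(rate * t)^k) with k the shape
    t <- stats::rweibull(n, shape = k, scale = 1 / rate)
    tibble::tibble(
      subject_id = paste0(g, "_fly", seq_len(n)),
      genotype = g,
      time = pmin(t, config$study_days),
      event = t <= config$study_days
    )
  })
  # observation-day times: deaths are recorded at whole days, never day 0
  out$time <- pmax(ceiling(out$time), 1)
  out
}

#' Simulate four miRNA target prediction databases with planted signal
#'
#' Each database receives its coverage fraction of the screened miRNAs and
#' an independent random subset of the gene universe (inclusion rate
#' `overlap_target^(1/n_db)`, so the expected four-way overlap matches
#' `overlap_target`). Background (miRNA, gene) scores are log-normal;
#' planted essential genes receive the 99th-percentile background score from
#' every targeting miRNA present in the database, making the ground truth
#' separable without degenerate ties. Scores are emitted in each database's
#' native dialect: microRNA.org raw scores negative (square root of the
#' intended magnitude), TargetScan as site lists whose points sum to the
#' intended score.
#'
#' @param config A [screen_sim_config()].
#' @param planted Named list: essential gene id -> character vector of
#'   targeting miRNA labels. Defaults to the planted map drawn by
#'   [simulate_screen()]; may be empty.
#' @return List with `databases` (named list of dialect tibbles ready for
#'   [read_prediction_tsv()]-style ingestion), `records` (the same data as
#'   transformed gene-level prediction records), `families` (TargetScan
#'   family table), `mirnas` (screened miRNA labels) and `present_mirnas`
#'   (per-database subsets, before family grouping).
#' @export
simulate_prediction_databases <- function(config, planted = list()) {
  stopifnot(inherits(config, "screen_sim_config"), is.list(planted))
  withr::local_seed(stream_seed(config$seed, "predictions"))
  mirnas <- sprintf("miR-s%02d", seq_len(config$n_mirnas))
  genes <- sprintf("CGS%05d", seq_len(config$n_genes))
  stopifnot(all(unlist(planted) %in% mirnas) || length(planted) == 0L,
            all(names(planted) %in% genes))
  dbs <- names(config$db_coverage)
  q <- config$overlap_target^(1 / length(dbs))
  meanlog <- 1; sdlog <- 1
  planted_score <- stats::qlnorm(0.99, meanlog, sdlog)

  # TargetScan families: a few 2-3 member groups among the screened miRNAs
  fam_members <- if (config$n_mirnas >= 10) {
    list(mirnas[1:3], mirnas[4:5])
  } else {
    list()
  }
  families <- purrr::map_dfr(fam_members, function(m) {
    tibble::tibble(family = paste(m, collapse = "/"), member = m)
  })
  to_family <- function(m) {
    if (nrow(families) == 0L) return(m)
    i <- match(m, families$member)
    ifelse(is.na(i), m, families$family[i])
  }

  records <- list()
  dialects <- list()
  present_mirnas <- list()
  for (db in dbs) {
    present <- sort(sample(mirnas, round(config$db_coverage[[db]] *
                                           config$n_mirnas)))
    present_mirnas[[db]] <- present
    covered <- genes[stats::runif(config$n_genes) < q]
    n_per_gene <- pmin(1L + stats::rpois(length(covered), 2), length(present))
    bg <- purrr::map2_dfr(covered, n_per_gene, function(g, k) {
      tibble::tibble(mirna = sample(present, k), gene_id = g)
    })
    bg$score <- stats::rlnorm(nrow(bg), meanlog, sdlog)
    pl <- purrr::map_dfr(names(planted), function(g) {
      hit <- intersect(planted[[g]], present)
      if (length(hit) == 0L) return(NULL)
      tibble::tibble(mirna = hit, gene_id = g, score = planted_score)
    })
    rec <- dplyr::bind_rows(bg, pl)
    rec <- rec[!duplicated(rec[, c("mirna", "gene_id")], fromLast = TRUE), ]
    rec$gene_name <- rec$gene_id
    if (db == "targetscan") {
      rec$mirna <- to_family(rec$mirna)
      rec <- dplyr::summarise(
        dplyr::group_by(rec, .data$mirna, .data$gene_id, .data$gene_name),
        score = max(.data$score), .groups = "drop"
      )
      dialects[[db]] <- targetscan_dialect(rec)
      rec$score <- purrr::map_dbl(rec$score, ts_quantised)
    } else if (db == "mirnaorg") {
      dialects[[db]] <- tibble::tibble(
        mirna = rec$mirna, gene_id = rec$gene_id, gene_name = rec$gene_name,
        transcript_id = paste0(rec$gene_id, "-RA"),
        raw_score = -sqrt(rec$score)
      )
    } else {
      dialects[[db]] <- tibble::tibble(
        mirna = rec$mirna, gene_id = rec$gene_id, gene_name = rec$gene_name,
        transcript_id = paste0(rec$gene_id, "-RA"),
        raw_score = rec$score
      )
    }
    rec$database <- db
    records[[db]] <- rec
  }
  list(databases = dialects, records = records, families = families,
       mirnas = mirnas, present_mirnas = present_mirnas)
}

# quantise a continuous score to the nearest achievable TargetScan point sum
ts_quantised <- function(score) {
  max(2, 2 * round(score / 2))
}

# decompose gene-level scores into site rows: conserved 8mers plus one
# smaller site for the remainder (all point values are even)
targetscan_dialect <- function(rec) {
  purrr::map_dfr(seq_len(nrow(rec)), function(i) {
    s <- ts_quantised(rec$score[i])
    n8 <- s %/% 10
    rem <- s - 10 * n8
    rows <- tibble::tibble(
      site_type = character(), conservation = character(), count = integer()
    )
    if (n8 > 0) rows <- tibble::add_row(rows, site_type = "8mer",
                                        conservation = "conserved",
                                        count = as.integer(n8))
    rem_site <- switch(as.character(rem),
      "8" = c("8mer", "poorly_conserved"),
      "6" = c("7mer-m8", "conserved"),
      "4" = c("7mer-1A", "conserved"),
      "2" = c("7mer-1A", "poorly_conserved"),
      NULL
    )
    if (!is.null(rem_site)) {
      rows <- tibble::add_row(rows, site_type = rem_site[1],
                              conservation = rem_site[2], count = 1L)
    }
    tibble::tibble(
      mirna_or_family = rec$mirna[i], gene_id = rec$gene_id[i],
      gene_name = rec$gene_name[i], site_type = rows$site_type,
      conservation = rows$conservation, count = rows$count
    )
  })
}

#' Simulate a complete screen with planted ground truth
#'
#' Draws per-miRNA hazard ratios (log-uniform over
#' `config$hazard_ratio_range`), simulates the miRNA lifespan screen against
#' a control genotype, computes per-miRNA strengths, plants
#' `n_essential_genes` essential genes each targeted by 3-5 of the
#' strongest-half miRNAs, generates the four prediction databases, and
#' simulates a two-line RNAi validation screen against every planted gene at
#' `rnai_hazard_ratio`.
#'
#' @param config A [screen_sim_config()].
#' @return List with `survival` (miRNA screen records incl. control),
#'   `line_results`, `strengths` (miRNA + family strengths), `predictions`
#'   (from [simulate_prediction_databases()]), `rnai_survival`,
#'   `rnai_lines` (per-line results keyed by gene), and `ground_truth`
#'   (planted genes, their targeting miRNAs, hazard ratios, seed).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  mirnas <- sprintf("miR-s%02d", seq_len(config$n_mirnas))
  genes <- sprintf("CGS%05d", seq_len(config$n_genes))

  withr::local_seed(stream_seed(config$seed, "design"))
  hr <- exp(stats::runif(config$n_mirnas,
                         log(config$hazard_ratio_range[1]),
                         log(config$hazard_ratio_range[2])))
  names(hr) <- mirnas
  strong_half <- names(sort(hr, decreasing = TRUE))[
    seq_len(ceiling(config$n_mirnas / 2))]
  planted_genes <- sample(genes, config$n_essential_genes)
  planted <- lapply(planted_genes, function(g) {
    sample(strong_half, min(sample(3:5, 1), length(strong_half)))
  })
  names(planted) <- planted_genes

  survival_records <- simulate_survival(config, c(control = 1, hr))
  ctrl <- survival_records[survival_records$genotype == "control", ]
  line_results <- screen_line_results(survival_records, "control")
  strengths <- line_strengths(
    tibble::tibble(mirna = line_results$line_id, chi2 = line_results$chi2,
                   direction = line_results$direction)
  )

  predictions <- simulate_prediction_databases(config, planted)
  if (nrow(predictions$families) > 0L) {
    strengths <- dplyr::bind_rows(
      strengths, family_strengths(strengths, predictions$families)
    )
  }

  rnai <- NULL
  rnai_lines <- NULL
  if (config$n_essential_genes > 0L) {
    rnai_hr <- stats::setNames(
      rep(config$rnai_hazard_ratio, 2L * config$n_essential_genes),
      paste0(rep(planted_genes, each = 2L), "_IR", 1:2)
    )
    rnai_cfg <- config
    rnai_cfg$seed <- stream_seed(config$seed, "rnai")
    rnai <- simulate_survival(rnai_cfg, c(control = 1, rnai_hr))
    rl <- screen_line_results(rnai, "control")
    rnai_lines <- tibble::tibble(
      gene_id = sub("_IR[12]$", "", rl$line_id),
      line_id = rl$line_id, median = rl$median_survival,
      chi2 = rl$chi2, p_value = rl$p_value, direction = rl$direction
    )
  }

  list(
    survival = survival_records, line_results = line_results,
    strengths = strengths, predictions = predictions,
    rnai_survival = rnai, rnai_lines = rnai_lines,
    ground_truth = list(planted = planted, hazard_ratios = hr,
                        seed = config$seed)
  )
}

#' Write a simulated screen to disk in the canonical formats
#'
#' Emits the survival TSV, one prediction TSV per database plus a manifest
#' JSON, the family table, the RNAi per-line TSV and a ground-truth JSON.
#'
#' @param sim Output of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_screen <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  surv <- sim$survival
  surv$event <- as.integer(surv$event)
  readr::write_tsv(surv, file.path(dir, "survival.tsv"))
  for (db in names(sim$predictions$databases)) {
    readr::write_tsv(sim$predictions$databases[[db]],
                     file.path(dir, paste0(db, ".tsv")))
  }
  jsonlite::write_json(
    stats::setNames(as.list(paste0(names(sim$predictions$databases), ".tsv")),
                    names(sim$predictions$databases)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  readr::write_tsv(sim$predictions$families, file.path(dir, "families.tsv"))
  if (!is.null(sim$rnai_lines)) {
    out <- sim$rnai_lines
    out$p_value <- format_p(out$p_value)
    readr::write_tsv(out, file.path(dir, "rnai_lines.tsv"))
  }
  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
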