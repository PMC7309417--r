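#' Kaplan-Meier estimate for one genotype
#'
#' Computes the product-limit estimate of the survival function from a set of
#' per-fly survival records. Censored records (flies alive at the end of the
#' study) reduce the number at risk without stepping the curve down.
#'
#' @param records A data frame with numeric column `time` (days, > 0) and
#'   logical/0-1 column `event` (`TRUE` = observed death, `FALSE` =
#'   right-censored).
#' @return A tibble of class `survival_curve` with one row per distinct
#'   observation time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#'   The curve is 1 before the first row and non-increasing thereafter.
#' @examples
#' km_estimate(data.frame(time = c(2, 3, 4), event = c(TRUE, FALSE, TRUE)))
#' @export
km_estimate <- function(records) {
  records <- check_survival_records(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = records, conf.type = "none"
  )
  curve <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  class(curve) <- c("survival_curve", class(curve))
  curve
}

#' Mantel-Cox log-rank test between two groups of survival records
#'
#' One-degree-of-freedom log-rank (Mantel-Cox) chi-square comparing two
#' survival samples, with ties handled by the standard discrete-time
#' hypergeometric variance. This is the statistic used to score every
#' transgenic line of the screen against its control.
#'
#' @param group_a,group_b Data frames with columns `time` and `event`.
#' @return A list with elements `chi2` (>= 0) and `p_value` (from the
#'   chi-square distribution with 1 df).
#' @examples
#' a <- data.frame(time = 1:3, event = TRUE)
#' b <- data.frame(time = 4:6, event = TRUE)
#' logrank_chi2(a, b)
#' @export
logrank_chi2 <- function(group_a, group_b) {
  group_a <- check_survival_records(group_a)
  group_b <- check_survival_records(group_b)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) {
    stop("no records", call. = FALSE)
  }
  pooled <- rbind(
    data.frame(time = group_a$time, event = group_a$event, group = "a"),
    data.frame(time = group_b$time, event = group_b$event, group = "b")
  )
  if (sum(pooled$event) == 0L) stop("no events", call. = FALSE)
  # identical samples give O = E everywhere; survdiff would divide 0/0
  if (nrow(group_a) == nrow(group_b)) {
    oa <- group_a[order(group_a$time, group_a$event), ]
    ob <- group_b[order(group_b$time, group_b$event), ]
    if (all(oa$time == ob$time) && all(oa$event == ob$event)) {
      return(list(chi2 = 0, p_value = 1))
    }
  }
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ group,
    data = pooled, rho = 0
  )
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest observed time at which the survival estimate drops to 0.5 or
#' below. Returns `NA_real_` when the curve never reaches 0.5 (more than half
#' the group still alive at the end of the study).
#'
#' @param curve A `survival_curve` as returned by [km_estimate()].
#' @return Median survival in days, or `NA_real_`.
#' @export
median_survival <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) > 0L)
  hit <- which(curve$survival <= 0.5 + 1e-12)
  if (length(hit) == 0L) return(NA_real_)
  curve$time[hit[1L]]
}

#' Score one screen line against its control
#'
#' Runs the log-rank comparison of a test genotype against the control group
#' and classifies the direction of the lifespan effect: `"shorten"` when the
#' difference is significant and the test median falls below the control
#' median, `"extend"` for a significant increase, `"none"` otherwise.
#'
#' @param test,control Data frames of survival records (`time`, `event`).
#' @param alpha Significance level for calling a direction (default 0.05).
#' @param line_id,gene_or_mirna Optional labels carried into the result.
#' @return A one-row tibble: `line_id`, `gene_or_mirna`, `chi2`, `p_value`,
#'   `median_survival`, `direction`.
#' @export
classify_direction <- function(test, control, alpha = 0.05,
                               line_id = NA_character_,
                               gene_or_mirna = NA_character_) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  lr <- logrank_chi2(test, control)
  med_test <- median_survival(km_estimate(test))
  med_ctrl <- median_survival(km_estimate(control))
  direction <- "none"
  if (lr$p_value < alpha) {
    if (is.na(med_test) && is.na(med_ctrl)) {
      stop("ambiguous direction: equal medians at p < alpha", call. = FALSE)
    }
    # an undefined median (curve never reaches 0.5) outlives a defined one
    m_test <- if (is.na(med_test)) Inf else med_test
    m_ctrl <- if (is.na(med_ctrl)) Inf else med_ctrl
    if (m_test == m_ctrl) {
      stop("ambiguous direction: equal medians at p < alpha", call. = FALSE)
    }
    direction <- if (m_test < m_ctrl) "shorten" else "extend"
  }
  tibble::tibble(
    line_id = line_id,
    gene_or_mirna = gene_or_mirna,
    chi2 = lr$chi2,
    p_value = lr$p_value,
    median_survival = med_test,
    direction = direction
  )
}

#' Score every line of a screen against the control genotype
#'
#' @param records Long-format survival records with columns `subject_id`,
#'   `genotype`, `time`, `event`.
#' @param control Genotype label of the control group.
#' @param alpha Significance level passed to [classify_direction()].
#' @param labels Optional named character vector mapping genotype (line id)
#'   to the gene or miRNA it targets.
#' @return A tibble with one row per non-control genotype.
#' @export
screen_line_results <- function(records, control, alpha = 0.05,
                                labels = NULL) {
  stopifnot(is.data.frame(records), "genotype" %in% names(records))
  if (!control %in% records$genotype) {
    stop("control genotype '", control, "' not found", call. = FALSE)
  }
  ctrl <- records[records$genotype == control, , drop = FALSE]
  lines <- setdiff(unique(records$genotype), control)
  purrr::map_dfr(lines, function(g) {
    classify_direction(
      records[records$genotype == g, , drop = FALSE], ctrl,
      alpha = alpha, line_id = g,
      gene_or_mirna = if (is.null(labels)) NA_character_ else
        unname(labels[g])
    )
  })
}

#' Read long-format survival records from TSV
#'
#' Expects a header `subject_id genotype time event` with `event` coded 0/1.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble of survival records with logical `event`.
#' @export
read_survival_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         subject_id = readr::col_character(),
                         genotype = readr::col_character(),
                         time = readr::col_double(),
                         event = readr::col_integer()
                       ))
  x$event <- x$event == 1L
  check_survival_records(x)
}

#' Write per-line screen results to TSV
#'
#' Emits `line_id chi2 p median direction`, with p-values displayed to four
#' decimal places and values below 1e-4 rendered as `<0.0001`.
#'
#' @param results Tibble from [screen_line_results()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_line_results_tsv <- function(results, path) {
  out <- data.frame(
    line_id = results$line_id,
    chi2 = format_4dp(results$chi2),
    p = format_p(results$p_value),
    median = results$median_survival,
    direction = results$direction
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_survival_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("time", "event") %in% names(records))) {
    stop("records need columns 'time' and 'event'", call. = FALSE)
  }
  if (is.numeric(records$event)) records$event <- records$event != 0
  stopifnot(is.logical(records$event))
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("survival times must be positive and finite", call. = FALSE)
  }
  records
}

#' Display helpers matching the screen tables
#'
#' `format_p()` renders p-values to four decimals with `<0.0001` below 1e-4;
#' `format_4dp()` rounds half away from zero to four decimals, the convention
#' used throughout the exported tables.
#'
#' @param p,x Numeric vectors.
#' @return Character (`format_p`) or numeric (`round_half_up`) vectors.
#' @name display-helpers
NULL

#' @rdname display-helpers
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))
}

#' @rdname display-helpers
#' @param digits Number of decimal places.
#' @export
round_half_up <- function(x, digits = 4) {
  # snap to 6 extra decimals first so values sitting on a .5 boundary in
  # decimal (but a hair below it in binary) still round away from zero
  sign(x) * floor(round(abs(x) * 10^digits + 0.5, 6)) / 10^digits
}

format_4dp <- function(x) sprintf("%.4f", round_half_up(x, 4))
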