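#' Signed chi-square for a screen line
#'
#' Lines whose knockdown (or miRNA overexpression) significantly *extends*
#' lifespan act against the expected direction of the screen and their
#' chi-square enters all averages with a negative sign. Lines that shorten
#' lifespan, and non-significant lines, keep the positive sign regardless of
#' any median trend.
#'
#' @param chi2 Non-negative log-rank chi-square value(s).
#' @param direction Character vector in `c("shorten", "extend", "none")`.
#' @return Numeric vector of signed chi-square values.
#' @examples
#' signed_chi2(4.39, "extend")   # -4.39
#' signed_chi2(0.0939, "none")   # +0.0939
#' @export
signed_chi2 <- function(chi2, direction) {
  stopifnot(is.numeric(chi2), all(chi2 >= 0))
  bad <- setdiff(unique(direction), c("shorten", "extend", "none"))
  if (length(bad) > 0L) {
    stop("unknown direction: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ifelse(direction == "extend", -chi2, chi2)
}

#' Average strength from signed line values
#'
#' Two or more lines are averaged arithmetically. A miRNA or gene tested with
#' a single line is averaged with an assumed neutral (zero) second line, i.e.
#' its signed chi-square is halved, so that single-line evidence is
#' deliberately down-weighted.
#'
#' @param signed Numeric vector of signed chi-square values, one per line.
#' @return The average strength Av(chi-square), a single number.
#' @examples
#' average_strength(c(42.48, 48.28))  # 45.38
#' average_strength(0.3743)           # 0.18715
#' @export
average_strength <- function(signed) {
  stopifnot(is.numeric(signed))
  if (length(signed) == 0L) stop("no lines to average", call. = FALSE)
  if (any(!is.finite(signed))) stop("non-finite signed chi2", call. = FALSE)
  if (length(signed) == 1L) signed / 2 else mean(signed)
}

#' Per-label average strengths from a table of lines
#'
#' Groups a per-line table by its label column (miRNA for the primary screen,
#' gene for the RNAi validation screen) and applies [average_strength()] to
#' the signed chi-squares of each group.
#'
#' @param lines Data frame with columns `chi2`, `direction` and the grouping
#'   column named by `label`.
#' @param label Name of the grouping column (default `"mirna"`).
#' @return Tibble with columns `mirna_or_family` (the label), `av_chi2`,
#'   `n_lines_used`.
#' @export
line_strengths <- function(lines, label = "mirna") {
  stopifnot(is.data.frame(lines), label %in% names(lines),
            all(c("chi2", "direction") %in% names(lines)))
  lines$.signed <- signed_chi2(lines$chi2, lines$direction)
  out <- dplyr::summarise(
    dplyr::group_by(lines, mirna_or_family = .data[[label]]),
    av_chi2 = average_strength(.data$.signed),
    n_lines_used = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$mirna_or_family)
}

#' Average strength of a miRNA family
#'
#' TargetScan groups related miRNAs into seed families; a family is treated
#' as one unit whose strength is the plain arithmetic mean of its members'
#' average strengths (members with lifespan-extending effects contribute
#' negative values).
#'
#' @param member_strengths Numeric vector of member `av_chi2` values.
#' @return The family average strength.
#' @examples
#' family_strength(c(94.48, 106.515, 67.48))  # 89.49167
#' @export
family_strength <- function(member_strengths) {
  stopifnot(is.numeric(member_strengths))
  if (length(member_strengths) == 0L) stop("empty family", call. = FALSE)
  mean(member_strengths)
}

#' Family strengths from a member table
#'
#' @param strengths Tibble from [line_strengths()] (columns
#'   `mirna_or_family`, `av_chi2`).
#' @param families Data frame with columns `family`, `member`; members absent
#'   from `strengths` are dropped with a warning (their strengths were never
#'   measured).
#' @return Tibble with one row per family: `mirna_or_family`, `av_chi2`,
#'   `n_lines_used` (number of members averaged).
#' @export
family_strengths <- function(strengths, families) {
  stopifnot(all(c("family", "member") %in% names(families)))
  known <- families$member %in% strengths$mirna_or_family
  if (any(!known)) {
    warning("dropping family members without measured strength: ",
            paste(unique(families$member[!known]), collapse = ", "),
            call. = FALSE)
    families <- families[known, , drop = FALSE]
  }
  if (nrow(families) == 0L) {
    return(tibble::tibble(mirna_or_family = character(),
                          av_chi2 = double(), n_lines_used = integer()))
  }
  joined <- dplyr::inner_join(families,
                              strengths[, c("mirna_or_family", "av_chi2")],
                              by = c(member = "mirna_or_family"),
                              relationship = "many-to-one")
  dplyr::summarise(
    dplyr::group_by(joined, mirna_or_family = .data$family),
    av_chi2 = family_strength(.data$av_chi2),
    n_lines_used = dplyr::n(),
    .groups = "drop"
  )
}

#' Read per-line strengths input / write strength table
#'
#' `read_strength_lines_tsv()` expects a header
#' `mirna_or_gene line_id chi2 p direction`;
#' `write_strengths_tsv()` emits `label av_chi2 n_lines` with `av_chi2`
#' rounded half-up to four decimals.
#'
#' @param path File path.
#' @return A tibble (reader) or `path` invisibly (writer).
#' @name strength-io
NULL

#' @rdname strength-io
#' @export
read_strength_lines_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    mirna_or_gene = readr::col_character(),
                    line_id = readr::col_character(),
                    chi2 = readr::col_double(),
                    p = readr::col_double(),
                    direction = readr::col_character()
                  ))
}

#' @rdname strength-io
#' @param strengths Tibble with `mirna_or_family`, `av_chi2`, `n_lines_used`.
#' @export
write_strengths_tsv <- function(strengths, path) {
  out <- data.frame(
    label = strengths$mirna_or_family,
    av_chi2 = format_4dp(strengths$av_chi2),
    n_lines = strengths$n_lines_used
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
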