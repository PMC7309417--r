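test_that("Kaplan-Meier handles degenerate and censored inputs", {
  # all flies die on the same day
  curve <- km_estimate(small_records(rep(10, 10)))
  expect_equal(curve$time, 10)
  expect_equal(curve$survival, 0)
  expect_equal(curve$n_risk, 10)

  # all censored: curve stays at 1
  curve <- km_estimate(small_records(c(5, 7, 9), event = FALSE))
  expect_true(all(curve$survival == 1))

  # deaths at 2 and 4 with a censor at 3 among n = 3:
  # S(2) = 2/3, then at_risk = 1 so S(4) = 0
  curve <- km_estimate(data.frame(time = c(2, 3, 4),
                                  event = c(TRUE, FALSE, TRUE)))
  expect_equal(curve$survival[curve$time == 2], 2 / 3)
  expect_equal(curve$survival[curve$time == 4], 0)
  expect_equal(curve$n_risk[curve$time == 4], 1)

  expect_error(km_estimate(data.frame(time = numeric(), event = logical())),
               "no records")
  expect_error(km_estimate(small_records(c(1, -2))), "positive")
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  set.seed(11)
  for (rep in 1:5) {
    t <- ceiling(rexp(40, 0.05))
    curve <- km_estimate(small_records(t))
    oracle <- km_oracle(t, rep(TRUE, length(t)))
    expect_equal(curve$survival, oracle$survival, tolerance = 1e-12)
    # empirical: fraction strictly surviving past each time
    emp <- vapply(curve$time, function(x) mean(t > x), numeric(1))
    expect_equal(curve$survival, emp)
  }
})

test_that("Kaplan-Meier matches the hand product-limit oracle with censoring", {
  set.seed(42)
  for (rep in 1:5) {
    t <- ceiling(rexp(30, 0.04))
    ev <- runif(30) < 0.7
    curve <- km_estimate(data.frame(time = t, event = ev))
    oracle <- km_oracle(t, ev)
    expect_equal(curve$survival,
                 oracle$survival[oracle$time %in% curve$time],
                 tolerance = 1e-12)
  }
})

test_that("log-rank is zero for identical groups and matches the O-E/V oracle", {
  a <- small_records(c(3, 5, 8, 13))
  res <- logrank_chi2(a, a)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)

  # separated fixture evaluated against the direct observed-minus-expected sum
  a <- small_records(1:3)
  b <- small_records(4:6)
  res <- logrank_chi2(a, b)
  expect_equal(res$chi2, logrank_oracle(a$time, a$event, b$time, b$event),
               tolerance = 1e-10)

  # with ties and censoring
  set.seed(5)
  for (rep in 1:5) {
    p <- sim_exp_pair(25, 0.04, 0.08, 60)
    p$a$time <- ceiling(p$a$time); p$b$time <- ceiling(p$b$time)
    res <- logrank_chi2(p$a, p$b)
    expect_equal(res$chi2,
                 logrank_oracle(p$a$time, p$a$event, p$b$time, p$b$event),
                 tolerance = 1e-8)
    # symmetry in the arguments
    expect_equal(res$chi2, logrank_chi2(p$b, p$a)$chi2, tolerance = 1e-12)
  }

  expect_error(logrank_chi2(small_records(3, FALSE), small_records(4, FALSE)),
               "no events")
})

test_that("chi2 grows as the hazard ratio moves away from 1", {
  set.seed(99)
  mean_chi2 <- vapply(c(1, 1.5, 2.5, 4), function(hr) {
    mean(replicate(40, {
      p <- sim_exp_pair(60, log(2) / 31, log(2) / 31 * hr, 90)
      logrank_chi2(p$a, p$b)$chi2
    }))
  }, numeric(1))
  expect_true(all(diff(mean_chi2) > 0))
})

test_that("median survival follows the curve definition", {
  expect_equal(median_survival(km_estimate(small_records(rep(10, 8)))), 10)
  # survival never drops below 0.6
  curve <- km_estimate(data.frame(time = c(5, 30, 30, 30, 30),
                                  event = c(TRUE, FALSE, FALSE, FALSE, FALSE)))
  expect_true(all(curve$survival >= 0.6))
  expect_true(is.na(median_survival(curve)))
  # uniform deaths at days 1..100
  expect_equal(median_survival(km_estimate(small_records(1:100))), 50)
})

test_that("direction classification respects alpha and the median comparison", {
  set.seed(3)
  ctrl <- small_records(ceiling(rexp(60, log(2) / 31)))
  short <- small_records(ceiling(rexp(60, log(2) / 8)))
  res <- classify_direction(short, ctrl, line_id = "L1")
  expect_equal(res$direction, "shorten")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$line_id, "L1")

  long <- small_records(ceiling(rexp(60, log(2) / 120)))
  expect_equal(classify_direction(long, ctrl)$direction, "extend")

  # identical groups: no direction
  expect_equal(classify_direction(ctrl, ctrl)$direction, "none")

  # significant difference in shape but equal medians is refused
  a <- small_records(rep(c(10, 11), c(30, 30)))
  b <- small_records(rep(c(1, 10, 40), c(20, 21, 19)))
  med_a <- median_survival(km_estimate(a))
  med_b <- median_survival(km_estimate(b))
  if (med_a == med_b && logrank_chi2(a, b)$p_value < 0.05) {
    expect_error(classify_direction(a, b), "ambiguous direction")
  }
})

test_that("screen-level scoring and TSV round trips work", {
  set.seed(8)
  rec <- rbind(
    data.frame(subject_id = paste0("c", 1:40), genotype = "control",
               time = ceiling(rexp(40, 0.02)), event = TRUE),
    data.frame(subject_id = paste0("x", 1:40), genotype = "lineX",
               time = ceiling(rexp(40, 0.12)), event = TRUE)
  )
  res <- screen_line_results(rec, "control", labels = c(lineX = "geneX"))
  expect_equal(nrow(res), 1L)
  expect_equal(res$gene_or_mirna, "geneX")
  expect_equal(res$direction, "shorten")

  tsv <- tempfile(fileext = ".tsv")
  rec$event <- as.integer(rec$event)
  utils::write.table(rec, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_survival_tsv(tsv)
  expect_equal(nrow(back), 80L)
  expect_type(back$event, "logical")

  out <- tempfile(fileext = ".tsv")
  write_line_results_tsv(res, out)
  shown <- utils::read.delim(out)
  expect_equal(names(shown), c("line_id", "chi2", "p", "median", "direction"))

  expect_error(screen_line_results(rec, "nope"), "not found")
})

test_that("p-value display renders four decimals with a floor marker", {
  expect_equal(format_p(c(0.7593, 0.0361, 5e-5)),
               c("0.7593", "0.0361", "<0.0001"))
  expect_equal(round_half_up(c(0.99775, -2.14805, 0.18715), 4),
               c(0.9978, -2.1481, 0.1872))
})
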