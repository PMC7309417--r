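# Independent hand implementations used as oracles. These deliberately use
# plain loops over the definitions rather than any package code path.

# product-limit estimate by direct recursion over distinct times
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time))
  s <- 1
  out <- data.frame(time = times, survival = NA_real_, n_risk = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
    out$n_risk[i] <- at_risk
  }
  out
}

# two-group log-rank statistic from the O - E / V definition with
# hypergeometric tie handling
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  times <- sort(unique(c(time_a[event_a], time_b[event_b])))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t)
    d1 <- sum(time_a == t & event_a); d2 <- sum(time_b == t & event_b)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2 || d == 0) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# exponential survival pair with end-of-study censoring, for null simulations
sim_exp_pair <- function(n, rate_a, rate_b, study_days) {
  mk <- function(rate) {
    t <- stats::rexp(n, rate)
    data.frame(time = pmin(t, study_days), event = t <= study_days)
  }
  list(a = mk(rate_a), b = mk(rate_b))
}

# brute-force gene x database pooled sum over a long table of
# (database, gene_id, normalised) rows
pool_oracle <- function(long) {
  genes <- unique(long$gene_id)
  vapply(setNames(genes, genes), function(g) {
    sum(long$normalised[long$gene_id == g])
  }, numeric(1))
}

# brute-force Venn census: per gene, test membership in every set
venn_oracle <- function(sets) {
  universe <- unique(unlist(sets))
  pattern <- vapply(universe, function(g) {
    paste(vapply(sets, function(s) g %in% s, logical(1)), collapse = ",")
  }, character(1))
  table(pattern)
}

small_records <- function(time, event = TRUE) {
  data.frame(time = time, event = rep_len(event, length(time)))
}
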