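strengths_fixture <- tibble::tibble(
  mirna_or_family = c("miR-1", "fam-neg", "miR-9a"),
  av_chi2 = c(44.2375, -4.104, 94.48)
)

test_that("step 1 multiplies scores by miRNA strength and skips unscreened", {
  preds <- tibble::tibble(
    mirna = c("miR-1", "miR-1", "fam-neg", "miR-unknown"),
    gene_id = c("G1", "G2", "G1", "G3"),
    score = c(5, 0, 3, 2)
  )
  expect_warning(w <- step1_weighted(preds, strengths_fixture),
                 "miR-unknown")
  expect_equal(w$weighted[w$mirna == "miR-1" & w$gene_id == "G1"],
               5 * 44.2375)
  expect_equal(w$weighted[w$mirna == "miR-1" & w$gene_id == "G2"], 0)
  expect_equal(w$weighted[w$mirna == "fam-neg"], -12.312)
  expect_false("G3" %in% w$gene_id)
})

test_that("step 2 sums weighted values per gene, matching a brute-force loop", {
  s1 <- tibble::tibble(
    mirna = c("a", "b", "c", "a"),
    gene_id = c("G1", "G1", "G1", "G2"),
    gene_name = NA_character_,
    weighted = c(10, 20, 30, 7)
  )
  s2 <- step2_gene_sum(s1)
  expect_equal(s2$sigma[s2$gene_id == "G1"], 60)
  expect_equal(s2$sigma[s2$gene_id == "G2"], 7)

  set.seed(31)
  for (rep in 1:5) {
    rnd <- tibble::tibble(
      mirna = sample(letters[1:6], 40, TRUE),
      gene_id = sample(paste0("G", 1:12), 40, TRUE),
      gene_name = NA_character_,
      weighted = rnorm(40)
    )
    rnd <- rnd[!duplicated(rnd[, c("mirna", "gene_id")]), ]
    got <- step2_gene_sum(rnd)
    # brute force double loop over the (mirna, gene) grid
    for (g in unique(rnd$gene_id)) {
      expect_equal(got$sigma[got$gene_id == g],
                   sum(rnd$weighted[rnd$gene_id == g]))
    }
  }
})

test_that("normalisation scales the top gene to 100 x coverage fraction", {
  tbl <- tibble::tibble(gene_id = c("G1", "G2", "G3"),
                        gene_name = NA_character_,
                        sigma = c(200, 100, -40))
  out <- normalise_ranking(tbl, n_mirnas_present = 31, n_screened = 44)
  expect_equal(out$normalised[1], 100 * 31 / 44)  # 70.4545...
  expect_equal(round_half_up(out$normalised[1], 4), 70.4545)
  out2 <- normalise_ranking(tbl, 44, 44)
  expect_equal(out2$normalised[2], 50)
  # all-equal sigmas all get the full weighted value
  eqv <- tibble::tibble(gene_id = c("a", "b"), gene_name = NA, sigma = c(3, 3))
  expect_equal(normalise_ranking(eqv, 22, 44)$normalised, c(50, 50))
  # order preservation and range bound
  expect_equal(order(out$normalised, decreasing = TRUE),
               order(tbl$sigma, decreasing = TRUE))
  expect_true(all(abs(out$normalised) <= 100 * 31 / 44 + 1e-12))

  expect_error(normalise_ranking(
    tibble::tibble(gene_id = "g", gene_name = NA, sigma = -1), 10, 44),
    "degenerate ranking")
  expect_error(normalise_ranking(tbl, 0, 44))
})

test_that("pooling sums normalised values across databases", {
  mk <- function(genes, norms) {
    tibble::tibble(gene_id = genes, gene_name = genes,
                   sigma = norms, normalised = norms)
  }
  # a gene's pooled score is the sum of its per-database normalised values
  dbs <- list(
    microcosm = mk(c("garz", "x"), c(4.7120, 1)),
    pictar = mk(c("garz"), c(0.5962)),
    mirnaorg = mk(c("garz", "x"), c(6.4735, 2)),
    targetscan = mk(c("garz"), c(19.5843))
  )
  pooled <- pool_databases(dbs)
  expect_equal(pooled$pooled[pooled$gene_id == "garz"], 31.366)
  expect_equal(pooled$pooled[pooled$gene_id == "x"], 3)
  expect_true(pooled$in_all[pooled$gene_id == "garz"])
  expect_false(pooled$in_all[pooled$gene_id == "x"])
  # single-database gene keeps its value; invariant to database order
  expect_equal(pool_databases(rev(dbs))$pooled, pooled$pooled)

  # random instance vs brute force over the database x gene grid
  set.seed(13)
  for (rep in 1:3) {
    rnd <- lapply(setNames(1:4, paste0("db", 1:4)), function(i) {
      g <- sample(paste0("G", 1:15), sample(5:12, 1))
      mk(g, runif(length(g), -5, 50))
    })
    got <- pool_databases(rnd)
    long <- purrr::map_dfr(rnd, ~.x[, c("gene_id", "normalised")])
    oracle <- pool_oracle(long)
    expect_equal(setNames(got$pooled, got$gene_id)[names(oracle)], oracle)
    # dense descending rank with lexicographic tie-break
    expect_true(all(diff(got$pooled) <= 1e-12))
    expect_equal(got$rank, cumsum(!duplicated(got$pooled)))
  }
})

test_that("the common-target census matches brute-force membership tests", {
  same <- replicate(4, paste0("G", 1:7), simplify = FALSE)
  names(same) <- paste0("db", 1:4)
  ct <- common_targets(same)
  expect_equal(length(ct$intersection), 7L)
  only_all <- ct$regions$count[rowSums(ct$regions[, 1:4]) == 4]
  expect_equal(only_all, 7L)
  expect_true(all(ct$regions$count[rowSums(ct$regions[, 1:4]) < 4] == 0L))

  disjoint <- list(a = "G1", b = "G2", c = "G3", d = "G4")
  expect_equal(length(common_targets(disjoint)$intersection), 0L)

  set.seed(77)
  for (rep in 1:3) {
    sets <- lapply(setNames(1:4, paste0("db", 1:4)), function(i) {
      sample(paste0("G", 1:40), sample(10:30, 1))
    })
    ct <- common_targets(sets)
    oracle <- venn_oracle(sets)
    expect_equal(sum(ct$regions$count), length(unique(unlist(sets))))
    got_pattern <- apply(ct$regions[, 1:4], 1, paste, collapse = ",")
    for (i in seq_along(got_pattern)) {
      expected <- if (got_pattern[i] %in% names(oracle))
        unname(oracle[[got_pattern[i]]]) else 0L
      expect_equal(ct$regions$count[i], expected)
    }
    expect_equal(sort(ct$intersection),
                 sort(Reduce(intersect, sets)))
  }
})

test_that("stronger planted targeting yields higher pooled rank end-to-end", {
  # genes hit by many strong miRNAs with high scores must outrank weak ones
  set.seed(101)
  mirnas <- paste0("m", 1:10)
  strengths <- tibble::tibble(mirna_or_family = mirnas,
                              av_chi2 = runif(10, 5, 100))
  genes <- paste0("G", 1:60)
  effect_mass <- setNames(numeric(60), genes)
  dbs <- lapply(setNames(1:4, paste0("db", 1:4)), function(i) {
    rows <- purrr::map_dfr(genes, function(g) {
      k <- sample(1:4, 1)
      tibble::tibble(mirna = sample(mirnas, k), gene_id = g,
                     score = rlnorm(k, 1, 1))
    })
    rows
  })
  for (db in dbs) {
    m <- setNames(strengths$av_chi2, strengths$mirna_or_family)
    mass <- tapply(db$score * m[db$mirna], db$gene_id, sum)
    effect_mass[names(mass)] <- effect_mass[names(mass)] + mass
  }
  rankings <- lapply(dbs, function(d) {
    rank_database(d, strengths, n_screened = 10)
  })
  pooled <- pool_databases(rankings)
  rho <- cor(effect_mass[pooled$gene_id], pooled$pooled, method = "spearman")
  expect_gt(rho, 0.8)
})
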