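test_that("duplicated-column self-comparison yields the null everywhere", {
  m <- random_matrix(50, 3, seed = 2)
  mm <- cbind(m, m)
  colnames(mm) <- paste0("S", 1:6)
  de <- differential_expression(mm, paste0("S", 1:3), paste0("S", 4:6))
  expect_true(all(de$fold_change == 1))
  expect_true(all(de$p_value == 1))
  expect_identical(nrow(filter_hits(de)), 0L)
})

test_that("t statistics and p-values match the stats::t.test oracle", {
  m <- random_matrix(30, 9, seed = 9)
  ga <- paste0("S", sprintf("%03d", 1:4))
  gb <- paste0("S", sprintf("%03d", 5:9))
  for (ve in c(TRUE, FALSE)) {
    de <- differential_expression(m, ga, gb, var_equal = ve)
    p_oracle <- apply(m, 1, function(row)
      t.test(row[ga], row[gb], var.equal = ve)$p.value)
    expect_equal(de$p_value, unname(p_oracle), tolerance = 1e-12)
  }
})

test_that("a strong constructed probe gives the expected t-test and fold change", {
  # linear-scale means 8 vs 2, within-group SD 0.01, n = 3 vs 3
  set.seed(3)
  probe <- c(rnorm(3, 8, 0.01), rnorm(3, 2, 0.01))
  m <- rbind(signal = probe, noise = abs(rnorm(6, 5, 0.5)))
  colnames(m) <- paste0("S", 1:6)
  de <- differential_expression(m, paste0("S", 1:3), paste0("S", 4:6),
                                values = "linear")
  sig <- de[de$probe_id == "signal", ]
  expect_lt(sig$p_value, 1e-6)
  expect_equal(sig$fold_change, mean(probe[1:3]) / mean(probe[4:6]))
  expect_equal(sig$fold_change, 4, tolerance = 0.02)
  p_oracle <- t.test(log2(probe[1:3]), log2(probe[4:6]),
                     var.equal = TRUE)$p.value
  expect_equal(sig$p_value, p_oracle, tolerance = 1e-12)
})

test_that("log2 input reports geometric-mean fold changes with direction", {
  m <- matrix(c(rep(5, 3), rep(3, 3),    # +4-fold (log2 diff = 2)
                rep(2, 3), rep(4, 3)),   # -4-fold
              nrow = 2, byrow = TRUE,
              dimnames = list(c("up", "down"), paste0("S", 1:6)))
  m <- m + matrix(rnorm(12, sd = 1e-9), 2)  # break exact zero variance
  de <- differential_expression(m, paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(de$fold_change[de$probe_id == "up"], 4, tolerance = 1e-6)
  expect_equal(de$fold_change[de$probe_id == "down"], -4, tolerance = 1e-6)
})

test_that("BH adjustment matches a hand-applied step-up and is order-stable", {
  m <- random_matrix(100, 8, seed = 10)
  de <- differential_expression(m, sprintf("S%03d", 1:4), sprintf("S%03d", 5:8))
  expect_equal(de$q_value, oracle_bh(de$p_value), tolerance = 1e-12)
  # q non-decreasing in sorted-p order
  o <- order(de$p_value)
  expect_true(all(diff(de$q_value[o]) >= -1e-15))
  # permuting probe order does not change any q
  perm <- sample(nrow(m))
  de2 <- differential_expression(m[perm, ], sprintf("S%03d", 1:4),
                                 sprintf("S%03d", 5:8))
  expect_equal(de2$q_value[match(de$probe_id, de2$probe_id)], de$q_value)
})

test_that("filter thresholds are inclusive on p and strict on fold change", {
  rec <- data.frame(probe_id = c("a", "b", "c"),
                    mean_a = 1, mean_b = 1,
                    fold_change = c(2.5, 2.0, -3),
                    p_value = c(0.001, 0.001, 0.2),
                    q_value = c(0.05, 0.01, 0.2),
                    passes = NA)
  kept <- filter_hits(rec)
  expect_identical(kept$probe_id, "a")   # q = 0.05 exactly is kept
  # b dropped: fold change 2.0 is not > 2;  c dropped: q above cutoff
  raw <- filter_hits(rec, use_adjusted = FALSE)
  expect_setequal(raw$probe_id, c("a"))
  expect_identical(nrow(filter_hits(rec[0, ])), 0L)
})

test_that("group validation catches overlap, absence and tiny groups", {
  m <- random_matrix(5, 6, seed = 1)
  s <- colnames(m)
  expect_error(differential_expression(m, s[1:3], s[3:6]), "overlap")
  expect_error(differential_expression(m, s[1:3], c(s[4:5], "nope")),
               "not in matrix")
  expect_error(differential_expression(m, s[1], s[2:4]), "at least 2")
  neg <- m
  expect_error(differential_expression(neg, s[1:3], s[4:6], values = "linear"),
               "positive")
})

test_that("enrichment odds ratio is the cross product with Fisher p", {
  # proportional table: 10/100 hit rate both inside and outside the set
  universe <- paste0("g", 1:600)
  pathway <- paste0("g", 1:100)
  hits <- paste0("g", c(1:10, 101:150))
  res <- enrichment_odds_ratio(hits, pathway, universe)
  expect_equal(res$odds_ratio, 1.0)
  expect_false(res$continuity_corrected)

  # direct cross-product arithmetic on a fixed table
  universe2 <- paste0("u", 1:1000)
  pathway2 <- paste0("u", 1:100)
  hits2 <- paste0("u", c(1:10, 996:1000))
  res2 <- enrichment_odds_ratio(hits2, pathway2, universe2)
  expect_identical(res2$counts["in_set", "hit"], 10L)
  expect_equal(res2$odds_ratio, (10 * 895) / (90 * 5))
})

test_that("odds ratio and p agree with independent oracles on random tables", {
  set.seed(19)
  for (i in 1:50) {
    n_univ <- sample(50:400, 1)
    universe <- paste0("g", seq_len(n_univ))
    pathway <- sample(universe, sample(5:30, 1))
    hits <- sample(universe, sample(5:40, 1))
    res <- enrichment_odds_ratio(hits, pathway, universe)
    a <- length(intersect(pathway, hits)); b <- length(pathway) - a
    c <- length(hits) - a; d <- n_univ - a - b - c
    or_oracle <- if (any(c(a, b, c, d) == 0))
      (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)) else a * d / (b * c)
    expect_equal(res$odds_ratio, or_oracle, tolerance = 1e-9)
    expect_equal(res$p_value, oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("zero cells trigger the continuity correction and are flagged", {
  universe <- paste0("g", 1:50)
  res <- enrichment_odds_ratio(hits = paste0("g", 1:5),
                               pathway = paste0("g", 1:5),
                               universe = universe)
  expect_true(res$continuity_corrected)
  expect_true(is.finite(res$odds_ratio))
  expect_gt(res$odds_ratio, 1)
  expect_error(enrichment_odds_ratio(c("g1", "zz"), paste0("g", 1:5), universe),
               "not in universe")
})

test_that("gene-set files parse in plain and GMT form", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("GENE1", "GENE2", "GENE2", " GENE3"), f)
  sets <- read_gene_sets(f)
  expect_length(sets, 1)
  expect_setequal(sets[[1]], c("GENE1", "GENE2", "GENE3"))

  g <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tGENE1\tGENE2", "setB\tdesc\tGENE9"), g)
  gmt <- read_gene_sets(g)
  expect_identical(names(gmt), c("setA", "setB"))
  expect_identical(gmt$setB, "GENE9")
  expect_error(read_gene_sets(withr::local_tempfile()), "not found")
})
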