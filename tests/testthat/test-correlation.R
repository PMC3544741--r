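test_that("the screen recovers exact linear relationships", {
  x <- rbind(seedg = c(1, 2, 3, 4), dbl = c(2, 4, 6, 8))
  sc <- pearson_screen(x, "seedg")
  self <- sc[sc$probe_id == "seedg", ]
  expect_equal(self$pearson_R, 1)
  expect_equal(self$slope, 1)
  expect_true(self$is_seed)
  cand <- sc[sc$probe_id == "dbl", ]
  expect_equal(cand$pearson_R, 1)
  expect_equal(cand$slope, 2)
})

test_that("R, p and slope match the covariance-formula oracle", {
  set.seed(21)
  expr <- matrix(rnorm(12 * 10, 7, 1.2), 12, 10,
                 dimnames = list(sprintf("p%02d", 1:12), NULL))
  sc <- pearson_screen(expr, "p01")
  for (i in 2:12) {
    o <- pearson_oracle(expr["p01", ], expr[i, ])
    row <- sc[sc$probe_id == rownames(expr)[i], ]
    expect_equal(row$pearson_R, o$r, tolerance = 1e-12)
    expect_equal(row$p_two_sided, o$p, tolerance = 1e-12)
    expect_equal(row$slope, o$slope, tolerance = 1e-12)
  }
})

test_that("the screen is invariant to sample order and drops NA pairs", {
  set.seed(22)
  expr <- matrix(rnorm(5 * 30), 5, 30,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  perm <- sample(30)
  a <- pearson_screen(expr, "g1")
  b <- pearson_screen(expr[, perm], "g1")
  expect_equal(a$pearson_R, b$pearson_R, tolerance = 1e-12)
  expect_equal(a$slope, b$slope, tolerance = 1e-12)

  # pairwise deletion: NAs in a candidate shrink its n only
  expr2 <- expr
  expr2["g3", 1:4] <- NA
  sc <- pearson_screen(expr2, "g1")
  expect_equal(sc$n_samples[sc$probe_id == "g3"], 26L)
  expect_equal(sc$n_samples[sc$probe_id == "g2"], 30L)
  o <- pearson_oracle(expr["g1", 5:30], expr["g3", 5:30])
  expect_equal(sc$pearson_R[sc$probe_id == "g3"], o$r, tolerance = 1e-12)

  # zero-variance probes are flagged, not fatal
  expr2["g5", ] <- 4
  sc2 <- pearson_screen(expr2, "g1")
  expect_true(sc2$flagged[sc2$probe_id == "g5"])
  expect_true(is.na(sc2$pearson_R[sc2$probe_id == "g5"]))
})

test_that("candidate filtering applies inclusive cutoffs to positive correlations", {
  rec <- data.frame(
    probe_id = c("at_cut", "strong_neg", "weak", "good", "flagged"),
    gene_symbol = NA_character_,
    pearson_R = c(0.45, -0.9, 0.3, 0.8, NA),
    p_two_sided = c(0.001, 1e-10, 0.0005, 1e-6, NA),
    slope = c(1, -2, 0.2, 1.5, NA),
    n_samples = 100L,
    flagged = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    is_seed = FALSE)
  kept <- filter_candidates(rec)
  # boundary record kept (inclusive), negative and weak excluded
  expect_setequal(kept$probe_id, c("at_cut", "good"))
  # sorted by descending slope
  expect_equal(kept$probe_id, c("good", "at_cut"))

  # the seed row is never returned as its own candidate
  rec$is_seed[4] <- TRUE
  expect_false("good" %in% filter_candidates(rec)$probe_id)
})

test_that("a planted module at R = 0.7 survives the published cutoffs", {
  set.seed(23)
  seedp <- rnorm(263, 7, 1)
  M <- simulate_correlated_module(seedp, 20, target_R = 0.7, seed = 3)
  expr <- rbind(seedgene = seedp, M)
  sc <- pearson_screen(expr, "seedgene")
  kept <- filter_candidates(sc, min_R = 0.45, max_p = 0.001)
  expect_setequal(kept$probe_id, rownames(M))
})

test_that("top-k selection orders by p with the stated tie-breaks", {
  rec <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    gene_symbol = NA_character_,
    pearson_R = c(0.5, 0.9, 0.5, -0.4),
    p_two_sided = c(0.01, 0.01, 0.001, 1e-9),
    slope = 1, n_samples = 50L, flagged = FALSE, is_seed = FALSE)
  top <- top_k_by_p(rec, k = 2)
  # negative correlation never enters; ties on p broken by larger R
  expect_equal(top$probe_id, c("c", "b"))
  expect_message(all4 <- top_k_by_p(rec, k = 10), "returning all")
  expect_equal(nrow(all4), 3)

  # filtering commutes with ranking
  set.seed(24)
  expr <- rbind(seedgene = rnorm(50, 7, 1),
                simulate_correlated_module(rnorm(50, 7, 1), 30,
                                           target_R = 0.6, seed = 4))
  sc <- pearson_screen(expr, "seedgene")
  f_all <- filter_candidates(sc, min_R = 0.3, max_p = 0.05)
  f_top <- filter_candidates(top_k_by_p(sc, k = nrow(sc)),
                             min_R = 0.3, max_p = 0.05)
  expect_setequal(f_all$probe_id, f_top$probe_id)
})

test_that("cross-platform overlap collapses probes to unique genes", {
  annA <- data.frame(probe_id = c("a1", "a2", "a3"),
                     gene_symbol = c("GENE1", "gene1", "GENE2"))
  annB <- data.frame(probe_id = c("b1", "b2"),
                     gene_symbol = c("Gene1", "GENE3"))
  # two probes of one gene in A, one probe in B: counted once
  ov <- cross_platform_overlap(c("a1", "a2"), "b1", annA, annB)
  expect_equal(ov$n_a, 1)
  expect_equal(ov$overlap_genes, "GENE1")
  expect_equal(ov$n_overlap, 1)

  # identical lists overlap fully; disjoint symbol sets give zero
  ov2 <- cross_platform_overlap(c("a1", "a3"), c("a1", "a3"), annA, annA)
  expect_equal(ov2$n_overlap, ov2$n_a)
  ov3 <- cross_platform_overlap("a3", "b2", annA, annB)
  expect_equal(ov3$n_overlap, 0)

  # unannotated probes warn and drop from the gene-level overlap
  expect_warning(ov4 <- cross_platform_overlap(c("a1", "zz"), "b1",
                                               annA, annB),
                 "lack annotation")
  expect_equal(ov4$n_overlap, 1)
})
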