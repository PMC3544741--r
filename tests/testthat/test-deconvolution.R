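make_cohort <- function(n = 40, seed = 1) {
  generate_cohort(cohort_spec(n_samples = n, seed = seed))
}

test_that("the design matrix has the documented layout and rank checks", {
  ch <- make_cohort(10, seed = 2)
  X <- build_design(ch$composition, ch$relapse, study_types)
  expect_equal(dim(X), c(10L, 7L))
  expect_equal(colnames(X),
               c("(Intercept)", study_types, paste0(study_types, ":RS")))
  # interaction columns are elementwise products
  for (ct in study_types)
    expect_equal(X[, paste0(ct, ":RS")], X[, ct] * ch$relapse)

  # modeling the full simplex with an intercept is exactly collinear
  expect_error(build_design(ch$composition, ch$relapse,
                            colnames(ch$composition)),
               "rank-deficient")

  # percentages are auto-rescaled with a warning
  expect_warning(Xp <- build_design(ch$composition * 100, ch$relapse,
                                    study_types),
                 "percentages")
  expect_equal(unname(Xp), unname(X))

  # all-zero outcome zeroes the interaction block
  X0 <- build_design(ch$composition, rep(0, 10), study_types)
  expect_true(all(X0[, 5:7] == 0))
})

test_that("fit_gene interpolates noiseless data and matches the normal-equations oracle", {
  ch <- make_cohort(30, seed = 3)
  X <- build_design(ch$composition, ch$relapse, study_types)
  truth <- c(0.4, 1.125, 1.783, -8.409, -1.921, 0.856, 7.808)
  y <- drop(X %*% truth)
  f <- fit_gene(y, X)
  expect_equal(unname(f$coefficients), truth, tolerance = 1e-9)

  # oracle equivalence on 50 random small designs
  for (k in 1:50) {
    p <- sample(3:8, 1)
    X2 <- random_design(20, p, seed = 100 + k)
    y2 <- rnorm(20)
    f2 <- fit_gene(y2, X2)
    o <- ols_oracle(y2, X2)
    expect_equal(unname(f2$coefficients), unname(o$coefficients),
                 tolerance = 1e-8)
    expect_equal(unname(f2$se), unname(o$se), tolerance = 1e-8)
    expect_equal(unname(f2$p), unname(o$p), tolerance = 1e-8)
    expect_equal(f2$df, o$df)
  }

  # 6-sample toy system against the explicit solution
  X6 <- cbind(1, c(0, 0, 1, 1, 2, 2), c(1, 0, 0, 1, 0, 1))
  colnames(X6) <- c("(Intercept)", "a", "b")
  y6 <- c(1, 0, 2, 4, 3, 6)
  o6 <- ols_oracle(y6, X6)
  f6 <- fit_gene(y6, X6)
  expect_equal(unname(f6$coefficients), unname(o6$coefficients),
               tolerance = 1e-12)

  expect_error(fit_gene(c(1, NA, 3), X6[1:3, ]), "non-finite")
})

test_that("zero interaction columns are dropped and reported as absent", {
  ch <- make_cohort(20, seed = 4)
  X <- build_design(ch$composition, rep(0, 20), study_types)
  y <- rnorm(20)
  f <- fit_gene(y, X)
  expect_true(all(is.na(f$coefficients[paste0(study_types, ":RS")])))
  expect_false(anyNA(f$coefficients[c("(Intercept)", study_types)]))
  expect_equal(f$df, 20 - 4)
})

test_that("genome-wide fits equal per-gene fits and flag planted signal", {
  ch <- make_cohort(60, seed = 5)
  ct <- study_types
  models <- c(egr_presets(noise_sd = 0.5),
              lapply(1:97, function(i) {
                set.seed(500 + i)
                gene_model(sprintf("null%03d", i),
                           beta0 = runif(1, 4, 10),
                           beta = setNames(rnorm(3), ct),
                           gamma = setNames(numeric(3), ct),
                           noise_sd = 0.5)
              }))
  expr <- simulate_expression(ch$composition, ch$relapse, models, seed = 5)
  fit <- deconv(expr, ch$composition, ch$relapse, ct)
  expect_equal(nrow(coef(fit)), 100L)
  expect_equal(fit$n_failed, 0L)

  X <- build_design(ch$composition, ch$relapse, ct)
  for (g in c("Egr3", "null050")) {
    f1 <- fit_gene(expr[g, ], X)
    expect_equal(coef(fit)[g, ], f1$coefficients, tolerance = 1e-12)
    expect_equal(fit$p[g, ], f1$p, tolerance = 1e-12)
  }

  # a constant gene has all slope coefficients zero
  expr2 <- rbind(expr, flat = rep(3, ncol(expr)))
  fit2 <- deconv(expr2, ch$composition, ch$relapse, ct)
  expect_equal(unname(coef(fit2)["flat", -1]), rep(0, 6), tolerance = 1e-12)

  # planted extreme negative differential ranks first
  strong <- gene_model("sinker", beta0 = 0,
                       beta = setNames(c(1, 0, 0), ct),
                       gamma = setNames(c(-30, 0, 0), ct), noise_sd = 0.5)
  expr3 <- rbind(expr, simulate_expression(ch$composition, ch$relapse,
                                           strong, seed = 6))
  fit3 <- deconv(expr3, ch$composition, ch$relapse, ct)
  rk <- rank_by_gamma(fit3, "tumor")
  expect_equal(rk$gene_id[1], "sinker")
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(!is.unsorted(rk$gamma))
  expect_error(rank_by_gamma(fit3, "epithelium"), "unknown cell type")
})

test_that("gamma equals the relapse-minus-nonrelapse difference of subset fits", {
  ch <- make_cohort(50, seed = 7)
  m <- egr_presets(noise_sd = 0)[["Egr3"]]
  expr <- simulate_expression(ch$composition, ch$relapse, m)
  rel <- ch$relapse == 1
  fit_sub <- function(idx) {
    X <- cbind(1, ch$composition[idx, study_types])
    colnames(X) <- c("(Intercept)", study_types)
    fit_gene(expr[1, idx], X)$coefficients
  }
  b_rel <- fit_sub(rel)
  b_non <- fit_sub(!rel)
  X <- build_design(ch$composition, ch$relapse, study_types)
  f <- fit_gene(expr[1, ], X)
  for (ct in study_types)
    expect_equal(unname(b_rel[ct] - b_non[ct]),
                 unname(f$coefficients[paste0(ct, ":RS")]),
                 tolerance = 1e-8)
})

test_that("slope p-values are invariant to shifting the response", {
  ch <- make_cohort(40, seed = 8)
  X <- build_design(ch$composition, ch$relapse, study_types)
  y <- rnorm(40)
  f1 <- fit_gene(y, X)
  f2 <- fit_gene(y + 100, X)
  expect_equal(f1$p[-1], f2$p[-1], tolerance = 1e-10)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] + 100, tolerance = 1e-8)
})

test_that("deconv S3 methods are coherent", {
  ch <- make_cohort(30, seed = 9)
  expr <- simulate_expression(ch$composition, ch$relapse,
                              egr_presets(), seed = 9)
  fit <- deconv(expr, ch$composition, ch$relapse, study_types)
  expect_s3_class(fit, "deconv")
  expect_output(print(fit), "deconvolution")
  expect_output(print(summary(fit, "tumor")), "tumor")

  # fitted + residuals reconstructs the data
  expect_equal(predict(fit) + residuals(fit), expr, tolerance = 1e-10)

  # simulate() is reproducible and centered on the fit
  s1 <- simulate(fit, nsim = 2, seed = 1)
  s2 <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(s1, s2)
  expect_equal(dim(s1[[1]]), dim(expr))

  # replication-mode centering equals fitting the explicitly
  # sample-centered matrix
  fitc <- deconv(expr, ch$composition, ch$relapse, study_types,
                 center_samples = TRUE)
  fitm <- deconv(sweep(expr, 2, colMeans(expr)), ch$composition,
                 ch$relapse, study_types)
  expect_equal(coef(fitc), coef(fitm), tolerance = 1e-12)
})
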