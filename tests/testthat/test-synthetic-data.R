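test_that("compositions live on the simplex and honor the Dirichlet parameters", {
  spec <- cohort_spec(n_samples = 50, seed = 11)
  P <- generate_compositions(spec)
  expect_equal(dim(P), c(50L, 4L))
  expect_true(all(P >= 0))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))

  # bit-reproducible for a fixed seed
  expect_identical(P, generate_compositions(spec))

  # degenerate concentration pins the first compartment
  deg <- cohort_spec(n_samples = 20, dirichlet_alpha = c(1e6, 1e-9, 1e-9, 1e-9),
                     seed = 2)
  expect_true(all(generate_compositions(deg)[, 1] > 0.999))

  # law of large numbers: symmetric alpha = (2,2,2,2) has mean 1/4
  big <- cohort_spec(n_samples = 10000, dirichlet_alpha = rep(2, 4), seed = 3)
  expect_true(all(abs(colMeans(generate_compositions(big)) - 0.25) < 0.01))

  expect_error(cohort_spec(dirichlet_alpha = c(1, 1, 1, -1)), "positive")
  expect_error(cohort_spec(relapse_fraction = 1.2), "relapse_fraction")
})

test_that("relapse labels have the prescribed prevalence", {
  spec <- cohort_spec(n_samples = 108, relapse_fraction = 38 / 101, seed = 4)
  rs <- generate_relapse_labels(spec)
  expect_equal(sum(rs), round(108 * 38 / 101))
  expect_identical(rs, generate_relapse_labels(spec))
})

test_that("noiseless expression reproduces the linear predictor exactly", {
  ct <- study_types
  # one pure-tumor sample, published seed-gene tumor coefficients
  P <- matrix(c(1, 0, 0), 1, dimnames = list("S1", ct))
  m <- gene_model("g", beta0 = 0,
                  beta = setNames(c(1.125, 0, 0), ct),
                  gamma = setNames(c(-1.921, 0, 0), ct),
                  noise_sd = 0)
  expect_equal(unname(drop(simulate_expression(P, 0, m))), 1.125)
  # relapse sample: beta + gamma = -0.796
  expect_equal(unname(drop(simulate_expression(P, 1, m))), -0.796)

  # all-zero coefficients give the zero matrix
  z <- gene_model("z", beta0 = 0, beta = setNames(numeric(3), ct),
                  gamma = setNames(numeric(3), ct), noise_sd = 0)
  spec <- cohort_spec(n_samples = 12, seed = 5)
  ch <- generate_cohort(spec)
  expect_true(all(simulate_expression(ch$composition, ch$relapse, z) == 0))

  # general predictor at machine precision
  m2 <- gene_model("g2", beta0 = 2.5,
                   beta = setNames(c(0.7, -1.1, 3), ct),
                   gamma = setNames(c(-2, 0.5, 1), ct), noise_sd = 0)
  y <- drop(simulate_expression(ch$composition[, ct], ch$relapse, m2))
  Pm <- ch$composition[, ct]
  eta <- 2.5 + drop(Pm %*% m2$beta) + drop((Pm * ch$relapse) %*% m2$gamma)
  expect_equal(unname(y), unname(eta), tolerance = 1e-15)

  expect_error(simulate_expression(ch$composition, ch$relapse[-1], m2),
               "misaligned")
})

test_that("correlated modules hit the target Pearson correlation", {
  set.seed(9)
  seedp <- rnorm(5000, 7, 1)
  # target_R = 1 is exact
  M1 <- simulate_correlated_module(seedp, 3, target_R = 1, seed = 1)
  for (i in 1:3) expect_equal(cor(M1[i, ], seedp), 1)

  # noiseless output recovers the requested slope by regression
  sl <- attr(M1, "slopes")
  for (i in 1:3) {
    fit <- lm(M1[i, ] ~ seedp)
    expect_equal(unname(coef(fit)[2]), unname(sl[i]), tolerance = 1e-9)
  }

  # at n = 5000 the realized R concentrates on the target
  M <- simulate_correlated_module(seedp, 10, target_R = 0.45, seed = 2)
  rr <- apply(M, 1, cor, y = seedp)
  expect_true(all(abs(rr - 0.45) < 0.03))

  expect_error(simulate_correlated_module(rep(1, 10), 3), "constant")
  expect_error(simulate_correlated_module(rnorm(10), 3, target_R = 0), "target_R")
})

test_that("promoter generation plants sites at the exact requested fraction", {
  mat <- build_ere_matrix()
  all_pos <- generate_promoters(10, length = 60, matrix = mat,
                                site_fraction = 1, seed = 3)
  for (s in all_pos) {
    hits <- scan_sequence(s, mat, threshold = 0.999)
    expect_gte(nrow(hits), 1)   # a perfect-similarity window exists
  }
  none <- generate_promoters(10, length = 60, matrix = mat,
                             site_fraction = 0, seed = 4)
  fr0 <- fraction_with_site(none, mat, threshold = 0.80)
  expect_equal(fr0$fraction, 0)

  mixed <- generate_promoters(80, length = 300, matrix = mat,
                              site_fraction = 0.627, seed = 5)
  fr <- fraction_with_site(mixed, mat, threshold = 0.80)
  # negatives are rejection-sampled, positives planted: fraction exact
  expect_equal(fr$fraction, round(0.627 * 80) / 80)
  expect_equal(fr$per_gene$has_site, unname(attr(mixed, "has_site")))

  expect_error(generate_promoters(5, length = 4, matrix = mat), "width")
  expect_identical(generate_promoters(6, length = 100, seed = 8),
                   generate_promoters(6, length = 100, seed = 8))
})

test_that("synthetic IHC images have the constructed band structure", {
  img <- generate_ihc_image(96, 96,
                            list(gland_region(30, 30, 15, intensity = 90)),
                            stroma_intensity = 230, seed = 6)
  gl <- classify_pixels(img$image, img$masks$gland)
  expect_equal(gl$n_strong, gl$n_total)        # 100% strong at intensity ~90
  st <- classify_pixels(img$image, img$masks$stroma)
  expect_equal(st$n_negative, st$n_total)      # stroma all negative

  # uniform white image has zero positive pixels
  blank <- matrix(255, 10, 10)
  cc <- classify_pixels(blank)
  expect_equal(cc$n_negative, 100)
  expect_equal(cc$n_weak + cc$n_medium + cc$n_strong, 0)

  # half strong, half weak: NSR = 0.5 by direct count
  half <- matrix(c(rep(90, 50), rep(190, 50)), 10, 10)
  expect_equal(nsr(classify_pixels(half)), 0.5)

  expect_error(
    generate_ihc_image(64, 64, list(gland_region(20, 20, 10, 90),
                                    gland_region(25, 20, 10, 90))),
    "overlap")
  a <- generate_ihc_image(64, 64, list(gland_region(20, 20, 10, 90)), seed = 9)
  b <- generate_ihc_image(64, 64, list(gland_region(20, 20, 10, 90)), seed = 9)
  expect_identical(a$image, b$image)
})
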