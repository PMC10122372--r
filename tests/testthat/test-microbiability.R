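test_that("relationship matrix reproduces the two-taxon worked example", {
  A <- matrix(c(0.2, 0.6,
                0.4, 0.4,
                0.6, 0.2), 3, 2, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  M <- build_relationship_matrix(A)$M
  expected <- matrix(c(1.5, 0, -1.5,
                       0, 0, 0,
                       -1.5, 0, 1.5), 3, 3, byrow = TRUE,
                     dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  expect_equal(M, expected, tolerance = 1e-12)
})

test_that("relationship matrix has trace n, zero row sums, PSD", {
  for (seed in 1:3) {
    ab <- rand_composition(25, 40, seed)
    M <- build_relationship_matrix(ab)$M
    n <- nrow(M)
    expect_equal(sum(diag(M)), n, tolerance = 1e-8)
    expect_lt(max(abs(rowSums(M))), 1e-8)
    expect_lt(max(abs(M - t(M))), 1e-10)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("identical samples get identical relationship rows; taxon scaling is absorbed", {
  ab <- rand_composition(6, 12, seed = 9)
  ab[2, ] <- ab[1, ]
  M <- build_relationship_matrix(abundance_table(ab, filtered = TRUE))$M
  expect_equal(M[1, ], M[2, ], ignore_attr = TRUE)

  # multiplying one taxon's abundances by a positive constant leaves M
  # unchanged: standardization removes scale
  x <- ab; x[, 3] <- x[, 3] * 0.1
  Mx <- build_relationship_matrix(abundance_table(x, filtered = TRUE))$M
  M0 <- build_relationship_matrix(abundance_table(ab, filtered = TRUE))$M
  expect_equal(Mx, M0, tolerance = 1e-10)
})

test_that("zero-variance taxa are excluded with a warning", {
  ab <- rand_composition(5, 4, seed = 2)
  ab[, 2] <- 0.1
  expect_warning(M <- build_relationship_matrix(abundance_table(ab, filtered = TRUE)),
                 "zero-variance")
  expect_equal(M$n_taxa, 3L)
  expect_error(build_relationship_matrix(
    abundance_table(matrix(0.5, 3, 2,
                           dimnames = list(letters[1:3], c("x", "y"))))),
    "nonzero variance")
})

test_that("REML optimum matches the dense-algebra profile oracle on a grid", {
  # independent oracle: dense solve/determinant, no eigen-rotation
  for (seed in 1:2) {
    ab <- rand_composition(40, 30, seed + 100)
    M <- build_relationship_matrix(ab)
    sim <- simulate_phenotypes(abundance_table(ab), 0.5, seed = seed)
    ph <- as.data.frame(sim$phenotypes)
    X <- cbind(1, ph$parity, ph$milk_yield)
    fit <- fit_lmm_reml(ph$osi, ph[, c("parity", "milk_yield")], M)
    grid <- exp(seq(log(1e-6), log(1e6), length.out = 201))
    ll <- vapply(grid, oracle_reml_loglik, numeric(1), y = ph$osi,
                 design = X, kernel = M$M)
    i <- which.max(ll)
    # the optimizer's restricted likelihood beats every oracle grid point
    expect_gte(fit$loglik + 1e-6, max(ll))
    # and its lambda falls within one grid step of the oracle argmax
    step <- diff(log(grid))[1]
    expect_lte(abs(log(fit$lambda) - log(grid[i])), step + 1e-9)
  }
})

test_that("REML is shift invariant and scale equivariant", {
  ab <- rand_composition(35, 25, seed = 42)
  M <- build_relationship_matrix(ab)
  sim <- simulate_phenotypes(abundance_table(ab), 0.4, seed = 5)
  ph <- as.data.frame(sim$phenotypes)
  cov <- ph[, c("parity", "milk_yield")]
  f0 <- fit_lmm_reml(ph$osi, cov, M)
  f_shift <- fit_lmm_reml(ph$osi + 100, cov, M)
  expect_equal(f_shift$microbiability, f0$microbiability, tolerance = 1e-6)
  expect_equal(f_shift$beta[["(Intercept)"]],
               f0$beta[["(Intercept)"]] + 100, tolerance = 1e-6)
  f_scale <- fit_lmm_reml(ph$osi * 3, cov, M)
  expect_equal(f_scale$sigma2_m, 9 * f0$sigma2_m, tolerance = 1e-4)
  expect_equal(f_scale$sigma2_e, 9 * f0$sigma2_e, tolerance = 1e-4)
  expect_equal(f_scale$microbiability, f0$microbiability, tolerance = 1e-6)
})

test_that("noise-free fixed-effect data collapse both variances to zero", {
  ab <- rand_composition(30, 20, seed = 77)
  M <- build_relationship_matrix(ab)
  x <- rnorm(30)
  y <- 2 + 3 * x     # exactly in the column space of [1 | x]
  fit <- fit_lmm_reml(y, data.frame(x = x), M)
  expect_lt(fit$sigma2_e, 1e-12)
  expect_lt(fit$sigma2_m, 1e-6)
  expect_equal(unname(fit$beta), c(2, 3), tolerance = 1e-6)
})

test_that("rank-deficient designs and bad dimensions are rejected", {
  ab <- rand_composition(20, 10, seed = 3)
  M <- build_relationship_matrix(ab)
  x <- rnorm(20)
  expect_error(fit_lmm_reml(rnorm(20), data.frame(a = x, b = 2 * x), M),
               "rank deficient")
  expect_error(fit_lmm_reml(rnorm(19), NULL, M), "disagree")
})

test_that("microbiability ratio follows the model-based convention", {
  expect_equal(microbiability(list(sigma2_m = 0, sigma2_e = 1)), 0)
  expect_equal(microbiability(list(sigma2_m = 2, sigma2_e = 2)), 0.5)
  expect_equal(microbiability(list(sigma2_m = 3, sigma2_e = 1)), 0.75)
  expect_error(microbiability(list(sigma2_m = 0, sigma2_e = 0)), "undefined")
  # consistency with the fitted object
  ab <- rand_composition(30, 20, seed = 12)
  M <- build_relationship_matrix(ab)
  sim <- simulate_phenotypes(abundance_table(ab), 0.3, seed = 2)
  fit <- fit_lmm_reml(sim$phenotypes$osi, NULL, M)
  expect_equal(microbiability(fit), fit$microbiability, tolerance = 1e-12)
})

test_that("parametric bootstrap returns estimates around the fit", {
  ab <- rand_composition(60, 40, seed = 15)
  M <- build_relationship_matrix(ab)
  sim <- simulate_phenotypes(abundance_table(ab), 0.5, total_variance = 1,
                             seed = 3)
  fit <- fit_lmm_reml(sim$phenotypes$osi, NULL, M)
  bs <- microbiability_bootstrap(fit, NULL, M, n_boot = 8, seed = 4)
  expect_length(bs, 8)
  expect_true(all(bs >= 0 & bs <= 1))
  expect_true(is.finite(attr(bs, "se")))
})
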