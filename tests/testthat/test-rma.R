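test_that("background parameters are recovered from the convolution model", {
  set.seed(101)
  n <- 10000
  mu <- 100; sigma <- 10; alpha <- 0.01
  b <- mu + sigma * qnorm(runif(n, pnorm(-mu / sigma), 1))
  x <- b + rexp(n, alpha)
  p <- estimate_background_params(x)
  expect_lt(abs(p$mu_bg - mu) / mu, 0.15)
  expect_lt(abs(p$sigma_bg - sigma) / sigma, 0.15)
  expect_lt(abs(p$alpha - alpha) / alpha, 0.15)
})

test_that("background estimation rejects degenerate input", {
  expect_error(estimate_background_params(rep(50, 1000)),
               "degenerate intensity distribution")
  expect_error(estimate_background_params(runif(50) + 1), ">= 100")
})

test_that("background estimation is scale-equivariant", {
  set.seed(7)
  x <- 100 + 10 * rnorm(5000)^2 + rexp(5000, 0.01)
  p1 <- estimate_background_params(x)
  p2 <- estimate_background_params(x * 3)
  expect_equal(p2$mu_bg / p1$mu_bg, 3, tolerance = 0.02)
  expect_equal(p2$sigma_bg / p1$sigma_bg, 3, tolerance = 0.02)
  expect_equal(p1$alpha / p2$alpha, 3, tolerance = 0.02)
})

test_that("background correction matches the posterior-mean quadrature", {
  params <- structure(list(mu_bg = 100, sigma_bg = 10, alpha = 0.01),
                      class = "rma_params")
  o <- 200
  expect_equal(background_correct(o, params),
               bg_correct_quadrature(o, 100, 10, 0.01),
               tolerance = 1e-6)
})

test_that("background correction is bounded, monotone, and vanishes with the background", {
  params <- structure(list(mu_bg = 100, sigma_bg = 10, alpha = 0.01),
                      class = "rma_params")
  o <- seq(5, 1000, length.out = 200)
  s <- background_correct(o, params)
  expect_true(all(s > 0))
  expect_true(all(s < o))
  expect_true(all(diff(s) > 0))

  tiny <- structure(list(mu_bg = 0, sigma_bg = 1e-6, alpha = 1e-9),
                    class = "rma_params")
  o2 <- c(10, 100, 1000)
  expect_equal(background_correct(o2, tiny), o2, tolerance = 1e-4)
})

test_that("quantile normalisation equalises sorted columns", {
  m <- matrix(c(2, 4, 6, 4, 6, 8), ncol = 2)
  out <- quantile_normalize(m)
  expect_equal(out[, 1], c(3, 5, 7))
  expect_equal(out[, 2], c(3, 5, 7))

  # fixed point on identical columns
  m2 <- matrix(rep(c(5, 1, 9), 3), ncol = 3)
  expect_equal(quantile_normalize(m2), m2)

  # defining property and conservation on random input
  set.seed(42)
  for (i in 1:5) {
    r <- matrix(rexp(60), ncol = 4)
    q <- quantile_normalize(r)
    sorted <- apply(q, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
    expect_equal(mean(q), mean(r), tolerance = 1e-9)
    # within-column order preserved
    for (j in 1:4) expect_equal(order(q[, j]), order(r[, j]))
  }
  expect_warning(quantile_normalize(matrix(1:3, ncol = 1)),
                 "single column")
})

test_that("median polish recovers additive structure and degenerate shapes", {
  r <- c(1, 3, -2); cc <- c(0.5, -0.5, 2, 1)
  m <- outer(r, cc, "+") + 10
  fit <- median_polish(m)
  expect_true(all(abs(fit$residuals) < 1e-12))
  expect_lte(fit$iterations, 2L)
  recon <- fit$overall + outer(fit$row_effects, rep(1, 4)) +
    outer(rep(1, 3), fit$column_effects) + fit$residuals
  expect_equal(recon, m)

  v <- c(4, 7, 1, 6)
  fit1 <- median_polish(matrix(v, nrow = 1))
  expect_equal(fit1$overall, median(v))
  expect_equal(fit1$column_effects, v - median(v))
  expect_equal(fit1$row_effects, 0)

  fit0 <- median_polish(matrix(3.5, 1, 1))
  expect_equal(fit0$overall, 3.5)
})

test_that("median polish agrees with an independently coded sweep oracle", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rnorm(20), nrow = 5)
    fit <- median_polish(m, max_iter = 10L, tol = 0.01)
    ora <- median_polish_oracle(m, max_iter = 10L, tol = 0.01)
    expect_equal(fit$overall, ora$overall, tolerance = 1e-8)
    expect_equal(fit$row_effects, ora$row_effects, tolerance = 1e-8)
    expect_equal(fit$column_effects, ora$column_effects, tolerance = 1e-8)
    expect_equal(fit$residuals, ora$residuals, tolerance = 1e-8)
    expect_identical(fit$iterations, ora$iterations)
    # row effects re-centred exactly on the final half-sweep; column
    # effects are centred only up to the stopping tolerance
    expect_lt(abs(median(fit$row_effects)), 1e-12)
    expect_lt(abs(median(fit$column_effects)), 0.01)
  }
})

test_that("median polish cross-checks against stats::medpolish at convergence", {
  set.seed(12)
  m <- matrix(rnorm(20, sd = 2), nrow = 5)
  fit <- median_polish(m, max_iter = 200L, tol = 1e-12)
  ref <- stats::medpolish(m, eps = 1e-13, maxiter = 200L, trace.iter = FALSE)
  expect_equal(fit$overall, ref$overall, tolerance = 1e-6)
  expect_equal(fit$row_effects, unname(ref$row), tolerance = 1e-6)
  expect_equal(fit$column_effects, unname(ref$col), tolerance = 1e-6)
})

test_that("rma reduces to log2 for single-probe probesets on identical columns", {
  ann <- suppressWarnings(probe_annotation(
    probe_id = c("a1", "b1", "c1"),
    probeset_id = c("psA", "psB", "psC"),
    rna_class = rep("mature_miRNA", 3)
  ))
  vals <- c(64, 256, 1024)
  raw <- matrix(rep(vals, 3), ncol = 3,
                dimnames = list(c("a1", "b1", "c1"), c("s1", "s2", "s3")))
  expr <- rma(raw, ann, background = FALSE)
  expect_equal(expr, log2(raw),
               ignore_attr = TRUE)
  expect_equal(rownames(expr), c("psA", "psB", "psC"))
})

test_that("rma keeps every probeset including spike-ins", {
  cfg <- sim_config(n_mature = 30, n_precursor = 20, n_other = 40,
                    n_spikein = 3, cell_lines = "CL1", seed = 3)
  sim <- simulate_rip_experiment(cfg)
  expr <- rma(sim$intensities, sim$annotation)
  expect_equal(nrow(expr), 93L)
  expect_true(all(spikein_probesets(sim$annotation) %in% rownames(expr)))
  expect_true(all(is.finite(expr)))
})

test_that("rma is equivariant under column permutation", {
  cfg <- sim_config(n_mature = 25, n_precursor = 0, n_other = 30,
                    n_spikein = 3, cell_lines = "CL1", seed = 9)
  sim <- simulate_rip_experiment(cfg)
  raw <- sim$intensities
  perm <- c(3, 1, 4, 2)
  e1 <- rma(raw, sim$annotation)
  e2 <- rma(raw[, perm], sim$annotation)
  expect_equal(e2, e1[, perm], ignore_attr = TRUE)
})

test_that("planted 4-fold IP enrichment survives normalisation", {
  cfg <- sim_config(cell_lines = "MCF7", seed = 21)
  sim <- simulate_rip_experiment(cfg)
  expr <- rma(sim$intensities, sim$annotation)
  des <- rip_design(sim$sheet, "MCF7")
  planted <- sim$truth$bound[["MCF7"]]$probeset_id
  ipm <- apply(expr[planted, des$ip, drop = FALSE], 1, median)
  diff <- ipm - expr[planted, des$input]
  expect_lt(abs(mean(diff) - 2.0), 0.3)
})
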