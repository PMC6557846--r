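test_that("the inverse-Gaussian pdf has its closed-form values and unit mass", {
  expect_equal(ig_pdf(1, 1, 1), 1 / sqrt(2 * pi))
  expect_equal(ig_pdf(c(-1, 0), 2, 3), c(0, 0))
  mass <- integrate(ig_pdf, 0, Inf, mu = 5.95, lambda = 21.96,
                    rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  mean_ig <- integrate(function(w) w * ig_pdf(w, 7.01, 22.55), 0, Inf,
                       rel.tol = 1e-10)$value
  expect_equal(mean_ig, 7.01, tolerance = 1e-4)
  expect_error(ig_pdf(1, -1, 1), "positive")
})

test_that("the closed-form MLE matches hand-computed and numerical values", {
  fit <- fit_inverse_gaussian(c(1, 2, 4))
  expect_equal(fit$mu, 7 / 3, tolerance = 1e-12)
  # lambda = 3 / (1 + 1/2 + 1/4 - 9/7)
  expect_equal(fit$lambda, 3 / (7 / 4 - 9 / 7), tolerance = 1e-12)
  expect_equal(fit$lambda, 6.4615, tolerance = 1e-4)
  expect_error(fit_inverse_gaussian(c(0, 1, 2)), "positive")
  expect_error(fit_inverse_gaussian(c(2, 2, 2)), "dispersion")
  expect_error(fit_inverse_gaussian(3), "at least 2")
})

test_that("closed-form MLE agrees with numerical likelihood maximization", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    mu <- runif(1, 0.5, 10)
    lam <- runif(1, 0.5, 40)
    w <- rinvgauss(sample(20:100, 1), mu, lam)
    fit <- fit_inverse_gaussian(w)
    nll <- function(p) -sum(log(ig_pdf(w, exp(p[1]), exp(p[2]))))
    opt <- optim(log(c(fit$mu * 1.3, fit$lambda * 0.7)), nll,
                 control = list(reltol = 1e-15, maxit = 20000))
    worst <- max(worst, max(abs(exp(opt$par) - c(fit$mu, fit$lambda)) /
                              c(fit$mu, fit$lambda)))
  }
  expect_lt(worst, 1e-6)
})

test_that("the parameter distance is a plain Euclidean metric", {
  expect_equal(param_distance(c(5.95, 21.96), 5.95, 21.96), 0)
  expect_equal(param_distance(c(3, 4), 0, 0), 5)
  f <- fit_inverse_gaussian(c(1, 2, 4))
  expect_equal(param_distance(f, 1, 1),
               sqrt((f$mu - 1)^2 + (f$lambda - 1)^2))
  # symmetry under swapping fit and target
  expect_equal(param_distance(c(2, 3), 7, 11), param_distance(c(7, 11), 2, 3))
})

test_that("the density L2 distance satisfies the metric axioms", {
  expect_lt(l2_density_distance(c(5.95, 21.96), c(5.95, 21.96)), 1e-8)
  expect_identical(l2_density_distance(c(7, 20), c(5, 25)),
                   l2_density_distance(c(5, 25), c(7, 20)))
  set.seed(10)
  for (i in 1:10) {
    p <- matrix(runif(6, 1, 30), 3, 2)
    d12 <- l2_density_distance(p[1, ], p[2, ])
    d13 <- l2_density_distance(p[1, ], p[3, ])
    d23 <- l2_density_distance(p[2, ], p[3, ])
    expect_gte(d12, 0)
    expect_lte(d13, d12 + d23 + 1e-10)
  }
})

test_that("model-vs-empirical density distances reproduce the reference values", {
  d_non <- l2_density_distance(c(7.01, 22.55), empirical_target)
  d_lsa <- l2_density_distance(c(9.16, 22.46), empirical_target)
  expect_equal(round(d_non, 2), 0.07)
  expect_equal(round(d_lsa, 2), 0.15)
})

test_that("threshold scans find a self-target exactly and stay monotone", {
  m <- lsa_model()
  cfg <- sim_config(n_runs = 80, seed = 14)
  pilot <- fit_inverse_gaussian(simulate_wt_sample(m, 5, cfg))
  # with shared noise the grid point beta = 5 reproduces the pilot fit,
  # so E(5) = 0 and beta0 = 5
  scan <- optimize_threshold(m, pilot$mu, pilot$lambda,
                             betas = c(4, 5, 6), config = cfg,
                             share_noise = TRUE)
  expect_equal(attr(scan, "beta0"), 5)
  expect_equal(scan$E[scan$beta == 5], 0, tolerance = 1e-12)
  # shared-stream upcross scans have nondecreasing mu(beta)
  cfg_up <- sim_config(n_runs = 100, criterion = "upcross", seed = 15)
  scan_up <- optimize_threshold(m, 5.95, 21.96, betas = seq(2, 6, 1),
                                config = cfg_up, share_noise = TRUE)
  expect_true(all(diff(scan_up$mu) >= 0))
})

test_that("near-deterministic drift puts the optimal threshold at the target mean", {
  # drift 1, tiny noise: WT(beta) = beta almost surely, so matching a target
  # mean of 5 picks the grid point beta = 5
  m <- langevin_model(1, 1e-3)
  cfg <- sim_config(n_runs = 20, criterion = "upcross", t_max = 12, seed = 5)
  pilot <- fit_inverse_gaussian(simulate_wt_sample(m, 5, cfg))
  expect_equal(pilot$mu, 5, tolerance = 1e-2)
  scan <- optimize_threshold(m, 5, pilot$lambda, betas = seq(2, 8, 1),
                             config = cfg, share_noise = TRUE)
  expect_equal(attr(scan, "beta0"), 5)
})

test_that("the E(beta) landscape has an interior minimum for the LSA benchmark", {
  scan <- optimize_threshold(lsa_model(), 5.95, 21.96,
                             betas = seq(2, 8, 0.5),
                             config = sim_config(n_runs = 200, seed = 1))
  b0 <- attr(scan, "beta0")
  expect_gt(b0, 2)
  expect_lt(b0, 8)
})

test_that("waiting-time CSV round trip keeps values and censoring count", {
  s <- generate_ig_wt_sample(5.95, 21.96, 50, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_wt_sample(s, path)
  s2 <- read_wt_sample(path)
  expect_equal(waiting_times(s2), waiting_times(s), tolerance = 1e-12)
  expect_equal(attr(s2, "n_censored"), 0L)
  expect_true(any(startsWith(readLines(path), "#")))
})
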