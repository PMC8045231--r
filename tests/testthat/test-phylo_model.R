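# small shared fixtures ------------------------------------------------------

make_gaussian_fit <- function(seed = 5, n = 40, chains = 2, iter = 1200,
                              burnin = 400, thin = 2, phylo = FALSE) {
  set.seed(seed)
  dat <- data.frame(species = sprintf("s%02d", 1:n),
                    y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n))
  dat$y <- 0.5 * dat$x1 + dat$y
  spec <- model_spec("y", "gaussian", c("x1", "x2"), phylo = phylo,
                     mcmc = mcmc_control(chains = chains, iter = iter,
                                         burnin = burnin, thin = thin,
                                         seed = seed))
  C <- if (phylo) {
    tr <- simulate_tree(n, seed = seed)
    tr$tip.label <- dat$species
    phylo_vcv(tr)
  } else NULL
  design <- prepare_design(dat, C, spec)
  suppressWarnings(fit_phylo_model(design))
}

make_beta_fit <- function(seed = 6, n = 60) {
  tr <- simulate_tree(n, seed = seed)
  u <- simulate_phylo_effect(tr, 0.5, seed = seed + 1)
  set.seed(seed + 2)
  x <- rnorm(n)
  X <- cbind(1, x)
  y <- simulate_proportion(X, c(-1, 0.4), u, phi = 40, seed = seed + 3)
  dat <- data.frame(species = tr$tip.label, y = y, x = x)
  spec <- model_spec("y", "beta", "x", standardize = FALSE,
                     mcmc = mcmc_control(chains = 2, iter = 1200,
                                         burnin = 400, thin = 2,
                                         seed = seed))
  design <- prepare_design(dat, phylo_vcv(tr), spec)
  suppressWarnings(fit_phylo_model(design))
}

# design preparation ----------------------------------------------------------

test_that("design preparation standardizes, transforms and aligns", {
  dat <- data.frame(species = c("a", "b", "c", "d"),
                    y = c(10, 20, 30, 40), x = c(1, 2, 3, 4),
                    m = exp(c(1, 2, 3, 4)))
  spec <- model_spec("y", "gaussian", c("x", "m"), log_transform = "m",
                     phylo = FALSE)
  d <- prepare_design(dat, NULL, spec)
  sd4 <- sd(c(1, 2, 3, 4))
  expect_equal(unname(d$X[, "x"]), (c(1, 2, 3, 4) - 2.5) / sd4)
  # log applied before z-standardization
  expect_equal(unname(d$X[, "m"]), (c(1, 2, 3, 4) - 2.5) / sd4)
  expect_equal(mean(d$y), 0)
  expect_equal(sd(d$y), 1)
  expect_equal(unname(d$X[, 1]), rep(1, 4))
})

test_that("three-point predictor standardizes to (-1, 0, 1)", {
  dat <- data.frame(species = c("a", "b", "c"),
                    y = c(0.2, 0.5, 0.7), x = c(1, 2, 3))
  spec <- model_spec("y", "beta", "x", phylo = FALSE)
  d <- prepare_design(dat, NULL, spec)
  expect_equal(unname(d$X[, "x"]), c(-1, 0, 1))
  expect_equal(d$y, c(0.2, 0.5, 0.7))  # already fractions, untouched
})

test_that("beta responses convert mol% and squeeze boundary values", {
  dat <- data.frame(species = letters[1:5],
                    y = c(0, 25, 50, 75, 100), x = c(1, 2, 3, 4, 5))
  spec <- model_spec("y", "beta", "x", phylo = FALSE)
  expect_message(d <- prepare_design(dat, NULL, spec), "squeezed")
  expect_true(all(d$y > 0 & d$y < 1))
  expect_true(d$squeezed)
  # squeeze transform: y' = (y * (n - 1) + 0.5) / n on the fraction scale
  expect_equal(d$y, (c(0, .25, .5, .75, 1) * 4 + 0.5) / 5)
})

test_that("degenerate designs are rejected, missing species dropped", {
  dat <- data.frame(species = letters[1:4], y = c(0.1, 0.2, 0.3, 0.4),
                    x = rep(1, 4))
  spec <- model_spec("y", "beta", "x", phylo = FALSE)
  expect_error(prepare_design(dat, NULL, spec), "zero-variance")

  dat2 <- data.frame(species = letters[1:6], y = c(NA, 0.2, 0.3, 0.4, 0.5, 0.6),
                     x = c(1, 2, 3, 4, 5, NA))
  spec2 <- model_spec("y", "beta", "x", phylo = FALSE)
  expect_message(d2 <- prepare_design(dat2, NULL, spec2), "dropping 2 species")
  expect_equal(d2$species, letters[2:5])
  expect_equal(d2$n_dropped, 2)
})

# likelihood building blocks --------------------------------------------------

test_that("beta log-likelihood matches closed forms and integrates to one", {
  # mu = 0.5, phi = 2 is Beta(1, 1): the uniform density, log-density 0
  expect_equal(beta_loglik(0.5, matrix(0, 1, 1), 0, 0, phi = 2), 0)
  # density integrates to 1 for mu = 0.3, phi = 7 (quadrature oracle)
  f <- Vectorize(function(y)
    exp(beta_loglik(y, matrix(1, 1, 1), qlogis(0.3), 0, phi = 7)))
  expect_equal(integrate(f, 0, 1)$value, 1, tolerance = 1e-6)
})

test_that("beta log-likelihood peaks near truth on a large iid sample", {
  set.seed(30)
  y <- rbeta(4000, 0.4 * 10, 0.6 * 10)  # mu = 0.4, phi = 10
  X <- matrix(1, length(y), 1)
  grid <- expand.grid(mu = seq(0.3, 0.5, 0.01), phi = seq(6, 14, 0.5))
  ll <- mapply(function(m, p) beta_loglik(y, X, qlogis(m), 0, p),
               grid$mu, grid$phi)
  best <- grid[which.max(ll), ]
  expect_lt(abs(best$mu - 0.4), 0.02)
  expect_lt(abs(best$phi - 10), 1)
})

test_that("phylogenetic prior log-density matches dense evaluation", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  u <- c(0.3, -0.2, 0.5)
  sp <- 0.7
  # independent dense-matrix evaluation
  S <- sp^2 * C
  dense <- -0.5 * (3 * log(2 * pi) + determinant(S)$modulus[1] +
                   drop(u %*% solve(S, u)))
  expect_equal(phylo_prior_loglik(u, sp, C), dense, tolerance = 1e-12)
  # u = 0 leaves only the normalizing constant
  expect_equal(phylo_prior_loglik(c(0, 0, 0), sp, C),
               -0.5 * (3 * log(2 * pi) + determinant(S)$modulus[1]),
               tolerance = 1e-12)
  # identity covariance reduces to independent normals
  expect_equal(phylo_prior_loglik(u, sp, diag(3)),
               sum(dnorm(u, 0, sp, log = TRUE)), tolerance = 1e-12)
})

# diagnostics -----------------------------------------------------------------

test_that("R-hat follows the Gelman-Rubin formula and its conventions", {
  # identical constant chains: 0/0 guarded to exactly 1
  expect_equal(rhat(list(rep(2, 50), rep(2, 50))), 1)
  expect_error(rhat(list(rnorm(10))), "two chains")
  # hand evaluation on a 10-draw two-chain fixture with means 0 and 5
  c1 <- as.numeric(scale(1:10))        # mean 0, sd 1
  c2 <- c1 + 5
  W <- 1
  B_over_n <- var(c(0, 5))
  expect_equal(rhat(list(c1, c2)), sqrt((9 / 10 * W + B_over_n) / W))
  # iid standard normal chains sit within 0.01 of 1
  set.seed(77)
  chains <- replicate(4, rnorm(10000), simplify = FALSE)
  expect_lt(abs(rhat(chains) - 1), 0.01)
})

test_that("credible intervals use type-7 quantiles (sort-based oracle)", {
  d <- sample(1:1000)
  ci <- credible_interval(d, 0.95)
  s <- sort(d)
  # explicit linear interpolation of order statistics
  lo_h <- (1000 - 1) * 0.025 + 1
  hi_h <- (1000 - 1) * 0.975 + 1
  lo <- s[floor(lo_h)] + (lo_h - floor(lo_h)) * (s[floor(lo_h) + 1] - s[floor(lo_h)])
  hi <- s[floor(hi_h)] + (hi_h - floor(hi_h)) * (s[floor(hi_h) + 1] - s[floor(hi_h)])
  expect_equal(ci, c(lo, hi))
  set.seed(8)
  sym <- rnorm(20000)
  ci2 <- credible_interval(sym)
  expect_lt(abs(ci2[1] + ci2[2]), 0.06)
})

# fitting ---------------------------------------------------------------------

test_that("draw count honours the chains x (iter - burnin) / thin contract", {
  fit <- make_gaussian_fit(seed = 5)
  expect_equal(nrow(fit$draws), 2 * (1200 - 400) / 2)
  expect_equal(length(fit$chain_draws), 2)
})

test_that("identical seeds give identical draws", {
  f1 <- make_gaussian_fit(seed = 9)
  f2 <- make_gaussian_fit(seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- make_gaussian_fit(seed = 10)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior summary flags significance by interval exclusion", {
  fit <- make_gaussian_fit(seed = 5)
  s <- summary(fit)
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  expect_equal(s$significant, s$lower > 0 | s$upper < 0)
})

test_that("gaussian AME equals the coefficient draw-for-draw", {
  fit <- make_gaussian_fit(seed = 5)
  eff <- average_marginal_effect(fit, "x1")
  expect_equal(eff$draws, unname(fit$draws[, "b_x1"]))
  expect_error(average_marginal_effect(fit, "nope"), "not in the model")
})

test_that("beta AME matches a finite-difference oracle", {
  fit <- make_beta_fit(seed = 6)
  eff <- average_marginal_effect(fit, "x")
  X <- fit$design$X
  h <- 1e-5
  idx <- seq(1, nrow(fit$draws), by = 40)
  for (d in idx) {
    b <- fit$draws[d, c("b_(Intercept)", "b_x")]
    u <- fit$draws[d, paste0("u_", fit$design$species)]
    Xp <- X; Xp[, "x"] <- Xp[, "x"] + h
    Xm <- X; Xm[, "x"] <- Xm[, "x"] - h
    fd <- mean((plogis(Xp %*% b + u) - plogis(Xm %*% b + u)) / (2 * h))
    expect_equal(eff$draws[d], fd, tolerance = 1e-6)
  }
})

test_that("predictor standardization moves coefficients, not conclusions", {
  tr <- simulate_tree(50, seed = 21)
  u <- simulate_phylo_effect(tr, 0.4, seed = 22)
  set.seed(23)
  x <- rnorm(50, mean = 7, sd = 3)
  y <- simulate_proportion(cbind(1, scale(x)), c(-1, 0.5), u, 40, seed = 24)
  dat <- data.frame(species = tr$tip.label, y = y, x = x)
  C <- phylo_vcv(tr)
  mc <- mcmc_control(chains = 2, iter = 1200, burnin = 400, thin = 2,
                     seed = 25)
  f_std <- suppressWarnings(fit_phylo_model(prepare_design(
    dat, C, model_spec("y", "beta", "x", standardize = TRUE, mcmc = mc))))
  f_raw <- suppressWarnings(fit_phylo_model(prepare_design(
    dat, C, model_spec("y", "beta", "x", standardize = FALSE, mcmc = mc))))
  e_std <- average_marginal_effect(f_std, "x")
  e_raw <- average_marginal_effect(f_raw, "x")
  expect_equal(e_std$significant, e_raw$significant)
  # the coefficient scale differs by the predictor sd
  expect_equal(mean(f_std$draws[, "b_x"]) / sd(x),
               mean(f_raw$draws[, "b_x"]), tolerance = 0.1)
})

test_that("non-convergence is flagged, not fatal", {
  fit <- make_gaussian_fit(seed = 5)
  expect_true(is.logical(fit$converged))
  expect_true(all(is.finite(fit$rhat)))
  # an unattainable threshold must flag (and warn), never abort
  set.seed(5)
  dat <- data.frame(species = sprintf("s%02d", 1:40), y = rnorm(40),
                    x1 = rnorm(40), x2 = rnorm(40))
  spec <- model_spec("y", "gaussian", c("x1", "x2"), phylo = FALSE,
                     mcmc = mcmc_control(chains = 2, iter = 1200,
                                         burnin = 400, thin = 2, seed = 5))
  design <- prepare_design(dat, NULL, spec)
  # R-hat is bounded below by sqrt((n-1)/n), so 0.5 can never be met
  expect_warning(strict <- fit_phylo_model(design, rhat_threshold = 0.5),
                 "non-converged")
  expect_false(strict$converged)
  expect_s3_class(strict, "phylo_fit")
})
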