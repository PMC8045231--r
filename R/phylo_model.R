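#' MCMC settings
#'
#' Defaults are the package's desk-scale settings (4 chains of 4,000
#' iterations, 1,000 burn-in, thinning 2). The heavier published-style
#' configuration (25 chains of 6,000 iterations, 2,000 burn-in, thinning 10)
#' is available by passing those values explicitly.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iter Iterations per chain, including burn-in.
#' @param burnin Burn-in iterations discarded from each chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Master seed; chain `k` runs under `seed + k - 1`.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iter = 4000, burnin = 1000, thin = 2,
                         seed = 1) {
  stopifnot(chains >= 1, iter > burnin, burnin >= 0, thin >= 1,
            (iter - burnin) %% thin == 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_control")
}

#' Prior settings
#'
#' Weakly informative defaults: improper flat priors on regression
#' coefficients, half-Student-t(3, 0, 2.5) on the phylogenetic and residual
#' standard deviations, and Gamma(0.01, 0.01) on the beta precision.
#'
#' @param sd_df,sd_scale Degrees of freedom and scale of the half-t prior on
#'   standard deviations.
#' @param phi_shape,phi_rate Shape and rate of the Gamma prior on the beta
#'   precision `phi`.
#' @return A list of class `prior_control`.
#' @export
prior_control <- function(sd_df = 3, sd_scale = 2.5,
                          phi_shape = 0.01, phi_rate = 0.01) {
  stopifnot(sd_df > 0, sd_scale > 0, phi_shape > 0, phi_rate > 0)
  structure(list(sd_df = sd_df, sd_scale = sd_scale,
                 phi_shape = phi_shape, phi_rate = phi_rate),
            class = "prior_control")
}

#' Declare a phylogenetic regression model
#'
#' @param response Name of the response column. Beta-family responses are
#'   proportions; mol% columns are converted to (0, 1) fractions during
#'   design preparation. Gaussian-family responses are z-standardized by
#'   default.
#' @param family `"beta"` (logit link, mean-precision parameterization) or
#'   `"gaussian"` (identity link).
#' @param predictors Character vector of predictor column names.
#' @param log_transform Subset of `predictors` to log-transform before
#'   standardization.
#' @param standardize Z-standardize predictors (after any log transform).
#' @param standardize_response Z-standardize a Gaussian response.
#' @param phylo Include the phylogenetic random effect.
#' @param priors A [prior_control()].
#' @param mcmc An [mcmc_control()].
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, family = c("beta", "gaussian"), predictors,
                       log_transform = character(), standardize = TRUE,
                       standardize_response = TRUE, phylo = TRUE,
                       priors = prior_control(), mcmc = mcmc_control()) {
  family <- match.arg(family)
  stopifnot(is.character(response), length(response) == 1L,
            is.character(predictors), length(predictors) >= 1L,
            all(log_transform %in% predictors))
  structure(list(response = response, family = family,
                 predictors = predictors, log_transform = log_transform,
                 standardize = standardize,
                 standardize_response = standardize_response,
                 phylo = phylo, priors = priors, mcmc = mcmc),
            class = "model_spec")
}

#' Squeeze proportions off the boundary of (0, 1)
#'
#' Applies `y' = (y * (n - 1) + 0.5) / n` to the whole vector, but only when
#' exact 0 or 1 occur; otherwise returns `y` unchanged. This is the standard
#' compression used to make boundary observations admissible under a beta
#' likelihood, whose support is open.
#'
#' @param y Numeric vector in \[0, 1\].
#' @return Vector strictly inside (0, 1), with attribute `squeezed`.
#' @export
squeeze_proportions <- function(y) {
  stopifnot(all(y >= 0 & y <= 1))
  hit <- any(y == 0 | y == 1)
  if (hit) {
    n <- length(y)
    y <- (y * (n - 1) + 0.5) / n
  }
  attr(y, "squeezed") <- hit
  y
}

#' Prepare the response, design matrix and covariance for fitting
#'
#' Applies the model's transforms: log transforms where declared, then
#' z-standardization of predictors; Gaussian responses are z-standardized
#' (optional), beta responses are converted from mol% to fractions when
#' values exceed 1 and squeezed off the boundary when exact 0/1 occur.
#' Species with missing values in any model variable are dropped (with a
#' message), and the covariance is subset and aligned to the remaining
#' species.
#'
#' @param data Data frame with a `species` column and the model variables.
#' @param C Phylogenetic correlation/covariance matrix with species
#'   dimnames, e.g. from [phylo_vcv()]. May be `NULL` when `spec$phylo` is
#'   `FALSE`.
#' @param spec A [model_spec()].
#' @return A list of class `prepared_design` with elements `y`, `X`
#'   (intercept + predictors), `C`, `species`, `spec`, `scaling` and
#'   bookkeeping fields `n_dropped` and `squeezed`.
#' @export
prepare_design <- function(data, C, spec) {
  stopifnot(is.data.frame(data), "species" %in% names(data),
            inherits(spec, "model_spec"))
  vars <- c(spec$response, spec$predictors)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("variables absent from data: ", paste(missing_cols, collapse = ", "))
  d <- data[, c("species", vars)]
  keep <- stats::complete.cases(d)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropping ", n_dropped, " species with missing values")
  d <- d[keep, , drop = FALSE]
  if (spec$phylo) {
    if (is.null(C)) stop("spec requests a phylogenetic effect but C is NULL")
    absent <- setdiff(d$species, rownames(C))
    if (length(absent))
      stop("species absent from the covariance matrix: ",
           paste(absent, collapse = ", "))
    C <- C[d$species, d$species]
  } else {
    C <- NULL
  }
  if (nrow(d) < length(spec$predictors) + 2L)
    stop("too few complete cases to fit the model")

  Xr <- as.matrix(d[, spec$predictors, drop = FALSE])
  for (v in spec$log_transform) {
    if (any(Xr[, v] <= 0))
      stop("log transform of non-positive values in predictor ", sQuote(v))
    Xr[, v] <- log(Xr[, v])
  }
  mu <- colMeans(Xr)
  sdv <- apply(Xr, 2L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance predictor(s): ",
         paste(spec$predictors[sdv == 0], collapse = ", "))
  if (spec$standardize) Xr <- sweep(sweep(Xr, 2L, mu), 2L, sdv, "/")
  X <- cbind("(Intercept)" = 1, Xr)

  y <- d[[spec$response]]
  squeezed <- FALSE
  y_center <- 0; y_scale <- 1
  if (spec$family == "beta") {
    if (any(y > 1)) y <- y / 100  # mol% to fraction
    if (any(y < 0 | y > 1))
      stop("beta response outside [0, 1] after fraction conversion")
    y <- squeeze_proportions(y)
    squeezed <- attr(y, "squeezed")
    attributes(y) <- NULL
    if (squeezed) message("boundary proportions squeezed into (0, 1)")
  } else if (spec$standardize_response) {
    y_center <- mean(y); y_scale <- stats::sd(y)
    if (y_scale == 0) stop("zero-variance response")
    y <- (y - y_center) / y_scale
  }

  structure(list(y = y, X = X, C = C, species = d$species, spec = spec,
                 scaling = list(x_center = mu, x_scale = sdv,
                                y_center = y_center, y_scale = y_scale),
                 n_dropped = n_dropped, squeezed = squeezed),
            class = "prepared_design")
}

#' Beta-regression log-likelihood (mean-precision parameterization)
#'
#' `sum(log dBeta(y_i; mu_i * phi, (1 - mu_i) * phi))` with
#' `logit(mu_i) = x_i' beta + u_i`.
#'
#' @param y Response in (0, 1).
#' @param X Design matrix.
#' @param beta Coefficient vector.
#' @param u Species random effects (0 for none).
#' @param phi Precision, > 0.
#' @return Scalar log-likelihood.
#' @export
beta_loglik <- function(y, X, beta, u = 0, phi) {
  stopifnot(all(y > 0 & y < 1), phi > 0)
  mu <- stats::plogis(drop(X %*% beta) + u)
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Log-density of the phylogenetic random effect
#'
#' Multivariate normal log-density of `u` with mean 0 and covariance
#' `sigma_p^2 * C`, evaluated through a Cholesky factorization of `C`.
#'
#' @param u Numeric vector of species effects.
#' @param sigma_p Phylogenetic standard deviation, > 0.
#' @param C Positive-definite correlation/covariance matrix.
#' @return Scalar log-density.
#' @export
phylo_prior_loglik <- function(u, sigma_p, C) {
  stopifnot(sigma_p > 0, length(u) == nrow(C))
  L <- tryCatch(chol(C), error = function(e)
    stop("C is not positive definite: ", conditionMessage(e)))
  z <- backsolve(L, u, transpose = TRUE)
  n <- length(u)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - n * log(sigma_p) -
    0.5 * sum(z^2) / sigma_p^2
}

# Cholesky-based inverse with escalating jitter for near-PSD matrices
chol_inv <- function(C, jitter = c(0, 1e-10, 1e-8, 1e-6)) {
  for (j in jitter) {
    Cj <- C + diag(j, nrow(C))
    L <- tryCatch(chol(Cj), error = function(e) NULL)
    if (!is.null(L)) return(chol2inv(L))
  }
  stop("covariance matrix is not positive definite even after jitter")
}

#' Fit a Bayesian phylogenetic beta/Gaussian regression
#'
#' Samples the joint posterior of the regression coefficients, the
#' phylogenetic standard deviation, the dispersion (beta precision `phi` or
#' Gaussian residual sd) and the species effects with an adaptive
#' Metropolis-within-Gibbs sampler (univariate random-walk updates, with
#' both centered and non-centered moves on the phylogenetic scale; proposal
#' scales adapt during burn-in only). Chains are initialized from jittered
#' least-squares starting values under per-chain seeds derived from the
#' master seed, so fits are exactly reproducible.
#'
#' @param design A [prepare_design()] result.
#' @param rhat_threshold Convergence threshold on the Gelman-Rubin statistic;
#'   the fit is flagged (not aborted) when any parameter exceeds it.
#' @return An object of class `phylo_fit`: list with `draws` (matrix of all
#'   retained draws, chains stacked), `chain_draws` (per-chain matrices),
#'   `rhat` (named vector), `converged`, `design` and `mcmc`.
#' @export
fit_phylo_model <- function(design, rhat_threshold = 1.01) {
  stopifnot(inherits(design, "prepared_design"))
  spec <- design$spec
  mc <- spec$mcmc
  pr <- spec$priors
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  use_phylo <- isTRUE(spec$phylo)
  fam <- if (spec$family == "gaussian") 0L else 1L

  Cinv <- if (use_phylo) chol_inv(design$C) else diag(1, n)

  # deterministic least-squares starting point, jittered per chain
  y_work <- if (fam == 1L) stats::qlogis(pmin(pmax(y, 1e-4), 1 - 1e-4)) else y
  beta_start <- tryCatch(stats::lm.fit(X, y_work)$coefficients,
                         error = function(e) rep(0, p))
  beta_start[!is.finite(beta_start)] <- 0

  chain_draws <- vector("list", mc$chains)
  for (k in seq_len(mc$chains)) {
    set.seed(mc$seed + k - 1L)
    beta0 <- beta_start + stats::rnorm(p, 0, 0.2)
    u0 <- stats::rnorm(n, 0, 0.1)
    sp0 <- exp(stats::rnorm(1, log(0.5), 0.3))
    disp0 <- if (fam == 0L) stats::sd(y_work) * exp(stats::rnorm(1, 0, 0.2))
             else 20 * exp(stats::rnorm(1, 0, 0.4))
    dr <- run_chain_cpp(y, X, Cinv, fam, use_phylo,
                        mc$iter, mc$burnin, mc$thin,
                        pr$sd_df, pr$sd_scale, pr$phi_shape, pr$phi_rate,
                        beta0, u0, sp0, disp0)
    colnames(dr) <- c(paste0("b_", colnames(X)),
                      if (use_phylo) "sigma_phylo",
                      if (fam == 0L) "sigma_resid" else "phi",
                      if (use_phylo) paste0("u_", design$species))
    chain_draws[[k]] <- dr
  }

  rh <- if (mc$chains >= 2L) {
    vapply(colnames(chain_draws[[1L]]), function(nm)
      rhat(lapply(chain_draws, function(d) d[, nm])), numeric(1L))
  } else {
    stats::setNames(rep(NA_real_, ncol(chain_draws[[1L]])),
                    colnames(chain_draws[[1L]]))
  }
  converged <- all(is.na(rh)) || max(rh, na.rm = TRUE) <= rhat_threshold
  if (!converged)
    warning("fit flagged as non-converged: max R-hat = ",
            format(max(rh, na.rm = TRUE), digits = 4))

  structure(list(draws = do.call(rbind, chain_draws),
                 chain_draws = chain_draws, rhat = rh,
                 converged = converged, rhat_threshold = rhat_threshold,
                 design = design, mcmc = mc),
            class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  spec <- x$design$spec
  cat("phylo_fit:", spec$family, "regression of", sQuote(spec$response),
      "on", paste(spec$predictors, collapse = " + "), "\n")
  cat(sprintf("  %d species, %d chains x %d draws retained; max R-hat %.4f%s\n",
              length(x$design$y), x$mcmc$chains, nrow(x$chain_draws[[1L]]),
              suppressWarnings(max(x$rhat, na.rm = TRUE)),
              if (x$converged) "" else " (NOT converged)"))
  print(summary(x))
  invisible(x)
}

#' Posterior summary of a fit
#'
#' @param object A `phylo_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return Data frame of posterior mean, sd, equal-tailed interval,
#'   significance flag (interval excludes zero) and R-hat for the
#'   regression coefficients and variance parameters.
#' @export
summary.phylo_fit <- function(object, level = 0.95, ...) {
  keep <- !startsWith(colnames(object$draws), "u_")
  d <- object$draws[, keep, drop = FALSE]
  ci <- apply(d, 2L, credible_interval, level = level)
  data.frame(parameter = colnames(d), mean = colMeans(d),
             sd = apply(d, 2L, stats::sd),
             lower = ci[1L, ], upper = ci[2L, ],
             significant = ci[1L, ] > 0 | ci[2L, ] < 0,
             rhat = object$rhat[keep], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) form: with `m` chains of length `n`, `W` the mean
#' within-chain variance and `B/n` the variance of chain means,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Chains that are all identical
#' constants give 1 by convention.
#'
#' @param chains List of equal-length numeric vectors (one per chain) or a
#'   draws-by-chains matrix.
#' @return Scalar R-hat.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2L)
  chains <- lapply(chains, as.numeric)
  m <- length(chains)
  if (m < 2L) stop("R-hat needs at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal lengths")
  n <- as.numeric(n)
  means <- vapply(chains, mean, numeric(1L))
  W <- mean(vapply(chains, stats::var, numeric(1L)))
  B_over_n <- stats::var(means)
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Equal-tailed credible interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`, using
#' linear interpolation of order statistics (R's default type-7 quantile).
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Credible level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), names = FALSE, type = 7))
}

#' Average marginal effect of a predictor
#'
#' For each retained draw, the derivative of the response mean with respect
#' to the (standardized) predictor, averaged over species. Gaussian family:
#' the coefficient itself. Beta family: `beta_j * mean(mu_i (1 - mu_i))`
#' with `mu_i` evaluated at that draw's coefficients and, by default, its
#' species effects (`include_random = FALSE` sets u = 0 instead).
#'
#' @param fit A `phylo_fit`.
#' @param predictor Name of a predictor in the model.
#' @param level Credible level for the equal-tailed interval.
#' @param include_random Include the sampled species effects in `mu_i`.
#' @return A list of class `effect_summary`: `predictor`, `mean`, `lower`,
#'   `upper`, `significant` and the per-draw `draws` of the effect.
#' @export
average_marginal_effect <- function(fit, predictor, level = 0.95,
                                    include_random = TRUE) {
  stopifnot(inherits(fit, "phylo_fit"))
  spec <- fit$design$spec
  if (!predictor %in% spec$predictors)
    stop("predictor ", sQuote(predictor), " is not in the model")
  bj <- fit$draws[, paste0("b_", predictor)]
  if (spec$family == "gaussian") {
    ame <- bj
  } else {
    X <- fit$design$X
    bcols <- paste0("b_", colnames(X))
    eta <- fit$draws[, bcols, drop = FALSE] %*% t(X)  # draws x species
    if (include_random && spec$phylo) {
      ucols <- paste0("u_", fit$design$species)
      eta <- eta + fit$draws[, ucols, drop = FALSE]
    }
    mu <- stats::plogis(eta)
    ame <- bj * rowMeans(mu * (1 - mu))
  }
  ci <- credible_interval(ame, level = level)
  structure(list(predictor = predictor, mean = mean(ame),
                 lower = ci[1L], upper = ci[2L],
                 significant = ci[1L] > 0 | ci[2L] < 0, draws = ame),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("AME of %s: %.4f [%.4f, %.4f]%s\n", x$predictor, x$mean,
              x$lower, x$upper, if (x$significant) " *" else ""))
  invisible(x)
}
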