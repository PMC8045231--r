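#' Phylogenetic generalized least squares
#'
#' GLS with error covariance proportional to a Brownian-motion phylogenetic
#' matrix: `beta = (X' C^-1 X)^-1 X' C^-1 y`, computed through a Cholesky
#' factorization of `C`. With `C = I` this is ordinary least squares.
#'
#' @param y Response vector.
#' @param X Design matrix (include your own intercept column).
#' @param C Positive-definite covariance/correlation matrix aligned to `y`.
#' @return A list of class `pgls_fit`: `coefficients`, `residuals`
#'   (response-scale, species-aligned), `fitted` and the matrix `C` used.
#' @export
pgls_fit <- function(y, X, C) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), nrow(C) == length(y))
  L <- tryCatch(chol(C), error = function(e)
    stop("C is not positive definite: ", conditionMessage(e)))
  # whiten: solve L' z = v  =>  z' z = v' C^-1 w
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12)
    stop("design is singular under the C^-1 inner product")
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  structure(list(coefficients = beta, residuals = y - fitted,
                 fitted = fitted, C = C),
            class = "pgls_fit")
}

#' Pairwise correlations of PGLS residuals
#'
#' For each variable: apply its transform (`"logit"` for proportions, with
#' mol% converted to fractions and boundary values squeezed as in
#' [squeeze_proportions()]; `"log"`; or `"none"`), regress on log body mass
#' by PGLS, and correlate the residuals of every pair of variables
#' (Pearson, pairwise-complete observations).
#'
#' @param data Data frame with a `species` column, the variables and a body
#'   mass column.
#' @param C Phylogenetic matrix with species dimnames covering
#'   `data$species`.
#' @param variables Character vector of variable names to correlate.
#' @param transforms Named character vector mapping variables to `"logit"`,
#'   `"log"` or `"none"`; unnamed variables default to `"none"`.
#' @param mass_var Name of the body mass column (log-transformed internally).
#' @return Symmetric correlation matrix over `variables`, with attribute
#'   `"n_species"`.
#' @export
residual_correlations <- function(data, C, variables,
                                  transforms = character(),
                                  mass_var = "body_mass") {
  stopifnot(is.data.frame(data), "species" %in% names(data),
            mass_var %in% names(data),
            all(variables %in% names(data)))
  bad <- setdiff(names(transforms), variables)
  if (length(bad))
    stop("transforms named for unknown variables: ", paste(bad, collapse = ", "))
  sp <- data$species
  C <- C[sp, sp]
  lmass <- log(data[[mass_var]])
  res <- matrix(NA_real_, nrow(data), length(variables),
                dimnames = list(sp, variables))
  for (v in variables) {
    x <- data[[v]]
    tr <- if (v %in% names(transforms)) transforms[[v]] else "none"
    ok <- !is.na(x) & !is.na(lmass)
    xv <- x[ok]
    xv <- switch(tr,
      logit = {
        if (any(xv > 1)) xv <- xv / 100
        if (any(xv < 0 | xv > 1))
          stop("variable ", sQuote(v), " outside [0, 1] for logit transform")
        xv <- squeeze_proportions(xv)
        attributes(xv) <- NULL
        stats::qlogis(xv)
      },
      log = {
        if (any(xv <= 0)) stop("log transform of non-positive ", sQuote(v))
        log(xv)
      },
      none = xv,
      stop("unknown transform ", sQuote(tr)))
    fit <- pgls_fit(xv, cbind(1, lmass[ok]), C[ok, ok, drop = FALSE])
    res[ok, v] <- fit$residuals
  }
  out <- stats::cor(res, use = "pairwise.complete.obs", method = "pearson")
  attr(out, "n_species") <- nrow(data)
  out
}
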