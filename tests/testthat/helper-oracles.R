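# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with naive per-species loops or closed forms and
# never call the implementation paths they check.

# per-species loop evaluation of all composition indices
oracle_indices <- function(m, fa) {
  pi_w <- c(0.025, 1, 2, 4, 6, 8)
  out <- NULL
  for (s in rownames(m)) {
    sfa <- mufa <- pufa <- n3 <- acl <- dbi <- piv <- 0
    ai_num <- 0; ai_den <- 0
    for (k in seq_len(ncol(m))) {
      p <- m[s, k]
      cl <- fa$sat_class[k]
      if (cl == "SFA") sfa <- sfa + p
      if (cl == "MUFA") mufa <- mufa + p
      if (cl == "PUFA") pufa <- pufa + p
      if (cl == "PUFA" && fa$omega_class[k] == "n3") n3 <- n3 + p
      acl <- acl + p / 100 * fa$chain_length[k]
      dbi <- dbi + p * fa$n_double_bonds[k]
      if (fa$n_double_bonds[k] >= 1) piv <- piv + p * pi_w[fa$n_double_bonds[k]]
      if (fa$label[k] %in% c("C20:3n6", "C20:5n3", "C22:6n3"))
        ai_num <- ai_num + p
      if (fa$label[k] == "C20:4n6") ai_den <- ai_den + p
    }
    out <- rbind(out, data.frame(
      species = s, sfa = sfa, mufa = mufa, pufa = pufa,
      n3_over_total_pufa = if (pufa > 0) n3 / pufa else NA_real_,
      acl = acl, dbi = dbi, pi_index = piv,
      ai = if (ai_den > 0) 100 * ai_num / ai_den else NA_real_))
  }
  rownames(out) <- NULL
  out
}

# random valid composition over a label set, rows closing to exactly 100
random_composition <- function(n_species, labels, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n_species * length(labels)), n_species)
  m <- m / rowSums(m) * 100
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_species)), labels)
  m
}

# naive pairwise shared-root-path covariance: sum the lengths of the edges
# common to both tips' root paths
oracle_vcv <- function(tr) {
  n <- length(tr$tip.label)
  nmax <- max(tr$edge)
  pa <- integer(nmax); el <- numeric(nmax)
  pa[tr$edge[, 2]] <- tr$edge[, 1]
  el[tr$edge[, 2]] <- tr$edge.length
  root <- n + 1L
  root_path <- function(tip) {
    p <- integer(0); v <- tip
    while (v != root) { p <- c(p, v); v <- pa[v] }
    p
  }
  paths <- lapply(seq_len(n), root_path)
  V <- matrix(0, n, n, dimnames = list(tr$tip.label, tr$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n))
    V[i, j] <- sum(el[intersect(paths[[i]], paths[[j]])])
  V
}

# spherical law of cosines, an independent great-circle formula
oracle_sloc_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  R * acos(pmin(1, pmax(-1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))))
}

# independent maximum-likelihood beta regression (BFGS on the negative
# log-likelihood, mean-precision parameterization)
oracle_ml_betareg <- function(y, X) {
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    phi <- exp(par[ncol(X) + 1L])
    mu <- stats::plogis(drop(X %*% beta))
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(stats::coef(stats::lm(stats::qlogis(y) ~ X - 1)), log(10))
  fit <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500))
  list(beta = unname(fit$par[seq_len(ncol(X))]),
       phi = exp(fit$par[ncol(X) + 1L]))
}

# small composition fixture builder: named mol% per fatty acid, one species
one_species_comp <- function(...) {
  v <- c(...)
  m <- matrix(v, 1, dimnames = list("sp1", names(v)))
  composition_table(m)
}
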