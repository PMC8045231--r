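#' Default fatty-acid panel and baseline profile
#'
#' Nineteen fatty acids spanning the classes observed in avian liver, with
#' baseline mol% set to the published species-level medians for the seven
#' abundant acids (palmitic 23.3, stearic 22.2, oleic 21.1, linoleic 9.3,
#' arachidonic 8.5, docosahexaenoic 3.5, palmitoleic 1.3) and sub-1%
#' baselines for the remaining minor acids, closing to 100.
#'
#' @return Named numeric vector of baseline mol% values.
#' @export
default_fa_panel <- function() {
  c("C14:0" = 0.9, "C16:0" = 23.3, "C16:1n7" = 1.3, "C17:0" = 0.9,
    "C18:0" = 22.2, "C18:1n9" = 21.1, "C18:1n7" = 0.9, "C18:2n6" = 9.3,
    "C18:3n3" = 0.9, "C20:1n9" = 0.9, "C20:3n6" = 0.9, "C20:4n6" = 8.5,
    "C20:5n3" = 0.9, "C22:0" = 0.9, "C22:1n9" = 0.9, "C22:4n6" = 0.9,
    "C22:5n6" = 0.9, "C22:5n3" = 0.9, "C22:6n3" = 3.5)
}

#' Simulation configuration
#'
#' Ground-truth parameters for the synthetic-data generator. Defaults
#' emulate the structure of the 106-species study data: a unit-height Yule
#' tree, Dirichlet compositions centred on the published median profile,
#' allometrically scaled life-history traits, and a focal beta-regression
#' effect of 0.3 (per sd of the predictor, logit scale) with phylogenetic
#' sd 0.5 and beta precision 50.
#'
#' @param n_species Number of species.
#' @param birth_rate Yule speciation rate (trees are rescaled to unit
#'   height, so this only shapes relative node depths).
#' @param beta_focal True focal fixed effect, logit scale per predictor sd.
#' @param sigma_p Phylogenetic random-effect sd.
#' @param phi Beta precision.
#' @param mass_meanlog,mass_sdlog Log body mass distribution (grams).
#' @param lifespan_base,lifespan_slope Median life span (years) at the mean
#'   log mass, and allometric slope on log mass.
#' @param fecundity_base,fecundity_slope Median annual fecundity (eggs/year)
#'   and its slope on log mass.
#' @param bmr_base,bmr_slope Median BMR (kJ/h) at the mean log mass and its
#'   allometric slope.
#' @param recovery_meanlog,recovery_sdlog Ring-recovery counts
#'   (log-normal, rounded up to at least 1).
#' @param trait_phylo_sd,trait_noise_sd Phylogenetic and independent sd of
#'   the log-scale life-history traits.
#' @param migration_prob Probability a species is migratory.
#' @param origin_lat,origin_lon Migration origin (a Jutland-like centroid).
#' @param dirichlet_precision Dirichlet concentration total for
#'   compositions.
#' @param composition_phylo_sd Sd of the phylogenetic log-concentration
#'   shifts.
#' @param base_profile Named baseline mol% vector, see [default_fa_panel()].
#' @param seed Master seed; component seeds are derived deterministically.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 106, birth_rate = 1,
                              beta_focal = 0.3, sigma_p = 0.5, phi = 50,
                              mass_meanlog = log(30), mass_sdlog = 1.3,
                              lifespan_base = 10, lifespan_slope = 0.2,
                              fecundity_base = 6, fecundity_slope = -0.15,
                              bmr_base = 1.2, bmr_slope = 0.66,
                              recovery_meanlog = 5, recovery_sdlog = 1.5,
                              trait_phylo_sd = 0.3, trait_noise_sd = 0.3,
                              migration_prob = 0.5,
                              origin_lat = 56.0, origin_lon = 9.25,
                              dirichlet_precision = 60,
                              composition_phylo_sd = 0.3,
                              base_profile = default_fa_panel(), seed = 1) {
  stopifnot(n_species >= 4, phi > 0, sigma_p >= 0, birth_rate > 0,
            dirichlet_precision > 0, all(base_profile > 0))
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Grows a tree by drawing exponential waiting times with rate
#' `k * birth_rate` while `k` lineages are extant and splitting a uniformly
#' chosen lineage at each event; the process is stopped one waiting time
#' after the n-th lineage appears and the tree is rescaled to unit height.
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional seed.
#' @return An ultrametric `phylo` tree of height 1 with tips
#'   `sp001, sp002, ...`.
#' @export
simulate_tree <- function(n, birth_rate = 1, seed = NULL) {
  stopifnot(n >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rexp(n - 1L, rate = birth_rate * (2:n))
  tev <- cumsum(w)
  present <- tev[n - 1L]
  nmax <- 2L * n - 1L
  parent <- integer(nmax)
  birth <- numeric(nmax)
  parent[2:3] <- 1L
  alive <- c(2L, 3L)
  nid <- 3L
  if (n > 2L) for (t in tev[seq_len(n - 2L)]) {
    j <- alive[sample.int(length(alive), 1L)]
    kids <- nid + 1:2
    nid <- nid + 2L
    parent[kids] <- j
    birth[kids] <- t
    alive <- c(alive[alive != j], kids)
  }
  # relabel: extant lineages become tips 1..n; internal nodes n+1..2n-1
  # (ascending, so the original root, node 1, maps to n+1 as ape requires)
  internals <- setdiff(seq_len(nmax), alive)
  newid <- integer(nmax)
  newid[alive] <- seq_len(n)
  newid[internals] <- n + seq_along(internals)
  death <- numeric(nmax)
  death[alive] <- present
  for (v in 2:nmax) death[parent[v]] <- birth[v]
  vs <- 2:nmax
  tr <- structure(list(edge = cbind(newid[parent[vs]], newid[vs]),
                       edge.length = (death[vs] - birth[vs]) / present,
                       Nnode = n - 1L,
                       tip.label = sprintf("sp%03d", seq_len(n))),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  # diagnostic metadata on the unscaled process: cumulative split times, the
  # last entry being the stopping (present) time
  attr(tr, "event_times") <- tev
  attr(tr, "height") <- present
  tr
}

#' Draw a phylogenetic random effect
#'
#' `u ~ MVN(0, sigma_p^2 * C)` with `C` the normalized Brownian correlation
#' of the tree, drawn through its Cholesky factor.
#'
#' @param tree A `phylo` tree.
#' @param sigma_p Phylogenetic sd (>= 0; 0 gives exact zeros).
#' @param seed Optional seed.
#' @param C Optional precomputed correlation matrix (tip-ordered), to avoid
#'   refactorizing across replicate draws.
#' @return Named numeric vector over the tips.
#' @export
simulate_phylo_effect <- function(tree, sigma_p, seed = NULL, C = NULL) {
  stopifnot(sigma_p >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(C)) C <- phylo_vcv(tree, normalize = TRUE)
  n <- nrow(C)
  if (sigma_p == 0) return(stats::setNames(rep(0, n), rownames(C)))
  u <- sigma_p * drop(t(chol(C)) %*% stats::rnorm(n))
  stats::setNames(u, rownames(C))
}

#' Simulate a beta-distributed proportion with known structure
#'
#' `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)` with
#' `logit(mu_i) = x_i' beta + u_i`.
#'
#' @param X Design matrix.
#' @param beta Coefficient vector.
#' @param u Species effects (scalar 0 for none).
#' @param phi Beta precision, > 0.
#' @param seed Optional seed.
#' @return Vector of proportions strictly in (0, 1).
#' @export
simulate_proportion <- function(X, beta, u = 0, phi, seed = NULL) {
  stopifnot(phi > 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::plogis(drop(as.matrix(X) %*% beta) + u)
  y <- stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
  # guard against numerical underflow to the boundary
  eps <- .Machine$double.eps
  pmin(pmax(y, eps), 1 - eps)
}

#' Simulate a species x fatty-acid composition table
#'
#' Per species, a Dirichlet draw whose log-concentrations are the baseline
#' profile shifted by per-acid phylogenetically correlated noise; rows are
#' scaled to 100 mol%, so closure holds by construction.
#'
#' @param tree A `phylo` tree.
#' @param config A [simulation_config()] (supplies the baseline profile,
#'   Dirichlet precision and phylogenetic sd).
#' @param seed Optional seed.
#' @return A [composition_table()].
#' @export
simulate_composition <- function(tree, config = simulation_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prof <- config$base_profile / sum(config$base_profile)
  n <- length(tree$tip.label)
  K <- length(prof)
  C <- phylo_vcv(tree, normalize = TRUE)
  G <- vapply(seq_len(K), function(k)
    simulate_phylo_effect(tree, config$composition_phylo_sd, C = C),
    numeric(n))
  alpha <- config$dirichlet_precision *
    matrix(prof, n, K, byrow = TRUE) * exp(G)
  draws <- matrix(stats::rgamma(n * K, shape = alpha, rate = 1), n, K)
  m <- 100 * draws / rowSums(draws)
  dimnames(m) <- list(tree$tip.label, names(prof))
  composition_table(m)
}

#' Simulate life-history traits and migration fields
#'
#' Log body mass is normal; log life span, log annual fecundity and log BMR
#' follow configurable allometric slopes on centred log mass plus
#' phylogenetic and independent noise; ring recoveries are positive
#' log-normal counts; migratory status is Bernoulli, with non-breeding
#' centroids drawn over an Africa/Europe-like window for migrants.
#'
#' @param tree A `phylo` tree.
#' @param config A [simulation_config()].
#' @param seed Optional seed.
#' @return Data frame with columns `species`, `body_mass` (g), `lifespan`
#'   (y), `recoveries`, `fecundity` (eggs/y), `bmr` (kJ/h), `status`,
#'   `lat`, `lon`.
#' @export
simulate_life_history <- function(tree, config = simulation_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  C <- phylo_vcv(tree, normalize = TRUE)
  lmass <- stats::rnorm(n, config$mass_meanlog, config$mass_sdlog)
  lmass_c <- lmass - mean(lmass)
  allo <- function(base, slope) {
    exp(log(base) + slope * lmass_c +
          simulate_phylo_effect(tree, config$trait_phylo_sd, C = C) +
          stats::rnorm(n, 0, config$trait_noise_sd))
  }
  lifespan <- allo(config$lifespan_base, config$lifespan_slope)
  fecundity <- allo(config$fecundity_base, config$fecundity_slope)
  bmr <- allo(config$bmr_base, config$bmr_slope)
  recoveries <- pmax(1, round(stats::rlnorm(n, config$recovery_meanlog,
                                            config$recovery_sdlog)))
  status <- ifelse(stats::rbinom(n, 1, config$migration_prob) == 1,
                   "migratory", "sedentary")
  lat <- ifelse(status == "migratory", stats::runif(n, -30, 35), NA_real_)
  lon <- ifelse(status == "migratory", stats::runif(n, -17, 42), NA_real_)
  data.frame(species = tree$tip.label, body_mass = exp(lmass),
             lifespan = lifespan, recoveries = recoveries,
             fecundity = fecundity, bmr = bmr, status = status,
             lat = lat, lon = lon,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Combines a Yule tree, a Dirichlet composition table, life-history traits
#' and a focal beta-distributed response whose logit mean is linear in
#' standardized log body mass and standardized log life span (coefficient
#' `beta_focal`) plus a phylogenetic effect — the structure the regression
#' models assume. Component seeds are derived from the master seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_dataset`: `tree`, `composition`,
#'   `traits`, `focal` (list with `y`, `X`, `u`) and `truth` (the
#'   generating parameters).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  s <- config$seed
  tree <- simulate_tree(config$n_species, config$birth_rate, seed = s + 1L)
  composition <- simulate_composition(tree, config, seed = s + 2L)
  traits <- simulate_life_history(tree, config, seed = s + 3L)
  u <- simulate_phylo_effect(tree, config$sigma_p, seed = s + 4L)
  X <- cbind("(Intercept)" = 1,
             log_mass = as.numeric(scale(log(traits$body_mass))),
             log_lifespan = as.numeric(scale(log(traits$lifespan))))
  beta <- c(-1.5, 0, config$beta_focal)
  y <- simulate_proportion(X, beta, u, config$phi, seed = s + 5L)
  structure(list(tree = tree, composition = composition, traits = traits,
                 focal = list(y = y, X = X, u = u),
                 truth = list(beta = beta, sigma_p = config$sigma_p,
                              phi = config$phi, config = config)),
            class = "synthetic_dataset")
}

#' Assemble the species-level analysis table of a dataset
#'
#' Joins fatty-acid fractions (mol%/100 per acid), the composition indices,
#' `log_ai`, the life-history traits and the processed migration distance
#' into the single table the model pipeline consumes.
#'
#' @param dataset A [simulate_dataset()] result (or any list with
#'   `composition` and `traits` in the same shapes).
#' @param origin_lat,origin_lon Migration origin; defaults come from the
#'   dataset's configuration when present.
#' @return Data frame keyed by `species`.
#' @export
assemble_analysis_table <- function(dataset, origin_lat = NULL,
                                    origin_lon = NULL) {
  comp <- dataset$composition
  traits <- dataset$traits
  cfg <- dataset$truth$config
  if (is.null(origin_lat)) origin_lat <- cfg$origin_lat
  if (is.null(origin_lon)) origin_lon <- cfg$origin_lon
  idx <- fa_index_table(comp)
  idx$log_ai <- log(idx$ai)
  frac <- as.data.frame(comp$proportions / 100, check.names = FALSE)
  frac$species <- comp$species
  md <- migration_distance(traits[, c("species", "status", "lat", "lon")],
                           origin_lat = origin_lat, origin_lon = origin_lon)
  names(md)[names(md) == "distance"] <- "migration_dist"
  out <- merge(merge(merge(idx, frac, by = "species"), traits,
                     by = "species"), md, by = "species")
  out[match(comp$species, out$species), , drop = FALSE]
}
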