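#' Enumerate the four model families over all responses
#'
#' Builds the full model list the comparative analysis runs: every fatty
#' acid in the panel plus SFA, MUFA, PUFA and the n-3/total-PUFA ratio as
#' beta responses, and ACL, DBI, PI and log-AI as Gaussian responses, each
#' crossed with the four fixed-effect families — (1) body mass alone,
#' (2) life span controlling for body mass, recoveries and migration
#' distance, (3) annual fecundity controlling for body mass and migration
#' distance, (4) BMR controlling for body mass. Responses or covariates
#' absent from `data_cols` yield skipped rows with a reason rather than
#' errors.
#'
#' @param data_cols Character vector of columns available in the analysis
#'   table (see [assemble_analysis_table()]).
#' @param panel Character vector of fatty-acid labels to model.
#' @param include_indices Add the eight composition indices (SFA, MUFA,
#'   PUFA, n-3/total PUFA as beta responses; ACL, DBI, PI, log-AI as
#'   Gaussian) to the response list.
#' @return Data frame of class `analysis_plan` with columns `response`,
#'   `family`, `model`, `focal`, `predictors` (comma-separated),
#'   `skipped`, `reason`.
#' @export
build_plan <- function(data_cols, panel = names(default_fa_panel()),
                       include_indices = TRUE) {
  responses <- data.frame(
    response = c(panel,
                 if (include_indices)
                   c("sfa", "mufa", "pufa", "n3_over_total_pufa",
                     "acl", "dbi", "pi_index", "log_ai")),
    stringsAsFactors = FALSE)
  responses$family <- c(rep("beta", length(panel) + if (include_indices) 4L else 0L),
                        if (include_indices) rep("gaussian", 4L))
  if (anyDuplicated(responses$response))
    stop("duplicated responses in the panel")
  families <- list(
    body_mass = list(focal = "body_mass", predictors = "body_mass"),
    lifespan = list(focal = "lifespan",
                    predictors = c("lifespan", "body_mass", "recoveries",
                                   "migration_dist")),
    fecundity = list(focal = "fecundity",
                     predictors = c("fecundity", "body_mass",
                                    "migration_dist")),
    bmr = list(focal = "bmr", predictors = c("bmr", "body_mass")))
  rows <- list()
  for (mname in names(families)) {
    fam <- families[[mname]]
    missing_pred <- setdiff(fam$predictors, data_cols)
    for (r in seq_len(nrow(responses))) {
      resp <- responses$response[r]
      skipped <- FALSE; reason <- NA_character_
      if (!resp %in% data_cols) {
        skipped <- TRUE; reason <- "response absent from data"
      } else if (length(missing_pred)) {
        skipped <- TRUE
        reason <- paste("missing covariate(s):",
                        paste(missing_pred, collapse = ", "))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, family = responses$family[r], model = mname,
        focal = fam$focal,
        predictors = paste(fam$predictors, collapse = ","),
        skipped = skipped, reason = reason, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("analysis_plan", "data.frame"))
}

# covariates that enter the models on the log scale
.log_covariates <- c("body_mass", "lifespan", "recoveries", "fecundity", "bmr")

#' Run an analysis plan
#'
#' Fits every non-skipped model in the plan with [fit_phylo_model()] and
#' summarizes the average marginal effect of each model's focal predictor.
#' Per-model seeds are derived from `seed` plus the plan row, so reruns are
#' byte-identical; non-converged or failed fits are flagged rows, never
#' errors.
#'
#' @param plan A [build_plan()] result.
#' @param data Analysis table from [assemble_analysis_table()].
#' @param C Phylogenetic correlation matrix covering the species.
#' @param mcmc An [mcmc_control()]; its seed is offset per model.
#' @param priors A [prior_control()].
#' @return Data frame of class `results_table`: one row per planned model
#'   with the AME posterior mean, equal-tailed interval, significance flag,
#'   maximum R-hat, species count, convergence flag and failure reason.
#' @export
run_plan <- function(plan, data, C, mcmc = mcmc_control(),
                     priors = prior_control()) {
  stopifnot(inherits(plan, "analysis_plan"))
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    base <- data.frame(response = row$response, model = row$model,
                       focal = row$focal, ame = NA_real_,
                       lower = NA_real_, upper = NA_real_,
                       significant = NA, rhat_max = NA_real_,
                       n_species = NA_integer_, converged = NA,
                       status = "ok", stringsAsFactors = FALSE)
    if (row$skipped) {
      base$status <- paste("skipped:", row$reason)
      out[[i]] <- base
      next
    }
    res <- tryCatch({
      preds <- strsplit(row$predictors, ",")[[1L]]
      mc <- mcmc
      mc$seed <- mcmc$seed + i
      spec <- model_spec(row$response, family = row$family,
                        predictors = preds,
                        log_transform = intersect(preds, .log_covariates),
                        priors = priors, mcmc = mc)
      design <- suppressMessages(prepare_design(data, C, spec))
      fit <- suppressWarnings(fit_phylo_model(design))
      eff <- average_marginal_effect(fit, row$focal)
      base$ame <- eff$mean
      base$lower <- eff$lower
      base$upper <- eff$upper
      base$significant <- eff$significant
      base$rhat_max <- max(fit$rhat, na.rm = TRUE)
      base$n_species <- length(design$y)
      base$converged <- fit$converged
      if (!fit$converged) base$status <- "not converged"
      base
    }, error = function(e) {
      base$status <- paste("failed:", conditionMessage(e))
      base
    })
    out[[i]] <- res
  }
  structure(do.call(rbind, out), class = c("results_table", "data.frame"))
}

#' Forest-style listing of average marginal effects
#'
#' Orders results by model family and then by the configured response
#' order, appending a significance marker where the credible interval
#' excludes zero.
#'
#' @param results A [run_plan()] result.
#' @return Data frame grouped by model with columns of `results` plus
#'   `marker` (`"*"` where significant).
#' @export
forest_summary <- function(results) {
  stopifnot(inherits(results, "results_table"))
  if (!nrow(results)) return(results)
  ord <- order(match(results$model,
                     c("body_mass", "lifespan", "fecundity", "bmr")),
               match(results$response, unique(results$response)))
  out <- results[ord, , drop = FALSE]
  out$marker <- ifelse(!is.na(out$significant) & out$significant, "*", "")
  rownames(out) <- NULL
  out
}

#' Forest plot of average marginal effects
#'
#' Point estimates with 95% interval bars, one row per response, for one
#' model family at a time.
#'
#' @param results A [run_plan()] result.
#' @param model Which model family to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted subset.
#' @export
plot_forest <- function(results, model = "lifespan", ...) {
  d <- results[results$model == model & !is.na(results$ame), , drop = FALSE]
  if (!nrow(d)) stop("no fitted models for family ", sQuote(model))
  k <- nrow(d)
  graphics::plot(d$ame, seq_len(k), xlim = range(c(d$lower, d$upper, 0)),
                 yaxt = "n", ylab = "", pch = 19,
                 xlab = sprintf("average marginal effect of %s", model), ...)
  graphics::segments(d$lower, seq_len(k), d$upper, seq_len(k))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = d$response, las = 1,
                 cex.axis = 0.6)
  invisible(d)
}
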