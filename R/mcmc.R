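# MCMC over (beta, sigma2, lambda, tree identity), posterior prediction for
# a held-out focal tip, and the 95%-credible-interval singularity verdict.
#
# Model: y ~ N(X beta, sigma2 * V(lambda)), V(lambda) the Brownian VCV of the
# current tree with off-diagonals scaled by lambda. Priors: flat on beta,
# 1/sigma2 on sigma2 (both improper, conjugate), uniform[0,1] on lambda; the
# tree index is drawn uniformly from the supplied set each iteration, which
# marginalises the predictions over resolution uncertainty.

#' MCMC configuration
#'
#' Defaults follow the standard setting for this analysis: 100 burn-in
#' iterations, 200 000 sampling iterations thinned every 100, retaining 2000
#' posterior samples.
#'
#' @param burn_in Burn-in iterations (discarded).
#' @param n_iter Post-burn-in iterations.
#' @param thin Thinning interval; `n_iter / thin` samples are retained.
#' @param seed Integer seed.
#' @param lambda_mode `"estimated"` (lambda sampled by Metropolis) or a fixed
#'   numeric value in `[0, 1]`.
#' @param prop_sd Initial SD of the reflected-Gaussian lambda proposal.
#' @param adapt Adapt `prop_sd` during burn-in only (frozen afterwards, so
#'   detailed balance holds for the retained samples).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(burn_in = 100, n_iter = 200000, thin = 100, seed = 1,
                        lambda_mode = "estimated", prop_sd = 0.1,
                        adapt = TRUE) {
  stopifnot(burn_in >= 0, n_iter >= thin, thin >= 1)
  if (is.numeric(lambda_mode)) {
    if (lambda_mode < 0 || lambda_mode > 1)
      stop("fixed lambda must lie in [0, 1]")
  } else if (!identical(lambda_mode, "estimated")) {
    stop("lambda_mode must be \"estimated\" or a numeric value")
  }
  structure(list(burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = as.integer(seed),
                 lambda_mode = lambda_mode, prop_sd = prop_sd, adapt = adapt),
            class = "mcmc_config")
}

# Precompute, for each tree, the VCV split into observed block, focal column
# and focal variance, with a fixed tip order (observed species then focal).
prepare_tree_covariances <- function(trees, species, focal) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  lapply(unclass(trees), function(tr) {
    if (!ape::is.binary(tr))
      stop("non-bifurcating tree in the set; resolve polytomies first")
    if (!focal %in% tr$tip.label)
      stop("focal taxon '", focal, "' missing from a tree in the set")
    Cfull <- vcv_matrix(tr, c(species, focal))
    n <- length(species)
    list(Cobs = Cfull[seq_len(n), seq_len(n), drop = FALSE],
         cf = Cfull[seq_len(n), n + 1L],
         vff = Cfull[n + 1L, n + 1L])
  })
}

#' Sample the phylogenetic regression posterior by MCMC
#'
#' Gibbs updates draw the coefficients from their conditional Gaussian and
#' the residual variance from its conditional inverse-gamma; Pagel's lambda
#' is updated by a Metropolis step with a reflected Gaussian proposal on
#' `[0, 1]`; the tree identity is resampled uniformly from `trees` every
#' iteration. The focal taxon must be present in every tree but absent from
#' the trait table -- its trait values are withheld so the posterior (and
#' hence the prediction) is not biased by the very species under test.
#'
#' @param table A `species_traits` data.frame excluding the focal taxon.
#' @param trees A `multiPhylo` (or single `phylo`) of strictly bifurcating
#'   trees, all containing the focal tip.
#' @param focal Focal taxon label.
#' @param cfg An [mcmc_config()].
#' @return A `posterior_samples` data.frame with columns `iteration`,
#'   `intercept`, `slope`, `sigma2`, `lambda`, `tree_index`, and attributes
#'   carrying the configuration, acceptance rate and cached covariances.
#' @export
run_mcmc <- function(table, trees, focal, cfg = mcmc_config()) {
  focal <- normalize_labels(focal)
  if (focal %in% table$species)
    stop("focal taxon '", focal, "' found in the trait table; remove its ",
         "row before fitting (predictions must not be conditioned on it)")
  covs <- prepare_tree_covariances(trees, table$species, focal)
  y <- table$log_brain_volume
  X <- cbind(1, table$log_body_mass)
  lambda_fixed <- if (is.numeric(cfg$lambda_mode)) cfg$lambda_mode else -1
  set.seed(cfg$seed)
  res <- mcmc_pgls_cpp(y, X, lapply(covs, `[[`, "Cobs"),
                       cfg$burn_in, cfg$n_iter, cfg$thin,
                       lambda_fixed, 0.5, cfg$prop_sd, cfg$adapt)
  out <- data.frame(iteration = drop(res$iteration),
                    intercept = res$beta[, 1], slope = res$beta[, 2],
                    sigma2 = drop(res$sigma2), lambda = drop(res$lambda),
                    tree_index = drop(res$tree_index))
  class(out) <- c("posterior_samples", "data.frame")
  attr(out, "config") <- cfg
  attr(out, "focal") <- focal
  attr(out, "accept_rate") <- res$accept_rate
  attr(out, "jitter_events") <- res$jitter_events
  attr(out, "tree_covariances") <- covs
  attr(out, "data") <- list(y = y, X = X, species = table$species)
  out
}

#' Posterior-predictive draws for the focal taxon
#'
#' For each retained posterior sample, one value is drawn from the
#' conditional Gaussian of the focal tip given the observed tips:
#' `mean = xf' beta + cf' Vobs^-1 (y - X beta)` and
#' `variance = sigma2 * (vff - cf' Vobs^-1 cf)`, with `V` the
#' lambda-transformed VCV of that sample's tree and `cf` the focal/observed
#' covariance block. Numerically non-positive predictive variances are
#' clipped at 1e-12 (count reported in attribute `n_clipped`).
#'
#' @param samples A `posterior_samples` object from [run_mcmc()].
#' @param focal_predictor The focal taxon's log10 body mass (g).
#' @param seed Seed for the predictive draws; defaults to the sampler seed
#'   plus one.
#' @return A `prediction_result` list with `draws` (one per posterior
#'   sample), per-draw conditional `mean` and `var`, and empty verdict
#'   fields to be completed by [singularity_test()].
#' @export
posterior_predict <- function(samples, focal_predictor, seed = NULL) {
  covs <- attr(samples, "tree_covariances")
  dat <- attr(samples, "data")
  if (is.null(covs) || is.null(dat))
    stop("samples object lacks cached covariances; run run_mcmc() first")
  if (is.null(seed)) seed <- attr(samples, "config")$seed + 1L
  set.seed(seed)
  res <- predict_draws_cpp(as.matrix(samples[, c("intercept", "slope")]),
                           samples$sigma2, samples$lambda,
                           as.integer(samples$tree_index),
                           lapply(covs, `[[`, "Cobs"),
                           lapply(covs, `[[`, "cf"),
                           vapply(covs, `[[`, numeric(1), "vff"),
                           dat$y, dat$X, c(1, focal_predictor))
  out <- list(draws = drop(res$draws), mean = drop(res$mean),
              var = drop(res$var),
              focal = attr(samples, "focal"),
              focal_predictor = focal_predictor,
              n_draws = length(res$draws), n_clipped = res$n_clipped,
              observed = NA_real_, p_below = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, is_singularity = NA,
              seed = seed)
  if (res$n_clipped > 0)
    message(res$n_clipped, " predictive variance(s) clipped at 1e-12")
  class(out) <- "prediction_result"
  out
}

# conditional mean and variance of the focal tip for one parameter value --
# the same algebra the predictive loop uses, exposed for direct checking
#' Conditional predictive moments for the focal tip
#'
#' Computes the mean and variance of the focal tip's trait conditional on
#' the observed tips, at fixed parameter values -- the building block of
#' [posterior_predict()], exposed so the partitioned-Gaussian algebra can be
#' inspected and verified directly.
#'
#' @param Cfull Full VCV including the focal tip as last row/column.
#' @param lam,beta,sigma2 Parameter values.
#' @param y Observed responses (all tips except focal, in `Cfull` order).
#' @param X Design matrix of the observed tips.
#' @param xf Focal design row (e.g. `c(1, log10(body mass))`).
#' @return List with `mean` and `var`.
#' @export
predictive_moments <- function(Cfull, lam, beta, sigma2, y, X, xf) {
  n <- nrow(Cfull) - 1L
  V <- lambda_transform(Cfull, lam)
  Vobs <- V[seq_len(n), seq_len(n), drop = FALSE]
  cf <- V[seq_len(n), n + 1L]
  L <- chol_with_jitter(Vobs)
  zr <- backsolve(L, y - X %*% beta, transpose = TRUE)
  zc <- backsolve(L, cf, transpose = TRUE)
  list(mean = drop(xf %*% beta) + sum(zc * zr),
       var = sigma2 * (V[n + 1L, n + 1L] - sum(zc^2)))
}

#' Complete the singularity verdict for a prediction
#'
#' Computes the proportion of predictive draws below the observed value, the
#' central 95\% credible interval of the predictive distribution, and the
#' singularity flag: the focal taxon is an evolutionary singularity when its
#' observed trait value falls outside that interval. `p_below` mirrors the
#' one-tailed proportion conventionally reported alongside the two-tailed
#' interval verdict.
#'
#' @param result A `prediction_result` from [posterior_predict()].
#' @param observed Observed focal trait value (log10 ml).
#' @param conf Credible level (default 0.95).
#' @return The completed `prediction_result`.
#' @export
singularity_test <- function(result, observed, conf = 0.95) {
  stopifnot(inherits(result, "prediction_result"))
  if (length(result$draws) < 100)
    stop("need at least 100 predictive draws for a stable interval")
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(result$draws, c(alpha, 1 - alpha)))
  result$observed <- observed
  result$p_below <- mean(result$draws < observed)
  result$ci_low <- ci[1]
  result$ci_high <- ci[2]
  result$is_singularity <- observed < ci[1] || observed > ci[2]
  result
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("Posterior prediction for '%s' (%d draws)\n", x$focal,
              x$n_draws))
  if (!is.na(x$observed)) {
    cat(sprintf("  observed = %.4f, predicted 95%% CI = [%.4f, %.4f]\n",
                x$observed, x$ci_low, x$ci_high))
    cat(sprintf("  P(prediction < observed) = %.4f -> %s\n", x$p_below,
                if (x$is_singularity) "EVOLUTIONARY SINGULARITY"
                else "not a singularity"))
  } else {
    cat("  verdict pending: call singularity_test() with the observed value\n")
  }
  invisible(x)
}

#' Run the singularity pipeline for several focal trait combinations
#'
#' Repeats the fit-and-predict procedure once per row of `breed_table`, each
#' run with its own derived seed, as when several ancient dog breeds each
#' stand in for the ancestral state at domestication. The trait table and
#' trees are shared; only the focal predictor and observed value change.
#'
#' @param breed_table data.frame with columns `breed`, `body_mass_g`,
#'   `brain_volume_ml`.
#' @param base_table `species_traits` table excluding the focal taxon.
#' @param trees Bifurcating `multiPhylo` containing the focal tip.
#' @param focal Focal tip label shared by all runs.
#' @param cfg An [mcmc_config()]; run `i` uses seed `cfg$seed + i - 1`.
#' @return A `breed_runs` data.frame (one row per breed: `p_below`,
#'   `lambda_mean`, CI bounds, `is_singularity`, `n_below`), with aggregate
#'   attributes `n_nonsingular`, `mean_n_below` and `mean_pct_below`.
#' @export
batch_breed_runs <- function(breed_table, base_table, trees, focal = "dog",
                             cfg = mcmc_config()) {
  stopifnot(all(c("breed", "body_mass_g", "brain_volume_ml") %in%
                  names(breed_table)))
  rows <- lapply(seq_len(nrow(breed_table)), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    samples <- run_mcmc(base_table, trees, focal, cfg_i)
    pred <- posterior_predict(samples, log10(breed_table$body_mass_g[i]))
    pred <- singularity_test(pred, log10(breed_table$brain_volume_ml[i]))
    data.frame(breed = breed_table$breed[i],
               body_mass_g = breed_table$body_mass_g[i],
               brain_volume_ml = breed_table$brain_volume_ml[i],
               p_below = pred$p_below,
               lambda_mean = mean(samples$lambda),
               ci_low = pred$ci_low, ci_high = pred$ci_high,
               is_singularity = pred$is_singularity,
               n_below = sum(pred$draws < pred$observed),
               n_draws = pred$n_draws,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("breed_runs", "data.frame")
  attr(out, "n_nonsingular") <- sum(!out$is_singularity)
  attr(out, "mean_n_below") <- mean(out$n_below)
  attr(out, "mean_pct_below") <- 100 * mean(out$n_below / out$n_draws)
  out
}

#' MCMC convergence diagnostics
#'
#' Effective sample size and Geweke z-score for each scalar parameter, with
#' a pass/warn verdict (warn when any ESS < 200 or |z| > 2.5).
#'
#' @param samples A `posterior_samples` object (>= 200 retained samples).
#' @return A `convergence_report` list with a per-parameter data.frame and a
#'   `verdict` of "pass" or "warn".
#' @export
convergence_diagnostics <- function(samples) {
  if (nrow(samples) < 200)
    stop("need >= 200 retained samples for diagnostics")
  pars <- c("intercept", "slope", "sigma2")
  if (length(unique(samples$lambda)) > 1) pars <- c(pars, "lambda")
  ch <- coda::mcmc(as.matrix(samples[, pars, drop = FALSE]))
  ess <- coda::effectiveSize(ch)
  gz <- tryCatch(coda::geweke.diag(ch)$z,
                 error = function(e) setNames(rep(NA_real_, length(pars)),
                                              pars))
  tab <- data.frame(parameter = pars,
                    mean = colMeans(samples[, pars, drop = FALSE]),
                    sd = apply(samples[, pars, drop = FALSE], 2, sd),
                    ess = unname(ess[pars]), geweke_z = unname(gz[pars]),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  warn <- any(tab$ess < 200, na.rm = TRUE) |
    any(abs(tab$geweke_z) > 2.5, na.rm = TRUE)
  out <- list(table = tab, verdict = if (warn) "warn" else "pass",
              n_samples = nrow(samples),
              accept_rate = attr(samples, "accept_rate"))
  class(out) <- "convergence_report"
  out
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("MCMC diagnostics (%d retained samples): %s\n", x$n_samples,
              toupper(x$verdict)))
  print(x$table, digits = 4)
  if (!is.null(x$accept_rate) && !is.na(x$accept_rate))
    cat(sprintf("lambda proposal acceptance rate: %.2f\n", x$accept_rate))
  invisible(x)
}

#' Write posterior samples to CSV
#' @param samples A `posterior_samples` object.
#' @param path Output path.
#' @export
write_posterior_csv <- function(samples, path) {
  write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}
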