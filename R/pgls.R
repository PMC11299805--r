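# Frequentist allometry fits: OLS for description/residual ranking and GLS
# under a lambda-scaled Brownian covariance, with ML lambda profiling. The
# GLS likelihood here is the analytic backbone of the MCMC sampler.

#' Ordinary least-squares allometry
#'
#' Fits `log10(brain volume) ~ log10(body mass)` across all species in the
#' table by ordinary (non-phylogenetic) least squares, as used for the
#' descriptive regression line and the residual ranking that suggests
#' candidate outliers.
#'
#' @param table A `species_traits` data.frame.
#' @return A `regression_fit` list with `intercept`, `slope`, `sigma2` (ML,
#'   i.e. RSS/n), `lambda` (NA for OLS), `loglik`, and named `residuals` and
#'   `fitted`.
#' @export
fit_ols <- function(table) {
  stopifnot(nrow(table) >= 3)
  if (var(table$log_body_mass) <= 0)
    stop("degenerate predictor: zero variance in log body mass")
  fit <- lm(log_brain_volume ~ log_body_mass, data = table)
  r <- setNames(resid(fit), table$species)
  n <- nrow(table)
  s2 <- sum(r^2) / n
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  out <- list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
              sigma2 = s2, lambda = NA_real_, loglik = ll,
              residuals = r, fitted = setNames(fitted(fit), table$species),
              method = "OLS", n = n)
  class(out) <- "regression_fit"
  out
}

#' Generalized least-squares allometry on a phylogeny
#'
#' Fits the allometric regression with residual covariance
#' `sigma2 * V(lambda)`, where `V(lambda)` is the Brownian-motion
#' variance-covariance matrix of the tree with off-diagonals scaled by
#' Pagel's lambda. Coefficients are the exact GLS solution, `sigma2` its
#' maximum-likelihood estimate (quadratic form / n), and `loglik` the exact
#' Gaussian log-likelihood. Solves go through a Cholesky factor with a
#' 1e-10 diagonal jitter fallback (a message is emitted when triggered).
#'
#' @param table A `species_traits` data.frame.
#' @param C Phylogenetic VCV whose dimnames cover the table's species.
#' @param lam Pagel's lambda in `[0, 1]`.
#' @return A `regression_fit` list (see [fit_ols()]) with `lambda = lam`.
#' @export
fit_gls <- function(table, C, lam = 1) {
  species <- table$species
  missing <- setdiff(species, rownames(C))
  if (length(missing))
    stop("species missing from covariance matrix: ",
         paste(missing, collapse = ", "))
  C <- C[species, species, drop = FALSE]
  V <- lambda_transform(C, lam)
  L <- chol_with_jitter(V)
  y <- table$log_brain_volume
  X <- cbind(1, table$log_body_mass)
  W <- backsolve(L, X, transpose = TRUE)
  z <- backsolve(L, y, transpose = TRUE)
  A <- crossprod(W)
  beta <- solve(A, crossprod(W, z))
  rw <- z - W %*% beta
  n <- length(y)
  s2 <- sum(rw^2) / n
  logdet <- 2 * sum(log(diag(L)))
  ll <- -n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2
  r <- setNames(y - X %*% beta, species)
  out <- list(intercept = beta[1], slope = beta[2], sigma2 = s2, lambda = lam,
              loglik = ll, residuals = drop(r),
              fitted = setNames(drop(X %*% beta), species),
              method = "GLS", n = n)
  class(out) <- "regression_fit"
  out
}

# upper Cholesky with one retry after adding a small diagonal jitter
chol_with_jitter <- function(V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    message("covariance matrix near-singular; adding 1e-10 diagonal jitter ",
            "(consider lambda < 1)")
    L <- tryCatch(chol(V + diag(1e-10 * mean(diag(V)), nrow(V))),
                  error = function(e)
                    stop("singular covariance matrix even after jitter; ",
                         "try lambda < 1", call. = FALSE))
  }
  L
}

#' Profile Pagel's lambda by maximum likelihood
#'
#' Evaluates the GLS profile log-likelihood over a grid on `[0, 1]`, then
#' refines around the grid argmax with golden-section search
#' ([stats::optimize()]). Exact likelihood ties are broken toward the
#' smaller lambda.
#'
#' @param table A `species_traits` data.frame.
#' @param C Phylogenetic VCV covering the table's species.
#' @param grid Lambda grid within `[0, 1]`.
#' @return A list with `lambda_hat` and `fit` (the `regression_fit` at the
#'   optimum).
#' @export
profile_lambda <- function(table, C, grid = seq(0, 1, by = 0.05)) {
  stopifnot(all(grid >= 0 & grid <= 1), length(grid) >= 2)
  grid <- sort(grid)
  ll <- vapply(grid, function(l) fit_gls(table, C, l)$loglik, numeric(1))
  best <- which(ll == max(ll))[1]  # ties -> smaller lambda
  lo <- grid[max(best - 1L, 1L)]
  hi <- grid[min(best + 1L, length(grid))]
  lam_hat <- grid[best]
  if (hi > lo) {
    opt <- optimize(function(l) fit_gls(table, C, l)$loglik,
                    interval = c(lo, hi), maximum = TRUE,
                    tol = .Machine$double.eps^0.25)
    if (opt$objective > max(ll) + 1e-10) lam_hat <- opt$maximum
  }
  list(lambda_hat = lam_hat, fit = fit_gls(table, C, lam_hat),
       grid = grid, grid_loglik = ll)
}

#' Ranked residual table from a regression fit
#'
#' @param fit A `regression_fit`.
#' @return A data.frame with `species`, `fitted`, `residual` and
#'   `abs_residual_rank` (1 = largest absolute residual), sorted by rank.
#' @export
residual_table <- function(fit) {
  r <- fit$residuals
  out <- data.frame(species = names(r), fitted = unname(fit$fitted[names(r)]),
                    residual = unname(r), stringsAsFactors = FALSE)
  out$abs_residual_rank <- rank(-abs(out$residual), ties.method = "min")
  out[order(out$abs_residual_rank), , drop = FALSE]
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s allometric fit (n = %d)\n", x$method, x$n))
  cat(sprintf("  log10(brain volume) = %.4f + %.4f * log10(body mass)\n",
              x$intercept, x$slope))
  lam <- if (is.na(x$lambda)) "n/a" else sprintf("%.3f", x$lambda)
  cat(sprintf("  sigma2 (ML) = %.5f, lambda = %s, logLik = %.3f\n",
              x$sigma2, lam, x$loglik))
  invisible(x)
}
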