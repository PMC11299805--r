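# MCMC sampler, posterior prediction, singularity verdict, diagnostics

make_small_instance <- function(seed, n_tips = 8) {
  spec <- simulation_spec(n_tips = n_tips, seed = seed)
  study <- simulate_study(spec)
  list(spec = spec, study = study,
       tab = study$table[study$table$species != spec$focal, ])
}

test_that("configuration defaults give the standard 2000 retained samples", {
  cfg <- mcmc_config()
  expect_equal(cfg$burn_in, 100L)
  expect_equal(cfg$n_iter, 200000L)
  expect_equal(cfg$thin, 100L)
  expect_equal(cfg$n_iter / cfg$thin, 2000)
  expect_error(mcmc_config(lambda_mode = 1.4), "lambda")
  expect_error(mcmc_config(n_iter = 5, thin = 10), "n_iter")
})

test_that("sampler enforces its preconditions as hard errors", {
  inst <- make_small_instance(1)
  # focal trait row present in the table
  expect_error(run_mcmc(inst$study$table, inst$study$tree, inst$spec$focal),
               "found in the trait table")
  # focal tip missing from the tree
  expect_error(run_mcmc(inst$tab, ape::drop.tip(inst$study$tree,
                                                inst$spec$focal),
                        inst$spec$focal), "missing from a tree")
  # non-bifurcating tree
  poly <- read_newick("((A:1,B:1,C:1):1,focal_sp:2);")
  tab <- inst$tab[1:3, ]
  tab$species <- c("A", "B", "C")
  expect_error(run_mcmc(tab, poly, "focal_sp"), "non-bifurcating")
})

test_that("whole chain is reproducible bit-for-bit under a fixed seed", {
  inst <- make_small_instance(2)
  cfg <- mcmc_config(n_iter = 2000, thin = 10, seed = 11)
  s1 <- run_mcmc(inst$tab, inst$study$tree, inst$spec$focal, cfg)
  s2 <- run_mcmc(inst$tab, inst$study$tree, inst$spec$focal, cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  p1 <- singularity_test(posterior_predict(s1, 3.5), 1.5)
  p2 <- singularity_test(posterior_predict(s2, 3.5), 1.5)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$p_below, p2$p_below)
  # retained iteration bookkeeping: first draw at burn_in + thin
  expect_equal(s1$iteration[1], cfg$burn_in + cfg$thin)
  expect_equal(nrow(s1), cfg$n_iter / cfg$thin)
  expect_true(all(s1$sigma2 > 0))
  expect_true(all(s1$lambda >= 0 & s1$lambda <= 1))
  expect_true(all(s1$tree_index == 1))
})

test_that("fixed-lambda flat-prior chain matches the conjugate posterior", {
  # with lambda fixed and one tree the beta-marginal posterior mean is the
  # GLS estimate (normal-inverse-gamma conjugacy under flat/1-over-sigma2
  # priors); spot check here, the batched version lives in the acceptance
  # suite
  inst <- make_small_instance(3, n_tips = 9)
  C <- vcv_matrix(inst$study$tree, c(inst$tab$species, inst$spec$focal))
  Cobs <- C[inst$tab$species, inst$tab$species]
  cfg <- mcmc_config(n_iter = 40000, thin = 10, seed = 4, lambda_mode = 0.5)
  s <- run_mcmc(inst$tab, inst$study$tree, inst$spec$focal, cfg)
  expect_true(all(s$lambda == 0.5))
  gls <- fit_gls(inst$tab, Cobs, 0.5)
  se <- sd(s$slope) / sqrt(coda::effectiveSize(coda::mcmc(s$slope)))
  expect_lt(abs(mean(s$slope) - gls$slope), 4 * se)
})

test_that("predictive mean reduces to the regression line when lambda = 0", {
  inst <- make_small_instance(5)
  cfg <- mcmc_config(n_iter = 1000, thin = 10, seed = 6, lambda_mode = 0)
  s <- run_mcmc(inst$tab, inst$study$tree, inst$spec$focal, cfg)
  pred <- posterior_predict(s, 4.2)
  # no phylogenetic borrowing: mean_i = beta0_i + beta1_i * x_f exactly
  expect_equal(pred$mean, s$intercept + s$slope * 4.2, tolerance = 1e-10)
})

test_that("a zero-length cherry inherits its sister's value in the limit", {
  # focal F sits on a zero-length cherry with tip A (perfect correlation);
  # conditional mean -> y_A exactly, conditional variance -> 0, whatever
  # sigma2 is
  tr <- read_newick("(((A:0,F:0):2,B:2):1,C:3);")
  tab <- data.frame(species = c("A", "B", "C"), log_body_mass = c(3, 4, 5),
                    log_brain_volume = c(1.2, 1.6, 2.1), n_sources = 1L)
  Cfull <- vcv_matrix(tr, c("A", "B", "C", "F"))
  m <- predictive_moments(Cfull, 1, c(0, 0.4), 0.02, tab$log_brain_volume,
                          cbind(1, tab$log_body_mass), c(1, 3))
  expect_equal(m$mean, 1.2, tolerance = 1e-6)
  expect_lt(abs(m$var), 1e-8)
})

test_that("predictive moments match the partitioned-Gaussian oracle", {
  inst <- make_small_instance(6, n_tips = 6)
  tab <- inst$tab
  focal <- inst$spec$focal
  Cfull <- vcv_matrix(inst$study$tree, c(tab$species, focal))
  beta <- c(-0.2, 0.5); sigma2 <- 0.04; lam <- 0.63; xf <- c(1, 3.9)
  m <- predictive_moments(Cfull, lam, beta, sigma2, tab$log_brain_volume,
                          cbind(1, tab$log_body_mass), xf)
  mu_all <- c(cbind(1, tab$log_body_mass) %*% beta, sum(xf * beta))
  Sig <- sigma2 * lambda_transform(Cfull, lam)
  o <- brute_conditional(mu_all, Sig, length(mu_all), tab$log_brain_volume)
  expect_equal(m$mean, o$mean, tolerance = 1e-10)
  expect_equal(m$var, o$var, tolerance = 1e-10)
})

test_that("singularity verdict follows the credible-interval rule", {
  draws <- rnorm(2000)
  pred <- structure(list(draws = draws, mean = draws, var = rep(1, 2000),
                         focal = "x", focal_predictor = 1, n_draws = 2000,
                         n_clipped = 0L, observed = NA_real_,
                         p_below = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, is_singularity = NA, seed = 1),
                    class = "prediction_result")
  below <- singularity_test(pred, min(draws) - 1)
  expect_equal(below$p_below, 0)
  expect_true(below$is_singularity)
  mid <- singularity_test(pred, median(draws))
  expect_lt(abs(mid$p_below - 0.5), 0.01)
  expect_false(mid$is_singularity)
  # p_below invariant to adding a constant to draws and observed alike
  shifted <- pred; shifted$draws <- draws + 5
  expect_equal(singularity_test(shifted, median(draws) + 5)$p_below,
               mid$p_below)
  short <- pred; short$draws <- draws[1:50]
  expect_error(singularity_test(short, 0), "at least 100")
})

test_that("diagnostics calibrate on white noise and flag stuck chains", {
  set.seed(8)
  good <- data.frame(iteration = 1:1000, intercept = rnorm(1000),
                     slope = rnorm(1000), sigma2 = rgamma(1000, 2),
                     lambda = runif(1000), tree_index = 1L)
  class(good) <- c("posterior_samples", "data.frame")
  rep_good <- convergence_diagnostics(good)
  expect_equal(rep_good$verdict, "pass")
  expect_gt(min(rep_good$table$ess), 500)
  expect_true(all(abs(rep_good$table$geweke_z) < 3))

  stuck <- good
  stuck$slope <- 1 + 1e-9 * (1:1000)  # near-constant, maximal autocorrelation
  class(stuck) <- c("posterior_samples", "data.frame")
  expect_equal(convergence_diagnostics(stuck)$verdict, "warn")
  expect_error(convergence_diagnostics(good[1:100, ]), ">= 200")
})

test_that("batch breed runs are deterministic and respect per-run seeds", {
  inst <- make_small_instance(9, n_tips = 10)
  breeds <- data.frame(breed = c("b1", "b2", "b1_again"),
                       body_mass_g = c(20000, 30000, 20000),
                       brain_volume_ml = c(80, 95, 80))
  cfg <- mcmc_config(n_iter = 2000, thin = 10, seed = 20)
  r1 <- batch_breed_runs(breeds, inst$tab, inst$study$tree,
                         inst$spec$focal, cfg)
  r2 <- batch_breed_runs(breeds, inst$tab, inst$study$tree,
                         inst$spec$focal, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 3)
  expect_true(all(r1$p_below >= 0 & r1$p_below <= 1))
  # identical breeds under identical seeds give identical results
  single <- breeds[1, ]
  a <- batch_breed_runs(single, inst$tab, inst$study$tree, inst$spec$focal,
                        cfg)
  b <- batch_breed_runs(single, inst$tab, inst$study$tree, inst$spec$focal,
                        cfg)
  expect_identical(a$p_below, b$p_below)
  expect_equal(attr(r1, "mean_n_below"), mean(r1$n_below))
})
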