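# Pipeline drivers orchestrating the three analyses: descriptive allometry
# with residual ranking, a single-focal singularity test, and a batch of
# per-breed runs. Each driver accepts in-memory objects or file paths and
# optionally writes its outputs (CSV/JSON, every file stamped with the seed
# and a configuration hash).

#' Descriptive allometry and residual ranking
#'
#' Aggregates trait records if needed, fits the ordinary least-squares
#' allometric line across all species, and ranks species by absolute
#' residual -- the descriptive step used to spot candidate outliers before
#' any formal test.
#'
#' @param traits A trait-record data.frame, a `species_traits` table, or a
#'   CSV path in either layout.
#' @param output_dir Optional directory for `allometry_fit.json` and
#'   `residuals.csv`.
#' @param exclude Optional species labels to drop before fitting.
#' @return List with `fit` (a `regression_fit`) and `residuals` (the ranked
#'   residual table).
#' @export
run_allometry <- function(traits, output_dir = NULL, exclude = NULL) {
  table <- as_species_table(traits)
  if (!is.null(exclude))
    table <- table[!table$species %in% normalize_labels(exclude), ,
                   drop = FALSE]
  fit <- fit_ols(table)
  rt <- residual_table(fit)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(rt, file.path(output_dir, "residuals.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(intercept = fit$intercept, slope = fit$slope, sigma2 = fit$sigma2,
           loglik = fit$loglik, n = fit$n, method = fit$method),
      file.path(output_dir, "allometry_fit.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(fit = fit, residuals = rt)
}

as_species_table <- function(traits) {
  if (is.character(traits) && length(traits) == 1L) {
    df <- read.csv(traits, stringsAsFactors = FALSE)
    if ("log_brain_volume" %in% names(df)) {
      df$species <- normalize_labels(df$species)
      class(df) <- c("species_traits", "data.frame")
      return(df)
    }
    return(aggregate_species(read_trait_csv(traits)))
  }
  if (inherits(traits, "species_traits")) return(traits)
  if (is.data.frame(traits) && "log_brain_volume" %in% names(traits)) {
    class(traits) <- c("species_traits", "data.frame")
    return(traits)
  }
  aggregate_species(traits)
}

#' Full singularity analysis for one focal taxon
#'
#' End-to-end driver: loads/validates inputs, removes the focal taxon's row
#' from the trait table if asked (otherwise errors on finding it, since
#' conditioning on the focal data would bias the test), resolves polytomies
#' into a seeded tree set, runs the MCMC, draws the posterior-predictive
#' distribution at the focal body mass, applies the credible-interval
#' verdict, and checks convergence.
#'
#' @param traits Trait input accepted by [run_allometry()]; must not contain
#'   the focal species unless `drop_focal = TRUE`.
#' @param tree A `phylo`, `multiPhylo`, or Newick file path. Polytomies are
#'   resolved automatically.
#' @param focal Focal tip label (must be in the tree).
#' @param body_mass_g,brain_volume_ml Observed focal trait values.
#' @param cfg An [mcmc_config()].
#' @param n_resolutions Number of random polytomy resolutions (ignored when
#'   a `multiPhylo` is supplied).
#' @param drop_focal Remove the focal row from the trait table instead of
#'   erroring when present.
#' @param output_dir Optional output directory (`prediction.json`,
#'   `posterior.csv`, `diagnostics.json`).
#' @return List with `prediction` (completed `prediction_result`),
#'   `samples`, `diagnostics`, and `status` (0 = ok, 3 = diagnostics
#'   warning).
#' @export
run_singularity <- function(traits, tree, focal, body_mass_g,
                            brain_volume_ml, cfg = mcmc_config(),
                            n_resolutions = 100, drop_focal = FALSE,
                            output_dir = NULL) {
  stopifnot(body_mass_g > 0, brain_volume_ml > 0)
  focal <- normalize_labels(focal)
  table <- as_species_table(traits)
  if (drop_focal) table <- table[table$species != focal, , drop = FALSE]
  trees <- as_tree_set(tree, n_resolutions, cfg$seed)
  samples <- run_mcmc(table, trees, focal, cfg)
  pred <- posterior_predict(samples, log10(body_mass_g))
  pred <- singularity_test(pred, log10(brain_volume_ml))
  diag <- if (nrow(samples) >= 200) convergence_diagnostics(samples) else
    list(table = NULL, verdict = "skipped (fewer than 200 retained samples)")
  status <- if (identical(diag$verdict, "warn")) 3L else 0L
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_posterior_csv(samples, file.path(output_dir, "posterior.csv"))
    jsonlite::write_json(
      list(focal = focal, observed = pred$observed, p_below = pred$p_below,
           ci_low = pred$ci_low, ci_high = pred$ci_high,
           is_singularity = pred$is_singularity, n_draws = pred$n_draws,
           seed = cfg$seed, config_hash = config_hash(cfg)),
      file.path(output_dir, "prediction.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(
      list(verdict = diag$verdict, table = diag$table, seed = cfg$seed,
           config_hash = config_hash(cfg)),
      file.path(output_dir, "diagnostics.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(prediction = pred, samples = samples, diagnostics = diag,
       status = status)
}

as_tree_set <- function(tree, n_resolutions, seed) {
  if (is.character(tree) && length(tree) == 1L) {
    txt <- readLines(tree, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) > 1L) {
      trees <- lapply(txt, function(s) read_newick(text = s))
      class(trees) <- "multiPhylo"
      return(trees)
    }
    tree <- read_newick(text = txt)
  }
  if (inherits(tree, "multiPhylo")) return(tree)
  validate_tree(tree)
  if (ape::is.binary(tree)) {
    out <- structure(list(tree), class = "multiPhylo")
    return(out)
  }
  resolve_polytomies(tree, n_resolutions, seed = seed)
}

#' Per-breed singularity runs
#'
#' One independent MCMC + prediction per row of the breed table (see
#' [batch_breed_runs()]), with convergence checked on the first run, plus a
#' summary of how many breeds were and were not flagged.
#'
#' @param breeds data.frame or CSV path with `breed`, `body_mass_g`,
#'   `brain_volume_ml`.
#' @param traits,tree,focal,cfg,n_resolutions As in [run_singularity()].
#' @param output_dir Optional directory (`breed_runs.csv`,
#'   `breed_summary.json`).
#' @return The `breed_runs` data.frame.
#' @export
run_breeds <- function(breeds, traits, tree, focal = "dog",
                       cfg = mcmc_config(), n_resolutions = 100,
                       output_dir = NULL) {
  if (is.character(breeds) && length(breeds) == 1L)
    breeds <- read.csv(breeds, stringsAsFactors = FALSE)
  table <- as_species_table(traits)
  trees <- as_tree_set(tree, n_resolutions, cfg$seed)
  runs <- batch_breed_runs(breeds, table, trees, focal, cfg)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(runs), file.path(output_dir, "breed_runs.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(n_breeds = nrow(runs),
           n_nonsingular = attr(runs, "n_nonsingular"),
           n_singular = nrow(runs) - attr(runs, "n_nonsingular"),
           mean_n_below = attr(runs, "mean_n_below"),
           mean_pct_below = attr(runs, "mean_pct_below"),
           flagged = runs$breed[runs$is_singularity],
           seed = cfg$seed, config_hash = config_hash(cfg)),
      file.path(output_dir, "breed_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  runs
}

# short deterministic hash of the configuration, stamped into outputs so a
# result file can be traced to the exact settings that produced it
config_hash <- function(cfg) {
  s <- paste(vapply(cfg, function(v) paste(format(v), collapse = ","),
                    character(1)), collapse = "|")
  raw <- utf8ToInt(s)
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
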