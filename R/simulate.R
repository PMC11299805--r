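# Synthetic data with the exact statistical structure the analysis assumes:
# a Yule tree, Brownian-motion predictor, linear response with
# lambda-attenuated phylogenetic residuals, an optional additive shift on a
# focal tip, and multi-source lognormal measurement replicates.

#' Specification of a synthetic study
#'
#' Defaults mirror a canid-scale analysis: 25 species, a brain-body
#' allometry with slope ~0.47 on log10 axes, a residual Brownian rate giving
#' ~0.12 log10-ml residual scatter at unit tree depth, lambda 0.41, and a
#' predictor spread covering roughly 1-45 kg body mass.
#'
#' @param n_tips Number of tips (>= 4).
#' @param birth Yule speciation rate (topology/branch shape only; the tree
#'   is rescaled to unit root-to-tip depth).
#' @param collapse_frac Fraction of internal edges collapsed into polytomies
#'   (depth-preserving), 0 for a fully bifurcating tree, 1 for a star.
#' @param intercept,slope Allometric coefficients on log10 axes.
#' @param sigma2 Residual Brownian rate of the response (log10 ml squared
#'   per unit depth).
#' @param lambda Pagel's lambda of the residuals, in `[0, 1]`.
#' @param mean_x,sigma2_x Root state and Brownian rate of the predictor
#'   (log10 g).
#' @param focal Label given to the focal tip (the first tip).
#' @param focal_shift Additive shift (log10 ml) applied to the focal tip's
#'   response; 0 simulates the null of no singularity.
#' @param n_sources Measurement replicates per species.
#' @param cv Within-species coefficient of variation of raw measurements.
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_tips = 25, birth = 1, collapse_frac = 0,
                            intercept = -0.1, slope = 0.47, sigma2 = 0.015,
                            lambda = 0.41, mean_x = 3.8, sigma2_x = 0.25,
                            focal = "focal_sp", focal_shift = 0,
                            n_sources = 3, cv = 0.1, seed = 1) {
  stopifnot(n_tips >= 4, lambda >= 0, lambda <= 1, sigma2 > 0, cv >= 0,
            collapse_frac >= 0, collapse_frac <= 1, n_sources >= 1)
  structure(list(n_tips = as.integer(n_tips), birth = birth,
                 collapse_frac = collapse_frac, intercept = intercept,
                 slope = slope, sigma2 = sigma2, lambda = lambda,
                 mean_x = mean_x, sigma2_x = sigma2_x, focal = focal,
                 focal_shift = focal_shift, n_sources = as.integer(n_sources),
                 cv = cv, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with `n_tips` tips, rescaled to unit root-to-tip depth.
#' The first tip is renamed to the spec's focal label; the rest are
#' `sp_02`, `sp_03`, ... With `collapse_frac > 0`, that fraction of internal
#' (non-root-adjacent-only) edges is collapsed depth-preservingly -- each
#' collapsed edge's length is pushed onto its child edges -- creating
#' polytomies without moving any tip in time.
#'
#' @param spec A [simulation_spec()].
#' @return A `phylo` tree of depth 1.
#' @export
simulate_tree <- function(spec) {
  set.seed(spec$seed)
  tr <- ape::rphylo(spec$n_tips, birth = spec$birth, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- c(spec$focal,
                    sprintf("sp_%02d", seq_len(spec$n_tips)[-1]))
  if (spec$collapse_frac > 0) tr <- collapse_edges(tr, spec$collapse_frac)
  validate_tree(tr)
  tr
}

# collapse a fraction of internal edges while preserving all root-to-tip
# distances: chosen edges get length 0 (their length is added to the edges
# of their child node), then zero-length edges are deleted
collapse_edges <- function(tree, frac) {
  internal <- which(tree$edge[, 2] > length(tree$tip.label))
  if (!length(internal)) return(tree)
  k <- if (frac >= 1) length(internal) else
    floor(frac * length(internal))
  if (k == 0) return(tree)
  chosen <- if (k == length(internal)) internal else
    sample(internal, k)
  # process parents before children so pushed-down lengths accumulate
  ord <- chosen[order(node_depths(tree)[tree$edge[chosen, 2]])]
  for (e in ord) {
    node <- tree$edge[e, 2]
    kids <- which(tree$edge[, 1] == node)
    tree$edge.length[kids] <- tree$edge.length[kids] + tree$edge.length[e]
    tree$edge.length[e] <- 0
  }
  ape::di2multi(tree, tol = 1e-12)
}

# number of edges between each node and the root
node_depths <- function(tree) {
  n_nodes <- max(tree$edge)
  d <- rep(0L, n_nodes)
  # edges in tree$edge are not sorted root-down in general; iterate to fixpoint
  for (pass in seq_len(n_nodes)) {
    d_new <- d
    d_new[tree$edge[, 2]] <- d[tree$edge[, 1]] + 1L
    if (identical(d_new, d)) break
    d <- d_new
  }
  d
}

#' Simulate species trait values on a tree
#'
#' The predictor (log10 body mass, g) evolves by Brownian motion from the
#' root state; the response (log10 brain volume, ml) is
#' `intercept + slope * predictor` plus a residual drawn from
#' `MVN(0, sigma2 * V(lambda))`. The focal shift, if any, is added to the
#' focal tip's response after the residual.
#'
#' @param tree A `phylo` (typically from [simulate_tree()]).
#' @param spec A [simulation_spec()].
#' @param seed Seed; defaults to `spec$seed + 1`.
#' @return A list with `table` (a `species_traits` data.frame including the
#'   focal row) and `truth` (the generating parameters plus the focal tip's
#'   shift-free expected value).
#' @export
simulate_traits <- function(tree, spec, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  tips <- tree$tip.label
  n <- length(tips)
  C <- vcv_matrix(tree, tips)
  x <- spec$mean_x + mvn_draw(spec$sigma2_x * C)
  V <- spec$sigma2 * lambda_transform(C, spec$lambda)
  eps <- mvn_draw(V)
  y <- spec$intercept + spec$slope * x + eps
  fi <- match(spec$focal, tips)
  if (!is.na(fi)) y[fi] <- y[fi] + spec$focal_shift
  table <- data.frame(species = tips, log_body_mass = x,
                      log_brain_volume = y,
                      n_sources = 1L, stringsAsFactors = FALSE)
  class(table) <- c("species_traits", "data.frame")
  truth <- list(intercept = spec$intercept, slope = spec$slope,
                sigma2 = spec$sigma2, lambda = spec$lambda,
                focal = spec$focal, focal_shift = spec$focal_shift,
                x_focal = if (is.na(fi)) NA_real_ else x[fi],
                y_focal = if (is.na(fi)) NA_real_ else y[fi])
  list(table = table, truth = truth)
}

# one draw from MVN(0, Sigma) via eigendecomposition (tolerates the PSD
# matrices zero-length cherries create, where Cholesky would fail)
mvn_draw <- function(Sigma) {
  eig <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  drop(eig$vectors %*% (sqrt(vals) * rnorm(length(vals))))
}

#' Simulate multi-source measurement records
#'
#' Expands a species table into per-source records: `n_sources` lognormal
#' replicates per species around the species' raw-scale value with the
#' spec's coefficient of variation, for both body mass and brain volume.
#' This is the ground-truth structure the repeatability estimator assumes
#' (among-species signal plus within-species measurement noise).
#'
#' @param table A `species_traits` data.frame.
#' @param spec A [simulation_spec()].
#' @param seed Seed; defaults to `spec$seed + 2`.
#' @return A trait record data.frame (`species`, `source`, `body_mass_g`,
#'   `brain_mass_g`, `brain_volume_ml`).
#' @export
simulate_measurements <- function(table, spec, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed + 2L
  set.seed(seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  rows <- lapply(seq_len(nrow(table)), function(i) {
    k <- spec$n_sources
    data.frame(species = table$species[i], source = sprintf("src_%02d",
                                                            seq_len(k)),
               body_mass_g = 10^table$log_body_mass[i] *
                 exp(rnorm(k, -sdlog^2 / 2, sdlog)),
               brain_mass_g = NA_real_,
               brain_volume_ml = 10^table$log_brain_volume[i] *
                 exp(rnorm(k, -sdlog^2 / 2, sdlog)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: tree, species traits and measurement records from
#' one spec, all seeded from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `tree`, `table`, `truth`, `records`.
#' @export
simulate_study <- function(spec = simulation_spec()) {
  tree <- simulate_tree(spec)
  tt <- simulate_traits(tree, spec)
  records <- simulate_measurements(tt$table, spec)
  list(tree = tree, table = tt$table, truth = tt$truth, records = records)
}

#' Write a toy study directory
#'
#' Emits the same CSV and Newick dialects the loaders consume: `records.csv`
#' (per-source measurements), `species.csv` (aggregated table), `tree.nwk`
#' (the generating tree), `trees.nwk` (randomly resolved set when the tree
#' has polytomies) and `truth.json` (generating parameters). All files are
#' plain text and labelled synthetic in `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [simulation_spec()].
#' @param n_resolutions Size of the resolved tree set to write.
#' @return Invisibly, the directory path.
#' @export
make_fixtures <- function(dir, spec = simulation_spec(),
                          n_resolutions = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(spec)
  write.csv(study$records, file.path(dir, "records.csv"), row.names = FALSE)
  write_species_csv(study$table, file.path(dir, "species.csv"))
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  if (!ape::is.binary(study$tree))
    write_newick(resolve_polytomies(study$tree, n_resolutions,
                                    seed = spec$seed),
                 file.path(dir, "trees.nwk"))
  jsonlite::write_json(c(list(synthetic = TRUE), study$truth,
                         unclass(spec)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
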