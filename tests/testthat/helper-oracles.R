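# Independent oracles and small fixtures used across the test files. These
# deliberately avoid the package's own linear-algebra paths: the VCV oracle
# walks root-to-tip paths explicitly, the density oracle evaluates the full
# multivariate normal via solve()/determinant(), and the conditional oracle
# partitions the joint covariance directly.

# shared path length of every tip pair by explicit root-path enumeration
brute_vcv <- function(tree, tip_order = tree$tip.label) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # edges on the path from the root to each node
  parent_edge <- function(node) which(tree$edge[, 2] == node)
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge(node)
      edges <- c(e, edges)
      node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(ntip), path_edges)
  n <- length(tip_order)
  idx <- match(tip_order, tree$tip.label)
  C <- matrix(0, n, n, dimnames = list(tip_order, tip_order))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[idx[i]]], paths[[idx[j]]])
    C[i, j] <- sum(tree$edge.length[shared])
  }
  C
}

# log density of MVN(mu, Sigma) at y, via base solve()/determinant()
brute_mvn_logdens <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  q <- drop(crossprod(r, solve(Sigma, r)))
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + q)
}

# conditional mean/variance of component `f` of MVN(mu, Sigma) given the
# rest, by direct partitioning of the joint covariance
brute_conditional <- function(mu, Sigma, f, y_obs) {
  o <- setdiff(seq_along(mu), f)
  Soo <- Sigma[o, o, drop = FALSE]
  Sfo <- Sigma[f, o, drop = FALSE]
  w <- solve(Soo, y_obs - mu[o])
  list(mean = unname(mu[f] + drop(Sfo %*% w)),
       var = unname(drop(Sigma[f, f] - Sfo %*% solve(Soo, t(Sfo)))))
}

# which of three tips attaches basally in a resolved rooted triple: the
# cherry pair's MRCA is strictly deeper than the triple's MRCA
triplet_outgroup <- function(tree, tips) {
  m <- ape::mrca(tree)
  nodes <- c(m[tips[1], tips[2]], m[tips[1], tips[3]], m[tips[2], tips[3]])
  excluded <- c(tips[3], tips[2], tips[1])
  counts <- table(nodes)
  cherry <- which(nodes == as.integer(names(counts)[counts == 1]))
  excluded[cherry]
}

# a small ultrametric reference tree used across files
toy_tree <- function() read_newick("(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,E:3);")

# species table lying on a given line over a tree's tips
table_on_line <- function(tree, intercept = 1, slope = 0.5,
                          x = seq_along(tree$tip.label)) {
  out <- data.frame(species = tree$tip.label, log_body_mass = x,
                    log_brain_volume = intercept + slope * x,
                    n_sources = 1L, stringsAsFactors = FALSE)
  class(out) <- c("species_traits", "data.frame")
  out
}

# quick null-model replicate at reduced MCMC length; returns completed
# prediction (and samples) for the focal tip of a fresh synthetic study
null_replicate <- function(rep_seed, focal_shift = 0, observed = NULL,
                           n_iter = 20000, thin = 10, n_tips = 25) {
  spec <- simulation_spec(n_tips = n_tips, focal_shift = focal_shift,
                          seed = rep_seed)
  study <- simulate_study(spec)
  tab <- study$table[study$table$species != spec$focal, ]
  s <- run_mcmc(tab, study$tree, spec$focal,
                mcmc_config(n_iter = n_iter, thin = thin, seed = rep_seed))
  pred <- posterior_predict(s, study$truth$x_focal)
  if (is.null(observed)) observed <- study$truth$y_focal
  list(pred = singularity_test(pred, observed), samples = s, study = study,
       spec = spec)
}
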