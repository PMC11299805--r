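#' Read a rooted phylogeny from Newick text or file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream analyses rely on: a single root, unique tip labels, and
#' non-negative branch lengths. Polytomies are preserved. Tip labels are
#' normalised at load time by replacing spaces with underscores, so that
#' trait tables and trees written with either convention match.
#'
#' @param text A Newick string (terminated by `;`). Ignored when `file` is
#'   given.
#' @param file Path to a Newick file.
#' @return An object of class `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("supply either `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse failure: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse failure: unreadable tree string")
  tr$tip.label <- normalize_labels(tr$tip.label)
  validate_tree(tr)
  tr
}

# cheap structural scan so malformed input fails with a position, not an
# opaque parser error
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick format error: unmatched ')' at position %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "Newick format error: %d unclosed '(' (string ends at position %d)",
      depth, length(chars)), call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop(sprintf("Newick format error: missing ';' terminator at position %d",
                 nchar(text)), call. = FALSE)
  invisible(TRUE)
}

normalize_labels <- function(x) gsub(" ", "_", trimws(x))

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  if (anyDuplicated(tree$tip.label))
    stop("validation error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("validation error: tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("validation error: negative branch lengths present")
  # exactly one root: one node that never appears as a child
  kids <- tree$edge[, 2]
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, kids)
  if (length(roots) != 1L)
    stop("validation error: tree must have exactly one root")
  invisible(tree)
}

#' Write trees as Newick
#'
#' Branch lengths are always written, with 6 significant digits. A set of
#' trees is written one per line.
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param file Output path; when `NULL` the Newick string(s) are returned.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Graft a new tip next to an existing one
#'
#' Inserts a new tip whose stem attaches `attach_depth` time units below the
#' tip of `sister`, along the sister's terminal branch. All pairwise shared
#' path lengths among pre-existing tips are unchanged. This is how focal taxa
#' missing from a source phylogeny (e.g. the domesticated dog next to the
#' grey wolf, or an extinct relative) are added before analysis.
#'
#' @param tree A `phylo` object.
#' @param new_tip Label for the new tip.
#' @param sister Label of the existing tip to attach next to.
#' @param attach_depth Distance below the sister tip at which the new stem
#'   branches off; must not exceed the sister's terminal branch length.
#'   Default: 1\% of the sister's terminal branch.
#' @param stem_length Terminal branch length of the new tip. Default:
#'   `attach_depth`, which keeps the new tip contemporaneous with its sister
#'   on an ultrametric tree.
#' @return A `phylo` with one extra tip.
#' @examples
#' tr <- read_newick("((wolf:1,coyote:1):1,jackal:2);")
#' tr2 <- graft_tip(tr, "dog", "wolf", attach_depth = 0.01)
#' @export
graft_tip <- function(tree, new_tip, sister, attach_depth = NULL,
                      stem_length = NULL) {
  validate_tree(tree)
  new_tip <- normalize_labels(new_tip)
  sister <- normalize_labels(sister)
  if (new_tip %in% tree$tip.label)
    stop("validation error: tip '", new_tip, "' already present")
  idx <- match(sister, tree$tip.label)
  if (is.na(idx))
    stop("validation error: unknown sister label '", sister, "'")
  sister_edge <- which(tree$edge[, 2] == idx)
  sister_bl <- tree$edge.length[sister_edge]
  if (is.null(attach_depth)) attach_depth <- 0.01 * sister_bl
  if (attach_depth < 0 || attach_depth > sister_bl)
    stop("validation error: attach_depth (", attach_depth,
         ") exceeds sister terminal branch length (", sister_bl, ")")
  if (is.null(stem_length)) stem_length <- attach_depth
  if (stem_length < 0) stop("validation error: negative stem_length")
  out <- phytools::bind.tip(tree, tip.label = new_tip,
                            edge.length = stem_length,
                            where = idx, position = attach_depth)
  validate_tree(out)
  out
}

#' Randomly resolve polytomies into a set of bifurcating trees
#'
#' Each multifurcating node is resolved independently by sequential random
#' pairing: two of its children are drawn at random and joined under a new
#' internal node with a zero-length branch, repeatedly, until the node is
#' binary. Zero-length internal branches leave every root-to-tip distance --
#' and hence the Brownian-motion trait covariances -- unchanged; only the
#' (arbitrary) branching order at the polytomy differs across resolutions.
#' For a trifurcation the three rooted resolutions are drawn uniformly.
#'
#' @param tree A rooted `phylo`, possibly multifurcating.
#' @param n_trees Number of independent resolutions to draw.
#' @param seed Integer seed; the returned set is reproducible byte-for-byte.
#' @return A `multiPhylo` of length `n_trees` with attribute `seed`.
#' @export
resolve_polytomies <- function(tree, n_trees = 100, seed = 1) {
  validate_tree(tree)
  stopifnot(n_trees >= 1)
  set.seed(seed)
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) out[[i]] <- resolve_one(tree)
  class(out) <- "multiPhylo"
  attr(out, "seed") <- seed
  out
}

# resolve all polytomies of one tree by random sequential pairing, working on
# a recursive node representation and re-reading the emitted Newick
resolve_one <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  emit <- function(node, bl) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
    } else {
      kid_edges <- children[[as.character(node)]]
      parts <- vapply(kid_edges, function(e)
        emit(tree$edge[e, 2], tree$edge.length[e]), character(1))
      # sequential random pairing; new internal branches have length 0
      while (length(parts) > 2L) {
        pick <- sample.int(length(parts), 2L)
        merged <- sprintf("(%s,%s):0", parts[pick[1]], parts[pick[2]])
        parts <- c(parts[-pick], merged)
      }
      lab <- sprintf("(%s)", paste(parts, collapse = ","))
    }
    if (is.na(bl)) lab else sprintf("%s:%.17g", lab, bl)
  }
  txt <- paste0(emit(root, NA_real_), ";")
  out <- ape::read.tree(text = txt)
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion, the covariance between two tips is the path length
#' from the root to their most recent common ancestor, and a tip's variance
#' is its root-to-tip distance.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_order Optional character vector giving the row/column ordering;
#'   must be a permutation of (a subset of) the tip labels.
#' @return A symmetric positive semi-definite matrix with dimnames.
#' @export
vcv_matrix <- function(tree, tip_order = NULL) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(tip_order)) {
    tip_order <- normalize_labels(tip_order)
    missing <- setdiff(tip_order, rownames(C))
    if (length(missing))
      stop("validation error: unknown label(s) in tip_order: ",
           paste(missing, collapse = ", "))
    C <- C[tip_order, tip_order, drop = FALSE]
  }
  C
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies all off-diagonal entries by `lam`, leaving the diagonal
#' unchanged. `lam = 1` is pure Brownian motion; `lam = 0` removes all
#' phylogenetic covariance (a star phylogeny).
#'
#' @param C A phylogenetic variance-covariance matrix.
#' @param lam Scalar in `[0, 1]`.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1)
    stop("validation error: lambda must be a single value in [0, 1]")
  V <- C * lam
  diag(V) <- diag(C)
  V
}
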