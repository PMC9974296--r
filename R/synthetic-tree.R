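#' Simulate a clock-scaled Yule tree with Brownian-motion traits
#'
#' Generates a pure-birth (Yule) tree of `nTips` extant taxa, rescales it so
#' the root-to-tip depth equals `totalDepth` million years, and evolves
#' `nAxes` independent traits along it under Brownian motion with per-axis
#' rate `sigma2True` (variance accrued per My of branch length). The root
#' state is 0 on every axis. Used as the parameter-recovery fixture for the
#' contrast-based rate estimators: the estimated multivariate rate should
#' recover `nAxes * sigma2True`.
#'
#' @param nTips number of tips (>= 2).
#' @param totalDepth tree height in My.
#' @param sigma2True per-axis Brownian rate, trait variance per My (>= 0).
#' @param nAxes number of independent trait axes (default 3, matching
#'   3-D colour-space coordinates).
#' @param seed integer RNG seed; identical seeds give an identical Newick
#'   string and trait table.
#' @return list with `tree` (an [ape::phylo] object, ultrametric, binary) and
#'   `traits` (matrix tips x axes with tip labels as rownames).
#' @examples
#' x <- genTreeTraits(10, totalDepth = 5, sigma2True = 0.01, seed = 1)
#' ape::is.ultrametric(x$tree)
#' @export
genTreeTraits <- function(nTips, totalDepth = 10, sigma2True = 0.01,
                          nAxes = 3, seed = 1) {
  if (nTips < 2) stop("nTips must be >= 2")
  if (sigma2True < 0) stop("sigma2True must be >= 0")
  .withSeed(seed, {
    tree <- ape::rphylo(nTips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * (totalDepth / depth)
    tree <- ape::reorder.phylo(tree, "cladewise")   # parents precede children
    nNode <- nTips + tree$Nnode
    vals <- matrix(0, nNode, nAxes)                 # root state 0
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]; chi <- tree$edge[i, 2]
      bl <- tree$edge.length[i]
      vals[chi, ] <- vals[par, ] + rnorm(nAxes, 0, sqrt(sigma2True * bl))
    }
    traits <- vals[seq_len(nTips), , drop = FALSE]
    rownames(traits) <- tree$tip.label
    colnames(traits) <- paste0("axis", seq_len(nAxes))
    list(tree = tree, traits = traits)
  })
}

#' Write tip traits to CSV (`tip,axis1,axis2,...`)
#' @param traits matrix with tip labels as rownames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTipTraits <- function(traits, path) {
  df <- data.frame(tip = rownames(traits), traits, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read tip traits written by [writeTipTraits()]
#' @param path CSV path with a `tip` column.
#' @return numeric matrix with tips as rownames.
#' @export
readTipTraits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "tip"), drop = FALSE])
  rownames(m) <- df$tip
  m
}
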