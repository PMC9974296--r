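## Brownian rates of colour evolution from phylogenetic independent
## contrasts, multivariate phylogenetic signal, and divergence-time
## arithmetic.

.checkTree <- function(tree, traits) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("tree must be rooted and bifurcating; polytomies are not supported")
  if (is.null(dim(traits))) traits <- cbind(traits)
  if (is.null(rownames(traits)))
    stop("traits must have tip labels as rownames")
  miss <- setdiff(tree$tip.label, rownames(traits))
  if (length(miss))
    stop("missing trait values for tip(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(traits))) stop("traits must be finite (complete cases)")
  traits[tree$tip.label, , drop = FALSE]
}

#' Scaled phylogenetic independent contrasts
#'
#' Felsenstein's pruning contrasts for one trait: at each internal node the
#' difference between daughter values divided by the square root of the sum
#' of the (ancestrally inflated) daughter branch lengths. Standard-Brownian
#' contrasts are iid Normal(0, sigma^2). Delegates to [ape::pic()];
#' polytomies are rejected rather than silently resolved, since zero-length
#' resolution changes the contrast count.
#'
#' @param tree a rooted, binary [ape::phylo] with branch lengths (My).
#' @param x named numeric vector of tip values (or 1-column matrix).
#' @return numeric vector of standardized contrasts, one per internal node.
#' @export
picContrasts <- function(tree, x) {
  if (!is.null(dim(x))) x <- setNames(x[, 1], rownames(x))
  xm <- .checkTree(tree, cbind(x))
  ape::pic(setNames(xm[, 1], rownames(xm)), tree, scaled = TRUE)
}

#' Multivariate Brownian rate of trait evolution
#'
#' Estimates the rate of multivariate trait evolution from independent
#' contrasts: per internal node, the squared contrast length is the sum over
#' trait axes of the squared standardized contrast; the rate sigma^2 is the
#' mean of these squared lengths across the n - 1 internal nodes, in units
#' of squared trait distance (e.g. JND^2) per unit branch length (My). With
#' axes evolving independently at per-axis rate s, the estimator's
#' expectation is (number of axes) x s; `perAxis = TRUE` divides by the
#' number of axes instead.
#'
#' @param tree a rooted, binary [ape::phylo].
#' @param traits matrix tips x axes with tip labels as rownames (typically
#'   3-D noise-scaled colour coordinates).
#' @param perAxis if TRUE, report the mean across axes rather than the sum.
#' @return A [RateEstimate-class].
#' @export
multivariateRate <- function(tree, traits, perAxis = FALSE) {
  traits <- .checkTree(tree, traits)
  contr <- matrix(NA_real_, tree$Nnode, ncol(traits))
  for (j in seq_len(ncol(traits)))
    contr[, j] <- as.numeric(
      ape::pic(setNames(traits[, j], rownames(traits)), tree, scaled = TRUE))
  nodeSq <- rowSums(contr^2)
  if (perAxis) nodeSq <- nodeSq / ncol(traits)
  new("RateEstimate", sigma2 = mean(nodeSq), nodeSq = nodeSq,
      nNodes = as.integer(tree$Nnode))
}

#' Multivariate Blomberg's K with a tip-permutation test
#'
#' Phylogenetic signal for multivariate data: the ratio of the observed mean
#' squared Euclidean deviation from the phylogenetic mean to its
#' phylogenetically corrected counterpart (using the inverse of the tree's
#' expected trait covariance C), divided by the Brownian-motion expectation
#' (tr(C) - n / sum(C^-1)) / (n - 1). K is 1 in expectation under Brownian
#' motion, below 1 when close relatives resemble each other less than the
#' tree predicts. The p-value is the add-one proportion of tip-permuted K
#' values at least as large as the observed one.
#'
#' @param tree a rooted, binary [ape::phylo].
#' @param traits matrix tips x axes, tip labels as rownames.
#' @param nPerm number of tip permutations (>= 99 for a meaningful test; 0
#'   returns the statistic alone with p = NA).
#' @param seed integer RNG seed for the permutations.
#' @return A [SignalResult-class].
#' @export
blombergK <- function(tree, traits, nPerm = 999, seed = 1) {
  traits <- .checkTree(tree, traits)
  if (nPerm != 0 && nPerm < 99) stop("use nPerm >= 99 (or 0 for no test)")
  if (all(apply(cbind(traits), 2, var) == 0))
    stop("K undefined: traits are identical across tips")
  C <- ape::vcv(tree)
  C <- C[rownames(traits), rownames(traits)]
  n <- nrow(traits)
  invC <- solve(C)
  ones <- rep(1, n)
  denomExp <- (sum(diag(C)) - n / sum(invC)) / (n - 1)
  Kstat <- function(X) {
    a <- drop(ones %*% invC %*% X) / sum(invC)   # phylogenetic mean per axis
    D <- sweep(X, 2, a)
    mse0 <- sum(D^2) / (n - 1)
    mse <- sum(vapply(seq_len(ncol(X)),
                      function(j) drop(t(D[, j]) %*% invC %*% D[, j]),
                      numeric(1))) / (n - 1)
    (mse0 / mse) / denomExp
  }
  Kobs <- Kstat(cbind(traits))
  if (nPerm == 0)
    return(new("SignalResult", K = Kobs, p = NA_real_, nPerm = 0L,
               seed = as.integer(seed)))
  perm <- .withSeed(seed, vapply(seq_len(nPerm), function(b) {
    Kstat(cbind(traits)[sample.int(n), , drop = FALSE])
  }, numeric(1)))
  p <- (1 + sum(perm >= Kobs)) / (nPerm + 1)
  new("SignalResult", K = Kobs, p = p, nPerm = as.integer(nPerm),
      seed = as.integer(seed))
}

#' Time to evolve an observed colour distance under Brownian motion
#'
#' Under a Brownian rate sigma^2 (squared JND per My), the expected squared
#' displacement after T My is sigma^2 T, so the waiting time to accrue an
#' observed distance dS is T = dS^2 / sigma^2.
#'
#' @param dS observed colour distance, JND (>= 0).
#' @param sigma2 multivariate Brownian rate, JND^2 per My (> 0).
#' @return time in My.
#' @examples
#' divergenceTime(0.207, 0.0043)   # about 10 My
#' @export
divergenceTime <- function(dS, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (dS < 0) stop("dS must be >= 0")
  dS^2 / sigma2
}
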