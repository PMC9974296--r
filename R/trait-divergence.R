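## Transgression metrics: where does a hybrid sit relative to the line
## joining its parents, trait pair by trait pair?

#' Summarise raw nanostructure measurements per TEM image
#'
#' Collapses raw within-image measurements to per-image trait means. Air
#' space diameter is taken as the mean of the parallel and perpendicular
#' measurements (`air = (air_par + air_perp) / 2`), on the assumption that
#' air spaces are isometric in cross-section and perpendicular deformation
#' from sectioning should be averaged out. A cross-image summary (mean and
#' 95% t-interval per trait) is attached; with a single image the interval
#' is undefined and flagged `NA` with a warning.
#'
#' @param measurements data.frame of raw measurements with an `image` column
#'   and numeric trait columns including `air_par` and `air_perp`.
#' @return list with `perImage` (one row per image; `air_par`/`air_perp`
#'   replaced by `air`) and `summary` (per-trait `mean`, `ci_lo`, `ci_hi`).
#' @export
summarizeNanostructure <- function(measurements) {
  need <- c("image", "air_par", "air_perp")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  measurements$air <- (measurements$air_par + measurements$air_perp) / 2
  traits <- setdiff(names(measurements),
                    c("image", "air_par", "air_perp"))
  perImage <- aggregate(measurements[traits],
                        by = list(image = measurements$image), FUN = mean)
  summ <- do.call(rbind, lapply(traits, function(tr) {
    v <- perImage[[tr]]
    n <- length(v)
    if (n < 2L) {
      warning("single image: confidence interval undefined for '", tr, "'")
      data.frame(trait = tr, mean = mean(v), ci_lo = NA_real_,
                 ci_hi = NA_real_)
    } else {
      half <- qt(0.975, n - 1L) * sd(v) / sqrt(n)
      data.frame(trait = tr, mean = mean(v), ci_lo = mean(v) - half,
                 ci_hi = mean(v) + half)
    }
  }))
  rownames(summ) <- NULL
  list(perImage = perImage, summary = summ)
}

#' Principal component analysis with a deterministic sign convention
#'
#' Thin wrapper over the eigendecomposition of the (optionally scaled)
#' covariance matrix, with each component's sign fixed so that its
#' largest-magnitude loading is positive — making scores reproducible
#' bit-for-bit across platforms.
#'
#' @param x numeric matrix or data.frame (rows = observations).
#' @param center,scale. passed to [stats::prcomp()].
#' @return list with `scores`, `loadings` (columns orthonormal) and
#'   `varExplained` (fractions summing to 1).
#' @export
traitPCA <- function(x, center = TRUE, scale. = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 rows and >= 2 columns")
  if (all(apply(x, 2, var) == 0)) stop("rank-0 input: all columns constant")
  if (scale. && any(apply(x, 2, var) == 0))
    stop("cannot scale constant columns")
  p <- prcomp(x, center = center, scale. = scale.)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  list(scores = sweep(p$x, 2, flip, `*`),
       loadings = sweep(p$rotation, 2, flip, `*`),
       varExplained = p$sdev^2 / sum(p$sdev^2))
}

#' Parent-bias and mismatch distances of a hybrid phenotype
#'
#' With parental centroids P1, P2 and hybrid point H in a trait plane, let
#' v = P2 - P1, M = (P1 + P2)/2 and w = H - M. The parent-bias distance is
#' the along-transect displacement normalised by half the parental
#' separation, `|w . v_hat| / (|v|/2)` — 0 for a perfectly intermediate
#' hybrid and 1 for a hybrid sitting exactly on one parent. The mismatch
#' distance is the orthogonal displacement normalised by the full
#' separation, `|w - (w . v_hat) v_hat| / |v|` — 0 on the parental transect,
#' 1 at one full parental distance off it (> 1 = farther from the transect
#' than the parents are from each other). Both metrics are invariant under
#' rotation, reflection and uniform scaling of the plane.
#'
#' @param p1,p2 parental centroids (numeric vectors of equal length >= 2).
#' @param h hybrid point.
#' @return A [DivergenceResult-class] with a single-pair breakdown.
#' @examples
#' parentBiasMismatch(c(0, 0), c(2, 0), c(1, 0))   # (0, 0): intermediate
#' parentBiasMismatch(c(0, 0), c(2, 0), c(0, 0))   # (1, 0): on a parent
#' @export
parentBiasMismatch <- function(p1, p2, h) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); h <- as.numeric(h)
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("coincident parental centroids")
  vhat <- v / nv
  w <- h - (p1 + p2) / 2
  along <- sum(w * vhat)
  perp <- w - along * vhat
  new("DivergenceResult",
      parentBias = abs(along) / (nv / 2),
      mismatch = sqrt(sum(perp^2)) / nv,
      pairs = data.frame(pair = "single",
                         parentBias = abs(along) / (nv / 2),
                         mismatch = sqrt(sum(perp^2)) / nv))
}

#' Average pairwise transgression across all trait pairs
#'
#' For every unordered pair of trait columns, computes group centroids
#' (arithmetic means of the parent1, parent2 and hybrid rows) in that 2-D
#' plane and evaluates [parentBiasMismatch()]; the reported metrics are the
#' means across pairs, with the per-pair breakdown retained.
#'
#' @param traits data.frame or matrix of numeric trait columns.
#' @param group character vector per row: `parent1`, `parent2` or `hybrid`
#'   (or a column name of `traits` holding those labels).
#' @return A [DivergenceResult-class].
#' @export
averagePairwiseDivergence <- function(traits, group = "group") {
  if (length(group) == 1L && is.character(group) &&
      group %in% colnames(traits)) {
    g <- traits[[group]]
    traits <- traits[, setdiff(colnames(traits), group), drop = FALSE]
  } else g <- group
  traits <- as.matrix(traits)
  if (!all(c("parent1", "parent2", "hybrid") %in% g))
    stop("need rows labelled parent1, parent2 and hybrid")
  if (ncol(traits) < 2L) stop("need >= 2 trait columns")
  cent <- function(lab) colMeans(traits[g == lab, , drop = FALSE])
  c1 <- cent("parent1"); c2 <- cent("parent2"); ch <- cent("hybrid")
  prs <- utils::combn(colnames(traits), 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    d <- parentBiasMismatch(c1[pr], c2[pr], ch[pr])
    data.frame(pair = paste(pr, collapse = ":"),
               parentBias = d@parentBias, mismatch = d@mismatch)
  })
  pairs <- do.call(rbind, rows)
  new("DivergenceResult", parentBias = mean(pairs$parentBias),
      mismatch = mean(pairs$mismatch), pairs = pairs)
}
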