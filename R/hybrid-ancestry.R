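## Hybrid ancestry from diagnostic SNPs: filter genotype calls on coverage
## and quality, keep loci fixed for alternative alleles in the two parental
## panels, then estimate the hybrid index and interspecific heterozygosity
## of each focal individual.

.gtToDosage <- function(gt) {
  # "0/0", "0|1", "./." etc. -> ALT dosage 0/1/2/NA; anything else NA.
  out <- rep(NA_integer_, length(gt))
  g <- gsub("\\|", "/", gt)
  out[g %in% c("0/0")] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g %in% c("1/1")] <- 2L
  out
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses a VCF 4.x file via the vcfR package, drops multiallelic records
#' (with a message stating how many), and returns a [GenotypeMatrix-class]
#' of ALT-allele dosages with read depth (DP) and genotype quality (GQ)
#' matrices when those FORMAT fields are present. Missing calls are kept as
#' NA.
#'
#' @param path VCF path (plain or gzipped).
#' @param popMap data.frame with columns `sample` and `population`
#'   (`parent1`, `parent2` or `focal`); every VCF sample must appear.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, popMap) {
  stopifnot(all(c("sample", "population") %in% names(popMap)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) dropped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(.gtToDosage(gt), nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  fmtHas <- function(tag) any(grepl(tag, v@gt[, "FORMAT"]))
  getNum <- function(tag) {
    m <- vcfR::extract.gt(v, element = tag, as.numeric = TRUE)
    matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  }
  dp <- if (fmtHas("DP")) getNum("DP") else matrix(numeric(0), 0, 0)
  gq <- if (fmtHas("GQ")) getNum("GQ") else matrix(numeric(0), 0, 0)
  samples <- colnames(geno)
  idx <- match(samples, popMap$sample)
  if (any(is.na(idx)))
    stop("sample(s) missing from population map: ",
         paste(samples[is.na(idx)], collapse = ", "))
  loci <- vcfR::getID(v)
  if (all(is.na(loci)))
    loci <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  new("GenotypeMatrix", geno = geno, dp = dp, gq = gq,
      pop = popMap$population[idx], loci = loci, polarized = FALSE)
}

#' Filter genotype calls on coverage and quality
#'
#' A call passes only with read depth strictly greater than `depthGt` and
#' genotype quality strictly greater than `qualGt` (defaults: depth > 5,
#' Q > 20; boundary values fail). A locus is dropped entirely when any
#' parental call fails (parental fixity cannot be assessed on unreliable
#' calls); failing focal calls are set to missing. Filters for which the
#' matrix carries no metadata (e.g. a VCF without DP) are skipped.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param depthGt depth threshold; calls must exceed it (default 5).
#' @param qualGt quality threshold; calls must exceed it (default 20).
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterSNPs <- function(gm, depthGt = 5, qualGt = 20) {
  stopifnot(is(gm, "GenotypeMatrix"))
  fails <- matrix(FALSE, nrow(gm@geno), ncol(gm@geno))
  if (nrow(gm@dp) > 0) fails <- fails | is.na(gm@dp) | gm@dp <= depthGt
  if (nrow(gm@gq) > 0) fails <- fails | is.na(gm@gq) | gm@gq <= qualGt
  parental <- gm@pop %in% c("parent1", "parent2")
  dropLocus <- rowSums(fails[, parental, drop = FALSE]) > 0
  geno <- gm@geno
  geno[fails] <- NA_integer_       # focal failures -> missing
  keep <- !dropLocus
  new("GenotypeMatrix", geno = geno[keep, , drop = FALSE],
      dp = if (nrow(gm@dp)) gm@dp[keep, , drop = FALSE] else gm@dp,
      gq = if (nrow(gm@gq)) gm@gq[keep, , drop = FALSE] else gm@gq,
      pop = gm@pop, loci = gm@loci[keep], polarized = gm@polarized)
}

#' Ancestry-diagnostic loci: fixed differences between the parental panels
#'
#' Keeps loci at which every non-missing parent1 call is homozygous for one
#' allele, every non-missing parent2 call is homozygous for the other, the
#' two alleles differ, and each parental panel has at least
#' `minParentalCalls` non-missing calls. The returned matrix is polarized:
#' dosage counts parent2-derived alleles, so a parent1 homozygote is 0 and a
#' parent2 homozygote is 2 regardless of which allele was REF.
#'
#' @param gm a [GenotypeMatrix-class] with both parental panels present.
#' @param minParentalCalls minimum non-missing calls per parental panel.
#' @return the polarized diagnostic-locus [GenotypeMatrix-class].
#' @export
diagnosticLoci <- function(gm, minParentalCalls = 1) {
  stopifnot(is(gm, "GenotypeMatrix"))
  p1 <- gm@geno[, gm@pop == "parent1", drop = FALSE]
  p2 <- gm@geno[, gm@pop == "parent2", drop = FALSE]
  if (ncol(p1) == 0 || ncol(p2) == 0) stop("empty parental group")
  fixedAllele <- function(m) {
    # per locus: the single homozygous dosage (0 or 2) if fixed, else NA
    apply(m, 1, function(g) {
      g <- g[!is.na(g)]
      if (length(g) < minParentalCalls) return(NA_integer_)
      u <- unique(g)
      if (length(u) == 1L && u %in% c(0L, 2L)) u else NA_integer_
    })
  }
  a1 <- fixedAllele(p1); a2 <- fixedAllele(p2)
  keep <- !is.na(a1) & !is.na(a2) & a1 != a2
  geno <- gm@geno[keep, , drop = FALSE]
  flip <- a1[keep] == 2L            # parent1 carries ALT: flip polarity
  geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
  new("GenotypeMatrix", geno = geno,
      dp = if (nrow(gm@dp)) gm@dp[keep, , drop = FALSE] else gm@dp,
      gq = if (nrow(gm@gq)) gm@gq[keep, , drop = FALSE] else gm@gq,
      pop = gm@pop, loci = gm@loci[keep], polarized = TRUE)
}

# Profile-likelihood CI for a binomial proportion: {p : logL(p) >= logL(phat)
# - drop}; drop = 1.92 gives an asymptotic 95% interval.
.binomProfileCI <- function(k, n, drop = qchisq(0.95, 1) / 2) {
  phat <- k / n
  ll <- function(p) {
    t1 <- if (k > 0) k * log(p) else 0
    t2 <- if (k < n) (n - k) * log(1 - p) else 0
    t1 + t2
  }
  target <- ll(phat) - drop
  lo <- if (k == 0) 0 else
    uniroot(function(p) ll(p) - target, c(1e-12, phat), tol = 1e-10)$root
  hi <- if (k == n) 1 else
    uniroot(function(p) ll(p) - target, c(phat, 1 - 1e-12), tol = 1e-10)$root
  c(lo, hi)
}

#' Hybrid index of a focal individual
#'
#' The hybrid index h is the proportion of parent2-derived alleles among the
#' individual's non-missing diagnostic loci: h = (parent2 allele count) /
#' (2 x loci). The 95% confidence interval is a binomial profile-likelihood
#' interval (log-likelihood drop of 1.92), treating loci as independent.
#'
#' @param gm a polarized diagnostic-locus [GenotypeMatrix-class] from
#'   [diagnosticLoci()].
#' @param individual column name or index of the focal individual (default:
#'   the first `focal` individual).
#' @return An [AncestryEstimate-class] (the `het` slot is filled via
#'   [interspecificHeterozygosity()]).
#' @export
hybridIndex <- function(gm, individual = NULL) {
  g <- .focalGenotypes(gm, individual)
  g <- g[!is.na(g)]
  if (!length(g)) stop("zero usable diagnostic loci")
  k <- sum(g); n <- 2L * length(g)
  ci <- .binomProfileCI(k, n)
  new("AncestryEstimate", h = k / n, ci = ci,
      het = mean(g == 1L), nLoci = length(g),
      ciMethod = "binomial profile likelihood")
}

.focalGenotypes <- function(gm, individual = NULL) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!gm@polarized)
    stop("run diagnosticLoci() first: genotypes must be polarized")
  if (is.null(individual)) individual <- which(gm@pop == "focal")[1]
  if (is.character(individual))
    individual <- match(individual, colnames(gm@geno))
  if (is.na(individual)) stop("individual not found")
  gm@geno[, individual]
}

#' Interspecific heterozygosity of a focal individual
#'
#' The fraction of non-missing diagnostic loci at which the individual
#' carries one allele from each parental species — near 1 for an F1, halving
#' with each backcross generation.
#'
#' @inheritParams hybridIndex
#' @return numeric fraction in [0, 1].
#' @export
interspecificHeterozygosity <- function(gm, individual = NULL) {
  g <- .focalGenotypes(gm, individual)
  g <- g[!is.na(g)]
  if (!length(g)) stop("zero usable diagnostic loci")
  mean(g == 1L)
}

#' Classify a hybrid from its (h, het) triangle position
#'
#' Compares a point in the hybrid-index / interspecific-heterozygosity
#' triangle against the canonical expectations: parentals at (0, 0) and
#' (1, 0), F1 at (0.5, 1), F2 at (0.5, 0.5), first-generation backcrosses at
#' (0.25, 0.5) and (0.75, 0.5), and later-generation backcrosses halving
#' toward each parental corner (BC2 at (0.125, 0.25), BC3 at
#' (0.0625, 0.125), mirrored on the parent2 side). Returns the nearest
#' canonical class and all distances. Points must satisfy the triangle
#' constraint het <= 2 min(h, 1 - h) up to `tol`.
#'
#' @param h hybrid index in [0, 1].
#' @param het interspecific heterozygosity in [0, 1].
#' @param tol tolerance on the triangle constraint.
#' @return list with `class` (e.g. `"F1"`, `"BC1_P1"`, `"BC3_P1"`) and
#'   `distances` (named, sorted ascending).
#' @examples
#' classifyHybrid(0.5, 1)$class        # "F1"
#' classifyHybrid(0.163, 0.11)$class   # late-generation backcross to parent1
#' @export
classifyHybrid <- function(h, het, tol = 0.05) {
  if (h < 0 || h > 1 || het < 0 || het > 1)
    stop("h and het must lie in [0, 1]")
  if (het > 2 * min(h, 1 - h) + tol)
    stop("point lies outside the ancestry triangle beyond tolerance")
  pts <- rbind(P1 = c(0, 0), P2 = c(1, 0), F1 = c(0.5, 1), F2 = c(0.5, 0.5),
               BC1_P1 = c(0.25, 0.5), BC1_P2 = c(0.75, 0.5),
               BC2_P1 = c(0.125, 0.25), BC2_P2 = c(0.875, 0.25),
               BC3_P1 = c(0.0625, 0.125), BC3_P2 = c(0.9375, 0.125))
  d <- sqrt((pts[, 1] - h)^2 + (pts[, 2] - het)^2)
  d <- sort(d)
  list(class = names(d)[1], distances = d)
}
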