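## Mendelian cross simulator for hybrid-ancestry tests. Parental species are
## fixed for alternative alleles at every locus, so every locus is
## ancestry-diagnostic by construction; crosses are generated by unlinked
## gamete sampling and the realised (not expected) hybrid index and
## interspecific heterozygosity of each focal individual are recorded.

.validCrossTypes <- function() c("P1", "P2", "F1", "F2", "BC1_P1", "BC1_P2")

.parseCrossType <- function(crossType) {
  if (crossType %in% c("P1", "P2", "F1", "F2"))
    return(list(kind = crossType, gen = NA_integer_, side = NA_character_))
  m <- regmatches(crossType, regexec("^BC([0-9]+)_(P[12])$", crossType))[[1]]
  if (length(m) == 3L) {
    gen <- as.integer(m[2])
    if (gen >= 1L) return(list(kind = "BC", gen = gen, side = m[3]))
  }
  stop("unknown cross_type '", crossType, "'; use P1, P2, F1, F2 or BCn_P1/BCn_P2")
}

# A focal individual is a pair of haplotypes coding species-of-origin per
# locus: 0 = parent1 allele, 1 = parent2 allele.
.gamete <- function(hap) {
  pick <- runif(length(hap$a)) < 0.5
  ifelse(pick, hap$a, hap$b)
}

.makeFocal <- function(kind, gen, side, nLoci) {
  zero <- rep(0L, nLoci); one <- rep(1L, nLoci)
  f1 <- list(a = zero, b = one)
  switch(kind,
    P1 = list(a = zero, b = zero),
    P2 = list(a = one, b = one),
    F1 = f1,
    F2 = list(a = .gamete(f1), b = .gamete(f1)),
    BC = {
      parental <- if (side == "P1") zero else one
      ind <- f1
      for (g in seq_len(gen)) ind <- list(a = .gamete(ind), b = parental)
      ind
    })
}

#' Simulate a genotype panel for a Mendelian cross
#'
#' Generates two parental reference panels fixed for alternative alleles at
#' every locus, plus focal individuals of a stated cross type (`P1`, `P2`,
#' `F1`, `F2`, `BC1_P1`, `BC1_P2`, or later-generation backcrosses
#' `BCn_P1`/`BCn_P2`). Loci are unlinked; gametes are sampled per locus. The
#' returned truth record carries the realised hybrid index (fraction of
#' parent2 alleles) and realised interspecific heterozygosity of each focal
#' individual, which downstream estimators should recover exactly in the
#' absence of missing data.
#'
#' Read depths and genotype qualities are drawn high enough to pass default
#' coverage/quality filters (depth > 5, Q > 20), so filter behaviour is
#' exercised with hand-built edge cases rather than by chance.
#'
#' @param nLoci number of biallelic loci (>= 1).
#' @param nParentalPerSpecies individuals per parental reference panel.
#' @param crossType one of `P1`, `P2`, `F1`, `F2`, `BC1_P1`, `BC1_P2` or
#'   `BCn_P1`/`BCn_P2` with integer generation n.
#' @param nFocal number of focal individuals to simulate.
#' @param missingRate per-call missing-data fraction in [0, 1).
#' @param seed integer RNG seed.
#' @return list with elements `gm` (a [GenotypeMatrix-class]; focal genotypes
#'   are ALT = parent2 allele dosages) and `truth` (data.frame of realised
#'   `h` and `het` per focal individual).
#' @examples
#' x <- genCross(100, 4, "F1", seed = 1)
#' x$truth     # h = 0.5, het = 1 exactly for F1
#' @export
genCross <- function(nLoci = 1000, nParentalPerSpecies = 5, crossType = "F1",
                     nFocal = 1, missingRate = 0, seed = 1) {
  if (nLoci < 1) stop("nLoci must be >= 1")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  ct <- .parseCrossType(crossType)
  .withSeed(seed, {
    nP <- nParentalPerSpecies
    geno <- matrix(NA_integer_, nLoci, 2L * nP + nFocal)
    geno[, seq_len(nP)] <- 0L
    geno[, nP + seq_len(nP)] <- 2L
    truth <- data.frame(individual = character(nFocal), h = numeric(nFocal),
                        het = numeric(nFocal), stringsAsFactors = FALSE)
    for (k in seq_len(nFocal)) {
      ind <- .makeFocal(ct$kind, ct$gen, ct$side, nLoci)
      geno[, 2L * nP + k] <- ind$a + ind$b
      truth$individual[k] <- sprintf("focal_%02d", k)
      truth$h[k] <- mean(c(ind$a, ind$b))
      truth$het[k] <- mean(ind$a != ind$b)
    }
    if (missingRate > 0) {
      miss <- runif(length(geno)) < missingRate
      geno[miss] <- NA_integer_
    }
    dp <- matrix(6 + rpois(length(geno), 14), nrow(geno), ncol(geno))
    gq <- matrix(21 + rpois(length(geno), 40), nrow(geno), ncol(geno))
    ids <- c(sprintf("p1_%02d", seq_len(nP)), sprintf("p2_%02d", seq_len(nP)),
             truth$individual)
    colnames(geno) <- colnames(dp) <- colnames(gq) <- ids
    gm <- new("GenotypeMatrix", geno = geno, dp = dp, gq = gq,
              pop = c(rep("parent1", nP), rep("parent2", nP),
                      rep("focal", nFocal)),
              loci = sprintf("locus_%05d", seq_len(nLoci)), polarized = FALSE)
    list(gm = gm, truth = truth)
  })
}

#' Write a GenotypeMatrix as a minimal VCF 4.2 file
#'
#' Emits one biallelic record per locus with `GT:DP:GQ` sample fields so that
#' coverage/quality filtering is exercisable after a round trip through
#' [readGenotypes()]. REF is the parent1 allele (`A`), ALT the parent2 allele
#' (`T`); heterozygotes are written `0/1`, missing calls `./.`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  geno <- gm@geno
  gtStr <- matrix("./.", nrow(geno), ncol(geno))
  gtStr[!is.na(geno) & geno == 0L] <- "0/0"
  gtStr[!is.na(geno) & geno == 1L] <- "0/1"
  gtStr[!is.na(geno) & geno == 2L] <- "1/1"
  hasDP <- nrow(gm@dp) > 0; hasGQ <- nrow(gm@gq) > 0
  fmt <- paste(c("GT", if (hasDP) "DP", if (hasGQ) "GQ"), collapse = ":")
  cells <- gtStr
  if (hasDP) cells <- matrix(paste(cells, gm@dp, sep = ":"), nrow(geno))
  if (hasGQ) cells <- matrix(paste(cells, gm@gq, sep = ":"), nrow(geno))
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (hasDP) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           if (hasGQ) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(geno)), function(i) {
    paste(c("1", i, gm@loci[i], "A", "T", ".", "PASS", ".", fmt,
            cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
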