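test_that("hand-written VCFs parse with multiallelic records dropped", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"))
  rec <- function(pos, alt, g1, g2, g3)
    paste(c("1", pos, paste0("snp", pos), "A", alt, ".", "PASS", ".", "GT",
            g1, g2, g3), collapse = "\t")
  body <- c(vapply(1:10, function(i)
    rec(i, "T", "0/0", "1/1", "0/1"), character(1)),
    rec(11, "T,G", "0/0", "1/1", "1/2"))   # multiallelic -> dropped
  writeLines(c(hdr, body), tmp)
  pm <- data.frame(sample = c("s1", "s2", "s3"),
                   population = c("parent1", "parent2", "focal"))
  expect_message(gm <- readGenotypes(tmp, pm), "1 multiallelic")
  expect_equal(dim(genotypes(gm)), c(10L, 3L))
  expect_equal(unname(genotypes(gm)[1, ]), c(0L, 2L, 1L))
  expect_error(readGenotypes(tmp, pm[-3, ]), "missing from population map")
})

test_that("coverage/quality filters are strict and drop parental failures", {
  geno <- matrix(1L, 10, 3)
  dp <- matrix(20, 10, 3); gq <- matrix(60, 10, 3)
  dp[1, 1] <- 5          # parental depth at the boundary -> locus dropped
  gq[2, 2] <- 20         # parental quality at the boundary -> locus dropped
  dp[3, 1] <- 3          # clear parental failure -> locus dropped
  dp[4, 3] <- 5          # focal failure -> call set missing, locus kept
  gm <- toyGenotypes(geno, c("parent1", "parent2", "focal"), dp = dp,
                     gq = gq)
  f <- filterSNPs(gm)
  expect_equal(nrow(genotypes(f)), 7L)
  expect_true(is.na(genotypes(f)["L004", 3]))
  expect_equal(sum(is.na(genotypes(f))), 1L)
})

test_that("diagnostic loci require opposite parental fixation", {
  geno <- rbind(c(0, 0, 2, 2, 1),    # fixed difference -> kept
                c(2, 2, 0, 0, 1),    # fixed, flipped polarity -> kept
                c(0, 1, 2, 2, 1),    # het parental -> dropped
                c(0, 0, 0, 0, 1),    # same allele both sides -> dropped
                c(1, 1, 1, 1, 1),    # het everywhere -> dropped
                c(0, NA, 2, 2, 2))   # missing call ignored, still fixed
  gm <- toyGenotypes(geno,
                     c("parent1", "parent1", "parent2", "parent2", "focal"))
  dl <- diagnosticLoci(gm)
  expect_equal(dl@loci, c("L001", "L002", "L006"))
  # polarity: dosage counts parent2 alleles after flipping locus 2
  expect_equal(unname(genotypes(dl)[2, ]), c(0L, 0L, 2L, 2L, 1L))
  expect_error(diagnosticLoci(toyGenotypes(geno[, 1:2, drop = FALSE],
                                           c("parent1", "parent1"))),
               "empty parental group")
})

test_that("diagnostic subsetting equals a brute-force scan on random panels", {
  set.seed(31)
  geno <- matrix(sample(c(0:2, NA), 300, replace = TRUE,
                        prob = c(0.4, 0.15, 0.4, 0.05)), 60, 5)
  pop <- c("parent1", "parent1", "parent2", "parent2", "focal")
  gm <- toyGenotypes(geno, pop)
  dl <- diagnosticLoci(gm)
  brute <- vapply(seq_len(60), function(i) {
    g1 <- geno[i, 1:2]; g2 <- geno[i, 3:4]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    length(g1) >= 1 && length(g2) >= 1 &&
      length(unique(g1)) == 1 && length(unique(g2)) == 1 &&
      all(c(g1, g2) %in% c(0, 2)) && g1[1] != g2[1]
  }, logical(1))
  expect_equal(dl@loci, sprintf("L%03d", which(brute)))
})

test_that("hybrid index and its profile-likelihood CI are exact where checkable", {
  # pure parent1 focal: h = 0 and the CI starts at 0
  geno <- cbind(rep(0L, 50), rep(2L, 50), rep(0L, 50))
  gm <- diagnosticLoci(toyGenotypes(geno, c("parent1", "parent2", "focal")))
  est0 <- hybridIndex(gm)
  expect_equal(est0@h, 0)
  expect_equal(est0@ci[1], 0)
  expect_equal(est0@het, 0)
  # F1: h = 1/2 exactly, het = 1
  f1 <- genCross(300, 3, "F1", seed = 5)
  dl <- diagnosticLoci(filterSNPs(f1$gm))
  est <- hybridIndex(dl)
  expect_equal(est@h, 0.5)
  expect_equal(est@het, 1)
  expect_equal(interspecificHeterozygosity(dl), 1)
  expect_equal(est@nLoci, 300L)
})

test_that("the CI matches a grid-search likelihood oracle", {
  # 25 parent2 alleles among 2L = 100
  geno <- cbind(rep(0L, 50), rep(2L, 50),
                c(rep(1L, 25), rep(0L, 25)))
  gm <- diagnosticLoci(toyGenotypes(geno, c("parent1", "parent2", "focal")))
  est <- hybridIndex(gm)
  expect_equal(est@h, 0.25)
  grid <- seq(1e-6, 1 - 1e-6, by = 1e-6)
  ll <- 25 * log(grid) + 75 * log(1 - grid)
  keep <- grid[ll >= max(ll) - qchisq(0.95, 1) / 2]
  expect_equal(est@ci, range(keep), tolerance = 1e-4)
  expect_true(est@ci[1] <= est@h && est@h <= est@ci[2])
})

test_that("estimators are invariant to locus order and equivariant to label swap", {
  x <- genCross(400, 3, "BC1_P1", seed = 21)
  dl <- diagnosticLoci(x$gm)
  est <- hybridIndex(dl)
  perm <- sample(nrow(genotypes(dl)))
  gmP <- methods::new("GenotypeMatrix",
                      geno = genotypes(dl)[perm, , drop = FALSE],
                      dp = dl@dp[perm, , drop = FALSE],
                      gq = dl@gq[perm, , drop = FALSE],
                      pop = dl@pop, loci = dl@loci[perm], polarized = TRUE)
  estP <- hybridIndex(gmP)
  expect_equal(estP@h, est@h)
  expect_equal(estP@het, est@het)
  # swapping parental labels maps h -> 1 - h, leaves het unchanged
  gmS <- x$gm
  popS <- populations(gmS)
  popS[popS == "parent1"] <- "tmp"
  popS[popS == "parent2"] <- "parent1"
  popS[popS == "tmp"] <- "parent2"
  gmS <- methods::new("GenotypeMatrix", geno = genotypes(x$gm),
                      dp = x$gm@dp, gq = x$gm@gq, pop = popS,
                      loci = x$gm@loci, polarized = FALSE)
  estS <- hybridIndex(diagnosticLoci(gmS))
  expect_equal(estS@h, 1 - est@h, tolerance = 1e-12)
  expect_equal(estS@het, est@het)
})

test_that("simulated crosses respect the triangle constraint and recover truth", {
  for (ct in c("F1", "F2", "BC1_P1", "BC1_P2", "BC2_P2")) {
    x <- genCross(500, 2, ct, seed = 17)
    dl <- diagnosticLoci(x$gm)
    est <- hybridIndex(dl)
    expect_equal(est@h, x$truth$h)         # no missing data: exact recovery
    expect_equal(est@het, x$truth$het)
    expect_lte(est@het, 2 * min(est@h, 1 - est@h) + 1e-12)
  }
})

test_that("triangle classification places the canonical and reported points", {
  expect_equal(classifyHybrid(0.5, 1.0)$class, "F1")
  expect_equal(classifyHybrid(0, 0)$class, "P1")
  expect_equal(classifyHybrid(1, 0)$class, "P2")
  expect_equal(classifyHybrid(0.5, 0.5)$class, "F2")
  lateBC <- classifyHybrid(0.163, 0.11)
  expect_match(lateBC$class, "^BC[0-9]+_P1$")     # backcross toward parent1
  expect_error(classifyHybrid(0.1, 0.9), "outside")
  expect_error(classifyHybrid(-0.1, 0.5), "lie in")
})
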