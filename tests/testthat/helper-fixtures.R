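# Shared fixture builders. Everything is generated in code; no binary data.

# Two-group Gaussian-peak spectra (480 vs 560 nm) used across colour tests.
twoGroupSpec <- function(nPerGroup = 10, noiseSd = 0.5, seed = 1,
                         wavelength = seq(300, 700, by = 1)) {
  g <- data.frame(label = c("short", "long"), peak = c(480, 560),
                  height = 30, width = 40)
  genSpectra(g, nPerGroup = nPerGroup, noiseSd = noiseSd,
             wavelength = wavelength, seed = seed)
}

# Gorget nanostructure parameters from the bundled trait-mean table.
gorgetParams <- function(taxon, airShape = "block", lateralFill = 1) {
  tm <- nanostructureMeans(taxon, "gorget")
  m <- stats::setNames(tm$mean, tm$trait)
  nanostructure(m["cortex"], m["pt_top"], m["mel"], m["ker"], m["air"],
                m["n_layers"], airShape = airShape,
                lateralFill = lateralFill)
}

# Dispersionless optical materials: wavelength-scaling arguments are exact.
flatDispersion <- function() {
  opticalDispersion(keratin = list(B = 0, k0 = 0),
                    melanin = list(B = 0, k0 = 0))
}

# Balanced 4-tip tree ((A,B),(C,D)) with unit branches.
balancedTree4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# A GenotypeMatrix built directly from a dosage matrix (loci x individuals).
toyGenotypes <- function(geno, pop, dp = NULL, gq = NULL) {
  geno <- matrix(as.integer(geno), nrow(geno), ncol(geno),
                 dimnames = dimnames(geno))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("ind%02d", seq_len(ncol(geno)))
  rownames(geno) <- sprintf("L%03d", seq_len(nrow(geno)))
  methods::new("GenotypeMatrix", geno = geno,
               dp = if (is.null(dp)) matrix(numeric(0), 0, 0) else dp,
               gq = if (is.null(gq)) matrix(numeric(0), 0, 0) else gq,
               pop = pop, loci = sprintf("L%03d", seq_len(nrow(geno))),
               polarized = FALSE)
}
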