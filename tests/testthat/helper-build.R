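# Fixture builders shared across tests.  Everything is generated in code;
# no data files.

# Uniform allele frequencies: nLoci loci with A equifrequent alleles.
uniformFreqs <- function(nLoci, A, base = 100) {
  f <- lapply(seq_len(nLoci), function(j)
    setNames(rep(1 / A, A), base + 2 * (0:(A - 1))))
  names(f) <- paste0("L", seq_len(nLoci))
  f
}

# Allele array for one full-sib family: two parents drawn from the given
# frequency pools, n offspring by Mendelian segregation.
familyAlleles <- function(freqs, n) {
  mom <- lapply(freqs, function(f) kinpatch:::drawGenotype(f))
  dad <- lapply(freqs, function(f) kinpatch:::drawGenotype(f))
  al <- array(NA_integer_, c(n, length(freqs), 2))
  for (i in seq_len(n)) for (j in seq_along(freqs))
    al[i, j, ] <- sort(c(sample(mom[[j]], 1), sample(dad[[j]], 1)))
  al
}

# Stack several allele arrays (same loci) into one GenotypeTable.
bindAlleles <- function(arrays, sites, loci = NULL, idPrefix = "i") {
  n <- sum(vapply(arrays, function(a) dim(a)[1], 0L))
  L <- dim(arrays[[1]])[2]
  al <- array(NA_integer_, c(n, L, 2))
  off <- 0
  for (a in arrays) {
    al[off + seq_len(dim(a)[1]), , ] <- a
    off <- off + dim(a)[1]
  }
  genotypeTable(paste0(idPrefix, seq_len(n)), sites,
                loci %||% paste0("L", seq_len(L)), al)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny deterministic table: 4 individuals, 2 sites, 2 loci.
tinyTable <- function() {
  al <- array(NA_integer_, c(4, 2, 2))
  al[1, 1, ] <- c(101, 103); al[1, 2, ] <- c(200, 204)
  al[2, 1, ] <- c(101, 101); al[2, 2, ] <- c(200, 200)
  al[3, 1, ] <- c(103, 105); al[3, 2, ] <- NA
  al[4, 1, ] <- c(101, 105); al[4, 2, ] <- c(202, 204)
  genotypeTable(paste0("i", 1:4), c("A", "A", "B", "B"),
                c("L1", "L2"), al)
}
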