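# Independent oracles and small fixture builders used across the suite.

randomDNA <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# Hand-typed bacterial genetic code (translation table 11 coincides
# with the standard code over the 61 sense codons and 3 stops);
# deliberately independent of any library lookup.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracleTranslate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(CODON_TABLE[codons], collapse = "")
}

# Brute-force promoter scan: scores every (pos35, spacer) pair with an
# explicit per-position probability lookup, independent of the sliding
# implementation.
oracleSiteScore <- function(pwm, site) {
  p <- pwmProbs(pwm)
  q <- pwmBackground(pwm)
  rownames(p) <- c("A", "C", "G", "T")
  s <- 0
  for (i in seq_len(nchar(site))) {
    b <- substr(site, i, i)
    s <- s + log2(p[b, i] / q[[b]])
  }
  s
}

oracleScan <- function(model, window) {
  L <- nchar(window)
  sr <- spacerRange(model)
  rows <- list()
  for (sp in sr[1]:sr[2]) {
    for (pos35 in seq_len(max(0L, L - 13L - sp))) {
      pos10 <- pos35 + 6L + sp
      s35 <- oracleSiteScore(pwm35(model),
                             substr(window, pos35, pos35 + 5L))
      s10 <- oracleSiteScore(pwm10(model),
                             substr(window, pos10, pos10 + 7L))
      rows[[length(rows) + 1L]] <- data.frame(
        pos35 = pos35, spacer_len = sp, pos10 = pos10,
        total_score = s35 + s10, dist_to_start = L - (pos10 + 7L))
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$total_score, out$dist_to_start, out$pos35), ]
}

# Random protein strings over the 20 standard residues.
randomProtein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
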