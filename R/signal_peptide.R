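# Position-weight-matrix scorer for Sec-type secretion signal peptides.
#
# Phr propeptides begin with a classical tripartite signal: a short positively
# charged n-region (K/R), a hydrophobic h-region, and a small-residue c-region
# ending near an Ala-X-Ala-like cleavage site. The scorer encodes that
# architecture as a 30-position PWM; scores are normalised so the PWM consensus
# scores exactly 1 and the worst possible sequence scores 0. Residues beyond
# position 30 never influence the score.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Build the PWM once at load time. Columns are probability distributions over
# the 20 amino acids; each position concentrates 90% of the mass on the
# residue set expected for its signal-peptide region.
.make_signal_pwm <- function() {
  n_pos <- 30L
  pwm <- matrix(0.1 / 19, nrow = 20L, ncol = n_pos, dimnames = list(AA20, NULL))
  put <- function(pos, residues, mass = 0.9) {
    for (j in pos) {
      col <- rep((1 - mass) / (20 - length(residues)), 20L)
      names(col) <- AA20
      col[residues] <- mass / length(residues)
      pwm[, j] <<- col
    }
  }
  put(1L, "M", mass = 0.95)
  put(2:6, c("K", "R"))                      # n-region: positive charge
  put(7:18, c("L", "A", "V", "I", "F"))      # h-region: hydrophobic core
  put(19:24, c("A", "S", "G", "T"))          # c-region: small residues
  put(c(25L, 27L, 29L), c("A", "S"))         # A-x-A-like cleavage motif
  put(c(26L, 28L, 30L), c("A", "S", "G", "V", "T"), mass = 0.8)
  pwm
}

.SIGNAL_PWM <- .make_signal_pwm()
.SIGNAL_BG <- 1 / 20  # uniform background for the log-odds

# amino-acid frequencies of a typical coding background (equal codon usage
# over the 61 sense codons); the score's zero point is calibrated against
# this composition so that ordinary genomic ORFs score near 0
.CODING_AA_FREQ <- local({
  code <- Biostrings::GENETIC_CODE
  tab <- table(code[code != "*"])
  freq <- as.numeric(tab[AA20]) / sum(tab)
  names(freq) <- AA20
  freq
})

#' Secretion-signal score of a propeptide
#'
#' Scores the N-terminus of a protein against the package's signal-peptide
#' position weight matrix (positively charged n-region, hydrophobic h-region,
#' small-residue c-region). Per-position log-odds against a uniform background
#' are summed over the first `min(30, nchar(protein))` positions and rescaled
#' so that the PWM consensus scores exactly 1 while a sequence of typical
#' coding composition (equal-codon-usage amino-acid frequencies) scores 0 in
#' expectation (negative values are clamped to 0). The score is
#' deterministic and independent of residues beyond position 30.
#'
#' The default decision threshold used by [scan_propeptide_orfs()] is 0.3,
#' calibrated so that known propeptide N-termini pass while open reading
#' frames from background sequence rarely do.
#'
#' @param protein Protein string of length >= 15 (unknown residues `X`
#'   contribute the background probability).
#' @return Score in `[0, 1]`.
#' @export
signal_peptide_score <- function(protein) {
  if (length(protein) != 1L || !is.character(protein)) {
    stop("`protein` must be a single string", call. = FALSE)
  }
  if (nchar(protein) < 15L) {
    stop("undefined score: protein shorter than 15 residues", call. = FALSE)
  }
  n_use <- min(30L, nchar(protein))
  aa <- strsplit(substring(protein, 1L, n_use), "")[[1]]
  lods <- log(.SIGNAL_PWM / .SIGNAL_BG)
  s <- 0
  for (j in seq_len(n_use)) {
    s <- s + if (aa[j] %in% AA20) lods[aa[j], j] else 0
  }
  smax <- sum(apply(lods[, seq_len(n_use), drop = FALSE], 2L, max))
  # E[score] for a sequence of typical coding composition
  s0 <- sum(crossprod(.CODING_AA_FREQ, lods[, seq_len(n_use), drop = FALSE]))
  min(1, max(0, (s - s0) / (smax - s0)))
}

#' Consensus sequence of the signal-peptide PWM
#'
#' @return 30-residue string; scores exactly 1 under [signal_peptide_score()].
#' @export
signal_pwm_consensus <- function() {
  paste(AA20[apply(.SIGNAL_PWM, 2L, which.max)], collapse = "")
}

# Draw a signal-peptide N-terminus from the PWM (used by the generator).
# Position 1 is always the initiator methionine.
sample_signal_peptide <- function() {
  aa <- vapply(seq_len(ncol(.SIGNAL_PWM)), function(j) {
    sample(AA20, 1L, prob = .SIGNAL_PWM[, j])
  }, character(1))
  aa[1L] <- "M"
  paste(aa, collapse = "")
}
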