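# Low-level nucleotide/protein utilities shared by the miner and the generator.
# All genomic coordinates in this package are 1-based inclusive on the forward
# strand of a contig; minus-strand features store forward coordinates plus a
# strand flag.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
START_CODONS <- c("ATG", "GTG", "TTG")  # bacterial starts (translation table 11)

.codon_table <- function() {
  # genetic code 11 has the same codon->aa map as the standard code; only the
  # start-codon set differs, which we handle separately.
  Biostrings::GENETIC_CODE
}

.check_dna <- function(dna) {
  if (length(dna) != 1L || !is.character(dna)) {
    stop("`dna` must be a single character string", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(dna, "")[[1]]), DNA_ALPHABET)
  if (length(bad)) {
    stop("illegal nucleotide character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(dna)
}

#' Reverse complement of a nucleotide string
#'
#' @param dna Character scalar over `A,C,G,T,N`.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(dna) {
  .check_dna(dna)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
}

# translate one reading frame; codons containing N (or any ambiguity) -> "X",
# stop codons -> "*"
.translate_frame <- function(dna, offset) {
  L <- nchar(dna)
  n_codons <- (L - offset) %/% 3L
  if (n_codons <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(dna, starts, starts + 2L)
  tab <- .codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' Translates all three forward frames and the three frames of the reverse
#' complement. Codons containing `N` yield `X`; stop codons are rendered `*`.
#' Frame `f` (offset 0, 1, 2) of a sequence of length `L` yields
#' `floor((L - f) / 3)` residues.
#'
#' @param dna Character scalar over `A,C,G,T,N`.
#' @return Named character vector of length 6
#'   (`fwd0`, `fwd1`, `fwd2`, `rev0`, `rev1`, `rev2`).
#' @export
six_frame_translate <- function(dna) {
  .check_dna(dna)
  rc <- if (nchar(dna)) reverse_complement(dna) else dna
  c(fwd0 = .translate_frame(dna, 0L),
    fwd1 = .translate_frame(dna, 1L),
    fwd2 = .translate_frame(dna, 2L),
    rev0 = .translate_frame(rc, 0L),
    rev1 = .translate_frame(rc, 1L),
    rev2 = .translate_frame(rc, 2L))
}

#' Translate a CDS to protein
#'
#' Translates an in-frame coding sequence, rendering the initiator codon
#' (`ATG`/`GTG`/`TTG`) as `M` and dropping a terminal stop if present.
#'
#' @param cds In-frame coding nucleotide string, length divisible by 3.
#' @return Protein string without the terminal stop.
#' @export
translate_cds <- function(cds) {
  .check_dna(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  aa <- .translate_frame(cds, 0L)
  if (nchar(aa) && substring(aa, nchar(aa)) == "*") {
    aa <- substring(aa, 1L, nchar(aa) - 1L)
  }
  if (nchar(aa) && substring(cds, 1L, 3L) %in% START_CODONS) {
    aa <- paste0("M", substring(aa, 2L))
  }
  aa
}

#' GC fraction of a nucleotide string
#'
#' `N`s are excluded from the denominator.
#'
#' @param dna Character scalar over `A,C,G,T,N`.
#' @return `(G + C) / (A + C + G + T)`.
#' @export
gc_fraction <- function(dna) {
  .check_dna(dna)
  chars <- strsplit(dna, "")[[1]]
  informative <- chars != "N"
  if (!any(informative)) stop("no informative (non-N) bases", call. = FALSE)
  sum(chars %in% c("G", "C")) / sum(informative)
}

# Find all ORFs on the given (already strand-oriented) sequence.
# An ORF runs from a start codon to the next in-frame stop (stop included in
# the interval); ORFs sharing a stop are collapsed to the longest start unless
# collapse = FALSE. Coordinates are 1-based inclusive on `seq_` itself.
# Returns data.frame: start, end, frame, protein (start codon read as M).
find_orfs <- function(seq_, min_aa = 1L, max_aa = Inf, collapse = TRUE) {
  .check_dna(seq_)
  L <- nchar(seq_)
  out <- list()
  for (offset in 0:2) {
    n_codons <- (L - offset) %/% 3L
    if (n_codons < 2L) next
    starts_nt <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq_, starts_nt, starts_nt + 2L)
    is_start <- codons %in% START_CODONS
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    stop_idx <- which(is_stop)
    if (!length(stop_idx) || !any(is_start)) next
    for (si in which(is_start)) {
      nxt <- stop_idx[stop_idx > si]
      if (!length(nxt)) next
      e <- nxt[1L]
      aa_len <- e - si  # codons between start and stop, inclusive of start
      if (aa_len < min_aa || aa_len > max_aa) next
      cds <- substring(seq_, starts_nt[si], starts_nt[e] + 2L)
      out[[length(out) + 1L]] <- data.frame(
        start = starts_nt[si], end = starts_nt[e] + 2L, frame = offset,
        protein = translate_cds(cds), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, out)
  if (collapse) {
    # one ORF per stop codon: keep the longest (earliest start)
    orfs <- orfs[order(orfs$end, orfs$start), ]
    orfs <- orfs[!duplicated(orfs$end), ]
  }
  rownames(orfs) <- NULL
  orfs
}

# fraction of X residues in a protein
.x_fraction <- function(protein) {
  if (!nchar(protein)) return(0)
  mean(strsplit(protein, "")[[1]] == "X")
}
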