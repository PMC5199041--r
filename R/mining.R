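# Receptor-homolog mining and downstream propeptide ORF detection.
#
# The homology engine is NCBI tblastn (translated search of protein queries
# against genome nucleotide sequence), driven through temporary files; hit
# filtering (e-value, aligned length), merging of overlapping hits, in-frame
# ORF extension and the propeptide window scan are implemented here.
# Precomputed BLAST tabular hits (outfmt 6) can be imported instead of
# running the search.

#' Construct a genome record
#'
#' @param strain Strain identifier.
#' @param contigs Named character vector of contig nucleotide sequences
#'   (alphabet `A,C,G,T,N`; unique names).
#' @param species Species label (optional, used by population analyses).
#' @return Object of class `genome_record`.
#' @export
genome_record <- function(strain, contigs, species = NA_character_) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must have unique names", call. = FALSE)
  }
  for (s in contigs) .check_dna(s)
  structure(list(strain = strain, species = species, contigs = contigs),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> strain", x$strain, "|", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp\n")
  invisible(x)
}

#' Homology-search parameters
#'
#' Defaults follow the receptor-mining filters: hits are accepted when the
#' e-value against any query is at most `evalue_max` and the aligned length is
#' at least `min_homology_len_aa`. The `"rap"` profile uses 1e-20; the
#' `"nprr"` profile tightens the e-value to 1e-30.
#'
#' @param profile `"rap"` or `"nprr"`.
#' @param evalue_max Maximum e-value (> 0).
#' @param min_homology_len_aa Minimum aligned length in amino acids.
#' @return List of class `search_params`.
#' @export
search_params <- function(profile = c("rap", "nprr"),
                          evalue_max = NULL, min_homology_len_aa = 300L) {
  profile <- match.arg(profile)
  if (is.null(evalue_max)) evalue_max <- if (profile == "rap") 1e-20 else 1e-30
  stopifnot(evalue_max > 0, min_homology_len_aa >= 1)
  structure(list(profile = profile, evalue_max = evalue_max,
                 min_homology_len_aa = as.integer(min_homology_len_aa)),
            class = "search_params")
}

#' Propeptide scan parameters
#'
#' The scan window is anchored at the last base of the receptor stop codon,
#' measured in the receptor's orientation: the `"rap"` profile spans 100 bp
#' upstream to 600 bp downstream of the receptor end, the `"nprr"` profile
#' 100 bp upstream to 500 bp downstream. Candidate open reading frames must
#' start inside the window, lie on the receptor strand (when
#' `same_strand_required`), encode `orf_len_aa[1]`–`orf_len_aa[2]` residues,
#' and reach `signal_threshold` under [signal_peptide_score()].
#'
#' @param profile `"rap"` or `"nprr"`.
#' @param window Integer interval relative to the receptor stop (nt).
#' @param orf_len_aa Accepted ORF length interval (aa), within `[1, 1000]`.
#' @param same_strand_required Require candidates on the receptor strand.
#' @param signal_threshold Minimum secretion-signal score.
#' @param max_x_fraction ORFs with more than this fraction of `X` residues
#'   (ambiguous codons) are excluded.
#' @return List of class `propeptide_scan_params`.
#' @export
propeptide_scan_params <- function(profile = c("rap", "nprr"), window = NULL,
                                   orf_len_aa = c(35L, 120L),
                                   same_strand_required = TRUE,
                                   signal_threshold = 0.3,
                                   max_x_fraction = 0.05) {
  profile <- match.arg(profile)
  if (is.null(window)) window <- if (profile == "rap") c(-100L, 600L) else c(-100L, 500L)
  stopifnot(length(window) == 2, window[1] < window[2],
            length(orf_len_aa) == 2, orf_len_aa[1] >= 1, orf_len_aa[2] <= 1000,
            signal_threshold >= 0, signal_threshold <= 1)
  structure(list(profile = profile, window = as.integer(window),
                 orf_len_aa = as.integer(orf_len_aa),
                 same_strand_required = isTRUE(same_strand_required),
                 signal_threshold = signal_threshold,
                 max_x_fraction = max_x_fraction),
            class = "propeptide_scan_params")
}

.empty_hits <- function() {
  data.frame(contig = character(), strand = character(), start = integer(),
             end = integer(), frame = integer(), query = character(),
             pident = numeric(), length_aa = integer(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

# Filter raw tabular hits and merge overlapping hits on the same contig and
# strand into a single locus, keeping the best-scoring hit's annotation and
# the merged interval span.
.filter_merge_hits <- function(raw, params) {
  raw <- raw[raw$evalue <= params$evalue_max &
               raw$length_aa >= params$min_homology_len_aa, , drop = FALSE]
  if (!nrow(raw)) return(.empty_hits())
  out <- list()
  for (key in unique(paste(raw$contig, raw$strand))) {
    grp <- raw[paste(raw$contig, raw$strand) == key, , drop = FALSE]
    ir <- IRanges::IRanges(start = grp$start, end = grp$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (k in seq_along(red)) {
      members <- grp[revmap[[k]], , drop = FALSE]
      best <- members[order(members$evalue, -members$bitscore), ][1L, ]
      best$start <- IRanges::start(red)[k]
      best$end <- IRanges::end(red)[k]
      out[[length(out) + 1L]] <- best
    }
  }
  merged <- do.call(rbind, out)
  merged <- merged[order(merged$contig, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

.parse_outfmt6 <- function(path) {
  cols <- c("query", "contig", "pident", "length_aa", "evalue", "bitscore",
            "sstart", "send", "sframe")
  if (file.size(path) == 0) return(.empty_hits())
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  colnames(tab) <- cols
  data.frame(contig = as.character(tab$contig),
             strand = ifelse(tab$sframe > 0, "+", "-"),
             start = pmin(tab$sstart, tab$send),
             end = pmax(tab$sstart, tab$send),
             frame = abs(tab$sframe),
             query = as.character(tab$query),
             pident = tab$pident, length_aa = as.integer(tab$length_aa),
             evalue = tab$evalue, bitscore = tab$bitscore,
             stringsAsFactors = FALSE)
}

#' Search a genome for receptor homologs
#'
#' Runs a translated homology search (tblastn) of the seed receptor proteins
#' against the genome, keeps hits passing the e-value and aligned-length
#' filters against any query, and merges overlapping hits on the same locus,
#' retaining the best score.
#'
#' @param genome A [genome_record()].
#' @param queries Named character vector of seed receptor protein sequences.
#' @param params A [search_params()] object.
#' @return data.frame of merged hits with columns `contig`, `strand`,
#'   `start`, `end`, `frame`, `query`, `pident`, `length_aa`, `evalue`,
#'   `bitscore` (coordinates 1-based inclusive, forward strand).
#' @export
search_receptor_homologs <- function(genome, queries,
                                     params = search_params()) {
  stopifnot(inherits(genome, "genome_record"))
  if (length(queries) == 0) stop("empty query set", call. = FALSE)
  if (is.null(names(queries))) names(queries) <- paste0("query", seq_along(queries))
  for (exe in c("makeblastdb", "tblastn")) {
    if (Sys.which(exe) == "") {
      stop(exe, " not found on PATH; run BLAST externally and use ",
           "import_blast_hits()", call. = FALSE)
    }
  }
  wd <- tempfile("blast"); dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  db_fa <- file.path(wd, "genome.fa")
  q_fa <- file.path(wd, "queries.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), db_fa)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(queries), q_fa)
  out <- file.path(wd, "hits.tsv")
  system2("makeblastdb", c("-in", db_fa, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  status <- system2("tblastn",
                    c("-query", q_fa, "-db", db_fa, "-outfmt",
                      shQuote("6 qseqid sseqid pident length evalue bitscore sstart send sframe"),
                      "-evalue", format(params$evalue_max, scientific = TRUE),
                      "-out", out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("tblastn failed with status ", status, call. = FALSE)
  .filter_merge_hits(.parse_outfmt6(out), params)
}

#' Import precomputed BLAST tabular hits
#'
#' Reads a BLAST `-outfmt "6 qseqid sseqid pident length evalue bitscore
#' sstart send sframe"` file and applies the same filtering and merging as
#' [search_receptor_homologs()].
#'
#' @param path Path to the tabular file.
#' @param params A [search_params()] object.
#' @return Merged hit data.frame (see [search_receptor_homologs()]).
#' @export
import_blast_hits <- function(path, params = search_params()) {
  .filter_merge_hits(.parse_outfmt6(path), params)
}

# position on the strand-oriented sequence for a forward coordinate
.to_strand <- function(pos, L, strand) if (strand == "+") pos else L - pos + 1L

.codon_at <- function(s, p) substring(s, p, p + 2L)
.is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Extend a homology hit to a full open reading frame
#'
#' Walks in-frame from the hit to the nearest upstream stop, takes the first
#' start codon (`ATG`/`GTG`/`TTG`) after it, and extends downstream to the
#' next stop. The `frameshift_flag` is set when the resulting single-frame ORF
#' does not cover at least `min_homology_len_aa` residues (the automated
#' analogue of flagging high-homology/short-ORF loci for inspection). Hits
#' running off the contig without an in-frame stop are flagged `partial` and
#' are not valid receptor ORFs.
#'
#' @param genome A [genome_record()].
#' @param hit One row of the hit data.frame.
#' @param params A [search_params()] (supplies `min_homology_len_aa`).
#' @return One-row data.frame: `contig`, `strand`, `start`, `end` (forward
#'   coordinates including the stop codon), `protein`, `frameshift_flag`,
#'   `partial`, `valid`.
#' @export
extend_to_orf <- function(genome, hit, params = search_params()) {
  stopifnot(inherits(genome, "genome_record"))
  contig_seq <- genome$contigs[[hit$contig]]
  if (is.null(contig_seq)) stop("hit contig not in genome", call. = FALSE)
  L <- nchar(contig_seq)
  if (hit$start < 1 || hit$end > L) stop("hit coordinates off contig", call. = FALSE)
  s <- if (hit$strand == "+") contig_seq else reverse_complement(contig_seq)
  hs <- min(.to_strand(hit$start, L, hit$strand), .to_strand(hit$end, L, hit$strand))
  he <- max(.to_strand(hit$start, L, hit$strand), .to_strand(hit$end, L, hit$strand))

  # upstream: find the in-frame stop bounding the ORF
  p <- hs
  repeat {
    if (p - 3L < 1L) { p <- NA_integer_; break }
    if (.is_stop(.codon_at(s, p - 3L))) break
    p <- p - 3L
  }
  if (is.na(p)) {  # ran off the contig edge without a bounding stop
    return(data.frame(contig = hit$contig, strand = hit$strand,
                      start = NA_integer_, end = NA_integer_,
                      protein = NA_character_, frameshift_flag = TRUE,
                      partial = TRUE, valid = FALSE, stringsAsFactors = FALSE))
  }
  # first start codon at/after the bounding stop, searching up to the hit end
  orf_start <- NA_integer_
  q <- p
  while (q + 2L <= he) {
    if (.codon_at(s, q) %in% START_CODONS) { orf_start <- q; break }
    q <- q + 3L
  }
  start_found <- !is.na(orf_start)
  if (!start_found) orf_start <- p
  # downstream: next in-frame stop
  q <- orf_start
  orf_end <- NA_integer_
  while (q + 2L <= nchar(s)) {
    if (.is_stop(.codon_at(s, q))) { orf_end <- q + 2L; break }
    q <- q + 3L
  }
  if (is.na(orf_end)) {
    return(data.frame(contig = hit$contig, strand = hit$strand,
                      start = NA_integer_, end = NA_integer_,
                      protein = NA_character_, frameshift_flag = TRUE,
                      partial = TRUE, valid = FALSE, stringsAsFactors = FALSE))
  }
  cds <- substring(s, orf_start, orf_end)
  protein <- translate_cds(cds)
  frameshift <- !start_found || nchar(protein) < params$min_homology_len_aa
  fwd <- if (hit$strand == "+") c(orf_start, orf_end) else
    c(L - orf_end + 1L, L - orf_start + 1L)
  data.frame(contig = hit$contig, strand = hit$strand,
             start = fwd[1], end = fwd[2], protein = protein,
             frameshift_flag = frameshift, partial = FALSE, valid = TRUE,
             stringsAsFactors = FALSE)
}

#' Scan for propeptide ORFs downstream of a receptor
#'
#' Searches the window around the receptor stop codon (in the receptor's
#' orientation) for short same-strand open reading frames whose secretion
#' signal score passes the threshold. Candidates are ranked by score
#' (descending), then distance from the receptor stop (ascending), then
#' leftmost coordinate.
#'
#' @param genome A [genome_record()].
#' @param receptor_orf One row as returned by [extend_to_orf()].
#' @param params A [propeptide_scan_params()].
#' @return data.frame of candidates: `start`, `end` (forward coords, stop
#'   codon included), `strand`, `protein`, `signal_score`, `distance`, `rank`.
#' @export
scan_propeptide_orfs <- function(genome, receptor_orf,
                                 params = propeptide_scan_params()) {
  stopifnot(inherits(genome, "genome_record"))
  empty <- data.frame(start = integer(), end = integer(), strand = character(),
                      protein = character(), signal_score = numeric(),
                      distance = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (!isTRUE(receptor_orf$valid)) return(empty)
  contig_seq <- genome$contigs[[receptor_orf$contig]]
  L <- nchar(contig_seq)
  strand <- receptor_orf$strand
  s <- if (strand == "+") contig_seq else reverse_complement(contig_seq)
  stop_end <- if (strand == "+") receptor_orf$end else L - receptor_orf$start + 1L
  win <- stop_end + params$window
  # region large enough for ORFs starting at the window end to terminate
  reg_lo <- max(1L, win[1])
  reg_hi <- min(nchar(s), win[2] + 3L * (params$orf_len_aa[2] + 2L))
  if (reg_hi - reg_lo + 1L < 3L * (params$orf_len_aa[1] + 1L)) return(empty)
  region <- substring(s, reg_lo, reg_hi)
  orfs <- find_orfs(region, min_aa = params$orf_len_aa[1],
                    max_aa = params$orf_len_aa[2])
  if (!nrow(orfs)) return(empty)
  orfs$start_s <- orfs$start + reg_lo - 1L
  orfs$end_s <- orfs$end + reg_lo - 1L
  orfs <- orfs[orfs$start_s >= win[1] & orfs$start_s <= win[2], , drop = FALSE]
  if (!nrow(orfs)) return(empty)
  orfs <- orfs[vapply(orfs$protein, .x_fraction, 0) <= params$max_x_fraction, ,
               drop = FALSE]
  if (!nrow(orfs)) return(empty)
  orfs$signal_score <- vapply(orfs$protein, signal_peptide_score, 0)
  orfs <- orfs[orfs$signal_score >= params$signal_threshold, , drop = FALSE]
  if (!nrow(orfs)) return(empty)
  orfs$distance <- orfs$start_s - stop_end
  ord <- order(-orfs$signal_score, orfs$distance, orfs$start_s)
  orfs <- orfs[ord, , drop = FALSE]
  fwd_start <- if (strand == "+") orfs$start_s else L - orfs$end_s + 1L
  fwd_end <- if (strand == "+") orfs$end_s else L - orfs$start_s + 1L
  data.frame(start = fwd_start, end = fwd_end, strand = strand,
             protein = orfs$protein, signal_score = orfs$signal_score,
             distance = orfs$distance, rank = seq_len(nrow(orfs)),
             stringsAsFactors = FALSE)
}

#' Assemble receptor/propeptide cassettes
#'
#' Pairs each valid receptor ORF with its accepted propeptide candidates.
#' Overlapping candidates are resolved greedily in rank order so that the
#' accepted set is non-overlapping; a cassette with no accepted candidate is
#' an orphan, and one with two or more records a propeptide gene duplication.
#'
#' @param genome A [genome_record()].
#' @param receptor_orfs data.frame of receptor ORFs ([extend_to_orf()] rows).
#' @param candidates List of candidate data.frames, parallel to
#'   `receptor_orfs` rows.
#' @return data.frame of class `cassette_table`: one row per cassette with
#'   receptor coordinates/protein, `n_phr`, `orphan`, `duplication` flags and
#'   a `phr` list-column of accepted candidates.
#' @export
assemble_cassettes <- function(genome, receptor_orfs, candidates) {
  stopifnot(nrow(receptor_orfs) == length(candidates))
  rows <- list()
  for (i in seq_len(nrow(receptor_orfs))) {
    r <- receptor_orfs[i, ]
    if (!isTRUE(r$valid)) next
    cand <- candidates[[i]]
    acc <- cand[0, , drop = FALSE]
    if (nrow(cand)) {
      taken <- IRanges::IRanges()
      for (j in seq_len(nrow(cand))) {
        ij <- IRanges::IRanges(cand$start[j], cand$end[j])
        if (length(taken) == 0 ||
            !any(IRanges::overlapsAny(ij, taken))) {
          acc <- rbind(acc, cand[j, , drop = FALSE])
          taken <- c(taken, ij)
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      strain = genome$strain, species = genome$species,
      contig = r$contig, strand = r$strand,
      rap_start = r$start, rap_end = r$end, rap_protein = r$protein,
      frameshift_flag = r$frameshift_flag,
      n_phr = nrow(acc), orphan = nrow(acc) == 0, duplication = nrow(acc) >= 2,
      stringsAsFactors = FALSE)
    attr(rows[[length(rows)]], "phr") <- acc
  }
  if (!length(rows)) {
    res <- data.frame(strain = character(), species = character(),
                      contig = character(), strand = character(),
                      rap_start = integer(), rap_end = integer(),
                      rap_protein = character(), frameshift_flag = logical(),
                      n_phr = integer(), orphan = logical(),
                      duplication = logical(), stringsAsFactors = FALSE)
    res$phr <- list()
    class(res) <- c("cassette_table", class(res))
    return(res)
  }
  phr <- lapply(rows, attr, "phr")
  res <- do.call(rbind, rows)
  res$phr <- phr
  rownames(res) <- NULL
  class(res) <- c("cassette_table", class(res))
  res
}

#' Mine a genome end-to-end
#'
#' Runs homology search, ORF extension, propeptide scanning and cassette
#' assembly for one genome. Duplicate receptor ORFs arising from distinct
#' hits that extend to the same locus are collapsed.
#'
#' @param genome A [genome_record()].
#' @param queries Seed receptor proteins (named character vector).
#' @param search A [search_params()].
#' @param scan A [propeptide_scan_params()].
#' @param hits Optional precomputed merged hits (e.g. from
#'   [import_blast_hits()]); when supplied the search step is skipped.
#' @return A `cassette_table` (see [assemble_cassettes()]).
#' @export
mine_genome <- function(genome, queries, search = search_params(),
                        scan = propeptide_scan_params(), hits = NULL) {
  if (is.null(hits)) hits <- search_receptor_homologs(genome, queries, search)
  orfs <- lapply(seq_len(nrow(hits)), function(i)
    extend_to_orf(genome, hits[i, ], search))
  orfs <- if (length(orfs)) do.call(rbind, orfs) else
    data.frame(contig = character(), strand = character(), start = integer(),
               end = integer(), protein = character(),
               frameshift_flag = logical(), partial = logical(),
               valid = logical(), stringsAsFactors = FALSE)
  keep <- orfs$valid & !duplicated(paste(orfs$contig, orfs$strand,
                                         orfs$start, orfs$end))
  orfs <- orfs[which(keep), , drop = FALSE]
  cands <- lapply(seq_len(nrow(orfs)), function(i)
    scan_propeptide_orfs(genome, orfs[i, ], scan))
  assemble_cassettes(genome, orfs, cands)
}
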