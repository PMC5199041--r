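# Readers/writers: receptor-database loader (TSV/CSV/XLSX), cassette tables,
# GFF3 feature export.

.default_db_columns <- c(
  index = "index", strain = "strain", clade = "clade", cluster = "cluster",
  rap_dna = "rap_dna", rap_protein = "rap_protein",
  autoinducer = "autoinducer", phr_protein = "phr_protein",
  phr_dna = "phr_dna")

#' Load a receptor (Rap) database table
#'
#' Reads a database export with one record per receptor: index, strain
#' number, clade, cluster id, receptor nucleotide/protein sequence, putative
#' autoinducer peptide (empty for orphans) and propeptide protein/DNA
#' sequence. TSV and CSV are read natively; `.xlsx` requires the readxl
#' package. Records with an empty autoinducer field are flagged orphan.
#'
#' @param path File path (`.tsv`, `.csv` or `.xlsx`).
#' @param column_map Optional named character vector mapping the canonical
#'   names (`index`, `strain`, `clade`, `cluster`, `rap_dna`, `rap_protein`,
#'   `autoinducer`, `phr_protein`, `phr_dna`) to the file's column names.
#' @return data.frame with canonical columns plus `orphan`; attribute
#'   `clade_counts` tabulates records per clade.
#' @export
load_rap_database <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(
    ext,
    tsv = , txt = utils::read.delim(path, stringsAsFactors = FALSE),
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    xlsx = , xls = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading Excel requires the readxl package; export to TSV instead",
             call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path))
    },
    stop("unsupported extension: ", ext, call. = FALSE))
  if (!nrow(raw)) {
    out <- data.frame(matrix(ncol = length(.default_db_columns) + 1L, nrow = 0L))
    colnames(out) <- c(names(.default_db_columns), "orphan")
    return(out)
  }
  cmap <- .default_db_columns
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  required <- c("index", "strain", "cluster")
  for (cn in required) {
    if (!cmap[[cn]] %in% colnames(raw)) {
      stop("missing mandatory column: ", cmap[[cn]], call. = FALSE)
    }
  }
  get <- function(cn) {
    if (cmap[[cn]] %in% colnames(raw)) raw[[cmap[[cn]]]] else
      rep(NA_character_, nrow(raw))
  }
  out <- data.frame(index = get("index"), strain = get("strain"),
                    clade = get("clade"), cluster = get("cluster"),
                    rap_dna = get("rap_dna"), rap_protein = get("rap_protein"),
                    autoinducer = get("autoinducer"),
                    phr_protein = get("phr_protein"), phr_dna = get("phr_dna"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$index)) stop("duplicate index values", call. = FALSE)
  out$orphan <- is.na(out$autoinducer) | out$autoinducer == ""
  attr(out, "clade_counts") <- table(out$clade)
  out
}

#' Write a receptor database table
#' @param db data.frame as returned by [load_rap_database()].
#' @param path Output TSV path.
#' @export
write_rap_database <- function(db, path) {
  cols <- intersect(names(.default_db_columns), colnames(db))
  utils::write.table(db[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Flatten a cassette table for writing
#'
#' Collapses the `phr` list-column into comma-separated coordinate and
#' score fields.
#'
#' @param cassettes A `cassette_table`.
#' @return Plain data.frame with only atomic columns.
#' @export
flatten_cassettes <- function(cassettes) {
  flat <- cassettes[, setdiff(colnames(cassettes), "phr"), drop = FALSE]
  class(flat) <- "data.frame"
  collapse <- function(f) vapply(cassettes$phr, function(p)
    paste(f(p), collapse = ","), "")
  flat$phr_starts <- collapse(function(p) p$start)
  flat$phr_ends <- collapse(function(p) p$end)
  flat$phr_scores <- collapse(function(p) round(p$signal_score, 4))
  flat$phr_proteins <- collapse(function(p) p$protein)
  flat
}

#' Write a cassette table as TSV
#' @param cassettes A `cassette_table`.
#' @param path Output path.
#' @export
write_cassette_table <- function(cassettes, path) {
  utils::write.table(flatten_cassettes(cassettes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export mined cassette features as GFF3
#'
#' Writes receptor and propeptide features (1-based inclusive coordinates,
#' strand-aware) through rtracklayer.
#'
#' @param cassettes A `cassette_table`.
#' @param path Output `.gff3` path.
#' @export
write_cassette_gff3 <- function(cassettes, path) {
  feats <- list()
  for (i in seq_len(nrow(cassettes))) {
    r <- cassettes[i, ]
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = r$contig, start = r$rap_start, end = r$rap_end,
      strand = r$strand, type = "receptor_gene",
      ID = sprintf("rap_%03d", i), stringsAsFactors = FALSE)
    phr <- r$phr[[1L]]
    for (j in seq_len(nrow(phr))) {
      feats[[length(feats) + 1L]] <- data.frame(
        seqnames = r$contig, start = phr$start[j], end = phr$end[j],
        strand = phr$strand[j], type = "propeptide_gene",
        ID = sprintf("phr_%03d_%d", i, j), stringsAsFactors = FALSE)
    }
  }
  if (!length(feats)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, type = df$type, ID = df$ID)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
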