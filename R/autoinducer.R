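# Autoinducer calling and repeat/duplication detection.
#
# Mature Phr signals are 5- or 6-residue peptides carved from the C-terminal
# part of the propeptide. Within a cluster the autoinducer window is the most
# conserved stretch of the aligned propeptides; singletons fall back to
# similarity with a library of known autoinducers. Intragenic duplications of
# the autoinducer coding region are detected as >= 2 non-overlapping windows
# within a mismatch budget of a common consensus.

.aln_matrix <- function(aligned) {
  do.call(rbind, strsplit(unname(aligned), ""))
}

# modal non-gap residue of a column and its frequency (over all rows)
.column_consensus <- function(col) {
  col <- col[col != "-"]
  if (!length(col)) return(list(residue = "-", freq = 0))
  tab <- sort(table(col), decreasing = TRUE)
  list(residue = names(tab)[1L], freq = as.numeric(tab[1L]))
}

#' Call a putative autoinducer peptide for a propeptide group
#'
#' Slides 5- and 6-residue windows over the aligned propeptides and scores
#' each window by mean per-column conservation (fraction of rows carrying the
#' modal residue) plus, when a library of known autoinducers is supplied,
#' similarity of the window consensus to the closest library peptide of the
#' same length (equal weights). The highest-scoring window wins; ties are
#' resolved toward the C-terminus (the typical location of the mature
#' peptide; configurable). A single propeptide is called purely by library
#' similarity (`"known-motif"` method).
#'
#' A confidence below 0.5 flags the call as low-confidence rather than
#' failing.
#'
#' @param prepeptides Character vector of propeptide sequences (aligned if of
#'   equal length, otherwise aligned internally with [align_proteins()]).
#' @param known_peptides Character vector of known mature autoinducers
#'   (lengths 5 or 6). Required when `prepeptides` is a singleton.
#' @param motif_len Window widths to consider.
#' @param tie `"cterm"` (default) or `"nterm"` tie-breaking.
#' @return List: `peptide` (window consensus), `position` (start column),
#'   `width`, `confidence`, `method`, `low_confidence`.
#' @export
call_autoinducer <- function(prepeptides, known_peptides = character(),
                             motif_len = c(5L, 6L),
                             tie = c("cterm", "nterm")) {
  tie <- match.arg(tie)
  if (length(prepeptides) == 0) stop("empty propeptide group", call. = FALSE)
  singleton <- length(prepeptides) == 1L
  if (singleton && !length(known_peptides)) {
    stop("a singleton group requires a known-peptide library", call. = FALSE)
  }
  aligned <- if (singleton || length(unique(nchar(prepeptides))) == 1L) {
    prepeptides
  } else {
    align_proteins(prepeptides)
  }
  m <- .aln_matrix(aligned)
  W <- ncol(m)
  best <- NULL
  for (w in sort(as.integer(motif_len))) {
    if (W < w) next
    lib_w <- known_peptides[nchar(known_peptides) == w]
    for (j in seq_len(W - w + 1L)) {
      cols <- lapply(j:(j + w - 1L), function(k) .column_consensus(m[, k]))
      if (any(vapply(cols, function(x) x$residue == "-", TRUE))) next
      cons_frac <- mean(vapply(cols, function(x) x$freq, 0) / nrow(m))
      consensus <- paste(vapply(cols, function(x) x$residue, ""), collapse = "")
      sim <- if (length(lib_w)) {
        max(vapply(lib_w, function(p) {
          mean(strsplit(consensus, "")[[1]] == strsplit(p, "")[[1]])
        }, 0))
      } else 0
      score <- if (length(known_peptides)) 0.5 * cons_frac + 0.5 * sim else cons_frac
      cand <- list(peptide = consensus, position = j, width = w,
                   confidence = score)
      # ties: toward the configured terminus (window end), then the longer
      # (hexapeptide) form
      better <- if (is.null(best)) TRUE
      else if (score > best$confidence + 1e-12) TRUE
      else if (score < best$confidence - 1e-12) FALSE
      else {
        e_cand <- j + w; e_best <- best$position + best$width
        if (e_cand != e_best) {
          if (tie == "cterm") e_cand > e_best else e_cand < e_best
        } else w > best$width
      }
      if (better) best <- cand
    }
  }
  if (is.null(best)) stop("no scoreable window in propeptide group", call. = FALSE)
  best$method <- if (singleton) "known-motif" else "conservation"
  best$low_confidence <- best$confidence < 0.5
  best
}

.hamming <- function(a, b) sum(a != b)

# degenerate bracket pattern over the copies, e.g. "E[K/R]PVGT"
.degenerate_pattern <- function(copies_mat) {
  paste(apply(copies_mat, 2L, function(col) {
    u <- sort(unique(col))
    if (length(u) == 1L) u else paste0("[", paste(u, collapse = "/"), "]")
  }), collapse = "")
}

#' Detect intragenic autoinducer repeats
#'
#' Finds maximal sets of at least two non-overlapping windows of width
#' `motif_len` that each lie within `max_mismatch` substitutions of the set's
#' majority consensus. Every window start is tried as a seed; additional
#' copies are collected greedily left to right. The best report (most copies,
#' then fewest total mismatches, then leftmost) is returned.
#'
#' @param prepeptide Propeptide protein string (length >= `2 * motif_len`).
#' @param motif_len Repeat width, 5 or 6.
#' @param max_mismatch Maximum substitutions between a copy and the consensus.
#' @param anchor Optional known motif: when supplied, copies are the
#'   non-overlapping windows within `max_mismatch` of this fixed motif
#'   (greedy, fewest mismatches first) instead of a de-novo consensus.
#' @return `NULL` when no repeat is found, otherwise a list of class
#'   `repeat_report`: `motif` (consensus), `copies` (data.frame `position`,
#'   `mismatches`), `n_copies`, `max_pairwise_mismatch`, `pattern`
#'   (degenerate bracket notation).
#' @export
detect_intragenic_repeats <- function(prepeptide, motif_len = 6L,
                                      max_mismatch = 0L, anchor = NULL) {
  stopifnot(motif_len %in% c(5L, 6L))
  if (!is.null(anchor)) stopifnot(nchar(anchor) == motif_len)
  L <- nchar(prepeptide)
  if (L < 2L * motif_len) return(NULL)
  aa <- strsplit(prepeptide, "")[[1]]
  starts <- seq_len(L - motif_len + 1L)
  win <- t(vapply(starts, function(i) aa[i:(i + motif_len - 1L)],
                  character(motif_len)))
  # majority consensus; ties resolve to the seed window's residue when it is
  # among the tied majority (keeps the growing consensus stable)
  consensus_of <- function(mat, prefer = NULL) {
    vapply(seq_len(ncol(mat)), function(j) {
      tab <- table(mat[, j])
      top <- names(tab)[tab == max(tab)]
      if (!is.null(prefer) && prefer[j] %in% top) prefer[j] else sort(top)[1L]
    }, character(1))
  }
  make_report <- function(members, cons) {
    dists <- apply(win[members, , drop = FALSE], 1L, .hamming, b = cons)
    mat <- win[members, , drop = FALSE]
    pw <- if (length(members) > 1L) {
      max(utils::combn(length(members), 2L, function(ix)
        .hamming(mat[ix[1L], ], mat[ix[2L], ])))
    } else 0L
    structure(list(
      motif = paste(cons, collapse = ""),
      copies = data.frame(position = starts[members],
                          mismatches = as.integer(dists)),
      n_copies = length(members),
      total_mismatches = as.integer(sum(dists)),
      max_pairwise_mismatch = as.integer(pw),
      pattern = .degenerate_pattern(mat)), class = "repeat_report")
  }
  if (!is.null(anchor)) {
    cons <- strsplit(anchor, "")[[1]]
    d <- apply(win, 1L, .hamming, b = cons)
    cand <- order(d, starts)
    cand <- cand[d[cand] <= max_mismatch]
    members <- integer()
    taken_lo <- integer(); taken_hi <- integer()
    for (j in cand) {
      lo <- starts[j]; hi <- starts[j] + motif_len - 1L
      if (!length(taken_lo) || all(hi < taken_lo | lo > taken_hi)) {
        members <- c(members, j)
        taken_lo <- c(taken_lo, lo); taken_hi <- c(taken_hi, hi)
      }
    }
    if (length(members) < 2L) return(NULL)
    return(make_report(sort(members), cons))
  }
  best <- NULL
  for (seed in seq_along(starts)) {
    members <- seed
    cons <- win[seed, ]
    last_end <- starts[seed] + motif_len - 1L
    for (j in seq_along(starts)) {
      if (starts[j] <= last_end) next
      if (.hamming(win[j, ], cons) <= max_mismatch) {
        members <- c(members, j)
        cons <- consensus_of(win[members, , drop = FALSE], prefer = win[seed, ])
        last_end <- starts[j] + motif_len - 1L
      }
    }
    if (length(members) < 2L) next
    # final consistency against the settled consensus
    cons <- consensus_of(win[members, , drop = FALSE], prefer = win[seed, ])
    dists <- apply(win[members, , drop = FALSE], 1L, .hamming, b = cons)
    members <- members[dists <= max_mismatch]
    if (length(members) < 2L) next
    cons <- consensus_of(win[members, , drop = FALSE], prefer = win[seed, ])
    dists <- apply(win[members, , drop = FALSE], 1L, .hamming, b = cons)
    total_mm <- sum(dists)
    better <- is.null(best) ||
      length(members) > best$n_copies ||
      (length(members) == best$n_copies && total_mm < best$total_mismatches)
    if (better) {
      mat <- win[members, , drop = FALSE]
      pw <- if (length(members) > 1L) {
        max(utils::combn(length(members), 2L, function(ix)
          .hamming(mat[ix[1L], ], mat[ix[2L], ])))
      } else 0L
      best <- structure(list(
        motif = paste(cons, collapse = ""),
        copies = data.frame(position = starts[members],
                            mismatches = as.integer(dists)),
        n_copies = length(members),
        total_mismatches = as.integer(total_mm),
        max_pairwise_mismatch = as.integer(pw),
        pattern = .degenerate_pattern(mat)), class = "repeat_report")
    }
  }
  best
}

#' Detect whole-gene propeptide duplication in a cassette
#'
#' A cassette whose receptor is followed by two or more accepted propeptide
#' ORFs carries a phr gene duplication. The divergence reported is the
#' normalised Hamming distance between the autoinducer windows of the first
#' two propeptides after pairwise alignment (the window is located with
#' [call_autoinducer()] on the aligned pair).
#'
#' @param cassette One row of a `cassette_table` (with its `phr` list-column).
#' @param motif_len Autoinducer window widths passed to the caller.
#' @return List: `duplication` (logical), `divergence` (in `[0,1]`, `NA` when
#'   not duplicated), `peptides` (the two aligned autoinducer windows).
#' @export
detect_phr_gene_duplication <- function(cassette, motif_len = c(5L, 6L)) {
  phr <- cassette$phr[[1L]]
  if (is.null(phr) || nrow(phr) < 2L) {
    return(list(duplication = FALSE, divergence = NA_real_,
                peptides = character()))
  }
  pair <- phr$protein[1:2]
  aligned <- align_proteins(pair)
  call <- call_autoinducer(aligned, motif_len = motif_len)
  m <- .aln_matrix(aligned)
  idx <- call$position:(call$position + call$width - 1L)
  w1 <- m[1L, idx]; w2 <- m[2L, idx]
  list(duplication = TRUE,
       divergence = mean(w1 != w2),
       peptides = c(paste(w1, collapse = ""), paste(w2, collapse = "")))
}
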