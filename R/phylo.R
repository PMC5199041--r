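# Protein alignment, neighbor-joining trees, newick I/O, monophyletic
# same-peptide clustering, and phylogenetic-diversity fractions.
#
# Multiple alignment is delegated to mafft (the field-standard aligner);
# two-sequence inputs use global Needleman-Wunsch (BLOSUM62, affine gaps) via
# Biostrings. Maximum-likelihood inference is deliberately not provided:
# externally computed trees are imported as newick, and NJ with bootstrap is
# the self-contained default; all downstream analyses are tree-agnostic.

#' Align protein sequences
#'
#' Two sequences are aligned by global pairwise alignment (BLOSUM62, gap open
#' 10, gap extend 0.5); larger sets are passed to the mafft executable with
#' default (`--auto`) parameters. Row order is preserved and removing gaps
#' from any row returns the input sequence unchanged.
#'
#' @param sequences Named character vector of protein sequences (>= 2,
#'   unique names; unnamed input is labelled `seq1..n`).
#' @param method `"auto"` (pairwise for 2, mafft otherwise), `"mafft"`, or
#'   `"pairwise"` (2 sequences only).
#' @return Named character vector of aligned rows (equal lengths, gap `-`).
#' @export
align_proteins <- function(sequences, method = c("auto", "mafft", "pairwise")) {
  method <- match.arg(method)
  if (length(sequences) < 2L) stop("need at least two sequences", call. = FALSE)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  if (anyDuplicated(names(sequences))) stop("duplicate sequence ids", call. = FALSE)
  if (method == "auto") {
    method <- if (length(sequences) == 2L) "pairwise" else "mafft"
  }
  if (method == "pairwise") {
    if (length(sequences) != 2L) stop("pairwise method needs exactly 2 sequences",
                                      call. = FALSE)
    pa <- Biostrings::pairwiseAlignment(sequences[1L], sequences[2L],
                                        type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    out <- c(as.character(Biostrings::alignedPattern(pa)),
             as.character(Biostrings::alignedSubject(pa)))
    names(out) <- names(sequences)
    return(out)
  }
  if (Sys.which("mafft") == "") stop("mafft not found on PATH", call. = FALSE)
  wd <- tempfile("mafft"); dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  in_fa <- file.path(wd, "in.fa"); out_fa <- file.path(wd, "out.fa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), in_fa)
  status <- system2("mafft", c("--quiet", "--auto", in_fa),
                    stdout = out_fa, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status, call. = FALSE)
  aln <- Biostrings::readAAStringSet(out_fa)
  out <- toupper(as.character(aln))
  names(out) <- sub("\\s.*$", "", names(out))
  out[names(sequences)]
}

#' Remove gaps from aligned rows
#' @param aligned Character vector of aligned sequences.
#' @return The rows with all `-` removed.
#' @export
ungap <- function(aligned) {
  out <- gsub("-", "", aligned, fixed = TRUE)
  names(out) <- names(aligned)
  out
}

# p-distance with gap sites pairwise-deleted, via one-hot cross-products
.p_distance <- function(mat) {
  n <- nrow(mat)
  nongap <- (mat != "-") * 1
  shared <- tcrossprod(nongap)            # sites non-gap in both rows
  syms <- setdiff(unique(as.vector(mat)), "-")
  matches <- matrix(0, n, n)
  for (s in syms) matches <- matches + tcrossprod((mat == s) * 1)
  d <- ifelse(shared > 0, 1 - matches / pmax(shared, 1), 1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds an NJ tree from p-distances (gap sites pairwise-deleted) and
#' attaches nonparametric bootstrap support (column resampling) as node
#' labels in `[0, 100]`. Negative NJ branch lengths are clamped to zero.
#' Deterministic for a fixed seed.
#'
#' @param alignment Named character vector of aligned rows (>= 3 sequences).
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed Integer RNG seed for the resampling.
#' @return An [ape::phylo] tree with `node.label` bootstrap supports.
#' @export
build_nj_tree <- function(alignment, n_bootstrap = 100L, seed = 1L) {
  if (length(alignment) < 3L) stop("need at least 3 sequences", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L) {
    stop("rows are not aligned (unequal lengths)", call. = FALSE)
  }
  mat <- .aln_matrix(alignment)
  rownames(mat) <- names(alignment)
  nj_fun <- function(x) {
    tr <- ape::nj(stats::as.dist(.p_distance(x)))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  }
  tree <- nj_fun(mat)
  if (n_bootstrap > 0) {
    set.seed(seed)
    bp <- ape::boot.phylo(tree, mat, nj_fun, B = n_bootstrap,
                          quiet = TRUE, rooted = FALSE)
    tree$node.label <- round(100 * bp / n_bootstrap)
  }
  tree
}

#' Read a newick tree
#'
#' Accepts a newick string or a file path; node labels (e.g. bootstrap
#' supports) are preserved. Unbalanced parentheses are reported with the
#' offending character position.
#'
#' @param text Newick string (containing `(`...`;`) or path to a file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(text) {
  is_string <- grepl("\\(", text) && grepl(";", text)
  nwk <- if (is_string) text else paste(readLines(text, warn = FALSE),
                                        collapse = "")
  depth <- 0L
  chars <- strsplit(nwk, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at position ", i, call. = FALSE)
  }
  if (depth != 0L) stop("unbalanced '(' (", depth, " unclosed)", call. = FALSE)
  tree <- ape::read.tree(text = nwk)
  if (is.null(tree)) stop("newick parse failure", call. = FALSE)
  tree
}

#' Write a tree as newick
#' @param tree An [ape::phylo] object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

#' Cluster tree leaves into maximal monophyletic same-peptide groups
#'
#' Partitions the leaves into maximal clades whose members all encode the
#' same autoinducer peptide. Leaves without a peptide (orphans, `NA` or
#' empty) either merge when they form a monophyletic group
#' (`merge_orphans = TRUE`, the default) or become singleton clusters.
#' Cluster membership is invariant to leaf order.
#'
#' @param tree A rooted or unrooted [ape::phylo] tree (unrooted trees are
#'   treated via their internal representation root).
#' @param peptides Named character vector mapping every leaf label to its
#'   peptide (`NA`/`""` for orphans).
#' @param merge_orphans Merge monophyletic orphan leaves into one cluster.
#' @return data.frame: `cluster_id`, `peptide` (`NA` for orphan clusters),
#'   `n_members`, `mean_depth` (mean distance from the cluster ancestor to
#'   its leaves), and a `members` list-column.
#' @export
peptide_monophyletic_clusters <- function(tree, peptides,
                                          merge_orphans = TRUE) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(peptides))
  if (length(missing)) {
    stop("unmapped leaves: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  lab <- as.character(peptides[tips])
  orphan <- is.na(lab) | lab == ""
  lab[orphan] <- if (merge_orphans) "\r_orphan" else paste0("\r_none_", tips[orphan])
  n_tip <- length(tips)
  n_node <- tree$Nnode
  # label set per node: NA marks "impure"; computed in edge postorder
  node_lab <- character(n_tip + n_node)
  node_lab[seq_len(n_tip)] <- lab
  pure <- rep(TRUE, n_tip + n_node)
  pure[(n_tip + 1L):(n_tip + n_node)] <- NA
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]; ch <- edges[k, 2L]
    ch_pure <- pure[ch]; ch_lab <- node_lab[ch]
    if (is.na(pure[p])) {  # first child seen
      pure[p] <- ch_pure
      node_lab[p] <- ch_lab
    } else if (!pure[p] || !ch_pure || node_lab[p] != ch_lab) {
      pure[p] <- FALSE
    }
  }
  parent <- integer(n_tip + n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- n_tip + 1L
  cluster_root <- vapply(seq_len(n_tip), function(leaf) {
    node <- leaf
    while (node != root && pure[parent[node]]) node <- parent[node]
    node
  }, integer(1))
  depths <- ape::node.depth.edgelength(tree)
  groups <- split(seq_len(n_tip), cluster_root)
  rows <- lapply(groups, function(leaves) {
    anc <- cluster_root[leaves[1L]]
    pep <- node_lab[leaves[1L]]
    data.frame(peptide = if (startsWith(pep, "\r")) NA_character_ else pep,
               n_members = length(leaves),
               mean_depth = mean(depths[leaves] - depths[anc]),
               first_member = min(tips[leaves]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(groups, function(leaves) sort(tips[leaves]))
  out <- out[order(out$first_member), , drop = FALSE]
  out$cluster_id <- sprintf("C%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("cluster_id", "peptide", "n_members", "mean_depth", "members")]
}

#' Phylogenetic-diversity fraction of a leaf subset
#'
#' Faith-style diversity: the summed length of all branches on the paths from
#' the tree root to the subset leaves, divided by the total branch length of
#' the tree. With this (rooted, pendant-edge-inclusive) convention a single
#' leaf on a star tree of `n` equal branches scores `1/n` and the full leaf
#' set scores 1; the fraction is monotone nondecreasing in the subset.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param leaf_subset Nonempty character vector of leaf labels.
#' @return Fraction in `[0, 1]`.
#' @export
phylo_diversity_fraction <- function(tree, leaf_subset) {
  if (length(leaf_subset) == 0) stop("empty leaf subset", call. = FALSE)
  unknown <- setdiff(leaf_subset, tree$tip.label)
  if (length(unknown)) stop("unknown leaves: ",
                            paste(utils::head(unknown, 5), collapse = ", "),
                            call. = FALSE)
  n_tip <- length(tree$tip.label)
  in_subset <- logical(n_tip + tree$Nnode)
  in_subset[match(leaf_subset, tree$tip.label)] <- TRUE
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    if (in_subset[edges[k, 2L]]) in_subset[edges[k, 1L]] <- TRUE
  }
  spanned <- in_subset[tree$edge[, 2L]]
  sum(tree$edge.length[spanned]) / sum(tree$edge.length)
}
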