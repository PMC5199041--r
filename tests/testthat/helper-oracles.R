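# Independent oracles and small fixture builders used across the suite.

AA20_T <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_protein_str <- function(n) {
  paste(c("M", sample(AA20_T, n - 1, replace = TRUE)), collapse = "")
}

# independent translation oracle: Biostrings on each frame
biostrings_translate_frame <- function(dna, offset, rev = FALSE) {
  s <- Biostrings::DNAString(dna)
  if (rev) s <- Biostrings::reverseComplement(s)
  s <- Biostrings::subseq(s, start = offset + 1)
  n <- (length(s) %/% 3) * 3
  if (n == 0) return("")
  as.character(Biostrings::translate(Biostrings::subseq(s, 1, n),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# brute-force Needleman-Wunsch (match via BLOSUM62, affine-ish linear gap)
# used only to count gaps/matched columns on tiny inputs
nw_align_oracle <- function(a, b, gap = -4) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  M[, 1] <- gap * (0:n); M[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    M[i + 1, j + 1] <- max(M[i, j] + S[A[i], B[j]],
                           M[i, j + 1] + gap, M[i + 1, j] + gap)
  }
  M[n + 1, m + 1]
}

# exhaustive minimum-change parsimony for a binary trait on a rooted tree
brute_force_parsimony <- function(tree, states, root_state = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  s_tip <- as.integer(states[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^n_node - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(n_node)]
    if (!is.null(root_state) && internal[1] != root_state) next
    full <- c(s_tip, internal)
    if (anyNA(full[tree$edge[, 2]]) || anyNA(full[tree$edge[, 1]])) {
      # unknown tips: minimise over their states too
      na_ix <- which(is.na(full))
      sub_best <- Inf
      for (m2 in 0:(2^length(na_ix) - 1)) {
        full2 <- full
        full2[na_ix] <- as.integer(intToBits(m2))[seq_along(na_ix)]
        sub_best <- min(sub_best,
                        sum(full2[tree$edge[, 1]] != full2[tree$edge[, 2]]))
      }
      best <- min(best, sub_best)
    } else {
      best <- min(best, sum(full[tree$edge[, 1]] != full[tree$edge[, 2]]))
    }
  }
  best
}

# spanned-branch-length oracle: sum of edges whose child subtree holds a
# subset leaf, found by explicit leaf enumeration per edge
pd_fraction_oracle <- function(tree, subset) {
  total <- sum(tree$edge.length)
  spanned <- 0
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    leaves <- if (child <= length(tree$tip.label)) {
      tree$tip.label[child]
    } else {
      ape::extract.clade(tree, child)$tip.label
    }
    if (any(leaves %in% subset)) spanned <- spanned + tree$edge.length[k]
  }
  spanned / total
}

# maximal monophyletic same-label clustering by brute force over all clades
cluster_oracle <- function(tree, labels) {
  tips <- tree$tip.label
  lab <- labels[tips]
  clades <- list()
  for (node in (length(tips) + 1):(length(tips) + tree$Nnode)) {
    clades[[length(clades) + 1]] <- ape::extract.clade(tree, node)$tip.label
  }
  for (t in tips) clades[[length(clades) + 1]] <- t
  pure <- Filter(function(cl) length(unique(lab[cl])) == 1, clades)
  # keep maximal pure clades
  keep <- Filter(function(cl) {
    !any(vapply(pure, function(other)
      length(other) > length(cl) && all(cl %in% other), TRUE))
  }, pure)
  sorted <- lapply(keep, sort)
  unique(sorted)
}

# tiny simulated dataset shared by several tests (cached per session)
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_strains = 4, n_species = 2,
                                            mobile_cluster_pool = 10,
                                            mean_raps_per_strain = 6,
                                            core_clusters_per_species = 4,
                                            orphan_core_per_species = 1,
                                            phr_duplication_prob = 0.15,
                                            seed = 42))
    }
    cache
  }
})
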