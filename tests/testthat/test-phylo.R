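test_that("pairwise alignment matches the dynamic-programming score and gap count", {
  a <- align_proteins(c(x = "MKLV", y = "MKV"))
  expect_equal(unname(nchar(a[1])), unname(nchar(a[2])))
  expect_equal(sum(strsplit(a[["y"]], "")[[1]] == "-"), 1L)
  cols <- cbind(strsplit(a[[1]], "")[[1]], strsplit(a[[2]], "")[[1]])
  expect_equal(sum(cols[, 1] == cols[, 2]), 3L)

  ident <- align_proteins(c(a = "MKLVW", b = "MKLVW"))
  expect_false(any(grepl("-", ident)))
})

test_that("ungapping aligned rows returns the inputs exactly", {
  set.seed(20)
  for (rep in 1:5) {
    seqs <- stats::setNames(replicate(4, random_protein_str(sample(30:60, 1))),
                            paste0("s", 1:4))
    aln <- align_proteins(seqs)
    expect_equal(unname(nchar(aln)), rep(nchar(aln[1]), 4),
                 ignore_attr = TRUE)
    expect_equal(ungap(aln), seqs)
  }
  expect_error(align_proteins(c(a = "MK", a = "MV")), "duplicate")
  expect_error(align_proteins(c(a = "MK")), "two")
})

test_that("NJ recovers the generating topology from additive distances", {
  # substitutions at disjoint sites make hamming p-distances exactly additive
  base <- strsplit(strrep("A", 100), "")[[1]]
  mk <- function(sites) { s <- base; s[sites] <- "W"; paste(s, collapse = "") }
  seqs <- c(A = mk(1:4), B = mk(11:16), C = mk(c(31:40, 51:54)),
            D = mk(c(31:40, 61:68)))
  tree <- build_nj_tree(seqs, n_bootstrap = 10, seed = 1)
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("A", "B")))
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("C", "D")))
  # NJ reproduces additive input distances
  d_in <- rapphr:::.p_distance(do.call(rbind, strsplit(unname(seqs), "")))
  d_out <- ape::cophenetic.phylo(tree)[c("A","B","C","D"), c("A","B","C","D")]
  dimnames(d_in) <- dimnames(d_out)
  expect_equal(d_out, d_in, tolerance = 1e-9)
})

test_that("identical sequences give a zero-length star and reruns are identical", {
  seqs <- stats::setNames(rep("MKLVWAAC", 4), paste0("s", 1:4))
  tree <- build_nj_tree(seqs, n_bootstrap = 0)
  expect_true(all(tree$edge.length == 0))
  set.seed(99)
  seqs2 <- stats::setNames(replicate(8, random_protein_str(40)), paste0("t", 1:8))
  t1 <- write_newick(build_nj_tree(seqs2, n_bootstrap = 20, seed = 7))
  t2 <- write_newick(build_nj_tree(seqs2, n_bootstrap = 20, seed = 7))
  expect_identical(t1, t2)
  expect_error(build_nj_tree(seqs2[1:2]), "3")
})

test_that("newick round-trips and parse errors carry a position", {
  tree <- read_newick("(A:1,(B:1,C:1):2);")
  expect_equal(ape::Ntip(tree), 3L)
  expect_equal(tree$Nnode, 2L)
  expect_equal(sort(tree$edge.length, decreasing = TRUE)[1], 2)
  set.seed(21)
  for (rep in 1:20) {
    t0 <- ape::rtree(sample(4:15, 1))
    canon <- write_newick(t0)
    expect_identical(write_newick(read_newick(canon)), canon)
  }
  expect_error(read_newick("(A:1,(B:1);"), "unbalanced")
  expect_error(read_newick("(A:1))B;"), "position 6")
})

test_that("monophyletic same-peptide clustering matches the brute-force oracle", {
  tree <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  peptides <- c(A = "p1", B = "p1", C = "p2", D = "p1")
  cl <- peptide_monophyletic_clusters(tree, peptides)
  expect_equal(nrow(cl), 3L)
  expect_setequal(vapply(cl$members, paste, "", collapse = ","),
                  c("A,B", "C", "D"))
  expect_equal(length(unique(cl$peptide)), 2L)

  all_same <- peptide_monophyletic_clusters(tree, c(A = "p", B = "p",
                                                    C = "p", D = "p"))
  expect_equal(nrow(all_same), 1L)
  expect_error(peptide_monophyletic_clusters(tree, peptides[1:3]), "unmapped")

  set.seed(22)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    peps <- stats::setNames(sample(c("x", "y", "z"), n, replace = TRUE),
                            tr$tip.label)
    got <- lapply(peptide_monophyletic_clusters(tr, peps)$members, sort)
    want <- cluster_oracle(tr, peps)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("cluster membership is invariant to leaf order", {
  set.seed(23)
  tr <- ape::rtree(8)
  peps <- stats::setNames(sample(c("x", "y"), 8, replace = TRUE), tr$tip.label)
  c1 <- peptide_monophyletic_clusters(tr, peps)
  tr2 <- ape::reorder.phylo(ape::rotateConstr(tr, rev(tr$tip.label)))
  c2 <- peptide_monophyletic_clusters(tr2, peps)
  expect_setequal(unname(vapply(c1$members, paste, "", collapse = ",")),
                  unname(vapply(c2$members, paste, "", collapse = ",")))
})

test_that("diversity fraction matches the edge-enumeration oracle and is monotone", {
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  expect_equal(phylo_diversity_fraction(star, "A"), 1 / 5)
  expect_equal(phylo_diversity_fraction(star, LETTERS[1:5]), 1)
  expect_error(phylo_diversity_fraction(star, character()), "empty")
  expect_error(phylo_diversity_fraction(star, "Z"), "unknown")
  set.seed(24)
  for (rep in 1:15) {
    tr <- ape::rtree(sample(5:12, 1))
    sub <- sample(tr$tip.label, sample(1:ape::Ntip(tr), 1))
    expect_equal(phylo_diversity_fraction(tr, sub),
                 pd_fraction_oracle(tr, sub), tolerance = 1e-12)
    sub2 <- unique(c(sub, sample(tr$tip.label, 2)))
    expect_gte(phylo_diversity_fraction(tr, sub2),
               phylo_diversity_fraction(tr, sub))
  }
})
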