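make_group_with_motif <- function(n, motif, at = 30, len = 50) {
  vapply(seq_len(n), function(i) {
    p <- strsplit(random_protein_str(len), "")[[1]]
    p[at:(at + nchar(motif) - 1)] <- strsplit(motif, "")[[1]]
    paste(p, collapse = "")
  }, character(1))
}

test_that("a conserved window among diverged propeptides is called", {
  set.seed(10)
  grp <- make_group_with_motif(6, "ERPVGT")
  call <- call_autoinducer(grp)
  expect_equal(call$peptide, "ERPVGT")
  expect_equal(call$method, "conservation")
  expect_false(call$low_confidence)
})

test_that("identical sequences give the C-terminal-most maximal window at confidence 1", {
  grp <- rep("MKKLLAVSSAERPVGT", 3)
  call <- call_autoinducer(grp, motif_len = 6L)
  expect_equal(call$confidence, 1.0)
  expect_equal(call$position, nchar(grp[1]) - 6L + 1L)  # rightmost
  expect_equal(call$peptide, "ERPVGT")
})

test_that("a singleton is called through the known-peptide library", {
  set.seed(11)
  single <- make_group_with_motif(1, "GRAIF", at = 40, len = 50)
  call <- call_autoinducer(single, known_peptides = c("ERPVGT", "GRAIF"))
  expect_equal(call$peptide, "GRAIF")
  expect_equal(call$method, "known-motif")
  expect_error(call_autoinducer(single), "library")
  expect_error(call_autoinducer(character()), "empty")
})

test_that("the returned window attains the exhaustive maximum score", {
  set.seed(12)
  for (rep in 1:10) {
    grp <- replicate(4, random_protein_str(60))
    call <- call_autoinducer(grp)
    m <- do.call(rbind, strsplit(grp, ""))
    best <- 0
    for (w in c(5L, 6L)) {
      for (j in seq_len(ncol(m) - w + 1)) {
        cons <- mean(vapply(j:(j + w - 1), function(k)
          max(table(m[, k])) / nrow(m), 0))
        best <- max(best, cons)
      }
    }
    expect_equal(call$confidence, best, tolerance = 1e-12)
  }
})

test_that("exact and diverged intragenic repeats are reported with patterns", {
  p1 <- paste0("MKKLAVALSGTRAD", "ERPVGT", "QN", "ERPVGT", "W")
  r1 <- detect_intragenic_repeats(p1, motif_len = 6L, max_mismatch = 0L)
  expect_equal(r1$n_copies, 2L)
  expect_equal(r1$motif, "ERPVGT")
  expect_equal(r1$copies$mismatches, c(0L, 0L))

  p2 <- paste0("MKKLAVALSGTRAD", "ERPVGT", "QN", "EKPVGT", "W")
  expect_null(detect_intragenic_repeats(p2, motif_len = 6L, max_mismatch = 0L))
  r2 <- detect_intragenic_repeats(p2, motif_len = 6L, max_mismatch = 1L)
  expect_equal(r2$n_copies, 2L)
  expect_equal(sum(r2$copies$mismatches), 1L)
  expect_equal(r2$pattern, "E[K/R]PVGT")
})

test_that("anchored detection counts copies of a known motif", {
  p <- paste0("MKKLAVALSGTRAD", "ERPVGT", "QN", "EKPVGT", "DD", "ERPVGA")
  r <- detect_intragenic_repeats(p, motif_len = 6L, max_mismatch = 1L,
                                 anchor = "ERPVGT")
  expect_equal(r$n_copies, 3L)
  r0 <- detect_intragenic_repeats(p, motif_len = 6L, max_mismatch = 0L,
                                  anchor = "ERPVGT")
  expect_null(r0)  # only one exact copy
})

test_that("repeat detection has a low false-report rate on random sequence", {
  set.seed(13)
  hits <- vapply(1:1000, function(i) {
    p <- paste(sample(AA20_T, 60, replace = TRUE), collapse = "")
    !is.null(detect_intragenic_repeats(p, motif_len = 6L, max_mismatch = 0L))
  }, TRUE)
  expect_lt(mean(hits), 0.01)
})

test_that("a sequence with no self-similar window yields no report", {
  p <- paste(AA20_T, collapse = "")  # all windows pairwise-distinct
  expect_null(detect_intragenic_repeats(p, motif_len = 6L, max_mismatch = 2L))
})

test_that("phr gene duplication reports divergence of the autoinducer windows", {
  orphan <- data.frame(strain = "s", stringsAsFactors = FALSE)
  orphan$phr <- list(data.frame(protein = character(), stringsAsFactors = FALSE))
  expect_false(detect_phr_gene_duplication(orphan[1, ])$duplication)

  # two-phr cassettes straight from the generator
  spec <- list(cluster_id = "c", type = "core", orphan = FALSE,
               ancestor = random_protein_str(360), autoinducer = "ERPVGT",
               repeat_copies = 1L, repeat_mismatches = integer())
  as_cassette <- function(cass) {
    cs <- data.frame(strain = "s", stringsAsFactors = FALSE)
    cs$phr <- list(data.frame(
      protein = vapply(cass$phr, function(p) p$protein, ""),
      stringsAsFactors = FALSE))
    cs
  }
  set.seed(14)
  same <- synthesize_cassette(spec, sim_config(phr_pair_divergence = 0L),
                              n_phr = 2L)
  d0 <- detect_phr_gene_duplication(as_cassette(same)[1, ])
  expect_true(d0$duplication)
  expect_equal(d0$divergence, 0)

  # diverge the second autoinducer at an interior motif position (P -> W)
  div <- same
  p2 <- div$phr[[2]]$protein
  substr(p2, nchar(p2) - 3L, nchar(p2) - 3L) <- "W"
  div$phr[[2]]$protein <- p2
  d1 <- detect_phr_gene_duplication(as_cassette(div)[1, ])
  expect_true(d1$duplication)
  expect_equal(d1$divergence, 1 / 6, tolerance = 1e-9)
})
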