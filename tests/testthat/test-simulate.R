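test_that("strain trees are binary, ultrametric-scaled and species-monophyletic", {
  t1 <- simulate_strain_tree(1, 1, seed = 1)
  expect_equal(ape::Ntip(t1), 1L)
  t8 <- simulate_strain_tree(8, 2, seed = 1)
  expect_equal(ape::Ntip(t8), 8L)
  expect_true(all(t8$edge.length >= 0))
  sp <- attr(t8, "species")
  for (s in unique(sp)) {
    expect_true(ape::is.monophyletic(t8, names(sp)[sp == s]))
    expect_equal(sum(sp == s), 4L)
  }
  expect_identical(write_newick(simulate_strain_tree(8, 2, seed = 5)),
                   write_newick(simulate_strain_tree(8, 2, seed = 5)))
  expect_error(simulate_strain_tree(2, 3), "invalid config")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(propeptide_length_range = c(30, 80)), "35")
  expect_error(sim_config(background_gc = 1.2), "background_gc")
  expect_error(sim_config(mobile_gc_delta = -0.1), "delta")
  expect_error(sim_config(receptor_length_aa = 200), "300")
  expect_error(sim_config(n_strains = 2, n_species = 4), "n_strains")
})

test_that("zero mobile rate yields all-core repertoires at frequency 1", {
  cfg <- sim_config(n_strains = 8, n_species = 2,
                    core_clusters_per_species = 5, mean_raps_per_strain = 5,
                    orphan_core_per_species = 1, core_dropout = 0, seed = 2)
  tree <- simulate_strain_tree(8, 2, seed = 2)
  rep_ <- simulate_repertoires(tree, cfg)
  expect_true(all(rep_$plan$type == "core"))
  m <- build_association_matrix(rep_$plan)
  f <- per_species_frequency(m)
  expect_true(all(f$summary$mean_frequency == 1))
})

test_that("realized cassette counts track the configured mean across seeds", {
  means <- vapply(1:20, function(s) {
    tree <- simulate_strain_tree(100, 4, seed = s)
    rep_ <- simulate_repertoires(tree, sim_config(n_strains = 100,
                                                  n_species = 4, seed = s))
    nrow(rep_$plan) / 100
  }, 0)
  expect_gt(mean(means), 9)
  expect_lt(mean(means), 13)
})

test_that("replaying the event log from the root reproduces tip states", {
  tree <- simulate_strain_tree(12, 3, seed = 3)
  rep_ <- simulate_repertoires(tree, sim_config(n_strains = 12, n_species = 3,
                                                seed = 3))
  replay <- function(h) {
    n_tip <- length(tree$tip.label)
    states <- rep(NA_integer_, n_tip + tree$Nnode)
    states[n_tip + 1] <- h$root_state
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    for (k in rev(seq_len(nrow(edges)))) {
      p <- edges[k, 1]; ch <- edges[k, 2]
      flips <- sum(h$events$parent == p & h$events$child == ch)
      states[ch] <- (states[p] + flips) %% 2
    }
    stats::setNames(states[seq_len(n_tip)], tree$tip.label)
  }
  hs <- c(rep_$mobile_histories, rep_$trait_histories)
  expect_gt(sum(vapply(hs, function(h) nrow(h$events), 0)), 0)
  for (h in hs) expect_equal(replay(h), h$tip_states)
})

test_that("cassette synthesis honours divergence, repeats and feasibility", {
  cfg <- sim_config(seed = 4, within_cluster_divergence = 0)
  anc <- rapphr:::.random_protein(cfg$receptor_length_aa)
  spec <- list(cluster_id = "c", type = "core", orphan = FALSE,
               ancestor = anc, autoinducer = "ERPVGT",
               repeat_copies = 2L, repeat_mismatches = 0L)
  set.seed(1)
  cass <- synthesize_cassette(spec, cfg)
  expect_identical(cass$rap$protein, anc)  # divergence 0
  phr <- cass$phr[[1]]$protein
  expect_equal(lengths(regmatches(phr, gregexpr("ERPVGT", phr))), 2L)
  expect_gte(nchar(phr), 35L); expect_lte(nchar(phr), 120L)
  expect_equal(translate_cds(substring(cass$block, cass$rap$start,
                                       cass$rap$end)), anc)

  tight <- sim_config(seed = 4, propeptide_length_range = c(35, 50))
  spec3 <- spec; spec3$repeat_copies <- 3L; spec3$repeat_mismatches <- c(0L, 0L)
  expect_error(synthesize_cassette(spec3, tight), "infeasible")
})

test_that("planted coordinates, proteins and GC structure survive emission", {
  truth <- small_truth()
  cfg <- truth$config
  for (i in seq_len(nrow(truth$cassettes))) {
    r <- truth$cassettes[i, ]
    ctg <- truth$genomes[[r$strain]]$contigs[[1]]
    cds <- substring(ctg, r$rap_start, r$rap_end)
    if (r$strand == "-") cds <- reverse_complement(cds)
    expect_identical(translate_cds(cds), r$rap_protein)
    if (r$n_phr > 0) {
      ps <- as.integer(strsplit(r$phr_starts, ",")[[1]])
      pe <- as.integer(strsplit(r$phr_ends, ",")[[1]])
      pp <- strsplit(r$phr_proteins, ",")[[1]]
      for (j in seq_along(ps)) {
        pc <- substring(ctg, ps[j], pe[j])
        if (r$strand == "-") pc <- reverse_complement(pc)
        expect_identical(translate_cds(pc), pp[j])
      }
    }
    if (r$type == "mobile") {
      expect_lte(gc_fraction(cds), cfg$background_gc - cfg$mobile_gc_delta)
      island <- substring(ctg, r$island_start, r$island_end)
      expect_lte(gc_fraction(island),
                 cfg$background_gc - cfg$mobile_gc_delta)
    }
  }
})

test_that("emission is byte-identical under a fixed seed and writes truth files", {
  cfg <- sim_config(n_strains = 2, n_species = 1, mean_raps_per_strain = 4,
                    core_clusters_per_species = 3, orphan_core_per_species = 1,
                    mobile_cluster_pool = 5, seed = 9)
  d1 <- file.path(tempdir(), "emit1"); d2 <- file.path(tempdir(), "emit2")
  emit_genomes(simulate_dataset(cfg), d1)
  emit_genomes(simulate_dataset(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(all(c("strains.tsv", "cassettes_truth.tsv", "strain_tree.nwk",
                    "config.yaml") %in% f1))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # re-reading the FASTA reproduces recorded coordinates
  truth <- simulate_dataset(cfg)
  fa <- Biostrings::readDNAStringSet(file.path(d1, "genomes",
                                               paste0(truth$cassettes$strain[1],
                                                      ".fasta")))
  r <- truth$cassettes[1, ]
  cds <- substring(as.character(fa[[1]]), r$rap_start, r$rap_end)
  if (r$strand == "-") cds <- reverse_complement(cds)
  expect_identical(translate_cds(cds), r$rap_protein)
})

test_that("a cassette-free configuration yields genomes the miner leaves empty", {
  cfg <- sim_config(n_strains = 2, n_species = 1, mean_raps_per_strain = 0,
                    core_clusters_per_species = 0, orphan_core_per_species = 0,
                    mobile_cluster_pool = 3, seed = 10)
  truth <- simulate_dataset(cfg)
  expect_null(truth$cassettes)
  queries <- c(q = rapphr:::.random_protein(360))
  mined <- mine_genome(truth$genomes[[1]], queries)
  expect_equal(nrow(mined), 0L)
})

test_that("core clusters sit at higher per-species frequency than mobile ones", {
  set.seed(50)
  wins <- vapply(1:20, function(s) {
    tree <- simulate_strain_tree(12, 3, seed = 100 + s)
    rep_ <- simulate_repertoires(tree, sim_config(n_strains = 12,
                                                  n_species = 3,
                                                  seed = 100 + s))
    plan <- rep_$plan
    m <- build_association_matrix(plan)
    f <- per_species_frequency(m)$summary
    type_of <- tapply(plan$type, plan$cluster_id, function(x) x[1])
    core_f <- f$mean_frequency[type_of[f$cluster_id] == "core"]
    mob_f <- f$mean_frequency[type_of[f$cluster_id] == "mobile"]
    mean(core_f) > mean(mob_f)
  }, TRUE)
  expect_lt(binom.test(sum(wins), 20, alternative = "greater")$p.value, 0.01)
})
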