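# Synthetic-genome generator with full ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: strains on a species tree carry core cassettes (near-fixed within
# their species, at background GC) and mobile cassettes (gained and lost
# along branches of the strain tree, embedded in low-GC islands), receptor
# genes derive from diverged per-cluster ancestors of one family root,
# propeptide genes carry a PWM-drawn secretion signal and 1-3 exact or
# diverged autoinducer repeats, and binary regulatory traits evolve with a
# recorded per-branch gain/loss history. All outputs are pure functions of
# (config, seed).

#' Simulation configuration
#'
#' Defaults describe a Bacillus subtilis-group-like study population: ~11
#' cassettes per strain of which roughly half are species-core (including
#' ~2-3 orphan receptor clusters without a propeptide), the rest drawn from
#' a pool of low-frequency mobile clusters at GC depressed by
#' `mobile_gc_delta` relative to the 0.45 genomic background.
#'
#' @param n_strains Number of strains.
#' @param n_species Number of species (strains are split evenly).
#' @param core_clusters_per_species Core clusters carried by each species.
#' @param mobile_cluster_pool Size of the mobile-cluster pool.
#' @param mean_raps_per_strain Target mean cassettes per strain; the mobile
#'   gain rate is calibrated to meet it.
#' @param background_gc Genomic background GC fraction (0 < gc < 1).
#' @param mobile_gc_delta GC depression of mobile cassettes (>= 0).
#' @param repeat_copy_range Integer interval of autoinducer repeat copies.
#' @param repeat_mismatch_max Maximum substitutions of a diverged repeat copy.
#' @param receptor_length_aa Receptor protein length (>= 300).
#' @param propeptide_length_range Propeptide length interval within [35,120].
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @param orphan_core_per_species Expected orphan (propeptide-less) core
#'   clusters per strain.
#' @param phr_duplication_prob Probability a cassette carries two propeptide
#'   genes.
#' @param phr_pair_divergence Residues by which the second propeptide gene's
#'   autoinducer diverges from the first (duplication-and-divergence).
#' @param cassette_duplication_prob Probability a present cluster is carried
#'   twice by a strain (same-cluster-in-one-genome case).
#' @param cluster_divergence Protein divergence of cluster ancestors from the
#'   family root.
#' @param within_cluster_divergence Member divergence from the cluster
#'   ancestor.
#' @param mobile_loss_gain_ratio Loss rate / gain rate for mobile clusters.
#' @param core_dropout Per-strain dropout probability of a core cluster
#'   (capped so core clusters stay in >= 90% of each species' strains).
#' @param trait_rate Gain (= loss) rate of the binary regulatory traits.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 20L, n_species = 4L,
                       core_clusters_per_species = 6L,
                       mobile_cluster_pool = 25L,
                       mean_raps_per_strain = 11,
                       background_gc = 0.45, mobile_gc_delta = 0.08,
                       repeat_copy_range = c(1L, 3L),
                       repeat_mismatch_max = 2L,
                       receptor_length_aa = 360L,
                       propeptide_length_range = c(40L, 80L),
                       seed = 1L,
                       orphan_core_per_species = 3L,
                       phr_duplication_prob = 0.04,
                       phr_pair_divergence = 1L,
                       cassette_duplication_prob = 0.02,
                       cluster_divergence = 0.35,
                       within_cluster_divergence = 0.05,
                       mobile_loss_gain_ratio = 3,
                       core_dropout = 0.05,
                       trait_rate = 0.4) {
  cfg <- as.list(environment())
  if (n_strains < n_species || n_species < 1) {
    stop("invalid config: need n_strains >= n_species >= 1", call. = FALSE)
  }
  if (!(background_gc > 0 && background_gc < 1)) {
    stop("invalid config: background_gc must be in (0,1)", call. = FALSE)
  }
  if (mobile_gc_delta < 0) stop("invalid config: mobile_gc_delta < 0", call. = FALSE)
  if (propeptide_length_range[1] < 35 || propeptide_length_range[2] > 120 ||
      propeptide_length_range[1] > propeptide_length_range[2]) {
    stop("invalid config: propeptide_length_range must lie within [35,120]",
         call. = FALSE)
  }
  if (receptor_length_aa < 300) {
    stop("invalid config: receptor_length_aa must be >= 300", call. = FALSE)
  }
  if (orphan_core_per_species > core_clusters_per_species) {
    stop("invalid config: more orphan than core clusters", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a strain tree with species-monophyletic tips
#'
#' A coalescent species backbone (rescaled to depth 1) carries one
#' coalescent subtree of depth 0.1 per species, so every species' strains
#' are monophyletic by construction. The returned tree is binary, rooted and
#' ultrametric with a `species` attribute mapping strain to species.
#'
#' @param n_strains Number of strains (>= `n_species`).
#' @param n_species Number of species.
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with tip labels `strain_###` and attribute
#'   `species`.
#' @export
simulate_strain_tree <- function(n_strains, n_species, seed = 1L) {
  if (n_strains < n_species || n_species < 1) {
    stop("invalid config: need n_strains >= n_species >= 1", call. = FALSE)
  }
  set.seed(seed)
  per <- rep(n_strains %/% n_species, n_species)
  extra <- n_strains %% n_species
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  strain_ids <- sprintf("strain_%03d", seq_len(n_strains))
  species_of <- rep(sprintf("species_%02d", seq_len(n_species)), per)
  names(species_of) <- strain_ids
  groups <- split(strain_ids, species_of)

  rescale_depth <- function(tr, depth) {
    d <- max(ape::node.depth.edgelength(tr))
    if (d > 0) tr$edge.length <- tr$edge.length * depth / d
    tr
  }
  one_tip <- function(label) read_newick(sprintf("(%s:0.1);", label))

  if (n_species == 1L) {
    tree <- if (n_strains == 1L) one_tip(strain_ids) else
      rescale_depth(ape::rcoal(n_strains, tip.label = strain_ids), 0.1)
  } else {
    backbone <- rescale_depth(
      ape::rcoal(n_species, tip.label = names(groups)), 1)
    tree <- backbone
    for (sp in names(groups)) {
      ids <- groups[[sp]]
      where <- which(tree$tip.label == sp)
      if (length(ids) == 1L) {
        tree$tip.label[where] <- ids
      } else {
        sub <- rescale_depth(ape::rcoal(length(ids), tip.label = ids), 0.1)
        tree <- ape::bind.tree(tree, sub, where = where)
      }
    }
  }
  attr(tree, "species") <- species_of
  tree
}

# Gillespie simulation of a two-state (0/1) process along every branch.
# Returns tip/node states and a per-edge event log.
.simulate_binary_history <- function(tree, gain, loss, root_state) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  states <- rep(NA_integer_, n_all)
  states[n_tip + 1L] <- as.integer(root_state)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  ev <- list()
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; ch <- pre[k, 2L]
    len <- tree$edge.length[which(tree$edge[, 1L] == p &
                                    tree$edge[, 2L] == ch)]
    s <- states[p]; t <- 0
    repeat {
      rate <- if (s == 0L) gain else loss
      if (rate <= 0) break
      t <- t + stats::rexp(1L, rate)
      if (t > len) break
      s <- 1L - s
      ev[[length(ev) + 1L]] <- data.frame(
        parent = p, child = ch, time = t,
        type = if (s == 1L) "gain" else "loss", stringsAsFactors = FALSE)
    }
    states[ch] <- s
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(parent = integer(), child = integer(), time = numeric(),
               type = character(), stringsAsFactors = FALSE)
  list(states = states, tip_states = stats::setNames(states[seq_len(n_tip)],
                                                     tree$tip.label),
       events = events, root_state = as.integer(root_state))
}

# calibrate the mobile gain rate so the expected number of mobile clusters
# per strain matches the configured mean cassette count
.calibrate_mobile_gain <- function(tree, config) {
  expected_core <- config$core_clusters_per_species * (1 - config$core_dropout)
  target <- (config$mean_raps_per_strain - expected_core) /
    config$mobile_cluster_pool
  if (target <= 0) return(0)
  r <- config$mobile_loss_gain_ratio
  pi_stat <- 1 / (1 + r)
  if (target >= pi_stat) {
    stop("invalid config: mean_raps_per_strain unreachable; increase ",
         "mobile_cluster_pool or decrease mobile_loss_gain_ratio",
         call. = FALSE)
  }
  T_depth <- mean(ape::node.depth.edgelength(tree)[
    seq_along(tree$tip.label)])
  f <- function(g) pi_stat * (1 - exp(-(g + r * g) * T_depth)) - target
  stats::uniroot(f, c(1e-8, 1e4))$root
}

#' Simulate cluster repertoires and trait histories on a strain tree
#'
#' Core clusters are assigned per species (each species samples its core set
#' from a shared pool; a fixed subset of the pool is orphan) and are present
#' in at least 90% of the species' strains by construction. Mobile clusters
#' evolve by a two-state gain/loss process along the tree, with the gain
#' rate calibrated so the expected cassette count per strain matches
#' `mean_raps_per_strain`; every gain/loss event is logged per branch. Two
#' binary regulatory traits (ancestral Spo0A control on, ComA control off)
#' evolve with equal gain and loss rates.
#'
#' @param tree Output of [simulate_strain_tree()].
#' @param config A [sim_config()]; its `seed` (offset) drives this stage.
#' @return List of class `sim_repertoires`: `strain_table`, `plan` (one row
#'   per planned cassette), `cluster_catalog`, `mobile_histories` (per
#'   cluster: tip states + event log), `trait_histories`, `rates`.
#' @export
simulate_repertoires <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  species_of <- attr(tree, "species")
  strains <- tree$tip.label
  n_species <- length(unique(species_of))

  core_pool_size <- max(config$core_clusters_per_species,
                        ceiling(n_species * config$core_clusters_per_species * 0.75))
  core_pool <- sprintf("core_%02d", seq_len(core_pool_size))
  orphan_frac <- if (config$core_clusters_per_species > 0)
    config$orphan_core_per_species / config$core_clusters_per_species else 0
  orphan_pool <- core_pool[seq_len(round(orphan_frac * core_pool_size))]
  mobile_pool <- sprintf("mobile_%02d", seq_len(config$mobile_cluster_pool))

  core_sets <- lapply(sort(unique(species_of)), function(sp)
    sort(sample(core_pool, config$core_clusters_per_species)))
  names(core_sets) <- sort(unique(species_of))

  plan <- list()
  add_row <- function(strain, cluster, type) {
    plan[[length(plan) + 1L]] <<- data.frame(
      strain = strain, species = species_of[[strain]], cluster_id = cluster,
      type = type, orphan = cluster %in% orphan_pool,
      n_phr_genes = if (cluster %in% orphan_pool) 0L else
        if (stats::runif(1) < config$phr_duplication_prob) 2L else 1L,
      stringsAsFactors = FALSE)
  }

  # core clusters: present per species except a capped dropout
  for (sp in names(core_sets)) {
    sp_strains <- strains[species_of[strains] == sp]
    cap <- floor(0.1 * length(sp_strains))
    for (cl in core_sets[[sp]]) {
      n_absent <- min(cap, stats::rbinom(1L, length(sp_strains),
                                         config$core_dropout))
      absent <- if (n_absent > 0) sample(sp_strains, n_absent) else character()
      for (st in setdiff(sp_strains, absent)) add_row(st, cl, "core")
    }
  }

  # mobile clusters: gain/loss process along the tree
  gain <- .calibrate_mobile_gain(tree, config)
  loss <- gain * config$mobile_loss_gain_ratio
  mobile_histories <- list()
  for (cl in mobile_pool) {
    h <- .simulate_binary_history(tree, gain, loss, root_state = 0L)
    mobile_histories[[cl]] <- h
    for (st in names(h$tip_states)[h$tip_states == 1L]) {
      add_row(st, cl, "mobile")
      if (stats::runif(1) < config$cassette_duplication_prob) {
        add_row(st, cl, "mobile")  # duplicated introduction
      }
    }
  }

  trait_histories <- list(
    spo0a = .simulate_binary_history(tree, config$trait_rate,
                                     config$trait_rate, root_state = 1L),
    coma = .simulate_binary_history(tree, config$trait_rate,
                                    config$trait_rate, root_state = 0L))

  plan <- if (length(plan)) do.call(rbind, plan) else
    data.frame(strain = character(), species = character(),
               cluster_id = character(), type = character(),
               orphan = logical(), n_phr_genes = integer(),
               stringsAsFactors = FALSE)
  rownames(plan) <- NULL
  catalog <- data.frame(
    cluster_id = c(core_pool, mobile_pool),
    type = rep(c("core", "mobile"),
               c(length(core_pool), length(mobile_pool))),
    orphan = c(core_pool %in% orphan_pool, rep(FALSE, length(mobile_pool))),
    stringsAsFactors = FALSE)
  structure(list(
    strain_table = data.frame(strain = strains,
                              species = unname(species_of[strains]),
                              stringsAsFactors = FALSE),
    plan = plan, cluster_catalog = catalog,
    mobile_histories = mobile_histories, trait_histories = trait_histories,
    rates = list(mobile_gain = gain, mobile_loss = loss,
                 trait = config$trait_rate),
    tree = tree), class = "sim_repertoires")
}

# ---- sequence synthesis ------------------------------------------------

.codon_options <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
      tab[["*"]] <<- NULL
    }
    tab
  }
})

.gc_count <- function(codons) {
  vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")), 0L)
}

# codon sampling under an i.i.d. nucleotide model at GC fraction g,
# vectorised per amino acid
.reverse_translate <- function(protein, g) {
  aa <- strsplit(protein, "")[[1]]
  codons <- character(length(aa))
  opts_tab <- .codon_options()
  for (a in unique(aa)) {
    opts <- opts_tab[[a]]
    if (is.null(opts)) opts <- opts_tab[["A"]]  # X or unknown -> any
    ix <- which(aa == a)
    k <- .gc_count(opts)
    w <- (g / 2)^k * ((1 - g) / 2)^(3 - k)
    codons[ix] <- sample(opts, length(ix), replace = TRUE, prob = w)
  }
  paste(codons, collapse = "")
}

# swap codons toward their lowest-GC synonyms (largest savings first) until
# the CDS GC is <= limit
.depress_cds_gc <- function(cds, limit) {
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  gc_tab <- .codon_table()
  opts_tab <- .codon_options()
  cur <- .gc_count(codons)
  low_codon <- character(length(codons))
  low_gc <- integer(length(codons))
  for (i in seq_along(codons)) {
    opts <- opts_tab[[gc_tab[[codons[i]]]]]
    if (is.null(opts)) { low_codon[i] <- codons[i]; low_gc[i] <- cur[i]; next }
    j <- which.min(.gc_count(opts))
    low_codon[i] <- opts[j]
    low_gc[i] <- .gc_count(opts[j])
  }
  need <- sum(cur) - floor(limit * nchar(cds))
  if (need > 0) {
    gains <- cur - low_gc
    ord <- order(gains, decreasing = TRUE)
    saved <- 0L
    for (i in ord) {
      if (saved >= need || gains[i] == 0L) break
      codons[i] <- low_codon[i]
      saved <- saved + gains[i]
    }
  }
  paste(codons, collapse = "")
}

.random_protein <- function(len) {
  paste(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
}

# mutate exactly k positions anywhere in a short string (autoinducer motifs)
.mutate_positions <- function(s, k) {
  aa <- strsplit(s, "")[[1]]
  if (k > 0) {
    pos <- sample.int(length(aa), min(k, length(aa)))
    aa[pos] <- vapply(aa[pos], function(old)
      sample(setdiff(AA20, old), 1L), "")
  }
  paste(aa, collapse = "")
}

.mutate_protein <- function(protein, divergence) {
  aa <- strsplit(protein, "")[[1]]
  n_mut <- round(divergence * length(aa))
  if (n_mut > 0) {
    pos <- 1L + sample.int(length(aa) - 1L, min(n_mut, length(aa) - 1L))
    aa[pos] <- vapply(aa[pos], function(old)
      sample(setdiff(AA20, old), 1L), "")
  }
  paste(aa, collapse = "")
}

.random_dna <- function(n, g) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - g) / 2, (1 - g) / 2, g / 2, g / 2)),
        collapse = "")
}

# Build the per-cluster specifications: receptor ancestor, autoinducer motif
# and repeat plan, propeptide ancestor.
.build_cluster_specs <- function(repertoires, config) {
  catalog <- repertoires$cluster_catalog
  root_rap <- .random_protein(config$receptor_length_aa)
  specs <- list()
  motifs_used <- character()
  for (i in seq_len(nrow(catalog))) {
    cl <- catalog$cluster_id[i]
    repeat {  # unique motif per cluster
      w <- sample(c(5L, 6L), 1L)
      motif <- paste(sample(AA20, w, replace = TRUE), collapse = "")
      if (!motif %in% motifs_used) break
    }
    motifs_used <- c(motifs_used, motif)
    copies <- sample(seq(config$repeat_copy_range[1],
                         config$repeat_copy_range[2]), 1L)
    mm <- if (copies > 1L)
      sample(0:config$repeat_mismatch_max, copies - 1L, replace = TRUE)
    else integer()
    specs[[cl]] <- list(
      cluster_id = cl, type = catalog$type[i], orphan = catalog$orphan[i],
      ancestor = .mutate_protein(root_rap, config$cluster_divergence),
      autoinducer = motif, repeat_copies = copies, repeat_mismatches = mm)
  }
  attr(specs, "root_rap") <- root_rap
  specs
}

# propeptide protein for one cassette: PWM signal + linker + repeats + tail
.make_phr_protein <- function(spec, config) {
  motif <- spec$autoinducer
  w <- nchar(motif)
  copies <- c(motif, vapply(spec$repeat_mismatches, function(k)
    .mutate_positions(motif, k), character(1)))
  signal <- sample_signal_peptide()
  spacer_n <- 2L
  min_len <- nchar(signal) + 3L +
    length(copies) * w + (length(copies) - 1L) * spacer_n
  if (min_len > config$propeptide_length_range[2]) {
    stop("invalid config: repeat plan infeasible for propeptide length range",
         call. = FALSE)
  }
  linker_n <- max(3L, config$propeptide_length_range[1] - min_len + 3L)
  linker <- paste(sample(setdiff(AA20, c("L", "A", "V", "I", "F")),
                         linker_n, replace = TRUE), collapse = "")
  body <- paste(vapply(seq_along(copies), function(i) {
    sp <- if (i < length(copies))
      paste(sample(c("N", "Q", "E", "D"), spacer_n, replace = TRUE),
            collapse = "") else ""
    paste0(copies[i], sp)
  }, character(1)), collapse = "")
  protein <- paste0(signal, linker, body)
  if (nchar(protein) > config$propeptide_length_range[2]) {
    stop("invalid config: repeat plan infeasible for propeptide length range",
         call. = FALSE)
  }
  list(protein = protein, copies = length(copies),
       signal_end = nchar(signal))
}

#' Synthesize one cassette (receptor CDS + propeptide CDS)
#'
#' Builds the nucleotide block for a cassette from a cluster specification:
#' the receptor CDS (>= 300 aa, diverged from the cluster ancestor), an
#' in-frame stop pad before each gene (so open reading frames are bounded),
#' and 0-2 downstream same-strand propeptide CDSs starting within the
#' detection window. Codons are sampled under an i.i.d. nucleotide model at
#' the requested GC and depressed to at most `gc_limit` when given.
#'
#' @param spec Cluster specification (ancestor protein, divergence,
#'   autoinducer motif and repeat plan) as built inside
#'   [simulate_repertoires()] pipelines.
#' @param config A [sim_config()].
#' @param n_phr Number of propeptide genes to emit (0 for orphans).
#' @param gc Target GC for codon sampling.
#' @param gc_limit Optional hard upper bound for the gene GC (mobile
#'   cassettes).
#' @return List: `block` (nucleotide string), `rap` (protein + offsets within
#'   the block), `phr` (list of propeptide entries), `truth` fields
#'   (autoinducer, repeat copies).
#' @export
synthesize_cassette <- function(spec, config, n_phr = 1L, gc = NULL,
                                gc_limit = NULL) {
  if (is.null(gc)) gc <- config$background_gc
  rap_protein <- .mutate_protein(spec$ancestor,
                                 config$within_cluster_divergence)
  rap_cds <- paste0(.reverse_translate(rap_protein, gc), "TAA")
  if (!is.null(gc_limit)) rap_cds <- .depress_cds_gc(rap_cds, gc_limit)

  parts <- c("TAA", rap_cds)   # in-frame bounding stop, then receptor
  offsets <- list(rap = c(4L, 3L + nchar(rap_cds)))
  phr_entries <- list()
  cursor <- 3L + nchar(rap_cds)
  if (!spec$orphan && n_phr > 0) {
    for (j in seq_len(n_phr)) {
      spec_j <- spec
      if (j > 1L) {  # duplicated propeptide gene with a diverged autoinducer
        spec_j$autoinducer <- .mutate_positions(spec$autoinducer,
                                                config$phr_pair_divergence)
      }
      ph <- .make_phr_protein(spec_j, config)
      phr_cds <- paste0(.reverse_translate(ph$protein, gc), "TAA")
      if (!is.null(gc_limit)) phr_cds <- .depress_cds_gc(phr_cds, gc_limit)
      spacer_len <- 3L * sample(5:25, 1L)
      spacer <- .random_dna(spacer_len, if (is.null(gc_limit)) gc else
        max(0.05, gc_limit - 0.02))
      parts <- c(parts, spacer, "TAA", phr_cds)
      start <- cursor + spacer_len + 3L + 1L
      phr_entries[[j]] <- list(protein = ph$protein,
                               start = start, end = start + nchar(phr_cds) - 1L,
                               copies = ph$copies, signal_end = ph$signal_end)
      cursor <- start + nchar(phr_cds) - 1L
    }
  }
  block <- paste(parts, collapse = "")
  list(block = block, rap = list(protein = rap_protein,
                                 start = offsets$rap[1], end = offsets$rap[2]),
       phr = phr_entries,
       truth = list(autoinducer = spec$autoinducer,
                    repeat_copies = spec$repeat_copies))
}

#' Simulate a complete dataset
#'
#' Composes [simulate_strain_tree()], [simulate_repertoires()] and
#' [synthesize_cassette()] into genomes with full ground truth: one contig
#' per strain with background sequence at `background_gc`, core cassettes at
#' background GC and mobile cassettes inside low-GC islands (cassette
#' +/- 1100 bp), on random strands. Seed queries for the miner (the family
#' root and three cluster ancestors) are included.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_truth`: `config`, `tree`, `strain_table`,
#'   `cassettes` (truth table with coordinates, proteins, autoinducer and
#'   repeat copy counts), `genomes` (list of [genome_record()]),
#'   `seed_queries`, `repertoires`, `cluster_specs`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_strain_tree(config$n_strains, config$n_species,
                               seed = config$seed)
  repertoires <- simulate_repertoires(tree, config)
  set.seed(config$seed + 2L)
  specs <- .build_cluster_specs(repertoires, config)

  island_pad <- 1100L
  island_gc <- max(0.05, config$background_gc - config$mobile_gc_delta - 0.04)
  bg <- config$background_gc
  genomes <- list()
  truth_rows <- list()
  plan <- repertoires$plan
  for (st in repertoires$strain_table$strain) {
    rows <- plan[plan$strain == st, , drop = FALSE]
    if (nrow(rows)) rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    segments <- .random_dna(2500L + sample.int(1500L, 1L), bg)
    pos <- nchar(segments)
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      spec <- specs[[r$cluster_id]]
      mobile <- r$type == "mobile"
      cass <- synthesize_cassette(
        spec, config, n_phr = r$n_phr_genes,
        gc = if (mobile) island_gc else bg,
        gc_limit = if (mobile) bg - config$mobile_gc_delta else NULL)
      strand <- sample(c("+", "-"), 1L)
      insert <- if (mobile) {
        paste0(.random_dna(island_pad, island_gc),
               if (strand == "+") cass$block else reverse_complement(cass$block),
               .random_dna(island_pad, island_gc))
      } else {
        if (strand == "+") cass$block else reverse_complement(cass$block)
      }
      offset <- pos + if (mobile) island_pad else 0L
      blk_len <- nchar(cass$block)
      to_fwd <- function(interval) {
        if (strand == "+") offset + interval
        else c(offset + blk_len - interval[2] + 1L,
               offset + blk_len - interval[1] + 1L)
      }
      rap_fwd <- to_fwd(c(cass$rap$start, cass$rap$end))
      phr_list <- cass$phr
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        strain = st, species = r$species, cluster_id = r$cluster_id,
        type = r$type, orphan = r$orphan, strand = strand,
        rap_start = rap_fwd[1], rap_end = rap_fwd[2],
        rap_protein = cass$rap$protein,
        n_phr = length(phr_list),
        phr_starts = paste(vapply(phr_list, function(p)
          to_fwd(c(p$start, p$end))[1], 0), collapse = ","),
        phr_ends = paste(vapply(phr_list, function(p)
          to_fwd(c(p$start, p$end))[2], 0), collapse = ","),
        phr_proteins = paste(vapply(phr_list, function(p) p$protein, ""),
                             collapse = ","),
        autoinducer = if (r$orphan) NA_character_ else cass$truth$autoinducer,
        repeat_copies = if (r$orphan) NA_integer_ else cass$truth$repeat_copies,
        repeat_max_mismatch = if (r$orphan) NA_integer_ else
          as.integer(max(c(0L, spec$repeat_mismatches))),
        island_start = if (mobile) pos + 1L else NA_integer_,
        island_end = if (mobile) pos + 2L * island_pad + blk_len else NA_integer_,
        stringsAsFactors = FALSE)
      segments <- paste0(segments, insert,
                         .random_dna(2800L + sample.int(2000L, 1L), bg))
      pos <- nchar(segments)
    }
    segments <- paste0(segments, .random_dna(500L, bg))
    genomes[[st]] <- genome_record(
      st, stats::setNames(segments, paste0(st, "_c1")),
      species = repertoires$strain_table$species[
        repertoires$strain_table$strain == st])
  }
  cassettes <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  seed_queries <- c(family_root = attr(specs, "root_rap"))
  anc_from <- utils::head(names(specs), 3L)
  for (cl in anc_from) seed_queries[paste0("anc_", cl)] <- specs[[cl]]$ancestor
  structure(list(config = config, tree = tree,
                 strain_table = repertoires$strain_table,
                 cassettes = cassettes, genomes = genomes,
                 seed_queries = seed_queries, repertoires = repertoires,
                 cluster_specs = specs),
            class = "sim_truth")
}

#' Write a simulated dataset to disk
#'
#' Emits one FASTA per strain, the truth tables as TSV, the strain tree as
#' newick and a YAML echo of the configuration. Re-reading the FASTA files
#' reproduces all recorded coordinates.
#'
#' @param truth A `sim_truth` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
emit_genomes <- function(truth, out_dir) {
  stopifnot(inherits(truth, "sim_truth"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- character()
  gdir <- file.path(out_dir, "genomes")
  dir.create(gdir, showWarnings = FALSE)
  for (st in names(truth$genomes)) {
    p <- file.path(gdir, paste0(st, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(truth$genomes[[st]]$contigs), p)
    paths <- c(paths, p)
  }
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths,
             tsv(truth$strain_table, "strains.tsv"),
             tsv(truth$cassettes, "cassettes_truth.tsv"))
  nwk <- file.path(out_dir, "strain_tree.nwk")
  write_newick(truth$tree, nwk)
  qfa <- file.path(out_dir, "seed_queries.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(truth$seed_queries), qfa)
  cfg <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(truth$config), cfg)
  invisible(c(paths, nwk, qfa, cfg))
}
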