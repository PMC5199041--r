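# End-to-end pipeline: simulate/load genomes -> mine cassettes -> call
# autoinducers -> tree + monophyletic clusters -> mobility + association
# matrix -> rarefaction -> (optional) trait gain/loss parsimony.

#' Pipeline configuration
#'
#' All randomness derives from `seed` through fixed per-stage offsets, so a
#' rerun with the same configuration is byte-identical.
#'
#' @param profile Mining profile, `"rap"` or `"nprr"` (sets e-value and
#'   propeptide window defaults).
#' @param simulate Generate genomes with [simulate_dataset()] (`TRUE`) or
#'   read them from `genomes_dir`.
#' @param sim A [sim_config()] used when `simulate = TRUE` (its seed is
#'   overridden by `seed`).
#' @param genomes_dir Directory of per-strain FASTA files (used when
#'   `simulate = FALSE`).
#' @param species_map Path to a strain TSV (`strain`, `species`) for
#'   `genomes_dir` input.
#' @param queries Named character vector of seed receptor proteins, or path
#'   to a FASTA (required for `genomes_dir` input; the simulator supplies its
#'   own).
#' @param seed Master integer seed.
#' @param out_dir Optional output directory for tables, GFF3, log and summary.
#' @param n_bootstrap Bootstrap replicates for the receptor NJ tree.
#' @param rarefaction_resamples Random subsets per rarefaction size.
#' @param tail_window Tail sizes for the rarefaction slope (default
#'   `min(20, n_strains - 1)`).
#' @param cluster_cut Cophenetic-distance cut used to pre-group receptor
#'   leaves for autoinducer calling.
#' @param alpha Significance level of the GC mobility test.
#' @param known_peptides Optional library of known mature autoinducers.
#' @param run_traits Run trait gain/loss parsimony (simulated input only).
#' @param evalue,min_len,window,signal_threshold Optional overrides of the
#'   profile's mining parameters (see [search_params()] and
#'   [propeptide_scan_params()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("rap", "nprr"), simulate = TRUE,
                            sim = sim_config(), genomes_dir = NULL,
                            species_map = NULL, queries = NULL, seed = 1L,
                            out_dir = NULL, n_bootstrap = 25L,
                            rarefaction_resamples = 500L, tail_window = NULL,
                            cluster_cut = 0.25, alpha = 0.05,
                            known_peptides = character(),
                            run_traits = TRUE, evalue = NULL,
                            min_len = NULL, window = NULL,
                            signal_threshold = NULL) {
  profile <- match.arg(profile)
  cfg <- as.list(environment())
  if (!simulate && (is.null(genomes_dir) || is.null(queries))) {
    stop("genomes_dir and queries are required when simulate = FALSE",
         call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# strain gene-GC background: GC of all ORFs above a length floor, both
# strands, excluding ORFs near mined receptor loci (the tested genes and
# their flanking mobile-element context must not contaminate the null);
# the length floor is relaxed once if fewer than 20 ORFs are found
.strain_gene_gc <- function(genome, exclude = NULL, margin = 1300L) {
  collect <- function(min_aa) {
    unlist(lapply(names(genome$contigs), function(cn) {
      ctg <- genome$contigs[[cn]]
      L <- nchar(ctg)
      fw <- find_orfs(ctg, min_aa = min_aa)
      rv <- find_orfs(reverse_complement(ctg), min_aa = min_aa)
      ints <- rbind(fw[, c("start", "end")],
                    data.frame(start = L - rv$end + 1L, end = L - rv$start + 1L))
      seqs <- c(vapply(seq_len(nrow(fw)), function(i)
        substring(ctg, fw$start[i], fw$end[i]), ""),
        vapply(seq_len(nrow(rv)), function(i)
          substring(reverse_complement(ctg), rv$start[i], rv$end[i]), ""))
      keep <- rep(TRUE, nrow(ints))
      if (!is.null(exclude) && nrow(exclude)) {
        exc <- exclude[exclude$contig == cn, , drop = FALSE]
        if (nrow(exc)) {
          keep <- !vapply(seq_len(nrow(ints)), function(i)
            any(ints$start[i] <= exc$end + margin &
                  ints$end[i] >= exc$start - margin), TRUE)
        }
      }
      vapply(seqs[keep], gc_fraction, 0)
    }), use.names = FALSE)
  }
  gcs <- collect(100L)
  if (length(gcs) < 20L) gcs <- collect(50L)
  if (length(gcs) < 20L) gcs <- collect(30L)
  gcs
}

.neighborhood_gc <- function(genome, cassette_row) {
  ctg <- genome$contigs[[cassette_row$contig]]
  L <- nchar(ctg)
  win <- if (cassette_row$strand == "+") {
    c(cassette_row$rap_start - 1000L, cassette_row$rap_start - 300L)
  } else {
    c(cassette_row$rap_end + 300L, cassette_row$rap_end + 1000L)
  }
  win <- pmax(1L, pmin(L, win))
  if (win[2] - win[1] < 50L) return(NA_real_)
  gc_fraction(substring(ctg, win[1], win[2]))
}

.stage_log <- function(log, stage, detail) {
  message(sprintf("[%s] %s", stage, detail))
  rbind(log, data.frame(stage = stage, detail = detail,
                        stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes mining, autoinducer calling, tree building and monophyletic
#' clustering, GC mobility classification, association-matrix statistics,
#' rarefaction and (for simulated input) trait gain/loss parsimony, and
#' returns all intermediate tables plus a summary. With `out_dir` set, all
#' tables, a GFF3 of mined features, the resolved configuration echo and a
#' run log are written.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`; see `$summary` for the headline
#'   statistics and `$truth` for the simulator ground truth (simulated runs).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- data.frame(stage = character(), detail = character(),
                    stringsAsFactors = FALSE)
  search <- search_params(
    profile = config$profile, evalue_max = config$evalue,
    min_homology_len_aa = if (is.null(config$min_len)) 300L else config$min_len)
  scan <- propeptide_scan_params(
    profile = config$profile, window = config$window,
    signal_threshold = if (is.null(config$signal_threshold)) 0.3 else
      config$signal_threshold)

  # --- inputs ---------------------------------------------------------
  truth <- NULL
  if (config$simulate) {
    simc <- config$sim
    simc$seed <- config$seed
    truth <- simulate_dataset(simc)
    genomes <- truth$genomes
    queries <- truth$seed_queries
    log <- .stage_log(log, "simulate",
                      sprintf("%d strains, %d planted cassettes",
                              length(genomes), nrow(truth$cassettes)))
  } else {
    fa <- list.files(config$genomes_dir, pattern = "\\.fa(sta)?$",
                     full.names = TRUE)
    if (!length(fa)) stop("no FASTA files in ", config$genomes_dir, call. = FALSE)
    spmap <- if (!is.null(config$species_map)) {
      sm <- utils::read.delim(config$species_map, stringsAsFactors = FALSE)
      stats::setNames(sm$species, sm$strain)
    } else character()
    genomes <- lapply(fa, function(p) {
      contigs <- Biostrings::readDNAStringSet(p)
      st <- tools::file_path_sans_ext(basename(p))
      genome_record(st, stats::setNames(toupper(as.character(contigs)),
                                        sub("\\s.*$", "", names(contigs))),
                    species = if (st %in% names(spmap)) spmap[[st]] else NA)
    })
    names(genomes) <- vapply(genomes, function(g) g$strain, "")
    queries <- if (is.character(config$queries) &&
                   length(config$queries) == 1L &&
                   file.exists(config$queries)) {
      q <- Biostrings::readAAStringSet(config$queries)
      stats::setNames(as.character(q), sub("\\s.*$", "", names(q)))
    } else config$queries
    log <- .stage_log(log, "load", sprintf("%d genomes", length(genomes)))
  }

  # --- mining ---------------------------------------------------------
  mined <- lapply(genomes, mine_genome, queries = queries,
                  search = search, scan = scan)
  cassettes <- do.call(rbind, mined)
  if (is.null(cassettes) || !nrow(cassettes)) {
    stop("pipeline aborted at stage 'mine': no cassettes found", call. = FALSE)
  }
  class(cassettes) <- c("cassette_table", "data.frame")
  rownames(cassettes) <- NULL
  cassettes$uid <- sprintf("%s|%s|%d", cassettes$strain, cassettes$contig,
                           cassettes$rap_start)
  log <- .stage_log(log, "mine", sprintf("%d cassettes (%d orphan)",
                                         nrow(cassettes),
                                         sum(cassettes$orphan)))

  # --- GC / mobility --------------------------------------------------
  strain_gc <- lapply(genomes, function(g) {
    mine_here <- cassettes[cassettes$strain == g$strain, , drop = FALSE]
    .strain_gene_gc(g, exclude = data.frame(contig = mine_here$contig,
                                            start = mine_here$rap_start,
                                            end = mine_here$rap_end))
  })
  cassettes$gene_gc <- vapply(seq_len(nrow(cassettes)), function(i) {
    r <- cassettes[i, ]
    gc_fraction(substring(genomes[[r$strain]]$contigs[[r$contig]],
                          r$rap_start, r$rap_end))
  }, 0)
  cassettes$neighborhood_gc <- vapply(seq_len(nrow(cassettes)), function(i)
    .neighborhood_gc(genomes[[cassettes$strain[i]]], cassettes[i, ]), 0)
  calls <- lapply(seq_len(nrow(cassettes)), function(i)
    mobility_call(cassettes$gene_gc[i], strain_gc[[cassettes$strain[i]]],
                  alpha = config$alpha))
  cassettes$mobility <- vapply(calls, function(x) x$label, "")
  cassettes$mobility_z <- vapply(calls, function(x)
    if (is.na(x$z)) NA_real_ else x$z, 0)
  ok_nb <- !is.na(cassettes$neighborhood_gc)
  gc_reg <- if (sum(ok_nb) >= 3) {
    neighborhood_gc_regression(cassettes$gene_gc[ok_nb],
                               cassettes$neighborhood_gc[ok_nb])
  } else NULL
  log <- .stage_log(log, "mobility",
                    sprintf("%d mobile genes", sum(cassettes$mobility == "mobile")))

  # --- tree + autoinducer calls + clusters ----------------------------
  raps <- stats::setNames(cassettes$rap_protein, cassettes$uid)
  if (length(raps) < 3L) {
    stop("pipeline aborted at stage 'tree': fewer than 3 receptors",
         call. = FALSE)
  }
  aln <- align_proteins(raps)
  tree <- build_nj_tree(aln, n_bootstrap = config$n_bootstrap,
                        seed = config$seed + 10L)
  coph <- stats::cophenetic(tree)
  pregroups <- stats::cutree(stats::hclust(stats::as.dist(coph), "complete"),
                             h = config$cluster_cut)
  first_phr <- vapply(cassettes$phr, function(p)
    if (nrow(p)) p$protein[1L] else NA_character_, "")
  names(first_phr) <- cassettes$uid
  peptides <- stats::setNames(rep(NA_character_, nrow(cassettes)),
                              cassettes$uid)
  library_peptides <- config$known_peptides
  singletons <- list()
  for (g in unique(pregroups)) {
    uids <- names(pregroups)[pregroups == g]
    preps <- first_phr[uids]
    preps <- preps[!is.na(preps)]
    # conservation screen: a group where most receptors lack a propeptide is
    # an orphan group; its minority candidates are spurious window ORFs
    if (length(preps) < length(uids) / 2) next
    if (length(preps) >= 2L) {
      call <- call_autoinducer(unname(preps))
      peptides[uids] <- call$peptide
      library_peptides <- unique(c(library_peptides, call$peptide))
    } else if (length(preps) == 1L) {
      singletons[[length(singletons) + 1L]] <- preps
    }
  }
  for (preps in singletons) {  # called after the library is populated
    if (length(library_peptides)) {
      call <- call_autoinducer(unname(preps), known_peptides = library_peptides)
      peptides[names(preps)] <- call$peptide
    }
  }
  clusters <- peptide_monophyletic_clusters(tree, peptides)
  member_cluster <- stats::setNames(
    rep(clusters$cluster_id, clusters$n_members),
    unlist(clusters$members))
  cassettes$cluster_id <- unname(member_cluster[cassettes$uid])
  cassettes$peptide <- unname(peptides[cassettes$uid])
  log <- .stage_log(log, "cluster",
                    sprintf("%d clusters, %d unique peptides",
                            nrow(clusters),
                            length(unique(stats::na.omit(clusters$peptide)))))

  # --- repeats and phr duplications -----------------------------------
  rep_reports <- lapply(seq_len(nrow(cassettes)), function(i) {
    p <- first_phr[[cassettes$uid[i]]]
    pep <- peptides[[cassettes$uid[i]]]
    if (is.na(p)) return(NULL)
    if (!is.na(pep)) {
      # anchored on the called autoinducer of the cassette's group
      detect_intragenic_repeats(p, motif_len = nchar(pep), max_mismatch = 2L,
                                anchor = pep)
    } else {
      best <- NULL
      for (w in c(5L, 6L)) {
        r <- detect_intragenic_repeats(p, motif_len = w, max_mismatch = 1L)
        if (!is.null(r) && (is.null(best) || r$n_copies > best$n_copies)) best <- r
      }
      best
    }
  })
  cassettes$repeat_copies <- vapply(rep_reports, function(r)
    if (is.null(r)) 1L else r$n_copies, 0L)
  cassettes$repeat_copies[is.na(first_phr[cassettes$uid])] <- NA_integer_
  log <- .stage_log(log, "repeats",
                    sprintf("%d cassettes with repeated autoinducer",
                            sum(cassettes$repeat_copies > 1, na.rm = TRUE)))

  # --- population statistics ------------------------------------------
  assoc <- build_association_matrix(cassettes)
  cluster_mob <- cluster_mobility_labels(cassettes$mobility,
                                         cassettes$cluster_id)
  freq <- per_species_frequency(assoc)
  dups <- duplicate_cluster_cases(cassettes)
  tail_window <- if (is.null(config$tail_window))
    min(20L, nrow(assoc) - 1L) else config$tail_window
  rare <- rarefaction_curve(assoc,
                            n_resamples = config$rarefaction_resamples,
                            tail_window = tail_window,
                            seed = config$seed + 11L)
  log <- .stage_log(log, "population",
                    sprintf("matrix %d x %d; tail slope %.3f",
                            nrow(assoc), ncol(assoc), rare$tail_slope))

  # --- trait gain/loss (simulated runs) -------------------------------
  traits <- NULL
  if (config$run_traits && !is.null(truth)) {
    traits <- lapply(names(truth$repertoires$trait_histories), function(tr) {
      h <- truth$repertoires$trait_histories[[tr]]
      res <- parsimony_gainloss(truth$tree, h$tip_states,
                                root_state = h$root_state)
      list(trait = tr, inferred = res, true_events = nrow(h$events))
    })
    names(traits) <- names(truth$repertoires$trait_histories)
    log <- .stage_log(log, "traits",
                      sprintf("%d inferred events (truth %d)",
                              sum(vapply(traits, function(x)
                                x$inferred$n_events, 0L)),
                              sum(vapply(traits, function(x)
                                x$true_events, 0L))))
  }

  # --- summary ---------------------------------------------------------
  per_strain <- table(cassettes$strain)
  orphans_per_strain <- tapply(cassettes$orphan, cassettes$strain, sum)
  core_frac <- tapply(cassettes$mobility == "core", cassettes$strain, mean)
  summary <- list(
    n_strains = length(genomes),
    n_cassettes = nrow(cassettes),
    mean_raps_per_strain = mean(per_strain),
    mean_orphans_per_strain = mean(orphans_per_strain),
    pct_with_phr = 100 * mean(!cassettes$orphan),
    n_clusters = nrow(clusters),
    n_unique_peptides = length(unique(stats::na.omit(clusters$peptide))),
    mobile_cluster_fraction = mean(cluster_mob == "mobile"),
    mean_core_fraction_per_strain = mean(core_frac),
    duplicate_cases = dups$n_cases,
    orphan_duplicate_cases = dups$n_orphan_cases,
    rarefaction_tail_slope = rare$tail_slope,
    gc_regression_slope = if (is.null(gc_reg)) NA_real_ else gc_reg$slope,
    gc_regression_r2 = if (is.null(gc_reg)) NA_real_ else gc_reg$r_squared)

  result <- structure(list(
    config = config, cassettes = cassettes, tree = tree, clusters = clusters,
    assoc = assoc, cluster_mobility = cluster_mob, frequency = freq,
    duplicates = dups, rarefaction = rare, gc_regression = gc_reg,
    traits = traits, summary = summary, truth = truth, log = log),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) .write_pipeline_outputs(result, config$out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cassette_table(result$cassettes, file.path(out_dir, "cassettes.tsv"))
  write_cassette_gff3(result$cassettes, file.path(out_dir, "cassettes.gff3"))
  cl <- result$clusters
  cl$members <- vapply(cl$members, paste, "", collapse = ",")
  utils::write.table(cl, file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  m <- unclass(result$assoc); attr(m, "species") <- NULL
  utils::write.table(m, file.path(out_dir, "association_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(
    data.frame(size = result$rarefaction$sizes,
               mean_clusters = result$rarefaction$mean_clusters),
    file.path(out_dir, "rarefaction.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)
  yaml::write_yaml(result$summary, file.path(out_dir, "summary.yaml"))
  cfg <- result$config
  cfg$sim <- unclass(cfg$sim)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_echo.yaml"))
  utils::write.table(result$log, file.path(out_dir, "run_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  %d strains, %d cassettes (%.1f per strain, %.1f orphans)\n",
              s$n_strains, s$n_cassettes, s$mean_raps_per_strain,
              s$mean_orphans_per_strain))
  cat(sprintf("  %d clusters, %d unique peptides; %.0f%% of clusters mobile\n",
              s$n_clusters, s$n_unique_peptides,
              100 * s$mobile_cluster_fraction))
  cat(sprintf("  duplicate cases: %d (+%d orphan); rarefaction tail slope %.3f\n",
              s$duplicate_cases, s$orphan_duplicate_cases,
              s$rarefaction_tail_slope))
  invisible(x)
}
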