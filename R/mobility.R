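# Core-vs-mobile classification from GC content and population-level
# presence/absence statistics.
#
# Horizontally transferred cassettes sit in DNA whose GC content is depressed
# relative to the host genome; a cassette is called mobile when its gene GC
# is significantly below the strain's gene-GC distribution (one-sided z-test,
# the simplest defensible reading of "significantly lower"). Cluster-level
# labels are majority votes over members.

#' Core/mobile call for a single gene
#'
#' One-sided z-test of the gene's GC fraction against the strain's gene-GC
#' distribution; the gene is labelled `"mobile"` when `p < alpha` (which
#' implies its GC lies below the strain mean). With a degenerate distribution
#' (sd = 0) the label falls back to a strict comparison and the p-value is
#' flagged undefined.
#'
#' @param gene_gc GC fraction of the gene.
#' @param strain_gene_gc Numeric vector of gene GC fractions for the strain
#'   (>= 20 genes).
#' @param alpha One-sided significance level.
#' @return List: `label` (`"core"`/`"mobile"`), `p_value`, `z`,
#'   `degenerate_sd`.
#' @export
mobility_call <- function(gene_gc, strain_gene_gc, alpha = 0.05) {
  if (length(strain_gene_gc) < 20L) {
    stop("strain gene-GC distribution needs >= 20 genes", call. = FALSE)
  }
  mu <- mean(strain_gene_gc)
  sdev <- stats::sd(strain_gene_gc)
  if (sdev == 0) {
    return(list(label = if (gene_gc < mu) "mobile" else "core",
                p_value = NA_real_, z = NA_real_, degenerate_sd = TRUE))
  }
  z <- (gene_gc - mu) / sdev
  p <- stats::pnorm(z)
  list(label = if (p < alpha) "mobile" else "core",
       p_value = p, z = z, degenerate_sd = FALSE)
}

#' Majority-vote mobility label per cluster
#'
#' @param labels Character vector of per-gene `"core"`/`"mobile"` labels.
#' @param clusters Parallel vector of cluster ids.
#' @return Named character vector of cluster labels (ties resolve to
#'   `"core"`).
#' @export
cluster_mobility_labels <- function(labels, clusters) {
  vapply(split(labels, clusters), function(v) {
    if (mean(v == "mobile") > 0.5) "mobile" else "core"
  }, character(1))
}

#' Regression of gene GC on neighborhood GC through the origin
#'
#' Least-squares slope of `gene_gc = b * neighborhood_gc` with zero
#' intercept. The reported R-squared is `1 - RSS/TSS` with the total sum of
#' squares taken about the mean; it is floored at zero, so data that the
#' origin-constrained line fits worse than a constant (e.g. anti-correlated
#' pairs) score 0.
#'
#' @param gene_gc Response: per-gene GC fractions.
#' @param neighborhood_gc Predictor: GC of the upstream neighborhood window
#'   (the region 1 kb to 300 bp upstream of the gene start).
#' @return List: `slope`, `r_squared`, `n`.
#' @export
neighborhood_gc_regression <- function(gene_gc, neighborhood_gc) {
  stopifnot(length(gene_gc) == length(neighborhood_gc))
  if (length(gene_gc) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (all(neighborhood_gc == 0)) stop("all-zero predictor", call. = FALSE)
  fit <- stats::lm(gene_gc ~ 0 + neighborhood_gc)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((gene_gc - mean(gene_gc))^2)
  r2 <- if (tss == 0) as.numeric(rss == 0) else max(0, 1 - rss / tss)
  list(slope = unname(stats::coef(fit)[1L]), r_squared = r2,
       n = length(gene_gc))
}

#' Build a strains-by-clusters presence/absence matrix
#'
#' @param cassettes data.frame with columns `strain` and `cluster_id` (one
#'   row per cassette) and optionally `species`.
#' @param species Optional named character vector strain -> species,
#'   overriding/augmenting the `species` column.
#' @return Binary matrix (class `association_matrix`) with strains as rows,
#'   clusters as columns, and a `species` attribute (named by strain).
#' @export
build_association_matrix <- function(cassettes, species = NULL) {
  if (!nrow(cassettes)) {
    m <- matrix(0L, 0L, 0L)
    attr(m, "species") <- character()
    class(m) <- c("association_matrix", class(m))
    return(m)
  }
  strains <- sort(unique(cassettes$strain))
  clusters <- sort(unique(cassettes$cluster_id))
  m <- matrix(0L, length(strains), length(clusters),
              dimnames = list(strains, clusters))
  m[cbind(match(cassettes$strain, strains),
          match(cassettes$cluster_id, clusters))] <- 1L
  sp <- rep(NA_character_, length(strains)); names(sp) <- strains
  if (!is.null(cassettes$species)) {
    sp[as.character(cassettes$strain)] <- as.character(cassettes$species)
  }
  if (!is.null(species)) sp[names(species)] <- species
  attr(m, "species") <- sp
  class(m) <- c("association_matrix", class(m))
  m
}

#' Same-cluster-in-one-genome duplication cases
#'
#' Counts (strain, cluster) pairs carrying two or more cassettes of the same
#' cluster; cases where the cassettes are orphans (no propeptide) are
#' reported separately.
#'
#' @param cassettes data.frame with `strain`, `cluster_id` and logical
#'   `orphan` columns.
#' @return List: `n_cases` and `cases` (non-orphan duplications),
#'   `n_orphan_cases` and `orphan_cases`.
#' @export
duplicate_cluster_cases <- function(cassettes) {
  empty <- data.frame(strain = character(), cluster_id = character(),
                      n = integer(), stringsAsFactors = FALSE)
  if (!nrow(cassettes)) {
    return(list(n_cases = 0L, cases = empty,
                n_orphan_cases = 0L, orphan_cases = empty))
  }
  count_cases <- function(df) {
    if (!nrow(df)) return(empty)
    agg <- stats::aggregate(list(n = df$strain),
                            by = list(strain = df$strain,
                                      cluster_id = df$cluster_id),
                            FUN = length)
    agg <- agg[agg$n >= 2L, , drop = FALSE]
    rownames(agg) <- NULL
    agg
  }
  cases <- count_cases(cassettes[!cassettes$orphan, , drop = FALSE])
  orphan_cases <- count_cases(cassettes[cassettes$orphan, , drop = FALSE])
  list(n_cases = nrow(cases), cases = cases,
       n_orphan_cases = nrow(orphan_cases), orphan_cases = orphan_cases)
}

#' Per-species cluster frequencies
#'
#' For every cluster, the fraction of strains of each species carrying it;
#' the cross-species mean is taken over species where the cluster occurs at
#' least once.
#'
#' @param assoc An `association_matrix` with a species attribute.
#' @return List: `per_species` (long data.frame `cluster_id`, `species`,
#'   `frequency`) and `summary` (`cluster_id`, `mean_frequency`).
#' @export
per_species_frequency <- function(assoc) {
  sp <- attr(assoc, "species")
  if (is.null(sp) || all(is.na(sp))) stop("species labels missing", call. = FALSE)
  species <- sort(unique(sp[!is.na(sp)]))
  long <- do.call(rbind, lapply(species, function(s) {
    rows <- which(sp == s)
    data.frame(cluster_id = colnames(assoc), species = s,
               frequency = colMeans(assoc[rows, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  summ <- do.call(rbind, lapply(split(long, long$cluster_id), function(df) {
    present <- df$frequency > 0
    data.frame(cluster_id = df$cluster_id[1L],
               mean_frequency = if (any(present)) mean(df$frequency[present]) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_species = long, summary = summ)
}

#' Rarefaction (cluster accumulation) curve
#'
#' Mean number of distinct clusters discovered in uniform random strain
#' subsets of every size from 1 to the number of strains (sampling without
#' replacement, `n_resamples` permutations), with the least-squares slope
#' over the last `tail_window` sizes. Deterministic given `seed`. The
#' resampling is performed by [vegan::specaccum()].
#'
#' @param assoc Binary strains-by-clusters matrix.
#' @param n_resamples Number of random permutations.
#' @param tail_window Number of terminal sizes used for the tail slope
#'   (must be < number of strains).
#' @param seed Integer RNG seed.
#' @return List of class `rarefaction_curve`: `sizes`, `mean_clusters`,
#'   `tail_slope`, `n_resamples`, `seed`.
#' @export
rarefaction_curve <- function(assoc, n_resamples = 500L, tail_window = 20L,
                              seed = 1L) {
  n <- nrow(assoc)
  if (n < 2L) stop("need at least 2 strains", call. = FALSE)
  if (tail_window >= n) stop("tail_window must be smaller than the number of strains",
                             call. = FALSE)
  m <- unclass(assoc)
  attr(m, "species") <- NULL
  set.seed(seed)
  sa <- vegan::specaccum(m, method = "random", permutations = n_resamples)
  sizes <- sa$sites
  rich <- sa$richness
  tail_ix <- (length(sizes) - tail_window + 1L):length(sizes)
  slope <- unname(stats::coef(stats::lm(rich[tail_ix] ~ sizes[tail_ix]))[2L])
  structure(list(sizes = sizes, mean_clusters = rich, tail_slope = slope,
                 n_resamples = n_resamples, seed = seed),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("<rarefaction_curve>", length(x$sizes), "sizes;",
      "final richness", round(x$mean_clusters[length(x$mean_clusters)], 2),
      "; tail slope", signif(x$tail_slope, 3), "\n")
  invisible(x)
}

#' @export
plot.rarefaction_curve <- function(x, ...) {
  graphics::plot(x$sizes, x$mean_clusters, type = "l",
                 xlab = "strains sampled", ylab = "mean clusters discovered",
                 ...)
  invisible(x)
}
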