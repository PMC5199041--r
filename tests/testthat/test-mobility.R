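test_that("mobility call follows the one-sided z-test", {
  set.seed(30)
  bg <- rnorm(50, 0.45, 0.02)
  at_mean <- mobility_call(mean(bg), bg)
  expect_equal(at_mean$label, "core")
  low <- mobility_call(mean(bg) - 3 * sd(bg), bg)
  expect_equal(low$label, "mobile")
  expect_lt(low$p_value, 0.01)
  expect_equal(low$p_value, pnorm(-3), tolerance = 1e-9)
  expect_error(mobility_call(0.4, bg[1:10]), "20")
  deg <- mobility_call(0.40, rep(0.45, 25))
  expect_true(deg$degenerate_sd)
  expect_equal(deg$label, "mobile")
  expect_equal(cluster_mobility_labels(c("mobile", "mobile", "core"),
                                       c("a", "a", "a")),
               c(a = "mobile"))
})

test_that("through-origin regression recovers a planted slope of 1.1", {
  x <- seq(0.3, 0.6, length.out = 20)
  exact <- neighborhood_gc_regression(x, x)
  expect_equal(exact$slope, 1)
  expect_equal(exact$r_squared, 1)
  set.seed(31)
  slopes <- replicate(20, {
    xs <- runif(100, 0.3, 0.6)
    ys <- 1.1 * xs + rnorm(100, 0, 0.02)
    neighborhood_gc_regression(ys, xs)$slope
  })
  expect_lt(max(abs(slopes - 1.1)), 0.05)
  anti <- neighborhood_gc_regression(0.9 - seq(0.3, 0.6, 0.02),
                                     seq(0.3, 0.6, 0.02))
  expect_equal(anti$r_squared, 0)
  expect_error(neighborhood_gc_regression(1:2, 1:2), "3")
})

test_that("association matrix encodes presence exactly", {
  cs <- data.frame(strain = c("s1", "s1", "s2"),
                   cluster_id = c("c1", "c2", "c2"),
                   species = "sp1", stringsAsFactors = FALSE)
  m <- build_association_matrix(cs)
  expect_equal(unclass(m)[, ], matrix(c(1L, 0L, 1L, 1L), 2,
                                      dimnames = list(c("s1", "s2"),
                                                      c("c1", "c2"))),
               ignore_attr = TRUE)
  empty <- build_association_matrix(cs[0, ])
  expect_equal(dim(empty), c(0L, 0L))
})

test_that("duplicate-cluster cases count same-cluster pairs per genome", {
  cs <- data.frame(strain = c("s1", "s1", "s1", "s2", "s2"),
                   cluster_id = c("c7", "c7", "c1", "c9", "c9"),
                   orphan = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                   stringsAsFactors = FALSE)
  d <- duplicate_cluster_cases(cs)
  expect_equal(d$n_cases, 1L)
  expect_equal(d$cases$cluster_id, "c7")
  expect_equal(d$n_orphan_cases, 1L)
  expect_equal(duplicate_cluster_cases(cs[0, ])$n_cases, 0L)
})

test_that("per-species frequency averages across species where present", {
  cs <- data.frame(
    strain = c(paste0("a", 1:10), paste0("b", 1:10)),
    species = rep(c("spA", "spB"), each = 10),
    stringsAsFactors = FALSE)
  cs <- rbind(
    transform(cs, cluster_id = "c1"),  # everywhere
    data.frame(strain = c("a1", "a2", "b1", "b2", "b3", "b4"),
               species = c("spA", "spA", "spB", "spB", "spB", "spB"),
               cluster_id = "c2", stringsAsFactors = FALSE))
  f <- per_species_frequency(build_association_matrix(cs))
  s <- f$summary
  expect_equal(s$mean_frequency[s$cluster_id == "c1"], 1.0)
  expect_equal(s$mean_frequency[s$cluster_id == "c2"], 0.3)  # (0.2+0.4)/2
})

test_that("rarefaction endpoints, slopes and monotonicity behave", {
  full <- matrix(1L, 10, 7, dimnames = list(paste0("s", 1:10), paste0("c", 1:7)))
  r <- rarefaction_curve(full, n_resamples = 50, tail_window = 5, seed = 1)
  expect_equal(unname(r$mean_clusters), rep(7, 10))
  expect_equal(r$tail_slope, 0)

  uniq <- diag(1L, 10); dimnames(uniq) <- dimnames(full)[c(1, 1)]
  r2 <- rarefaction_curve(uniq, n_resamples = 50, tail_window = 5, seed = 1)
  expect_equal(unname(r2$mean_clusters), 1:10)
  expect_equal(r2$tail_slope, 1)
  expect_error(rarefaction_curve(full, tail_window = 10), "tail_window")

  set.seed(32)
  for (rep in 1:100) {
    m <- matrix(rbinom(8 * 6, 1, 0.4), 8, 6,
                dimnames = list(paste0("s", 1:8), paste0("c", 1:6)))
    rc <- rarefaction_curve(m, n_resamples = 30, tail_window = 4,
                            seed = rep)
    expect_true(all(diff(rc$mean_clusters) >= -1e-12))
    expect_equal(rc$mean_clusters[8], sum(colSums(m) > 0))
  }
  d1 <- rarefaction_curve(full, n_resamples = 20, tail_window = 3, seed = 5)
  d2 <- rarefaction_curve(full, n_resamples = 20, tail_window = 3, seed = 5)
  expect_identical(d1$mean_clusters, d2$mean_clusters)
})
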