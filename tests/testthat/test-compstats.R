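# compositional transforms and the nested-permutation PERMANOVA engine

test_that("relative abundance follows the volume ratios", {
  expect_equal(to_relative_abundance(c(8, 67, 25)), c(0.08, 0.67, 0.25))
  expect_equal(to_relative_abundance(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(to_relative_abundance(c(0, 0, 10)), c(0, 0, 1))
  expect_error(to_relative_abundance(c(0, 0, 0)), "undefined")
})

test_that("date-then-month aggregation weighs each date equally", {
  s <- data.frame(
    date = as.Date(c("2021-01-05", "2021-01-05", "2021-01-20", "2021-02-01")),
    clump_id = c(1, 2, 1, 1),
    vol_sni_ml = c(10, 30, 0, 20),
    vol_snviii_ml = c(10, 10, 50, 20),
    vol_sfiii_ml = c(20, 10, 50, 10))
  out <- aggregate_date_then_month(s)
  # hand-computed: date 1 mean of (.25,.25,.5) and (.6,.2,.2) = (.425,.225,.35)
  # date 2 = (0,.5,.5); January = mean of the two dates
  jan <- out[out$month == "2021-01", ]
  expect_equal(c(jan$p_sni, jan$p_snviii, jan$p_sfiii),
               c(0.2125, 0.3625, 0.425))
  expect_equal(jan$n_dates, 2L)
  feb <- out[out$month == "2021-02", ]
  expect_equal(c(feb$p_sni, feb$p_snviii, feb$p_sfiii), c(0.4, 0.4, 0.2))
  # a single sample passes through unchanged
  one <- aggregate_date_then_month(s[4, ])
  expect_equal(one$p_sni, 0.4)
})

test_that("the bivariate log-ratio transform matches its formulas and inverts", {
  expect_equal(unname(ilr_bivariate(rep(1 / 3, 3))[1, ]), c(0, 0))
  z <- ilr_bivariate(c(0.5, 0.25, 0.25))
  expect_equal(unname(z[1, 1]), log(2) / sqrt(2), tolerance = 1e-10)
  expect_equal(unname(z[1, 2]),
               sqrt(2 / 3) * log(sqrt(0.125) / 0.25), tolerance = 1e-10)
  expect_equal(unname(z[1, ]), c(0.4901, 0.2830), tolerance = 1e-4)
  # round trip over random compositions
  set.seed(3)
  comp <- rdirichlet_mean(50, c(0.2, 0.3, 0.5), 10)
  expect_equal(ilr_inverse(ilr_bivariate(comp)), comp, tolerance = 1e-9)
  # zero replacement keeps coordinates finite and compositions valid
  zz <- ilr_bivariate(c(0, 0.4, 0.6))
  expect_true(all(is.finite(zz)))
})

test_that("ternary coordinates map the simplex onto an equilateral triangle", {
  expect_equal(unname(ternary_coords(c(1, 0, 0))[1, ]), c(0, 0))
  expect_equal(unname(ternary_coords(rep(1 / 3, 3))[1, ]),
               c(0.5, sqrt(3) / 6))
  v <- ternary_coords(diag(3))
  d <- as.matrix(dist(v))
  expect_equal(d[lower.tri(d)], rep(1, 3))   # side length 1
})

test_that("identical groups give F = 0 and p = 1", {
  z <- matrix(rep(c(1, 2), each = 12), ncol = 2)
  dates <- rep(paste0("d", 1:6), each = 2)
  g <- c(d1 = "A", d2 = "A", d3 = "A", d4 = "B", d5 = "B", d6 = "B")
  res <- permanova_nested(z, dates, g, n_perm = 99, seed = 1)
  expect_equal(res$aov_tab$F.Model[1], 0)
  expect_equal(res$aov_tab$p[1], 1)
})

test_that("insufficient date replication is rejected", {
  z <- matrix(rnorm(12), ncol = 2)
  dates <- rep(c("d1", "d2", "d3"), each = 2)
  g <- c(d1 = "A", d2 = "B", d3 = "B")
  expect_error(permanova_nested(z, dates, g, n_perm = 9), "replication")
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on 6 dates", {
  set.seed(10)
  comp <- rbind(rdirichlet_mean(9, c(0.15, 0.25, 0.60), 12),
                rdirichlet_mean(9, c(0.10, 0.45, 0.45), 12))
  z <- ilr_bivariate(comp)
  dates <- rep(paste0("d", 1:6), each = 3)
  g <- setNames(rep(c("A", "B"), each = 3), paste0("d", 1:6))

  # independent oracle: enumerate all 20 assignments of 3 dates to A,
  # computing pseudo-F from coordinates (not from the distance matrix)
  picks <- combn(6, 3)
  f_all <- apply(picks, 2, function(ix) {
    gg <- rep("B", 6); gg[ix] <- "A"
    oracle_pseudo_f(z, gg[match(dates, paste0("d", 1:6))])
  })
  f_obs <- oracle_pseudo_f(z, g[dates])
  p_exh <- mean(f_all >= f_obs - 1e-12)

  res_ex <- permanova_nested(z, dates, g, method = "exhaustive")
  expect_equal(res_ex$aov_tab$F.Model[1], f_obs, tolerance = 1e-10)
  expect_equal(res_ex$aov_tab$p[1], p_exh, tolerance = 1e-12)

  res_mc <- permanova_nested(z, dates, g, n_perm = 20000, seed = 4)
  se <- sqrt(p_exh * (1 - p_exh) / 20000)
  expect_lt(abs(res_mc$aov_tab$p[1] - p_exh), 3 * se + 2 / 20001)
})

test_that("unrestricted mode reproduces a standard one-factor PERMANOVA", {
  set.seed(5)
  z <- rbind(matrix(rnorm(20, 0), ncol = 2), matrix(rnorm(16, 0.8), ncol = 2))
  grp <- rep(c("A", "B"), c(10, 8))
  dates <- paste0("s", seq_len(18))   # every sample its own date: free perms
  res <- permanova_nested(z, dates, setNames(grp, dates), n_perm = 999,
                          seed = 9)
  veg <- vegan::adonis2(dist(z) ~ grp, permutations = 999)
  expect_equal(res$aov_tab$F.Model[1], veg$F[1], tolerance = 1e-8)
  expect_equal(res$aov_tab$SumOfSqs[1:2], veg$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(res$aov_tab$p[1], veg$`Pr(>F)`[1], tolerance = 0.05)
})

test_that("the F statistic is invariant to rigid rotation of the response", {
  set.seed(6)
  z <- matrix(rnorm(36), ncol = 2)
  dates <- rep(paste0("d", 1:6), each = 3)
  g <- setNames(rep(c("A", "B"), 3), paste0("d", 1:6))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  r1 <- permanova_nested(z, dates, g, n_perm = 49, seed = 1)
  r2 <- permanova_nested(z %*% R, dates, g, n_perm = 49, seed = 1)
  expect_equal(r1$aov_tab$F.Model[1], r2$aov_tab$F.Model[1], tolerance = 1e-10)
  expect_equal(r1$aov_tab$p[1], r2$aov_tab$p[1])
})

test_that("dispersion test: translated groups are homogeneous, scaled are not", {
  set.seed(8)
  base <- matrix(rnorm(40), ncol = 2)
  shifted <- sweep(base, 2, c(5, -3), "+")
  z <- rbind(base, shifted)
  grp <- rep(c("A", "B"), each = 20)
  hom <- dispersion_homogeneity(z, grp, n_perm = 199, seed = 1)
  expect_equal(unname(diff(hom$group_means)), 0, tolerance = 1e-10)
  expect_lt(hom$F, 1e-10)
  expect_gt(hom$p, 0.9)
  z2 <- rbind(base, sweep(base, 2, colMeans(base)) * 5)
  het <- dispersion_homogeneity(z2, grp, n_perm = 199, seed = 1)
  expect_gt(het$F, 10)
  expect_lt(het$p, 0.05)
})

test_that("Euclidean embedding reproduces direct distances to centroids", {
  set.seed(9)
  z <- matrix(rnorm(30), ncol = 2)
  grp <- rep(c("A", "B"), each = 5)[c(1:5, 6:10, 1:5)]
  res <- dispersion_homogeneity(z, grp, n_perm = 9, seed = 1)
  direct <- sqrt(rowSums((z - (rowsum(z, grp) / as.vector(table(grp)))[grp, ])^2))
  expect_equal(unname(res$distances), unname(direct), tolerance = 1e-9)
})

test_that("dispersion cross-checks against the reference implementation", {
  set.seed(12)
  z <- rbind(matrix(rnorm(30), ncol = 2), matrix(rnorm(24, 0, 2.5), ncol = 2))
  grp <- factor(rep(c("A", "B"), c(15, 12)))
  ours <- dispersion_homogeneity(z, grp, n_perm = 99, seed = 2)
  ref <- vegan::betadisper(dist(z), grp, type = "centroid")
  expect_equal(unname(ours$distances), unname(ref$distances), tolerance = 1e-8)
  expect_equal(ours$F, stats::anova(ref)$`F value`[1], tolerance = 1e-8)
})
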