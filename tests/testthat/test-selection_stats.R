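test_that("call-rate filtering uses the 80% boundary inclusively", {
  rows <- data.frame(AN = c(121850L, 121849L, 0L))
  expect_equal(filter_call_rate(rows)$AN, 121850L)
  expect_equal(nrow(filter_call_rate(rows, frac = 0)), 3L)
})

test_that("constraint matching reproduces quartile occupancy exactly", {
  a <- data.frame(constraint_z = qnorm((1:100) / 101))
  b <- data.frame(constraint_z = rnorm(1000, 0, 1.3))
  mb <- constraint_matched_sample(a, b, seed = 2)
  expect_equal(attr(mb, "bin_counts"), c(25L, 25L, 25L, 25L))
  expect_equal(nrow(mb), 100L)
  # all of group_a in one quartile -> all of the sample from that bin
  a2 <- data.frame(constraint_z = rep(0, 40))
  mb2 <- constraint_matched_sample(a2, b, seed = 2)
  expect_equal(sum(attr(mb2, "bin_counts") > 0), 1L)
  # empty bin in b -> error naming the bin
  b2 <- data.frame(constraint_z = rnorm(50, 10))
  expect_error(constraint_matched_sample(a, b2, seed = 2),
               "constraint bin")
  # determinism
  expect_identical(constraint_matched_sample(a, b, seed = 5),
                   constraint_matched_sample(a, b, seed = 5))
})

test_that("MAF comparisons detect stochastic ordering", {
  expect_equal(compare_maf(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(compare_maf(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # complete separation: D = 1
  r <- compare_maf(c(0.01, 0.02, 0.03), c(0.5, 0.6, 0.7))
  expect_equal(r$statistic, 1)
  expect_lte(r$p, 0.05)  # exact one-sided p at n = 3 vs 3 is 1/20 = 0.05
  set.seed(7)
  br <- rbeta(2000, 0.3, 30); ne <- rbeta(2000, 0.5, 30)
  expect_lt(compare_maf(br, ne)$p, 0.05)
  expect_lt(compare_maf(br, ne, test = "mwu")$p, 0.05)
  expect_error(compare_maf(1, c(1, 2)), ">= 2")
})

test_that("rare fraction uses a strict threshold", {
  expect_equal(rare_fraction(data.frame(MAF = c(0.0005, 0.002, 0.05))),
               1 / 3)
  expect_equal(rare_fraction(c(0.5, 0.9)), 0)
  expect_equal(rare_fraction(c(0.001, 0.01), threshold = 0.001), 0)
  expect_error(rare_fraction(numeric(0)), "empty")
})

test_that("length stratification excludes the middle band", {
  rows <- data.frame(rg4_length = c(20, 25, 30))
  st <- length_stratify(rows)
  expect_equal(st$short$rg4_length, 20)
  expect_equal(st$long$rg4_length, 30)
  st2 <- length_stratify(rows, long_min = 31)
  expect_equal(nrow(st2$long), 0L)
  st3 <- length_stratify(rows[0, , drop = FALSE])
  expect_equal(nrow(st3$short) + nrow(st3$long), 0L)
})

test_that("CADD bins report means, SDs and monotone trends", {
  rows <- data.frame(cadd_raw = runif(50, 0, 10), delta = -0.5)
  tr <- cadd_bin_trend(rows, 5)
  expect_true(all(tr$mean_delta == -0.5))
  expect_true(all(tr$sd_delta == 0))
  single <- cadd_bin_trend(data.frame(cadd_raw = 3, delta = -0.2), 5)
  expect_equal(nrow(single), 1L)
  # deltas linear in CADD -> bin means monotone
  set.seed(9)
  cadd <- runif(400, 0, 20)
  rows2 <- data.frame(cadd_raw = cadd, delta = -0.05 * cadd)
  tr2 <- cadd_bin_trend(rows2, 8)
  expect_true(all(diff(tr2$mean_delta) < 0))
})

test_that("subtype distribution shifts use the 2xK chi-square", {
  same <- subtype_distribution_shift(c(a = 10, b = 20), c(a = 10, b = 20))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  disj <- subtype_distribution_shift(c(a = 1000, b = 0),
                                     c(a = 0, b = 1000))
  expect_lt(disj$p, 1e-10)
  expect_warning(subtype_distribution_shift(c(a = 5, b = 0, c = 3),
                                            c(a = 7, b = 0, c = 4)),
                 "zero-total")
  expect_error(suppressWarnings(
    subtype_distribution_shift(c(a = 5), c(a = 7))), "two non-empty")
  # cross-check against the closed form on a known table
  cs <- subtype_distribution_shift(c(a = 30, b = 10), c(a = 10, b = 30))
  ref <- chisq.test(rbind(c(30, 10), c(10, 30)))
  expect_equal(cs$statistic, unname(ref$statistic))
})

test_that("Welch ANOVA + Games-Howell flag the shifted group", {
  g0 <- list(a = c(1, 2, 3), b = c(2, 3, 1), c = c(3, 1, 2))
  r0 <- delta_by_subtype_test(g0)
  expect_equal(r0$omnibus$statistic, 0)
  expect_equal(r0$omnibus$p, 1)
  set.seed(8)
  g <- list(a = rnorm(200), b = rnorm(200), c = rnorm(200, -1))
  r <- delta_by_subtype_test(g)
  expect_lt(r$omnibus$p, 1e-6)
  pw <- r$pairwise
  expect_lt(pw$p_adj[pw$group1 == "a" & pw$group2 == "c"], 0.001)
  expect_lt(pw$p_adj[pw$group1 == "b" & pw$group2 == "c"], 0.001)
  expect_gt(pw$p_adj[pw$group1 == "a" & pw$group2 == "b"], 0.05)
  # omnibus agrees with the base-R Welch test
  ref <- oneway.test(v ~ grp, data.frame(v = unlist(g),
                                         grp = rep(names(g), each = 200)),
                     var.equal = FALSE)
  expect_equal(r$omnibus$statistic, unname(ref$statistic))
  # rank-based alternative
  rk <- delta_by_subtype_test(g, method = "kruskal_dunn")
  expect_lt(rk$omnibus$p, 1e-6)
  expect_lt(rk$pairwise$p_adj[rk$pairwise$group1 == "a" &
                                rk$pairwise$group2 == "c"], 0.001)
  expect_error(delta_by_subtype_test(g[1]), "two groups")
  expect_error(delta_by_subtype_test(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("pathogenicity contrast computes fold, binomial and MWU readouts", {
  rows <- data.frame(
    clinsig = c(rep("PATHOGENIC", 5), rep("BENIGN", 5),
                rep("BENIGN", 40)),
    delta = c(rep(-0.8, 10), rep(0, 40)))
  pc <- pathogenicity_contrast(rows)
  expect_equal(pc$fold_enrichment, 5)   # 0.5 / 0.1
  expect_equal(pc$binom_p, pbinom(4, 10, 0.1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(pc$mwu_p, 0.05)
  # no disrupting rows -> fold absent
  pc2 <- pathogenicity_contrast(data.frame(
    clinsig = c("PATHOGENIC", "BENIGN", "BENIGN"), delta = c(0, 0, 0)))
  expect_true(is.na(pc2$fold_enrichment))
  # identically distributed deltas -> MWU p near 0.5
  set.seed(12)
  d <- rnorm(4000)
  rows3 <- data.frame(clinsig = rep(c("PATHOGENIC", "BENIGN"), 2000),
                      delta = d)
  expect_gt(pathogenicity_contrast(rows3)$mwu_p, 0.05)
})

test_that("small-sample tests agree with brute-force permutation", {
  # permutation cross-check of the one-sided MWU on n <= 12
  x <- c(0.1, 0.5, 0.9); y <- c(0.2, 0.4, 0.6, 0.8)
  obs <- wilcox.test(x, y, alternative = "less")$p.value
  pool <- c(x, y)
  combs <- combn(7, 3)
  stat <- function(xi) sum(rank(pool)[xi]) # rank-sum of the x-sample
  obs_stat <- stat(1:3)
  perm_p <- mean(apply(combs, 2, stat) <= obs_stat)
  expect_equal(obs, perm_p, tolerance = 1e-12)
})
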