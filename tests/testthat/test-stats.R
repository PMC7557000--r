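test_that("equivalent sphere diameter matches the reported landmarks", {
  expect_equal(equivalent_sphere_diameter(4 / 3 * pi), 2) # unit sphere r=1
  r <- equivalent_sphere_diameter(c(1000, 500000), rounded = TRUE)
  expect_equal(r$diameter_um_rounded, c(12, 98))
  expect_error(equivalent_sphere_diameter(0), "positive")
  expect_error(equivalent_sphere_diameter(-5), "positive")
})

test_that("volume distribution bins are closed-open and sum to 100", {
  vd <- volume_distribution(c(500, 2000, 60000, 600000))
  expect_equal(vd$percent, c(25, 25, 25, 25))
  expect_equal(sum(vd$percent), 100)
  # boundary values fall in the upper bin (closed-open)
  vb <- volume_distribution(c(1000, 50000, 500000))
  expect_equal(vb$percent, c(0, 100 / 3, 100 / 3, 100 / 3))
  one <- volume_distribution(rep(2000, 7))
  expect_equal(one$percent, c(0, 100, 0, 0))
  expect_equal(one$median_um3, 2000)
  expect_error(volume_distribution(numeric(0)), "empty")
})

test_that("innervated comparison reports ratio and volume share", {
  rec <- data.frame(islet_id = 1:4, volume_um3 = c(100, 300, 10, 30),
                    innervated = c(TRUE, TRUE, FALSE, FALSE),
                    region = NA_integer_)
  ic <- innervated_comparison(rec)
  expect_equal(ic$mean_volume_ratio, 10)
  expect_equal(ic$innervated_volume_share_pct, 100 * 400 / 440)
  # single class: ratio undefined
  rec1 <- rec
  rec1$innervated <- FALSE
  expect_true(is.na(innervated_comparison(rec1)$mean_volume_ratio))
  # equal means: ratio 1
  rec2 <- data.frame(islet_id = 1:4, volume_um3 = c(50, 150, 60, 140),
                     innervated = c(TRUE, TRUE, FALSE, FALSE),
                     region = NA_integer_)
  expect_equal(innervated_comparison(rec2)$mean_volume_ratio, 1)
  expect_error(innervated_comparison(rec[0, ]), "empty")
})

test_that("median CI matches binomial order-statistic enumeration", {
  set.seed(1)
  for (n in c(8, 15, 30)) {
    x <- rnorm(n)
    ci <- median_ci(x, conf = 0.95)
    xs <- sort(x)
    # oracle: widest j with coverage >= 0.95 by direct enumeration
    j_or <- NA
    for (j in seq_len(floor(n / 2))) {
      cov <- sum(dbinom(j:(n - j), n, 0.5))
      if (cov >= 0.95) j_or <- j
    }
    expect_equal(ci$lower, xs[j_or])
    expect_equal(ci$upper, xs[n - j_or + 1])
    expect_gte(ci$coverage, 0.95)
  }
})

test_that("normality gate chooses the tests the design prescribes", {
  # identical samples: t statistic 0, p = 1, never significant
  d <- data.frame(y = c(1, 2, 3, 1, 2, 3), group = rep(c("a", "b"), each = 3))
  gs <- group_compare(d, "y")
  expect_equal(gs$test, "t")
  expect_equal(gs$statistic, 0)
  expect_equal(gs$p_value, 1)
  expect_false(gs$significant)

  # forced nonparametric, fully separated ranks: exact two-sided MW p = 0.1
  d2 <- data.frame(y = c(1, 2, 3, 4, 5, 6), group = rep(c("a", "b"), each = 3))
  gs2 <- group_compare(d2, "y", force = "nonparametric")
  expect_equal(gs2$test, "MannWhitney")
  # oracle: 2 of choose(6,3)=20 orderings as extreme in either direction
  expect_equal(gs2$p_value, 2 / 20)
  expect_false(gs2$significant) # 0.1 > alpha

  # significance flag is exactly p < alpha
  expect_false(group_compare(d2, "y", force = "nonparametric",
                             alpha = 0.05)$significant)
  expect_true(group_compare(d2, "y", force = "nonparametric",
                            alpha = 0.11)$significant)

  # three normal groups -> ANOVA + Tukey with a pairwise table
  set.seed(2)
  d3 <- data.frame(y = c(rnorm(8), rnorm(8, 3), rnorm(8, 6)),
                   group = rep(c("a", "b", "c"), each = 8))
  gs3 <- group_compare(d3, "y")
  expect_equal(gs3$test, "ANOVA+Tukey")
  expect_equal(nrow(gs3$pairwise), 3)
  expect_true(all(gs3$pairwise$p_value >= 0 & gs3$pairwise$p_value <= 1))

  # grossly skewed group trips the gate -> Kruskal-Wallis + Dunn
  d4 <- d3
  d4$y[d4$group == "a"] <- c(0.01, 0.02, 0.03, 0.05, 20, 40, 80, 160)
  gs4 <- group_compare(d4, "y")
  expect_equal(gs4$test, "KruskalWallis+Dunn")
  expect_equal(nrow(gs4$pairwise), 3)

  expect_error(group_compare(d3[d3$group == "a", ], "y"), "two groups")
  expect_error(group_compare(data.frame(y = c(1, 2), group = c("a", "b")),
                             "y"), "at least two observations")
})

test_that("Dunn test agrees with the omnibus Kruskal-Wallis on separation", {
  set.seed(9)
  y <- c(rnorm(10), rnorm(10, 10), rnorm(10, 20))
  g <- rep(c("a", "b", "c"), each = 10)
  dn <- dunn_test(y, g)
  kw <- kruskal.test(y, factor(g))
  expect_lt(kw$p.value, 0.001)
  expect_lt(dn$p_value[dn$group1 == "a" & dn$group2 == "c"], 0.001)
  # unadjusted p never exceeds adjusted
  dn0 <- dunn_test(y, g, p_adjust = "none")
  expect_true(all(dn0$p_value <= dn$p_value + 1e-12))
  # z for the extreme pair has the expected sign (a below c in mean rank)
  expect_lt(dn$z[dn$group1 == "a" & dn$group2 == "c"], 0)
})

test_that("correlation gate and estimates behave", {
  x <- 1:10
  co <- correlate(x, 2 * x)
  expect_equal(co$method, "pearson")
  expect_equal(co$estimate, 1)
  expect_lt(co$p_value, 0.05)
  set.seed(2)
  co2 <- correlate(x, -x + rnorm(10, 0, 1e-6))
  expect_lt(co2$estimate, -0.999)
  # non-normal marginal flips to spearman
  set.seed(3)
  xs <- exp(rnorm(30, 0, 2))
  co3 <- correlate(xs, rank(xs) + rnorm(30, 0, 4))
  expect_equal(co3$method, "spearman")
  expect_error(correlate(1:3, 1:4), "mismatched")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("analytic correlation p is consistent with a permutation oracle", {
  set.seed(8)
  x <- rnorm(12)
  y <- 0.8 * x + rnorm(12, 0, 0.8)
  co <- correlate(x, y)
  r_obs <- abs(co$estimate)
  perm <- replicate(10000, abs(cor(x, sample(y))))
  p_perm <- (1 + sum(perm >= r_obs)) / 10001
  expect_lt(abs(p_perm - co$p_value), 0.02) # Monte-Carlo slack
})

test_that("region summary reproduces hand-computed toy volumetrics", {
  d <- c(10L, 10L, 10L)
  vs <- c(5, 5, 5)
  tissue <- array(TRUE, d)
  islet <- array(FALSE, d)
  islet[1, 1, 1:10] <- TRUE
  islet[1, 2, 1:3] <- TRUE # 13 voxels, 26-connected to the row above
  islets <- connected_components(islet, vs)
  nerve <- array(FALSE, d)
  nerve[1, 1, 1:5] <- TRUE  # 5 voxels inside the islet
  nerve[5, 5, 1:5] <- TRUE  # 5 voxels outside
  rec <- islet_nerve_distances(islets, nerve)
  rs <- region_summary(rec, nerve, tissue, vs, tissue_mean_intensity = 1)
  tot <- rs[rs$scope == "total", ]
  expect_equal(tot$beta_volume_percent, 1.3) # 13 / 1000 voxels
  # endocrine: 5 nerve voxels / 13 islet voxels; exocrine: 5 / 987
  expect_equal(tot$endocrine_nerve_density_percent, 100 * 5 / 13)
  expect_equal(tot$exocrine_nerve_density_percent, 100 * 5 / 987)
  # conservation: endocrine + exocrine nerve volume = total nerve volume
  expect_equal(tot$endocrine_nerve_volume_um3 + tot$exocrine_nerve_volume_um3,
               sum(nerve) * 125)
  # all percentages bounded
  pct_cols <- grep("percent|pct", names(tot), value = TRUE)
  for (cl in pct_cols) {
    v <- tot[[cl]]
    if (is.finite(v)) expect_true(v >= 0 && v <= 100 + 1e-9)
  }
  expect_equal(sum(tot[paste0("volume_bin_pct_", 1:4)]), 100)
  expect_error(region_summary(rec, nerve, array(FALSE, d), vs), "positive")
})

test_that("normalization against itself yields exactly 1", {
  d <- c(6L, 6L, 6L)
  vs <- c(5, 5, 5)
  islet <- array(FALSE, d)
  islet[2:3, 2:3, 2:3] <- TRUE
  chan <- array(0, d)
  chan[islet] <- 700
  islets <- connected_components(islet, vs,
                                 intensity_channels = list(insulin = chan))
  rec <- islet_nerve_distances(islets, array(FALSE, d))
  rs <- region_summary(rec, NULL, array(TRUE, d), vs,
                       normalization_reference = 700)
  expect_equal(rs$normalized_insulin_intensity[1], 1)
})
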