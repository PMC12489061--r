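test_that("relative level returns paired ratios with mean and SEM", {
  r <- relative_level(c(2, 4, 6), c(2, 4, 6))
  expect_equal(r$mean_ratio, 1)
  expect_equal(r$ratio_of_means, 1)
  r2 <- relative_level(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$ratios, c(2, 2, 2))
  expect_equal(r2$mean_ratio, 2)
  expect_equal(r2$sem, 0)
  expect_error(relative_level(c(1, 2), c(1, 0)), "zero control")
  expect_error(relative_level(c(1, 2), c(1, 2, 3)), "paired")
  # planted ratio recovered from the synthetic generator: with cv 0.3 and
  # n = 8 the ratio-of-means SE is ~ 7 * sqrt(2 * 0.09 / 8) ~ 1.05, so a
  # 40% band is > 2.5 sigma for the fixed seed
  tab <- generate_assay_replicates(7, cv = 0.3, n = 8, seed = 5)
  est <- relative_level(tab$value[tab$condition == "sample"],
                        tab$value[tab$condition == "control"])
  expect_equal(est$ratio_of_means, 7, tolerance = 0.4)
})

test_that("fold inhibition, donor preference and their arithmetic", {
  expect_equal(fold_inhibition(c(0.7, 0.7), c(0.1, 0.1)), 7)
  expect_equal(fold_inhibition(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_warning(f <- fold_inhibition(c(1, 2), c(0, 0)), "infinite")
  expect_identical(f, Inf)
  expect_equal(donor_preference(c(2, 2), c(2, 2))$fold, 1)
  expect_equal(donor_preference(c(20, 40), c(1, 2))$fold, 20)
  # transcription dividing intra by 1.8 and multiplying inter by 2.6
  # collapses a 20-fold preference to 20 / (1.8 * 2.6)
  set.seed(8)
  base_intra <- 20 * exp(rnorm(8, 0, 0.05))
  base_inter <- 1 * exp(rnorm(8, 0, 0.05))
  pref0 <- donor_preference(base_intra, base_inter)$fold
  pref1 <- donor_preference(base_intra / 1.8, base_inter * 2.6)$fold
  expect_equal(pref1, pref0 / (1.8 * 2.6))
  expect_equal(pref1, 20 / (1.8 * 2.6), tolerance = 0.1)
  # ratio composition on group means
  inactive <- c(0.8, 0.6, 0.7); active <- c(0.12, 0.08, 0.1)
  ctrl <- c(1.1, 0.9, 1.0)
  expect_equal(
    fold_inhibition(inactive, active) *
      relative_level(active, ctrl)$ratio_of_means,
    relative_level(inactive, ctrl)$ratio_of_means)
})

test_that("recombinant frequency normalizes to circularization efficiency", {
  r <- recombinant_frequency(c(5, 5), c(5, 5), c(2, 2))
  expect_equal(r$mean, 100)
  expect_equal(recombinant_frequency(c(0, 0), c(4, 4), c(1, 1))$mean, 0)
  # loading control cancels: scaling it must not change the result
  r1 <- recombinant_frequency(c(3, 4), c(6, 8), c(1, 1))
  r2 <- recombinant_frequency(c(3, 4), c(6, 8), c(10, 20))
  expect_equal(r1$percent, r2$percent)
  expect_equal(r1$mean, 50)
  expect_error(recombinant_frequency(c(1, 1), c(0, 1), c(1, 1)), "circ")
})

test_that("viability and translocation frequency arithmetic", {
  expect_equal(plating_viability(50, 100), 50)
  expect_equal(plating_viability(100, 100), 100)
  expect_equal(plating_viability(50, 100, dilution_factor = 2), 100)
  expect_error(plating_viability(10, 0), "undefined")
  m <- mir_frequency(10, 1e5, 1, 1e6)
  expect_equal(m$frequency, 9.9e-5)
  expect_equal(mir_frequency(5, 1e5, 50, 1e6)$frequency, 0)  # floored
  expect_error(mir_frequency(1, 0, 1, 10), "viable")
  # Poisson resampling around a true 46% viability is unbiased
  viab <- vapply(1:200, function(s) {
    set.seed(s)
    plating_viability(rpois(1, 0.46 * 400), rpois(1, 400))
  }, numeric(1))
  expect_equal(mean(viab), 46, tolerance = 0.05)
})

test_that("estimators are invariant to rescaling every raw signal", {
  set.seed(99)
  a <- runif(6, 1, 5); b <- runif(6, 1, 5); k <- 137.5
  expect_equal(relative_level(a, b)$ratios, relative_level(k * a, k * b)$ratios)
  expect_equal(fold_inhibition(a, b), fold_inhibition(k * a, k * b))
  expect_equal(donor_preference(a, b)$fold, donor_preference(k * a, k * b)$fold)
  expect_equal(recombinant_frequency(a, b, rep(1, 6))$percent,
               recombinant_frequency(k * a, k * b, rep(k, 6))$percent)
  expect_equal(plating_viability(a[1], b[1]),
               plating_viability(k * a[1], k * b[1]))
})

test_that("two-group comparison follows the small-n switch rule", {
  # clearly separated groups, n = 4: exact rank-sum p is 2 / choose(8, 4)
  r <- rank_sum_compare(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_identical(r$method, "wilcoxon")
  expect_equal(r$p.value, 2 / choose(8, 4))
  # n = 3: the t-branch is invoked and flagged
  r3 <- rank_sum_compare(c(1, 2, 3), c(10, 11, 12))
  expect_identical(r3$method, "t")
  # identical groups: p = 1 by convention
  expect_equal(rank_sum_compare(c(2, 2, 2, 2), c(2, 2, 2, 2))$p.value, 1)
  expect_equal(rank_sum_compare(c(1, 2), c(1, 2), paired = TRUE)$p.value, 1)
  expect_error(rank_sum_compare(1, c(1, 2)), "n >= 2")
})

test_that("exact rank-sum p-values equal exhaustive permutation enumeration", {
  # oracle: two-sided p = fraction of all C(n1+n2, n1) group assignments
  # whose rank-sum statistic is at least as extreme as observed
  exact_p <- function(a, b) {
    v <- c(a, b); n1 <- length(a)
    obs <- sum(rank(v)[seq_len(n1)])
    idx <- utils::combn(length(v), n1)
    stats <- apply(idx, 2, function(i) sum(rank(v)[i]))
    mu <- n1 * (length(v) + 1) / 2
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(55)
  for (i in 1:20) {
    n1 <- sample(4:6, 1); n2 <- sample(4:6, 1)
    a <- sample(100, n1); b <- sample(200, n2) + 0.5  # distinct, no ties
    r <- rank_sum_compare(a, b)
    expect_equal(r$p.value, exact_p(a, b), info = paste("case", i))
  }
})
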