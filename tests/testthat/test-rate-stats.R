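# Rates, bootstrap, permutation and Wasserstein tests, chi-square, BH,
# windows.

test_that("event rates reproduce the published count arithmetic", {
  w <- event_rate(785, 79, 800)
  expect_equal(w$rate_per_genome, 1.24e-2, tolerance = 0.005)
  expect_equal(event_rate(936, 83, 800)$rate_per_genome, 1.41e-2,
               tolerance = 0.005)
  expect_equal(event_rate(553, 79, 800)$per_line, 7.0, tolerance = 0.001)
  expect_identical(event_rate(0, 10, 100)$rate_per_genome, 0)
  expect_equal(event_rate(50, 10, 100, L = 5e4)$rate_per_bp,
               50 / (10 * 100 * 5e4))
})

test_that("conversion rate is mean fraction over generations", {
  expect_equal(conversion_rate(0.061, 800), 7.625e-5)
  expect_identical(conversion_rate(0, 800), 0)
  expect_identical(conversion_rate(1, 1), 1)
  expect_error(conversion_rate(1.2, 800))
})

test_that("bootstrap CI is percentile-correct, deterministic and collapses
           for constant data", {
  expect_equal(unname(bootstrap_ci(rep(5, 10), seed = 1)),
               c(5, 5, 5))
  set.seed(51)
  x <- rpois(60, 9)
  ci1 <- bootstrap_ci(x, seed = 9)
  ci2 <- bootstrap_ci(x, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lower"]], ci1[["estimate"]])
  expect_gte(ci1[["upper"]], ci1[["estimate"]])
})

test_that("bootstrap CI covers the true mean at roughly the nominal rate", {
  n_rep <- 200
  hit <- vapply(seq_len(n_rep), function(i) {
    set.seed(1000 + i)
    x <- rpois(95, 13.2)
    ci <- bootstrap_ci(x, n_boot = 500)
    ci[["lower"]] <= 13.2 && 13.2 <= ci[["upper"]]
  }, TRUE)
  # binomial band around 0.95 at 200 replicates (percentile bootstrap
  # under-covers slightly at this n)
  expect_gt(mean(hit), 0.88)
  expect_lte(mean(hit), 1)
})

test_that("permutation p matches exhaustive enumeration for 3 vs 3", {
  a <- c(1, 4, 9)
  b <- c(2, 3, 12)
  x <- c(a, b)
  splits <- utils::combn(6, 3)
  d_all <- apply(splits, 2, function(idx) {
    abs(mean(x[idx]) - mean(x[-idx]))
  })
  obs <- abs(mean(a) - mean(b))
  # exhaustive analogue of the package's mid-p convention: ties (which
  # include the observed split and its mirror) carry half weight
  p_exact <- mean(d_all > obs) + 0.5 * mean(d_all == obs)
  res <- permutation_test(a, b, n_perm = 20000, seed = 3)
  expect_equal(res$p_value, p_exact, tolerance = 0.02)
})

test_that("identical groups give p near 1; p is never 0 or above 1", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  res <- permutation_test(x, x, n_perm = 500, seed = 4)
  expect_gt(res$p_value, 0.8)
  set.seed(5)
  for (i in 1:20) {
    r <- permutation_test(rpois(8, 5), rpois(8, 50), n_perm = 200)
    expect_gt(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
  expect_warning(permutation_test(1:5, 2:6, n_perm = 50), "n_perm")
})

test_that("median-statistic permutation test detects a location shift", {
  set.seed(6)
  a <- rpois(40, 20)
  b <- rpois(40, 9)
  res <- permutation_test(a, b, statistic = "median", n_perm = 500, seed = 6)
  expect_lt(res$p_value, 0.02)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(52)
  p <- vapply(seq_len(1000), function(i) {
    permutation_test(rpois(30, 13.2), rpois(30, 13.2),
                     n_perm = 999)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Wasserstein statistic has closed-form values and symmetry", {
  expect_identical(wasserstein_stat(c(5, 5), c(5, 5)), 0)
  expect_equal(wasserstein_stat(c(0, 1), c(2, 3)), 2)  # shift by 2
  expect_equal(wasserstein_stat(1:4, 1:4), 0)
  a <- runif(9); b <- runif(14)
  expect_equal(wasserstein_stat(a, b), wasserstein_stat(b, a))
})

test_that("Wasserstein test separates disjoint distributions and matches
           exhaustive enumeration on tiny samples", {
  set.seed(53)
  res <- wasserstein_test(runif(20, 0, 1e4), runif(20, 9e4, 1e5),
                          n_mc = 500, seed = 7)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$statistic, 8e4)

  a <- c(10, 30, 70)
  b <- c(22, 41, 95)
  x <- c(a, b)
  splits <- utils::combn(6, 3)
  d_all <- apply(splits, 2, function(idx) wasserstein_stat(x[idx], x[-idx]))
  obs <- wasserstein_stat(a, b)
  p_exact <- mean(d_all > obs) + 0.5 * mean(d_all == obs)  # mid-p analogue
  res2 <- wasserstein_test(a, b, n_mc = 20000, seed = 8)
  expect_equal(res2$p_value, p_exact, tolerance = 0.02)
})

test_that("Wasserstein p-values are uniform under the null", {
  set.seed(54)
  p <- vapply(seq_len(400), function(i) {
    wasserstein_test(runif(15), runif(15), n_mc = 200)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("arm chi-square matches the 2x2 hand formula and calibrates", {
  a <- c(arm1 = 30, arm2 = 10)
  b <- c(arm1 = 20, arm2 = 25)
  res <- arm_chisq(a, b)
  # hand Pearson chi-square
  tab <- rbind(a, b)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_lt(res$p_value, 0.05)

  same <- arm_chisq(c(10, 10, 10), c(10, 10, 10))
  expect_gt(same$p_value, 0.99)

  # size under equal rates
  set.seed(55)
  rej <- vapply(seq_len(400), function(i) {
    ka <- rpois(8, 20); kb <- rpois(8, 20)
    arm_chisq(ka, kb)$p_value <= 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("BH adjustment matches the hand-computed step-up on 5 values", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  # step-up: p_(i) * m / i, cumulative minimum from the largest
  want <- rev(cummin(rev(p * 5 / seq_len(5))))
  out <- bh_adjust(p)
  expect_equal(out$p_adj, want)
  expect_identical(bh_adjust(0.03)$p_adj, 0.03)
  allsame <- bh_adjust(rep(0.04, 6))
  expect_true(all(allsame$p_adj == 0.04))
  expect_true(all(out$p_adj >= out$p))
})

test_that("normalized rate is antisymmetric with the documented edge cases", {
  expect_identical(normalized_rate(5, 5), 0)
  expect_identical(normalized_rate(3, 0), 1)
  expect_equal(normalized_rate(2, 1), 1 / 3)
  expect_true(is.na(normalized_rate(0, 0)))
  for (i in 1:20) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    expect_equal(normalized_rate(a, b), -normalized_rate(b, a))
  }
})

test_that("windows tile chromosomes, truncate at ends and conserve counts", {
  map <- mk_map(list(chrA = c(100, 229000)), c(chrA = 230000))
  win <- make_windows(map)
  expect_identical(nrow(win), 5L)
  expect_equal(win$start, c(1, 50001, 100001, 150001, 200001))
  expect_equal(win$end[5], 230000)
  expect_true(win$truncated[5])
  expect_false(any(win$truncated[1:4]))

  set.seed(56)
  ev <- data.frame(chrom = "chrA",
                   breakpoint = sample.int(230000, 300, replace = TRUE))
  wr <- window_rates(ev, map, n = 10, T_gen = 100)
  expect_identical(sum(wr$k), 300)
  expect_equal(wr$rate, wr$k / (10 * 100 * wr$length))

  # boundary: breakpoint exactly at 50,000 belongs to the first window
  b <- window_rates(data.frame(chrom = "chrA", breakpoint = 50000),
                    map, n = 1, T_gen = 1)
  expect_identical(b$k[1], 1)
  expect_identical(sum(b$k), 1)
})

test_that("sliding windows cover each breakpoint once per covering window", {
  map <- mk_map(list(chrA = c(100, 140000)), c(chrA = 150000))
  ev <- data.frame(chrom = "chrA", breakpoint = 60000)
  wr <- window_rates(ev, map, n = 1, T_gen = 1, window = 50000,
                     slide = 10000)
  hit <- wr[wr$k > 0, ]
  expect_true(all(hit$start <= 60000 & hit$end >= 60000))
  expect_identical(nrow(hit), 5L)  # 50-kb window, 10-kb step
})

test_that("arm counts split at the centromere and conserve totals", {
  map <- mk_map(list(chrA = c(100, 99000)), c(chrA = 1e5), cen_rel = 0.5)
  ev <- data.frame(chrom = "chrA", breakpoint = c(1e4, 2e4, 8e4))
  ac <- arm_counts(ev, map)
  expect_identical(sum(ac), 3)
  expect_identical(unname(ac["chrA_L"]), 2)
  expect_identical(unname(ac["chrA_R"]), 1)
})
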