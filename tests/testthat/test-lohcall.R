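# Tract calling, merging, classification, breakpoints and the
# undetected-event correction.

test_that("the midpoint boundary rule matches the worked example", {
  map <- map5()
  calls <- c("HET", "HET", "HOM_P1", "HOM_P1", "HET")
  tr <- call_tracts(calls, map)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$left, 250)
  expect_equal(tr$right, 450)
  expect_identical(tr$homolog, "HOM_P1")
  expect_identical(tr$n_markers, 2L)
})

test_that("all-heterozygous input yields no tracts and unknown symbols fail", {
  map <- map5()
  expect_identical(nrow(call_tracts(rep("HET", 5), map)), 0L)
  expect_error(call_tracts(c("HET", "HET", "XX", "HET", "HET"), map),
               "unknown genotype call")
})

test_that("tract boundaries reach chromosome ends at terminal runs", {
  map <- map5()
  tr <- call_tracts(c("HOM_P2", "HOM_P2", "HET", "HET", "HOM_P1"), map)
  expect_equal(tr$left, c(1, 450))
  expect_equal(tr$right, c(250, 1000))
})

test_that("tract calls equal the brute-force oracle on random call strings", {
  set.seed(21)
  pos <- sort(sample(1:5000, 40))
  map <- mk_map(list(chrA = pos), c(chrA = 5000))
  for (i in 1:200) {
    calls <- sample(c("HET", "HOM_P1", "HOM_P2", "MISSING"), 40,
                    replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
    got <- call_tracts(calls, map)
    want <- oracle_tracts(calls, pos, 5000)
    expect_equal(got$first_pos, want$first_pos)
    expect_equal(got$last_pos, want$last_pos)
    expect_equal(got$left, want$left)
    expect_equal(got$right, want$right)
    expect_identical(got$homolog, want$homolog)
    expect_identical(as.integer(got$n_markers), as.integer(want$n_markers))
  }
})

test_that("MISSING is transparent by default but can break runs", {
  map <- map5()
  calls <- c("HOM_P1", "MISSING", "HOM_P1", "HET", "HET")
  transparent <- call_tracts(calls, map)
  expect_identical(nrow(transparent), 1L)
  expect_identical(transparent$n_markers, 2L)
  broken <- call_tracts(calls, map, missing = "break")
  expect_identical(nrow(broken), 2L)
  expect_identical(broken$n_markers, c(1L, 1L))
})

test_that("the 10-kb merge rule is strict and homolog-aware", {
  # markers at 1k..30k; geometry tuned so boundary gaps hit 9,999/10,000
  pos <- c(1000, 2000, 11999, 21999, 32000, 42000)
  map <- mk_map(list(chrA = pos), c(chrA = 50000))
  # tract1 = markers 1-2 (right boundary (2000+11999)/2 = 6999.5)
  # tract2 = markers 4   (left boundary (11999+21999)/2 = 16999)
  calls <- c("HOM_P1", "HOM_P1", "HET", "HOM_P1", "HET", "HET")
  tr <- call_tracts(calls, map)
  expect_equal(tr$left[2] - tr$right[1], 9999.5)
  ev <- merge_tracts(tr, map)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$n_tracts, 2L)
  expect_equal(ev$length, ev$right - ev$left)

  # push the gap to exactly 10,000: two events
  pos2 <- c(1000, 2000, 12000, 22000, 32000, 42000)
  map2 <- mk_map(list(chrA = pos2), c(chrA = 50000))
  tr2 <- call_tracts(calls, map2)
  expect_equal(tr2$left[2] - tr2$right[1], 10000)
  expect_identical(nrow(merge_tracts(tr2, map2)), 2L)
})

test_that("tracts of different homologs never merge", {
  pos <- c(1000, 1100, 1200, 1300, 1400, 1500)
  map <- mk_map(list(chrA = pos), c(chrA = 10000))
  calls <- c("HOM_P1", "HOM_P1", "HOM_P2", "HOM_P1", "HET", "HET")
  ev <- merge_tracts(call_tracts(calls, map), map)
  expect_identical(nrow(ev), 3L)
  expect_identical(ev$homolog, c("HOM_P1", "HOM_P2", "HOM_P1"))
})

test_that("merging a single tract is the identity and re-merging is
           idempotent", {
  set.seed(22)
  pos <- sort(sample(1:60000, 60))
  map <- mk_map(list(chrA = pos), c(chrA = 60000))
  calls <- sample(c("HET", "HOM_P1", "HOM_P2"), 60, replace = TRUE)
  tr <- call_tracts(calls, map)
  ev <- merge_tracts(tr, map)
  again <- merge_tracts(ev[, c("chrom", "left", "right", "homolog",
                               "n_markers", "first_pos", "last_pos")], map)
  expect_equal(again$left, ev$left)
  expect_equal(again$right, ev$right)
  expect_identical(as.integer(again$n_markers), as.integer(ev$n_markers))
  # shuffled input gives the same events
  sh <- merge_tracts(tr[sample(nrow(tr)), ], map)
  expect_equal(sh$left, ev$left)
  expect_equal(sh$right, ev$right)

  single <- call_tracts(c("HET", "HET", "HOM_P1", "HET", "HET"), map5())
  ev1 <- merge_tracts(single, map5())
  expect_identical(nrow(ev1), 1L)
  expect_equal(ev1$left, single$left)
  expect_equal(ev1$right, single$right)
})

test_that("classification keys on arm-end markers", {
  map <- map5()
  ev_r <- classify_events(merge_tracts(call_tracts(
    c("HET", "HET", "HET", "HOM_P1", "HOM_P1"), map), map), map)
  expect_identical(ev_r$class, "terminal")
  expect_false(ev_r$possible_aneuploidy)

  ev_mid <- classify_events(merge_tracts(call_tracts(
    c("HET", "HOM_P1", "HOM_P1", "HET", "HET"), map), map), map)
  expect_identical(ev_mid$class, "interstitial")

  ev_all <- classify_events(merge_tracts(call_tracts(
    rep("HOM_P2", 5), map), map), map)
  expect_identical(ev_all$class, "terminal")
  expect_true(ev_all$possible_aneuploidy)
})

test_that("breakpoints follow the midpoint / 10-kb-offset rules", {
  # iLOH: midpoint
  ev <- data.frame(chrom = "chrA", left = 1000, right = 2000, length = 1000,
                   class = "interstitial", possible_aneuploidy = FALSE)
  map <- mk_map(list(chrA = c(500, 1500, 2500, 250000)), c(chrA = 3e5))
  expect_equal(estimate_breakpoints(ev, map)$breakpoint, 1500)

  # right-arm tLOH of 200 kb: centromere-proximal boundary + 10 kb
  ev_t <- data.frame(chrom = "chrA", left = 100000, right = 300000,
                     length = 200000, class = "terminal",
                     possible_aneuploidy = FALSE)
  map_t <- mk_map(list(chrA = c(1000, 150000, 299000)), c(chrA = 3e5))
  expect_equal(estimate_breakpoints(ev_t, map_t)$breakpoint, 110000)

  # left-arm tLOH: offset from the right (centromere-proximal) boundary
  ev_l <- data.frame(chrom = "chrA", left = 1, right = 120000,
                     length = 119999, class = "terminal",
                     possible_aneuploidy = FALSE)
  expect_equal(estimate_breakpoints(ev_l, map_t)$breakpoint, 110000)

  # short tLOH (15 kb < 20 kb): midpoint
  ev_s <- data.frame(chrom = "chrA", left = 285000, right = 300000,
                     length = 15000, class = "terminal",
                     possible_aneuploidy = FALSE)
  expect_equal(estimate_breakpoints(ev_s, map_t)$breakpoint, 292500)
})

test_that("interstitial detection probability matches Monte-Carlo placement", {
  s <- 320
  for (len in c(160, 320, 1000)) {
    set.seed(round(len))
    n_mc <- 4000
    det <- vapply(seq_len(n_mc), function(i) {
      # markers as a Poisson process around an event of length len
      x <- -rexp(1, 1 / s)
      while (x < len) {
        x <- x + rexp(1, 1 / s)
        if (x >= 0 && x < len) return(TRUE)
      }
      FALSE
    }, TRUE)
    p_closed <- detection_probability(len, s)
    expect_lt(abs(mean(det) - p_closed),
              3.5 * sqrt(p_closed * (1 - p_closed) / n_mc))
  }
})

test_that("corrected counts are never below detected and approach them for
           long events", {
  map <- build_marker_map(c(chrA = 2e5), mean_spacing = 300, seed = 31)
  cfg <- sim_config(loh_rate = 2e-2, n_lines = 6, seed = 31,
                    rate_multipliers = c(W = 1))
  sim <- simulate_cohort(map, cfg)
  ev <- call_loh(sim$genotypes)
  cc <- correct_counts(ev, map)
  expect_true(all(cc$corrected >= cc$detected))

  # all-long events: per-event correction factor ~ 1
  long_model <- correction_model(mean_spacing = 300,
                                 iloh_meanlog = log(5e4), iloh_sdlog = 0.1)
  ev_long <- data.frame(clone = "c1", class = "interstitial",
                        length = c(5e4, 6e4))
  cc_long <- correct_counts(ev_long, map, long_model)
  expect_equal(cc_long$corrected, cc_long$detected, tolerance = 1e-6)
})

test_that("corrected totals recover the true simulated event count", {
  # chromosome-scale arms keep terminal-event footprints a small fraction
  # of the genome, as in the system being modelled; on toy chromosomes
  # overlapping terminal events merge away a visible share of the truth
  map <- build_marker_map(seed = 32)
  cfg <- sim_config(loh_rate = 1.76e-2, n_lines = 20, seed = 32,
                    rate_multipliers = c(W = 1))
  sim <- simulate_cohort(map, cfg)
  ev <- call_loh(sim$genotypes)
  cc <- correct_counts(ev, map,
                       correction_model(mean_spacing = 320,
                                        iloh_meanlog = cfg$iloh_meanlog,
                                        iloh_sdlog = cfg$iloh_sdlog))
  true_n <- nrow(sim$truth$events)
  expect_gt(sum(cc$detected), 0)
  expect_lt(abs(sum(cc$corrected) - true_n) / true_n, 0.10)
})

test_that("terminal plus interstitial counts sum to the total", {
  map <- build_marker_map(c(chrA = 3e5, chrB = 2e5), mean_spacing = 320,
                          seed = 33)
  sim <- simulate_cohort(map, sim_config(loh_rate = 2e-2, n_lines = 10,
                                         seed = 33))
  ev <- call_loh(sim$genotypes)
  expect_identical(sum(ev$class == "terminal") +
                     sum(ev$class == "interstitial"), nrow(ev))
  expect_true(all(ev$class %in% c("terminal", "interstitial")))
})
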