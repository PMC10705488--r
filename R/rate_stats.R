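# Rate estimation and strain comparison: event/conversion rates, bootstrap
# CIs, permutation and Wasserstein resampling tests, arm-scale chi-square,
# BH correction, window rates.

#' LOH event rate from counts
#'
#' `k` events over `n` clones propagated for `T_gen` generations give a
#' per-genome per-generation rate `k/(n*T)`; dividing additionally by a
#' monitored length `L` gives a per-bp rate (the window-scale
#' `lambda_s = k_s / (n_s * T * L)`).
#'
#' @param k Event count (possibly corrected, real-valued).
#' @param n Number of clones.
#' @param T_gen Generations.
#' @param L Optional monitored length in bp for a per-bp rate.
#' @return One-row data.frame: k, n, T_gen, L, per_line (k/n),
#'   rate_per_genome (k/(nT)) and rate_per_bp (NA when L is NULL).
#' @export
#' @examples
#' event_rate(785, 79, 800)$rate_per_genome  # 1.24e-2
event_rate <- function(k, n, T_gen, L = NULL) {
  stopifnot(n > 0, T_gen > 0, k >= 0)
  data.frame(
    k = k, n = n, T_gen = T_gen, L = if (is.null(L)) NA_real_ else L,
    per_line = k / n,
    rate_per_genome = k / (n * T_gen),
    rate_per_bp = if (is.null(L)) NA_real_ else k / (n * T_gen * L)
  )
}

#' LOH conversion rate
#'
#' The probability per generation that a heterozygous position is converted
#' to homozygosity: the mean fraction of the heterozygous genome converted
#' per clone, divided by the number of generations.
#'
#' @param fractions Per-clone converted fractions in \[0, 1\].
#' @param T_gen Generations.
#' @return Per-bp per-generation conversion rate.
#' @export
#' @examples
#' conversion_rate(0.061, 800)  # 7.6e-5
conversion_rate <- function(fractions, T_gen) {
  stopifnot(all(fractions >= 0 & fractions <= 1), T_gen > 0)
  mean(fractions) / T_gen
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples per-clone values with replacement from their empirical
#' distribution and returns the percentile interval of the resampled mean
#' (or another statistic).
#'
#' @param values Per-clone values (length >= 2).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Coverage level (default 0.95).
#' @param statistic Function applied to each resample (default `mean`).
#' @param seed Optional seed.
#' @return Named vector with `lower`, `upper` and `estimate`.
#' @export
#' @examples
#' bootstrap_ci(rpois(50, 10), seed = 1)
bootstrap_ci <- function(values, n_boot = 1000, level = 0.95,
                         statistic = mean, seed = NULL) {
  stopifnot(length(values) >= 2, n_boot >= 1, level > 0, level < 1)
  .maybe_seed(seed)
  n <- length(values)
  boot <- vapply(seq_len(n_boot), function(i) {
    statistic(values[sample.int(n, n, replace = TRUE)])
  }, 0)
  ci <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(lower = ci[1], upper = ci[2], estimate = statistic(values))
}

# Shared resampling p-value: add-one mid-p convention,
#   p = (1 + #{d > obs} + 0.5 * #{d == obs}) / (1 + n_perm).
# Event counts are integers, so permuted statistics tie the observed one
# often (~20% of draws at MA sample sizes); counting ties as fully extreme
# pushes the null p-value distribution conservative and costs real power,
# ignoring them is anti-conservative. Half-weighting keeps the null
# distribution closest to uniform while never returning exactly 0.
.resample_p <- function(d, obs, n_perm) {
  if (!any(d != obs)) return(1)  # degenerate: point-mass null distribution
  (1 + sum(d > obs) + 0.5 * sum(d == obs)) / (1 + n_perm)
}

# Fast permutation p-value for the difference in group means.
.perm_p_mean <- function(a, b, n_perm, two_sided = TRUE) {
  x <- c(a, b)
  n <- length(x)
  na <- length(a)
  tot <- sum(x)
  obs <- mean(a) - mean(b)
  if (two_sided) obs <- abs(obs)
  sa <- vapply(seq_len(n_perm), function(i) sum(x[sample.int(n, na)]), 0)
  d <- sa / na - (tot - sa) / (n - na)
  if (two_sided) d <- abs(d)
  .resample_p(d, obs, n_perm)
}

#' Permutation test for a difference between two groups
#'
#' Reshuffles group labels to build the null distribution of the
#' difference in group means (or medians). The default is two-sided on the
#' absolute difference; p-values use the add-one mid-p convention
#' `p = (1 + #{|d_perm| > |d_obs|} + 0.5 #{|d_perm| = |d_obs|}) /
#' (1 + n_perm)` and are therefore never exactly zero. With integer event
#' counts, permuted statistics tie the observed one frequently;
#' half-weighting ties keeps the null p-value distribution closest to
#' uniform (fully counting them is conservative, ignoring them
#' anti-conservative).
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param statistic "mean" (default) or "median".
#' @param n_perm Number of label permutations (default 1000; fewer than
#'   100 triggers a warning).
#' @param alternative "two.sided" (default) or "greater" (mean of A larger).
#' @param seed Optional seed.
#' @return List of class `loh_test`: statistic (observed difference),
#'   p_value, n_resamples, null ("label permutation"), alternative.
#' @export
#' @examples
#' permutation_test(rpois(20, 10), rpois(20, 14), seed = 1)$p_value
permutation_test <- function(values_a, values_b,
                             statistic = c("mean", "median"),
                             n_perm = 1000,
                             alternative = c("two.sided", "greater"),
                             seed = NULL) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is poor")
  .maybe_seed(seed)
  two_sided <- alternative == "two.sided"

  if (statistic == "mean") {
    obs <- mean(values_a) - mean(values_b)
    p <- .perm_p_mean(values_a, values_b, n_perm, two_sided)
  } else {
    x <- c(values_a, values_b)
    n <- length(x)
    na <- length(values_a)
    obs <- median(values_a) - median(values_b)
    d <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      median(x[idx]) - median(x[-idx])
    }, 0)
    o <- if (two_sided) abs(obs) else obs
    if (two_sided) d <- abs(d)
    p <- .resample_p(d, o, n_perm)
  }
  structure(list(statistic = obs, p_value = p, n_resamples = n_perm,
                 null = "label permutation", alternative = alternative),
            class = "loh_test")
}

#' @export
print.loh_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%d resamples, %s)\n",
              x$null, x$statistic, x$p_value, x$n_resamples,
              x$alternative))
  invisible(x)
}

#' Wasserstein statistic between two position samples
#'
#' The integral over position of the absolute difference between the two
#' empirical cumulative distribution functions,
#' `W = \int |E1(x) - E2(x)| dx`. For one-dimensional samples this equals
#' the 1-Wasserstein (earth mover's) distance when sample sizes are equal.
#'
#' @param positions_a,positions_b Numeric position vectors (non-empty).
#' @return The statistic in bp.
#' @export
#' @examples
#' wasserstein_stat(c(1, 2), c(3, 4))
wasserstein_stat <- function(positions_a, positions_b) {
  stopifnot(length(positions_a) >= 1, length(positions_b) >= 1)
  xs <- sort(unique(c(positions_a, positions_b)))
  if (length(xs) == 1) return(0)
  e1 <- ecdf(positions_a)(xs)
  e2 <- ecdf(positions_b)(xs)
  # E1, E2 are right-continuous step functions constant on [xs_i, xs_{i+1})
  sum(abs(e1 - e2)[-length(xs)] * diff(xs))
}

#' Monte-Carlo Wasserstein two-sample test
#'
#' Compares the genomic distributions of two sets of event positions with
#' the Wasserstein statistic; the null distribution is obtained by
#' reshuffling the founder labels of all events (`n_mc` reshuffles),
#' keeping the two sample sizes fixed. Add-one mid-p convention as in
#' [permutation_test()].
#'
#' @param positions_a,positions_b Event positions (e.g. breakpoints) on one
#'   chromosome.
#' @param n_mc Number of Monte-Carlo label reshuffles (default 5000).
#' @param seed Optional seed.
#' @return A `loh_test` list (statistic in bp).
#' @export
wasserstein_test <- function(positions_a, positions_b, n_mc = 5000,
                             seed = NULL) {
  stopifnot(length(positions_a) >= 1, length(positions_b) >= 1)
  .maybe_seed(seed)
  obs <- wasserstein_stat(positions_a, positions_b)
  x <- c(positions_a, positions_b)
  na <- length(positions_a)
  n <- length(x)
  d <- vapply(seq_len(n_mc), function(i) {
    idx <- sample.int(n, na)
    wasserstein_stat(x[idx], x[-idx])
  }, 0)
  p <- .resample_p(d, obs, n_mc)
  structure(list(statistic = obs, p_value = p, n_resamples = n_mc,
                 null = "label reshuffling (Wasserstein)",
                 alternative = "two.sided"),
            class = "loh_test")
}

#' Chi-square test of event distribution across chromosome arms
#'
#' Pearson chi-square on the founder-by-arm contingency table of event
#' counts, comparing where in the genome two founders accumulate events
#' (marginal rates cancel). Arms with zero events in both founders are
#' dropped (they carry no information and break the expected-count
#' approximation).
#'
#' @param counts_a,counts_b Named numeric vectors of per-arm event counts
#'   (same arms).
#' @return A `loh_test` list with the chi-square statistic, df attribute
#'   and asymptotic p-value.
#' @export
arm_chisq <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 2)
  keep <- (counts_a + counts_b) > 0
  if (sum(keep) < 2) stop("fewer than 2 arms with events")
  tab <- rbind(A = counts_a[keep], B = counts_b[keep])
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), p_value = ct$p.value,
                 n_resamples = NA_integer_,
                 null = sprintf("chi-square, df = %d", unname(ct$parameter)),
                 alternative = "two.sided"),
            class = "loh_test")
}

#' Benjamini-Hochberg adjustment with discovery flags
#'
#' Standard step-up FDR control (via [stats::p.adjust()]) plus a logical
#' discovery flag at the requested FDR.
#'
#' @param p_values Raw p-values in (0, 1].
#' @param fdr Target false discovery rate (default 0.05).
#' @return data.frame with p, p_adj, discovery.
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  stopifnot(all(p_values > 0 & p_values <= 1, na.rm = TRUE))
  adj <- p.adjust(p_values, method = "BH")
  data.frame(p = p_values, p_adj = adj, discovery = !is.na(adj) & adj <= fdr)
}

#' Normalized rate difference
#'
#' Computes `(R_s - R_w) / (R_s + R_w)`, in \[-1, 1\]: 0 when the rates are
#' equal, +1 when only the focal strain has events, antisymmetric under
#' swapping the arguments. Undefined (NA) when both rates are zero.
#'
#' @param R_s,R_w Non-negative rates (vectorised).
#' @return Normalized difference(s); NA where `R_s + R_w == 0`.
#' @export
#' @examples
#' normalized_rate(2, 1)  # 1/3
normalized_rate <- function(R_s, R_w) {
  stopifnot(all(R_s >= 0, na.rm = TRUE), all(R_w >= 0, na.rm = TRUE))
  tot <- R_s + R_w
  ifelse(tot > 0, (R_s - R_w) / tot, NA_real_)
}

#' Genomic windows over a marker map
#'
#' Non-overlapping (slide = window) or sliding windows per chromosome,
#' 1-based closed intervals; the last window of a chromosome is truncated
#' at the chromosome end and flagged.
#'
#' @param map A `marker_map`.
#' @param window Window length in bp (default 50,000).
#' @param slide Step size in bp (default `window`, i.e. non-overlapping).
#' @return data.frame: chrom, start, end, length, truncated.
#' @export
make_windows <- function(map, window = 50000, slide = window) {
  stopifnot(window > 0, slide > 0)
  out <- lapply(seq_len(nrow(map$chromosomes)), function(i) {
    L <- map$chromosomes$length[i]
    starts <- seq(1, max(1, L - 1), by = slide)
    starts <- starts[starts <= L]
    ends <- pmin(starts + window - 1, L)
    data.frame(chrom = map$chromosomes$name[i], start = starts, end = ends,
               length = ends - starts + 1,
               truncated = ends - starts + 1 < window,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-window LOH event rates
#'
#' Assigns events to windows by their estimated breakpoint position (a
#' long event is localised to its causal break, not smeared over every
#' window it touches; window intervals are closed, so a breakpoint on the
#' boundary belongs to the earlier window) and computes the per-bp
#' per-generation rate `k / (n * T * L)` with `L` the actual window length
#' (terminal short windows are length-normalized, not dropped).
#'
#' @param events Event data.frame with `chrom` and `breakpoint` columns.
#' @param map A `marker_map`.
#' @param n Number of clones the events came from.
#' @param T_gen Generations.
#' @param window,slide Window geometry in bp; see [make_windows()].
#' @return The window table with `k` and `rate` columns. For sliding
#'   windows (`slide < window`) an event contributes to every window
#'   containing its breakpoint.
#' @export
window_rates <- function(events, map, n, T_gen,
                         window = 50000, slide = window) {
  win <- make_windows(map, window, slide)
  k <- vapply(seq_len(nrow(win)), function(i) {
    sum(events$chrom == win$chrom[i] &
          events$breakpoint >= win$start[i] &
          events$breakpoint <= win$end[i])
  }, 0)
  win$k <- k
  win$rate <- k / (n * T_gen * win$length)
  win
}

#' Per-arm event counts
#'
#' Counts events per chromosome arm by breakpoint position; breakpoints
#' inside the centromere interval are assigned to the nearer arm.
#'
#' @param events Event data.frame with `chrom` and `breakpoint`.
#' @param map A `marker_map`.
#' @return Named vector of counts over arms ("chr_L", "chr_R").
#' @export
arm_counts <- function(events, map) {
  ch <- map$chromosomes
  arms <- c(paste0(ch$name, "_L"), paste0(ch$name, "_R"))
  counts <- stats::setNames(numeric(length(arms)), sort(arms))
  if (nrow(events)) {
    cen_mid <- (ch$cen_start + ch$cen_end) / 2
    mid <- cen_mid[match(events$chrom, ch$name)]
    arm <- paste0(events$chrom, ifelse(events$breakpoint <= mid, "_L", "_R"))
    tab <- table(arm)
    counts[names(tab)] <- as.numeric(tab)
  }
  counts
}

#' Per-clone fraction of the heterozygous genome converted
#'
#' The fraction of non-missing marker sites called homozygous in each
#' clone — the marker-level estimate of the fraction of the initially
#' heterozygous genome that lost heterozygosity.
#'
#' @param gm A `genotype_matrix`.
#' @return Named numeric vector (one fraction per clone) in \[0, 1\].
#' @export
conversion_fractions <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  apply(gm$calls, 2, function(cc) {
    nm <- cc != "MISSING"
    if (!any(nm)) return(NA_real_)
    mean(cc[nm] %in% HOMOLOG_CALLS)
  })
}
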