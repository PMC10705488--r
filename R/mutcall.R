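# De novo mutation identification: founder imputation, unique-variant
# filtering, complex-event merging, and the duplicate-site expectation.

#' Impute a missing founder genotype from its descendants
#'
#' When a founder was not sequenced, its genotype at a marker site is
#' imputed as heterozygous (or homozygous for an allele) only when at least
#' `min_descendants` of its descendant end-point clones *and* all other
#' founders genotyped at the site agree on that call; any disagreement or
#' insufficient support yields MISSING.
#'
#' @param descendant_calls Character vector of calls from the founder's
#'   end-point clones (MISSING entries are ignored).
#' @param founder_calls Character vector of calls from the other genotyped
#'   founders (MISSING entries are ignored).
#' @param min_descendants Minimum number of agreeing descendants
#'   (default 6).
#' @return The imputed call, or "MISSING".
#' @export
#' @examples
#' impute_founder(rep("HET", 7), rep("HET", 3))
#' impute_founder(rep("HET", 5), rep("HET", 3))  # below threshold
impute_founder <- function(descendant_calls, founder_calls,
                           min_descendants = 6) {
  .assert_calls(descendant_calls)
  .assert_calls(founder_calls)
  d <- descendant_calls[descendant_calls != "MISSING"]
  f <- founder_calls[founder_calls != "MISSING"]
  if (!length(d)) return("MISSING")
  # descendants may legitimately differ from the founder (LOH during the MA
  # phase), so only >= min_descendants supporting calls are required of
  # them; the other founders must be unanimous.
  ok <- vapply(c("HET", HOMOLOG_CALLS), function(cand) {
    sum(d == cand) >= min_descendants && all(f == cand)
  }, TRUE)
  if (sum(ok) == 1) names(ok)[ok] else "MISSING"
}

#' Identify de novo mutations as unique variants
#'
#' Putative variants (already purged of parental-difference marker sites
#' and ancestrally heterozygous sites) are accepted as new mutations only
#' when observed in exactly one end-point clone: with genome-wide mutation
#' rates, the expected number of sites hit twice across an MA experiment is
#' negligible (see [expected_duplicate_sites()]), so recurrent variants are
#' artefacts.
#'
#' @param variants data.frame with columns clone, chrom, pos, type (and
#'   optionally zygosity).
#' @return The unique-variant subset, ordered by clone, chrom, pos.
#' @export
call_de_novo <- function(variants) {
  stopifnot(all(c("clone", "chrom", "pos", "type") %in% names(variants)))
  if (!nrow(variants)) return(variants)
  site <- paste(variants$chrom, variants$pos, variants$type)
  # a site counts as recurrent only across different clones
  n_clones <- tapply(variants$clone, site, function(x) length(unique(x)))
  keep <- n_clones[site] == 1
  out <- variants[keep, , drop = FALSE]
  out[order(out$clone, out$chrom, out$pos), , drop = FALSE]
}

#' Group nearby mutations into complex events
#'
#' Mutations in the same clone and chromosome within `window` bp of each
#' other (single-linkage, so chains are allowed) are assigned a shared
#' `complex_group` id and count as one mutational event: co-occurrence this
#' close is vanishingly unlikely for independent mutations and indicates a
#' single complex repair outcome.
#'
#' @param records Mutation data.frame with clone, chrom, pos.
#' @param window Linkage distance in bp (default 100, inclusive).
#' @return The records with `complex_group` (NA for singletons) and an
#'   `n_events` attribute giving the number of mutational events after
#'   merging.
#' @export
merge_complex <- function(records, window = 100) {
  if (!nrow(records)) {
    records$complex_group <- character()
    attr(records, "n_events") <- 0L
    return(records)
  }
  records <- records[order(records$clone, records$chrom, records$pos), ,
                     drop = FALSE]
  key <- paste(records$clone, records$chrom)
  newgrp <- c(TRUE, key[-1] != key[-nrow(records)] |
                diff(records$pos) > window)
  grp <- cumsum(newgrp)
  size <- table(grp)
  records$complex_group <- ifelse(size[as.character(grp)] > 1,
                                  sprintf("cx%03d", grp), NA_character_)
  attr(records, "n_events") <- length(unique(grp))
  records
}

#' Expected number of multiply-hit sites
#'
#' With per-site mutation rate `rate` per generation, `T` generations and
#' `n_clones` lines, the expected mutation count at a given site across the
#' experiment is `mu = rate * T * n_clones`, so a site is hit twice or more
#' with probability `P = 1 - exp(-mu) * (1 + mu) ~ mu^2/2`. Over a diploid
#' genome of haploid length `L` the expected number of such sites is
#' `2 * L * P`.
#'
#' @param rate Per-bp per-generation mutation rate.
#' @param T_gen Number of generations.
#' @param n_clones Number of end-point clones.
#' @param L Haploid genome length in bp.
#' @return List with `mu`, `p_exact`, `p_approx`, `expected_sites` (exact)
#'   and `expected_sites_approx`.
#' @export
#' @examples
#' expected_duplicate_sites(1.67e-10, 800, 229, 1.2e7)$expected_sites
expected_duplicate_sites <- function(rate, T_gen, n_clones, L) {
  stopifnot(rate >= 0, T_gen >= 0, n_clones >= 0, L >= 0)
  mu <- rate * T_gen * n_clones
  p_exact <- 1 - exp(-mu) * (1 + mu)
  p_approx <- mu^2 / 2
  list(mu = mu, p_exact = p_exact, p_approx = p_approx,
       expected_sites = 2 * L * p_exact,
       expected_sites_approx = 2 * L * p_approx)
}
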