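# Internal helpers shared across modules.

GENOTYPE_LEVELS <- c("HET", "HOM_P1", "HOM_P2", "MISSING")
HOMOLOG_CALLS <- c("HOM_P1", "HOM_P2")

#' Derive a reproducible child seed from a root seed
#'
#' Deterministic counter-based seed derivation so that every clone, bootstrap
#' replicate or simulation batch gets an independent, reproducible stream
#' from a single root seed. Values stay below 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param counter Non-negative integer stream index.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, 0:3)
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter))
  as.integer((abs(seed) %% 1000003) * 2099 + (counter %% 1000003) * 7919 + 1) %%
    2147483646L + 1L
}

# Set the RNG only when a seed is supplied.
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.assert_calls <- function(calls) {
  bad <- setdiff(unique(calls), GENOTYPE_LEVELS)
  if (length(bad)) {
    stop("unknown genotype call value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(calls)
}

# Empty event table with the canonical column set.
.empty_events <- function() {
  data.frame(
    clone = character(), chrom = character(),
    left = numeric(), right = numeric(), length = numeric(),
    homolog = character(), n_markers = integer(), n_tracts = integer(),
    class = character(), possible_aneuploidy = logical(),
    breakpoint = numeric(), stringsAsFactors = FALSE
  )
}
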