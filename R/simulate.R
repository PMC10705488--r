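# Cohort simulator: Poisson accumulation of LOH events and de novo
# mutations on a hybrid marker map, with full ground truth for oracle tests.

#' Simulation configuration for an MA cohort
#'
#' Collects the parameters of the mutation-accumulation generative model.
#' Defaults reproduce the conditions of a yeast hybrid MA design: LOH events
#' accumulate as a Poisson process at `loh_rate` per genome per generation,
#' a fraction `terminal_fraction` of events are terminal (extending from a
#' breakpoint drawn uniformly along a chromosome arm to the telomere), the
#' rest are interstitial with log-normal lengths (median 471 bp), and
#' single-nucleotide mutations / indels accumulate at per-bp per-generation
#' rates over the effective genome.
#'
#' @param loh_rate LOH events per genome per generation (default 1.76e-2).
#' @param generations Number of generations `T` (default 800; use 750 to
#'   reproduce a priori power calculations).
#' @param n_lines MA lines per founder label; scalar or named vector.
#' @param terminal_fraction Probability a drawn event is terminal
#'   (default 0.192).
#' @param iloh_meanlog,iloh_sdlog Log-normal parameters of interstitial
#'   event length in bp (defaults: median 471 bp, sdlog 1.5).
#' @param snm_rate Single-nucleotide mutation rate per bp per generation.
#' @param indel_rate Indel rate per bp per generation.
#' @param ploidy Copies per locus (2 for a diploid).
#' @param rate_multipliers Named positive multipliers of `loh_rate` per
#'   founder label; names define the founder set.
#' @param seed Root seed; per-clone streams are derived by counter via
#'   [derive_seed()].
#' @return A `sim_config` object (validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 5, seed = 1)
#' cfg$loh_rate * cfg$generations  # expected events per clone
sim_config <- function(loh_rate = 1.76e-2,
                       generations = 800,
                       n_lines = 95,
                       terminal_fraction = 0.192,
                       iloh_meanlog = log(471),
                       iloh_sdlog = 1.5,
                       snm_rate = 1.67e-10,
                       indel_rate = 7.5e-12,
                       ploidy = 2,
                       rate_multipliers = c(W = 1, C = 1, D = 1),
                       seed = 1L) {
  stopifnot(loh_rate >= 0, snm_rate >= 0, indel_rate >= 0,
            generations >= 1, terminal_fraction >= 0, terminal_fraction <= 1,
            all(rate_multipliers > 0), ploidy >= 1)
  if (is.null(names(rate_multipliers))) {
    stop("rate_multipliers must be a named vector of founder labels")
  }
  structure(list(
    loh_rate = loh_rate, generations = generations, n_lines = n_lines,
    terminal_fraction = terminal_fraction,
    iloh_meanlog = iloh_meanlog, iloh_sdlog = iloh_sdlog,
    snm_rate = snm_rate, indel_rate = indel_rate, ploidy = ploidy,
    rate_multipliers = rate_multipliers, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Expected LOH events per clone under a configuration
#'
#' The Poisson mean `mu = lambda * T` for a given founder label.
#'
#' @param cfg A [sim_config()].
#' @param founder_label Founder whose rate multiplier applies.
#' @return Expected event count per end-point clone.
#' @export
#' @examples
#' expected_event_count(sim_config(loh_rate = 1.76e-2, generations = 750))
expected_event_count <- function(cfg, founder_label = names(cfg$rate_multipliers)[1]) {
  cfg$loh_rate * cfg$rate_multipliers[[founder_label]] * cfg$generations
}

# Draw one LOH event on the map. Returns list(chrom, start, end, class_drawn).
.draw_event <- function(map, terminal_fraction) {
  ch <- map$chromosomes
  i <- sample.int(nrow(ch), 1, prob = ch$length)
  L <- ch$length[i]
  if (runif(1) < terminal_fraction) {
    left_arm_len <- ch$cen_start[i] - 1
    right_arm_len <- L - ch$cen_end[i]
    if (runif(1) < left_arm_len / (left_arm_len + right_arm_len)) {
      bp <- sample.int(left_arm_len, 1)           # uniform on [1, cen_start-1]
      ev <- list(start = 1, end = bp, class_drawn = "terminal")
    } else {
      bp <- ch$cen_end[i] + sample.int(right_arm_len, 1)
      ev <- list(start = bp, end = L, class_drawn = "terminal")
    }
  } else {
    len <- min(L, max(1, round(rlnorm(1, attr(map, "iloh_meanlog"),
                                      attr(map, "iloh_sdlog")))))
    start <- sample.int(L - len + 1, 1)
    ev <- list(start = start, end = start + len - 1, class_drawn = "interstitial")
  }
  ev$chrom <- ch$name[i]
  ev
}

# Realised class of a true interval: terminal iff it covers the telomeric
# (first or last) marker of its chromosome.
.realized_class <- function(map, chrom, start, end) {
  m <- map$markers[[chrom]]
  covers_first <- start <= m[1] && end >= m[1]
  covers_last <- start <= m[length(m)] && end >= m[length(m)]
  if (covers_first || covers_last) "terminal" else "interstitial"
}

#' Simulate one MA clone
#'
#' Draws a Poisson number of LOH events (rate `loh_rate * multiplier *
#' generations`), places each on the map (terminal events run from a
#' uniform arm breakpoint to the telomere; interstitial events get a
#' log-normal length and uniform placement), converts the spanned markers
#' to a homolog chosen with equal probability (later events overwrite
#' earlier ones), and draws Poisson numbers of SNMs and indels placed
#' uniformly over the genome. Mutations are recorded in the truth only and
#' never alter marker calls.
#'
#' @param map A `marker_map`.
#' @param cfg A [sim_config()].
#' @param founder_label Label with an entry in `cfg$rate_multipliers`.
#' @param seed Integer seed for this clone's stream.
#' @return List with `calls` (character vector over the map's markers),
#'   `events` (true event data.frame: chrom, start, end, class_drawn,
#'   class, homolog, order) and `mutations` (chrom, pos, type).
#' @export
simulate_clone <- function(map, cfg, founder_label, seed) {
  stopifnot(inherits(map, "marker_map"), inherits(cfg, "sim_config"))
  if (!founder_label %in% names(cfg$rate_multipliers)) {
    stop("founder label '", founder_label, "' has no rate multiplier")
  }
  set.seed(as.integer(seed))
  attr(map, "iloh_meanlog") <- cfg$iloh_meanlog
  attr(map, "iloh_sdlog") <- cfg$iloh_sdlog

  calls <- rep("HET", n_markers(map))
  mt <- marker_table(map)
  mu <- cfg$loh_rate * cfg$rate_multipliers[[founder_label]] * cfg$generations
  n_events <- rpois(1, mu)

  events <- vector("list", n_events)
  for (k in seq_len(n_events)) {
    ev <- .draw_event(map, cfg$terminal_fraction)
    homolog <- sample(HOMOLOG_CALLS, 1)
    idx <- which(mt$chrom == ev$chrom & mt$pos >= ev$start & mt$pos <= ev$end)
    calls[idx] <- homolog
    events[[k]] <- data.frame(
      chrom = ev$chrom, start = ev$start, end = ev$end,
      class_drawn = ev$class_drawn,
      class = .realized_class(map, ev$chrom, ev$start, ev$end),
      homolog = homolog, order = k, stringsAsFactors = FALSE
    )
  }
  events <- if (n_events) do.call(rbind, events) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               class_drawn = character(), class = character(),
               homolog = character(), order = integer(),
               stringsAsFactors = FALSE)

  # de novo mutations over the effective genome (ploidy copies monitored)
  mut_mu <- c(SNM = cfg$snm_rate, indel = cfg$indel_rate) *
    cfg$ploidy * map$effective_length * cfg$generations
  muts <- lapply(names(mut_mu), function(type) {
    n <- rpois(1, mut_mu[[type]])
    if (!n) return(NULL)
    ci <- sample.int(nrow(map$chromosomes), n, replace = TRUE,
                     prob = map$chromosomes$length)
    data.frame(chrom = map$chromosomes$name[ci],
               pos = vapply(map$chromosomes$length[ci],
                            function(L) sample.int(L, 1), 1L),
               type = type, stringsAsFactors = FALSE)
  })
  muts <- do.call(rbind, c(muts, list(
    data.frame(chrom = character(), pos = integer(), type = character(),
               stringsAsFactors = FALSE))))

  list(calls = calls, events = events, mutations = muts)
}

#' Simulate a full MA cohort with ground truth
#'
#' Generates independent clones for every founder label in
#' `cfg$rate_multipliers` (`cfg$n_lines` clones per label, or a named
#' per-label vector). Per-clone seeds are derived from `cfg$seed` by
#' counter, so the same configuration is always bit-identical.
#'
#' @param map A `marker_map`.
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (a `genotype_matrix`), and `truth`: a list
#'   with per-clone `events` and `mutations` data.frames (clone column
#'   added), the simulator's ground truth.
#' @export
#' @examples
#' map <- build_marker_map(c(chrA = 2e5), mean_spacing = 500, seed = 1)
#' sim <- simulate_cohort(map, sim_config(n_lines = 3, seed = 1))
#' dim(sim$genotypes$calls)
simulate_cohort <- function(map, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  labels <- names(cfg$rate_multipliers)
  n_lines <- cfg$n_lines
  if (is.null(names(n_lines))) {
    n_lines <- stats::setNames(rep_len(n_lines, length(labels)), labels)
  }
  stopifnot(all(n_lines >= 1))

  clone_meta <- do.call(rbind, lapply(labels, function(lab) {
    data.frame(
      clone = sprintf("%s_%03d", lab, seq_len(n_lines[[lab]])),
      founder = lab, generations = cfg$generations,
      stringsAsFactors = FALSE
    )
  }))

  calls <- matrix("HET", nrow = n_markers(map), ncol = nrow(clone_meta),
                  dimnames = list(NULL, clone_meta$clone))
  events <- vector("list", nrow(clone_meta))
  muts <- vector("list", nrow(clone_meta))
  for (j in seq_len(nrow(clone_meta))) {
    cl <- simulate_clone(map, cfg, clone_meta$founder[j],
                         seed = derive_seed(cfg$seed, j))
    calls[, j] <- cl$calls
    if (nrow(cl$events)) cl$events$clone <- clone_meta$clone[j]
    if (nrow(cl$mutations)) cl$mutations$clone <- clone_meta$clone[j]
    events[[j]] <- cl$events
    muts[[j]] <- cl$mutations
  }

  list(
    genotypes = genotype_matrix(map, calls, clone_meta),
    truth = list(
      events = do.call(rbind, events[vapply(events, nrow, 1L) > 0]),
      mutations = do.call(rbind, muts[vapply(muts, nrow, 1L) > 0])
    )
  )
}

#' Construct a genotype matrix
#'
#' Per-clone genotype calls at every marker site of a map; the sole input
#' of the LOH caller. Calls take values HET, HOM_P1, HOM_P2 or MISSING.
#'
#' @param map A `marker_map`.
#' @param calls Character matrix, rows = markers in map order, columns =
#'   clones.
#' @param clones data.frame with columns `clone`, `founder` and optionally
#'   `generations`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(map, calls, clones) {
  stopifnot(inherits(map, "marker_map"), is.matrix(calls))
  if (nrow(calls) != n_markers(map)) {
    stop("calls has ", nrow(calls), " rows but the map has ",
         n_markers(map), " markers")
  }
  if (anyDuplicated(clones$clone)) stop("duplicate clone ids")
  if (ncol(calls) != nrow(clones)) stop("calls/clone metadata mismatch")
  .assert_calls(calls)
  colnames(calls) <- clones$clone
  structure(list(map = map, calls = calls, clones = clones),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "markers x", ncol(x$calls),
      "clones; founders:",
      paste(sprintf("%s (%d)", names(table(x$clones$founder)),
                    table(x$clones$founder)), collapse = ", "), "\n")
  invisible(x)
}
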