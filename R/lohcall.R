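# LOH calling: tracts -> merged events -> classification -> breakpoints,
# plus the inverse-detection-probability correction for undetected events.
# Coordinates are 1-based, intervals closed.

#' Call LOH tracts from one clone's marker genotypes
#'
#' An LOH tract is a maximal run of adjacent marker sites called homozygous
#' for the same homolog. Tract boundaries are estimated as the midpoint
#' between the first (last) converted marker and the adjacent unconverted
#' marker, or a marker converted to a different homolog; where a tract
#' reaches a chromosome end, the boundary is the chromosome end itself.
#' MISSING calls are by default transparent: they neither break a run nor
#' count as converted markers (`missing = "break"` makes them terminate
#' runs instead, with the boundary midpointed to the missing marker).
#'
#' @param calls Character vector of genotype calls over the map's markers
#'   (values HET, HOM_P1, HOM_P2, MISSING), in map order.
#' @param map A `marker_map`.
#' @param missing Either "transparent" (default) or "break".
#' @return data.frame of tracts: chrom, first_pos, last_pos (outermost
#'   converted markers, bp), left, right (boundary interval, bp), homolog,
#'   n_markers.
#' @export
#' @examples
#' map <- build_marker_map(c(chrA = 1000), mean_spacing = 100, seed = 1)
#' calls <- rep("HET", n_markers(map)); calls[3:4] <- "HOM_P1"
#' call_tracts(calls, map)
call_tracts <- function(calls, map, missing = c("transparent", "break")) {
  missing <- match.arg(missing)
  stopifnot(inherits(map, "marker_map"))
  if (length(calls) != n_markers(map)) {
    stop("calls length (", length(calls), ") != marker count (",
         n_markers(map), ")")
  }
  .assert_calls(calls)

  offsets <- c(0, cumsum(lengths(map$markers)))
  out <- vector("list", nrow(map$chromosomes))
  for (i in seq_len(nrow(map$chromosomes))) {
    chrom <- map$chromosomes$name[i]
    L <- map$chromosomes$length[i]
    pos <- map$markers[[chrom]]
    cc <- calls[(offsets[i] + 1):offsets[i + 1]]

    if (missing == "transparent") {
      keep <- cc != "MISSING"
    } else {
      keep <- rep(TRUE, length(cc))   # MISSING acts as an unconverted site
    }
    p <- pos[keep]
    v <- cc[keep]
    if (!length(p)) { out[[i]] <- NULL; next }

    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hom <- r$values %in% HOMOLOG_CALLS
    if (!any(hom)) { out[[i]] <- NULL; next }

    first_i <- starts[hom]
    last_i <- ends[hom]
    left <- ifelse(first_i == 1, 1,
                   (p[pmax(first_i - 1, 1)] + p[first_i]) / 2)
    right <- ifelse(last_i == length(p), L,
                    (p[last_i] + p[pmin(last_i + 1, length(p))]) / 2)
    out[[i]] <- data.frame(
      chrom = chrom,
      first_pos = p[first_i], last_pos = p[last_i],
      left = left, right = right,
      homolog = r$values[hom],
      n_markers = r$lengths[hom],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), first_pos = numeric(),
                      last_pos = numeric(), left = numeric(),
                      right = numeric(), homolog = character(),
                      n_markers = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Merge LOH tracts into events
#'
#' Tracts on the same chromosome converted to the same homolog are merged
#' (transitively) into a single event when their boundary intervals are
#' separated by less than `merge_gap` (strictly; a gap of exactly
#' `merge_gap` keeps two events). Tracts of different homologs are never
#' merged: a homolog switch implies distinct repair products.
#'
#' @param tracts Tract data.frame from [call_tracts()] (one clone).
#' @param map A `marker_map`.
#' @param merge_gap Maximum boundary separation in bp (default 10,000).
#' @return data.frame of events: chrom, left, right, length, homolog,
#'   n_markers, n_tracts, first_pos, last_pos.
#' @export
merge_tracts <- function(tracts, map, merge_gap = 10000) {
  stopifnot(inherits(map, "marker_map"))
  if (!nrow(tracts)) {
    return(data.frame(chrom = character(), left = numeric(),
                      right = numeric(), length = numeric(),
                      homolog = character(), n_markers = integer(),
                      n_tracts = integer(), first_pos = numeric(),
                      last_pos = numeric(), stringsAsFactors = FALSE))
  }
  tracts <- tracts[order(tracts$chrom, tracts$left), , drop = FALSE]
  out <- lapply(split(tracts, tracts$chrom), function(tr) {
    tr <- tr[order(tr$left), , drop = FALSE]
    if (nrow(tr) > 1) {
      gap <- tr$left[-1] - tr$right[-nrow(tr)]
      same <- tr$homolog[-1] == tr$homolog[-nrow(tr)]
      brk <- as.integer(!(same & gap < merge_gap))
    } else {
      brk <- integer(0)
    }
    grp <- cumsum(c(0L, brk))
    do.call(rbind, lapply(split(tr, grp), function(g) {
      data.frame(
        chrom = g$chrom[1], left = min(g$left), right = max(g$right),
        length = max(g$right) - min(g$left),
        homolog = g$homolog[1], n_markers = sum(g$n_markers),
        n_tracts = nrow(g),
        first_pos = min(g$first_pos), last_pos = max(g$last_pos),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$left), , drop = FALSE]
}

#' Classify LOH events as interstitial or terminal
#'
#' An event is terminal when it contains the telomere-proximal (last)
#' marker of a chromosome arm, i.e. the first marker of the chromosome
#' (left arm) or the last (right arm); all other events are interstitial.
#' Events spanning both arm ends (a fully homozygous chromosome) are
#' terminal and flagged `possible_aneuploidy`, since chromosome loss can
#' produce the same marker signature.
#'
#' @param events Event data.frame from [merge_tracts()].
#' @param map A `marker_map`.
#' @return The events with `class` and `possible_aneuploidy` columns.
#' @export
classify_events <- function(events, map) {
  stopifnot(inherits(map, "marker_map"))
  if (!nrow(events)) {
    events$class <- character()
    events$possible_aneuploidy <- logical()
    return(events)
  }
  first_mark <- vapply(events$chrom, function(ch) map$markers[[ch]][1], 0)
  last_mark <- vapply(events$chrom, function(ch) {
    m <- map$markers[[ch]]; m[length(m)]
  }, 0)
  at_left <- events$first_pos <= first_mark
  at_right <- events$last_pos >= last_mark
  events$class <- ifelse(at_left | at_right, "terminal", "interstitial")
  events$possible_aneuploidy <- at_left & at_right
  events
}

#' Estimate causal double-strand-break positions
#'
#' Interstitial events and terminal events shorter than `tloh_threshold`
#' get the midpoint of their boundary interval. Longer terminal events get
#' a breakpoint placed `tloh_offset` bp from the centromere-proximal
#' boundary toward the telomere (resection during break-induced replication
#' extends the homozygous tract far beyond the break). Whole-chromosome
#' events have no centromere-proximal side and fall back to the midpoint.
#'
#' @param events Classified event data.frame (from [classify_events()]).
#' @param map A `marker_map`.
#' @param tloh_threshold Terminal-event length (bp) above which the offset
#'   rule applies (default 20,000).
#' @param tloh_offset Offset from the centromere-proximal boundary in bp
#'   (default 10,000).
#' @return The events with a `breakpoint` column (bp).
#' @export
estimate_breakpoints <- function(events, map, tloh_threshold = 20000,
                                 tloh_offset = 10000) {
  if (!nrow(events)) {
    events$breakpoint <- numeric()
    return(events)
  }
  bp <- (events$left + events$right) / 2
  long_t <- events$class == "terminal" & events$length >= tloh_threshold &
    !events$possible_aneuploidy
  if (any(long_t)) {
    L <- map$chromosomes$length[match(events$chrom, map$chromosomes$name)]
    # a terminal event reaches exactly one chromosome end (both ends =
    # possible aneuploidy, excluded above); the centromere-proximal
    # boundary is the opposite, interior one
    right_arm <- abs(events$right - L) < 0.5
    bp[long_t & right_arm] <- events$left[long_t & right_arm] + tloh_offset
    bp[long_t & !right_arm] <- events$right[long_t & !right_arm] - tloh_offset
  }
  events$breakpoint <- pmin(pmax(bp, events$left), events$right)
  events
}

#' Call LOH events for every clone of a genotype matrix
#'
#' Convenience wrapper running [call_tracts()], [merge_tracts()],
#' [classify_events()] and [estimate_breakpoints()] per clone.
#'
#' @param gm A `genotype_matrix`.
#' @param merge_gap Tract merge distance in bp (default 10,000).
#' @param missing MISSING-call policy, see [call_tracts()].
#' @return data.frame of events with a `clone` column.
#' @export
#' @examples
#' map <- build_marker_map(c(chrA = 2e5), mean_spacing = 500, seed = 1)
#' sim <- simulate_cohort(map, sim_config(n_lines = 2, seed = 1))
#' head(call_loh(sim$genotypes))
call_loh <- function(gm, merge_gap = 10000,
                     missing = c("transparent", "break")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  missing <- match.arg(missing)
  out <- lapply(seq_len(ncol(gm$calls)), function(j) {
    ev <- call_tracts(gm$calls[, j], gm$map, missing = missing)
    ev <- merge_tracts(ev, gm$map, merge_gap = merge_gap)
    ev <- classify_events(ev, gm$map)
    ev <- estimate_breakpoints(ev, gm$map)
    if (nrow(ev)) ev$clone <- colnames(gm$calls)[j]
    ev
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out)) {
    out <- .empty_events()
  }
  rownames(out) <- NULL
  out
}

#' Detection probability of an interstitial event
#'
#' Under exponentially distributed inter-marker gaps (a Poisson marker
#' process with mean spacing `s`), an interstitial event of length `l`
#' covers at least one marker with probability `1 - exp(-l/s)`.
#'
#' @param length Event length(s) in bp.
#' @param mean_spacing Mean inter-marker spacing in bp.
#' @return Detection probability in (0, 1].
#' @export
#' @examples
#' detection_probability(320, 320)  # 1 - exp(-1)
detection_probability <- function(length, mean_spacing) {
  stopifnot(mean_spacing > 0)
  1 - exp(-pmax(length, 0) / mean_spacing)
}

#' Correction model for undetected LOH events
#'
#' A single inverse-detection-probability correction approximating (not
#' replicating) the multi-step corrections used with dual-reference
#' genotyping pipelines. The universe of correctable events is those longer
#' than `min_detectable_length`. Interstitial detection follows
#' [detection_probability()]; terminal events reach a telomere-adjacent
#' marker and are treated as always detected.
#'
#' For the default `method = "parametric"`, the interstitial weight is the
#' reciprocal of the *marginal* detection probability
#' `E[1 - exp(-l/s)]` under a configured length model (log-normal,
#' truncated below `min_detectable_length`). This is unbiased for the true
#' event count, whereas evaluating `1/p` at each event's called boundary
#' length (`method = "per_event"`) over-estimates short-event lengths and
#' under-corrects; the per-event form is kept for sensitivity analyses.
#'
#' @param mean_spacing Mean inter-marker spacing in bp.
#' @param min_detectable_length Shortest event in the corrected universe,
#'   bp (default 17).
#' @param iloh_meanlog,iloh_sdlog Log-normal length model of interstitial
#'   events (defaults: median 471 bp, sdlog 1.5). Taken from prior
#'   knowledge or the simulation configuration, not fitted to the
#'   (length-biased) detected events.
#' @param p_floor Lower floor for any detection probability.
#' @param method "parametric" (default) or "per_event".
#' @return A `correction_model` object.
#' @export
correction_model <- function(mean_spacing, min_detectable_length = 17,
                             iloh_meanlog = log(471), iloh_sdlog = 1.5,
                             p_floor = 0.01,
                             method = c("parametric", "per_event")) {
  method <- match.arg(method)
  stopifnot(mean_spacing > 0, min_detectable_length >= 0,
            p_floor > 0, p_floor <= 1)
  # marginal detection probability of an iLOH event under the length model,
  # truncated to the correctable universe [min_detectable_length, Inf)
  dens <- function(l) stats::dlnorm(l, iloh_meanlog, iloh_sdlog)
  lo <- max(min_detectable_length, 1e-9)
  mass <- 1 - plnorm(lo, iloh_meanlog, iloh_sdlog)
  if (mass <= 0) stop("length model has no mass above min_detectable_length")
  # integrate over the bulk of the length model; beyond the upper quantile
  # detection is certain for any realistic spacing
  hi <- stats::qlnorm(1 - 1e-9, iloh_meanlog, iloh_sdlog)
  lo2 <- max(lo, stats::qlnorm(1e-12, iloh_meanlog, iloh_sdlog))
  p_marg <- (integrate(function(l) detection_probability(l, mean_spacing) *
                         dens(l),
                       lower = lo2, upper = hi, rel.tol = 1e-8)$value +
               (1 - plnorm(hi, iloh_meanlog, iloh_sdlog))) / mass
  if (p_marg <= 0) stop("marginal detection probability is not positive")
  structure(list(
    mean_spacing = mean_spacing,
    min_detectable_length = min_detectable_length,
    iloh_meanlog = iloh_meanlog, iloh_sdlog = iloh_sdlog,
    p_floor = p_floor, p_marginal_iloh = p_marg, method = method
  ), class = "correction_model")
}

#' Correct per-clone LOH counts for undetected events
#'
#' Horvitz-Thompson style correction: each detected event contributes the
#' reciprocal of its class's detection probability (see
#' [correction_model()]). Terminal events contribute 1. Returns real-valued
#' corrected counts, never below the detected counts.
#'
#' @param events Event data.frame with `clone`, `class` and `length`
#'   columns (from [call_loh()]).
#' @param map A `marker_map`.
#' @param model A [correction_model()]; default built from the map's mean
#'   spacing.
#' @return data.frame with clone, detected, corrected.
#' @export
correct_counts <- function(events, map,
                           model = correction_model(map$mean_spacing)) {
  stopifnot(inherits(model, "correction_model"))
  if (!nrow(events)) {
    return(data.frame(clone = character(), detected = integer(),
                      corrected = numeric(), stringsAsFactors = FALSE))
  }
  is_iloh <- events$class == "interstitial"
  if (model$method == "parametric") {
    p <- ifelse(is_iloh, model$p_marginal_iloh, 1)
  } else {
    p <- ifelse(is_iloh,
                pmax(detection_probability(events$length,
                                           model$mean_spacing),
                     model$p_floor),
                1)
  }
  if (any(p <= 0)) stop("non-positive detection probability")
  agg <- stats::aggregate(cbind(detected = rep(1, nrow(events)),
                                corrected = 1 / p),
                          by = list(clone = events$clone), FUN = sum)
  agg$detected <- as.integer(agg$detected)
  agg
}
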