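# Marker maps: chromosome structure, centromeres and heterozygous marker
# positions of a hybrid founder.

#' Yeast-like chromosome lengths
#'
#' Sixteen chromosome lengths in the proportions of the *S. cerevisiae*
#' karyotype, rescaled to a requested total genome size. Used as the default
#' chromosome set for synthetic marker maps.
#'
#' @param total_bp Total genome length in bp.
#' @return Named integer vector of chromosome lengths (chrI..chrXVI).
#' @export
#' @examples
#' sum(yeast_chrom_lengths(12e6))
yeast_chrom_lengths <- function(total_bp = 12e6) {
  kb <- c(230, 813, 316, 1532, 577, 270, 1091, 562, 440, 746,
          667, 1078, 924, 784, 1091, 948)
  len <- round(kb / sum(kb) * total_bp)
  names(len) <- paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII",
                                "VIII", "IX", "X", "XI", "XII", "XIII",
                                "XIV", "XV", "XVI"))
  len
}

#' Build a synthetic heterozygous marker map
#'
#' Places marker sites along each chromosome with i.i.d. exponential
#' inter-marker gaps (truncated so gaps are at least 1 bp), emulating a
#' hybrid founder heterozygous at tens of thousands of parental-difference
#' sites. A mean spacing of 320 bp over a 12 Mb genome yields roughly
#' 37,500 markers. Centromeres are placed at a configurable relative
#' position on each chromosome.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param mean_spacing Mean inter-marker distance in bp (> 0).
#' @param centromere_rel Relative centromere position in (0, 1); scalar or
#'   one value per chromosome.
#' @param centromere_width Width of the centromere interval in bp (yeast
#'   point centromeres are ~120 bp).
#' @param effective_length Genome length monitored for LOH, in bp. Defaults
#'   to the total chromosome length; set lower to represent masked repeats
#'   and excluded subtelomeres.
#' @param seed Optional integer seed for reproducible maps.
#' @return A `marker_map` object: list with `chromosomes` (data.frame of
#'   name, length, cen_start, cen_end), `markers` (named list of ascending
#'   1-based positions), `mean_spacing` and `effective_length`.
#' @export
#' @examples
#' map <- build_marker_map(c(chrA = 100000), mean_spacing = 500, seed = 1)
#' length(map$markers$chrA)
build_marker_map <- function(chrom_lengths = yeast_chrom_lengths(),
                             mean_spacing = 320,
                             centromere_rel = 0.5,
                             centromere_width = 120,
                             effective_length = NULL,
                             seed = NULL) {
  stopifnot(mean_spacing > 0, all(chrom_lengths > 0))
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  short <- chrom_lengths < 2 * mean_spacing
  if (any(short)) {
    stop("chromosome(s) shorter than 2 x mean_spacing: ",
         paste(names(chrom_lengths)[short], collapse = ", "), call. = FALSE)
  }
  centromere_rel <- rep_len(centromere_rel, length(chrom_lengths))
  stopifnot(all(centromere_rel > 0 & centromere_rel < 1))
  .maybe_seed(seed)

  markers <- vector("list", length(chrom_lengths))
  names(markers) <- names(chrom_lengths)
  cen_start <- cen_end <- numeric(length(chrom_lengths))
  for (i in seq_along(chrom_lengths)) {
    L <- chrom_lengths[[i]]
    n_max <- ceiling(L / mean_spacing * 1.5) + 20
    gaps <- pmax(1, round(rexp(n_max, rate = 1 / mean_spacing)))
    pos <- cumsum(gaps)
    while (pos[length(pos)] <= L) {  # rare: extend until past the end
      extra <- pmax(1, round(rexp(n_max, rate = 1 / mean_spacing)))
      pos <- c(pos, pos[length(pos)] + cumsum(extra))
    }
    pos <- pos[pos <= L]
    if (length(pos) < 2) {
      stop("fewer than 2 markers realised on ", names(chrom_lengths)[i],
           "; increase its length or decrease mean_spacing", call. = FALSE)
    }
    markers[[i]] <- as.numeric(pos)
    cen_mid <- round(centromere_rel[i] * L)
    cen_start[i] <- max(2, cen_mid - floor(centromere_width / 2))
    cen_end[i] <- min(L - 1, cen_mid + ceiling(centromere_width / 2))
  }

  map <- structure(list(
    chromosomes = data.frame(
      name = names(chrom_lengths),
      length = as.numeric(chrom_lengths),
      cen_start = cen_start, cen_end = cen_end,
      stringsAsFactors = FALSE
    ),
    markers = markers,
    mean_spacing = mean_spacing,
    effective_length = if (is.null(effective_length)) {
      sum(chrom_lengths)
    } else {
      effective_length
    }
  ), class = "marker_map")
  validate_marker_map(map)
}

#' Validate a marker map
#'
#' Checks the structural invariants of a `marker_map`: strictly increasing
#' marker positions within chromosome bounds, at least two markers per
#' chromosome, centromere intervals interior to the chromosome, and an
#' effective length no larger than the genome.
#'
#' @param map A `marker_map` object.
#' @return The map, invisibly usable, or an error describing the violation.
#' @export
validate_marker_map <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  ch <- map$chromosomes
  for (i in seq_len(nrow(ch))) {
    m <- map$markers[[ch$name[i]]]
    if (length(m) < 2) stop("chromosome ", ch$name[i], " has < 2 markers")
    if (any(diff(m) <= 0)) {
      stop("marker positions not strictly increasing on ", ch$name[i])
    }
    if (m[1] < 1 || m[length(m)] > ch$length[i]) {
      stop("marker positions outside [1, length] on ", ch$name[i])
    }
    if (ch$cen_start[i] <= 1 || ch$cen_end[i] >= ch$length[i] ||
        ch$cen_start[i] > ch$cen_end[i]) {
      stop("invalid centromere interval on ", ch$name[i])
    }
  }
  if (map$effective_length > sum(ch$length)) {
    stop("effective_length exceeds total genome length")
  }
  map
}

#' @export
print.marker_map <- function(x, ...) {
  n_mark <- sum(lengths(x$markers))
  cat("marker_map:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp,",
      format(n_mark, big.mark = ","), "markers",
      sprintf("(mean spacing %.0f bp)\n",
              sum(x$chromosomes$length) / n_mark))
  invisible(x)
}

#' Total number of markers in a map
#' @param map A `marker_map`.
#' @return Integer marker count.
#' @export
n_markers <- function(map) sum(lengths(map$markers))

# Long-form marker table: chrom, pos, global row index.
marker_table <- function(map) {
  data.frame(
    chrom = rep(map$chromosomes$name, lengths(map$markers)),
    pos = unlist(map$markers, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
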