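# PAM-site indexing and gRNA similarity scoring (MIT/Hsu single-site
# scheme), plus the window-level similarity/rate regression.

# Hsu et al. experimentally derived per-position mismatch penalties for
# SpCas9, position 1 = PAM-distal (5') end of the 20-bp protospacer.
# Vendored from the published MIT specificity weight vector used by the
# standard scoring implementations (crispor, CRISPOR/MIT web tools).
MIT_WEIGHTS <- c(0, 0, 0.014, 0, 0, 0.395, 0.317, 0, 0.389, 0.079,
                 0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615,
                 0.804, 0.685, 0.583)

#' MIT/Hsu single-site gRNA similarity score
#'
#' Scores a 20-bp protospacer against a 20-bp gRNA spacer with the
#' empirically informed MIT scheme: the product over mismatched positions
#' of `(1 - W[p])` (W = Hsu position weights, position 20 adjacent to the
#' PAM), a penalty for tightly clustered mismatches based on the mean
#' distance `d` between adjacent mismatch positions,
#' `1 / (((19 - d)/19) * 4 + 1)`, and a `1/m^2` penalty for the mismatch
#' count `m`. A perfect match scores 1. Note that the published weight
#' vector assigns zero penalty to positions 1, 2, 4, 5 and 8 (PAM-distal
#' numbering), so a single mismatch confined to those positions also
#' scores 1 — a documented property of the empirical scheme, not a bug.
#'
#' @param protospacer 20-character string over ACGT (the genomic sequence
#'   5' of the PAM, read 5'->3' on the PAM strand).
#' @param grna 20-character gRNA spacer sequence.
#' @return Score in \[0, 1\].
#' @export
#' @examples
#' mit_score("GGGGGGGGGGGGGGGGGGGG", "GGGGGGGGGGGGGGGGGGGG")
#' mit_score("AGGGGGGGGGGGGGGGGGGG", "GGGGGGGGGGGGGGGGGGGG")
mit_score <- function(protospacer, grna) {
  p <- strsplit(toupper(protospacer), "")[[1]]
  g <- strsplit(toupper(grna), "")[[1]]
  if (length(p) != 20 || length(g) != 20) {
    stop("protospacer and gRNA must both be 20 bp")
  }
  if (!all(c(p, g) %in% c("A", "C", "G", "T"))) {
    stop("sequences must be over A, C, G, T")
  }
  mm <- which(p != g)
  m <- length(mm)
  if (m == 0) return(1)
  t1 <- prod(1 - MIT_WEIGHTS[mm])
  d <- if (m > 1) mean(diff(mm)) else 19
  t2 <- 1 / (((19 - d) / 19) * 4 + 1)
  t3 <- 1 / m^2
  t1 * t2 * t3
}

#' Index PAM-adjacent sites in a genome
#'
#' Finds all occurrences of the requested PAM classes (canonical NGG and
#' the weakly interacting NAG) on both strands and extracts the 20-bp
#' protospacer immediately 5' of each PAM on its strand
#' (reverse-complemented for minus-strand sites). Sites whose 20-bp
#' context runs off the contig or contains an N are dropped; ambiguity
#' codes other than N are rejected.
#'
#' @param genome A named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param classes PAM classes to index (subset of "NGG", "NAG").
#' @param grna Optional 20-bp gRNA; when given, a `score` column with
#'   [mit_score()] values is added.
#' @return data.frame of sites: chrom, pam_start (1-based plus-strand
#'   coordinate of the leftmost PAM base), strand, pam_class, protospacer
#'   (and score).
#' @export
#' @examples
#' index_pam_sites(c(chrA = "AAAAAAAAAAAAAAAAAAAATGG"))
index_pam_sites <- function(genome, classes = c("NGG", "NAG"),
                            grna = NULL) {
  classes <- match.arg(classes, c("NGG", "NAG"), several.ok = TRUE)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  letters_used <- Biostrings::uniqueLetters(genome)
  if (!all(letters_used %in% c("A", "C", "G", "T", "N"))) {
    stop("sequences must be over A, C, G, T, N")
  }

  scan_strand <- function(seqs, strand) {
    out <- list()
    for (chrom in names(seqs)) {
      s <- seqs[[chrom]]
      L <- length(s)
      s_chr <- as.character(s)
      for (cls in classes) {
        hits <- Biostrings::matchPattern(cls, s,
                                         fixed = c(pattern = FALSE,
                                                   subject = TRUE))
        starts <- Biostrings::start(hits)
        starts <- starts[starts > 20]
        if (!length(starts)) next
        proto <- substring(s_chr, starts - 20, starts - 1)
        ok <- !grepl("N", proto, fixed = TRUE)
        starts <- starts[ok]
        proto <- proto[ok]
        if (!length(starts)) next
        pam_start <- if (strand == "+") starts else L - (starts + 2) + 1
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, pam_start = as.integer(pam_start), strand = strand,
          pam_class = cls, protospacer = proto, stringsAsFactors = FALSE
        )
      }
    }
    out
  }

  plus <- scan_strand(genome, "+")
  minus <- scan_strand(Biostrings::reverseComplement(genome), "-")
  sites <- do.call(rbind, c(plus, minus, list(data.frame(
    chrom = character(), pam_start = integer(), strand = character(),
    pam_class = character(), protospacer = character(),
    stringsAsFactors = FALSE))))
  sites <- sites[order(sites$chrom, sites$pam_start, sites$strand), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  if (!is.null(grna)) {
    sites$score <- vapply(sites$protospacer, mit_score, 0, grna = grna,
                          USE.NAMES = FALSE)
  }
  sites
}

#' Aggregate gRNA similarity per genomic window
#'
#' Summarises site scores in each window with `max` (default; the single
#' best off-target candidate drives cutting probability) or `mean`.
#' Windows without any scored site get NA.
#'
#' @param sites Site data.frame from [index_pam_sites()] with a `score`
#'   column.
#' @param map A `marker_map` providing chromosome lengths.
#' @param window Window size in bp (default 50,000, non-overlapping).
#' @param statistic "max" or "mean".
#' @return Window table ([make_windows()]) with `n_sites` and `similarity`.
#' @export
window_similarity <- function(sites, map, window = 50000,
                              statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot("score" %in% names(sites))
  win <- make_windows(map, window)
  fun <- if (statistic == "max") max else mean
  win$n_sites <- 0L
  win$similarity <- NA_real_
  for (i in seq_len(nrow(win))) {
    sc <- sites$score[sites$chrom == win$chrom[i] &
                        sites$pam_start >= win$start[i] &
                        sites$pam_start <= win$end[i]]
    win$n_sites[i] <- length(sc)
    if (length(sc)) win$similarity[i] <- fun(sc)
  }
  win
}

#' Regression of normalized LOH rates on window gRNA similarity
#'
#' Ordinary least squares of the normalized per-window rate difference
#' `r_si` on the window similarity aggregate, optionally with PAM-site
#' density as a covariate. A positive, significant slope would indicate
#' sequence-directed off-target LOH induction.
#'
#' @param r Normalized rates per window (see [normalized_rate()]); NA
#'   entries dropped pairwise.
#' @param similarity Per-window similarity aggregates.
#' @param pam_density Optional per-window PAM-site counts (covariate).
#' @return List: slope, p_value, n (complete pairs), fit (the `lm`
#'   object).
#' @export
rate_similarity_regression <- function(r, similarity, pam_density = NULL) {
  df <- data.frame(r = r, similarity = similarity)
  if (!is.null(pam_density)) df$pam_density <- pam_density
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3) stop("fewer than 3 complete window pairs")
  if (length(unique(df$similarity)) < 2) {
    return(list(slope = NA_real_, p_value = NA_real_, n = nrow(df),
                fit = NULL, degenerate = TRUE))
  }
  fit <- lm(r ~ ., data = df)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)["similarity"]),
       p_value = unname(sm["similarity", "Pr(>|t|)"]),
       n = nrow(df), fit = fit, degenerate = FALSE)
}
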