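# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are deliberately naive (loops over the call string) so they stay
# independent of the vectorised implementation they check.

# A hand-made marker map with exactly known marker positions.
mk_map <- function(markers, lengths, cen_rel = 0.5, effective = NULL) {
  stopifnot(identical(names(markers), names(lengths)))
  cen_mid <- round(cen_rel * lengths)
  structure(list(
    chromosomes = data.frame(
      name = names(lengths), length = as.numeric(lengths),
      cen_start = pmax(2, cen_mid - 60), cen_end = pmin(lengths - 1, cen_mid + 60),
      stringsAsFactors = FALSE
    ),
    markers = lapply(markers, as.numeric),
    mean_spacing = sum(lengths) / sum(vapply(markers, length, 1L)),
    effective_length = if (is.null(effective)) sum(lengths) else effective
  ), class = "marker_map")
}

# One chromosome, 5 markers at 100..500, length 1000 (the worked example
# geometry used across caller tests).
map5 <- function(L = 1000) {
  mk_map(list(chrA = seq(100, 500, by = 100)), c(chrA = L))
}

# Brute-force tract finder: walk the calls left to right.
oracle_tracts <- function(calls, pos, L, missing = "transparent") {
  if (missing == "transparent") {
    keep <- calls != "MISSING"
    pos <- pos[keep]
    calls <- calls[keep]
  }
  tracts <- list()
  i <- 1
  n <- length(calls)
  while (i <= n) {
    if (calls[i] %in% c("HOM_P1", "HOM_P2")) {
      j <- i
      while (j < n && calls[j + 1] == calls[i]) j <- j + 1
      left <- if (i == 1) 1 else (pos[i - 1] + pos[i]) / 2
      right <- if (j == n) L else (pos[j] + pos[j + 1]) / 2
      tracts[[length(tracts) + 1]] <- data.frame(
        first_pos = pos[i], last_pos = pos[j], left = left, right = right,
        homolog = calls[i], n_markers = j - i + 1,
        stringsAsFactors = FALSE
      )
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  do.call(rbind, c(tracts, list(data.frame(
    first_pos = numeric(), last_pos = numeric(), left = numeric(),
    right = numeric(), homolog = character(), n_markers = integer(),
    stringsAsFactors = FALSE))))
}

# Brute-force merge of oracle tracts (one chromosome): adjacent tracts in
# positional order merge iff same homolog and boundary gap < merge_gap.
oracle_events <- function(tracts, merge_gap = 10000) {
  if (!nrow(tracts)) return(tracts)
  groups <- list()
  cur <- tracts[1, , drop = FALSE]
  for (i in seq_len(nrow(tracts))[-1]) {
    gap <- tracts$left[i] - cur$right[nrow(cur)]
    if (tracts$homolog[i] == cur$homolog[1] && gap < merge_gap) {
      cur <- rbind(cur, tracts[i, ])
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- tracts[i, , drop = FALSE]
    }
  }
  groups[[length(groups) + 1]] <- cur
  do.call(rbind, lapply(groups, function(g) data.frame(
    left = min(g$left), right = max(g$right),
    first_pos = min(g$first_pos), last_pos = max(g$last_pos),
    homolog = g$homolog[1], n_markers = sum(g$n_markers),
    stringsAsFactors = FALSE)))
}

# Expected per-marker calls from simulator truth (last writer wins),
# independent of the simulator's own call vector construction.
oracle_calls_from_truth <- function(map, events) {
  mt <- data.frame(
    chrom = rep(map$chromosomes$name, lengths(map$markers)),
    pos = unlist(map$markers, use.names = FALSE)
  )
  calls <- rep("HET", nrow(mt))
  if (!is.null(events) && nrow(events)) {
    for (k in order(events$order)) {
      hit <- mt$chrom == events$chrom[k] & mt$pos >= events$start[k] &
        mt$pos <= events$end[k]
      calls[hit] <- events$homolog[k]
    }
  }
  calls
}

# A small deterministic genome for PAM-scan tests.
random_genome <- function(n = 1000, seed = 1, chroms = c("cA", "cB")) {
  set.seed(seed)
  out <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, "")
  out
}

# Naive PAM scanner over a plain character genome (plus strand of the
# given string only).
oracle_pam_plus <- function(seq, classes = c("NGG", "NAG")) {
  hits <- list()
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(nchar(seq) - 2)) {
    pam <- paste(chars[i:(i + 2)], collapse = "")
    cls <- if (substr(pam, 2, 3) == "GG") "NGG" else
      if (substr(pam, 2, 3) == "AG") "NAG" else NA
    if (is.na(cls) || !(cls %in% classes)) next
    if (i <= 20) next
    proto <- paste(chars[(i - 20):(i - 1)], collapse = "")
    if (grepl("N", proto)) next
    hits[[length(hits) + 1]] <- data.frame(
      pam_start = i, pam_class = cls, protospacer = proto,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(hits, list(data.frame(
    pam_start = integer(), pam_class = character(),
    protospacer = character(), stringsAsFactors = FALSE))))
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
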