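# Plain-text readers/writers. Internal coordinates are 1-based closed;
# BED exports are 0-based half-open. Every writer states the convention
# and the originating seed/config hash in its header.

.header_lines <- function(what, extra = character()) {
  c(sprintf("# lohdrive %s", what),
    "# coordinates: internal 1-based closed unless stated otherwise",
    extra)
}

#' Write / read a marker map
#'
#' The marker positions go to a two-column TSV (chrom, pos; 1-based) and
#' the chromosome structure (lengths, centromeres, mean spacing, effective
#' length) to a JSON sidecar `<prefix>.json`.
#'
#' @param map A `marker_map`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return `write_marker_map`: the prefix, invisibly. `read_marker_map`:
#'   the reconstructed `marker_map`.
#' @export
write_marker_map <- function(map, prefix) {
  stopifnot(inherits(map, "marker_map"))
  tsv <- paste0(prefix, ".tsv")
  con <- file(tsv, "w")
  writeLines(.header_lines("marker map (chrom, pos)"), con)
  write.table(marker_table(map), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  side <- list(
    chromosomes = map$chromosomes,
    mean_spacing = map$mean_spacing,
    effective_length = map$effective_length
  )
  jsonlite::write_json(side, paste0(prefix, ".json"), digits = NA,
                       dataframe = "columns")
  invisible(prefix)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(prefix) {
  tab <- read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  chroms <- as.data.frame(side$chromosomes, stringsAsFactors = FALSE)
  markers <- lapply(chroms$name, function(ch) {
    as.numeric(tab$pos[tab$chrom == ch])
  })
  names(markers) <- chroms$name
  validate_marker_map(structure(list(
    chromosomes = chroms, markers = markers,
    mean_spacing = side$mean_spacing,
    effective_length = side$effective_length
  ), class = "marker_map"))
}

#' Write / read a genotype matrix
#'
#' TSV layout: header comment lines, then clone metadata encoded as
#' `#clone`/`#founder`/`#generations` comment rows, then one row per
#' marker: chrom, pos, followed by one call column per clone.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output TSV path.
#' @param map The `marker_map` the file refers to (reader only).
#' @return `write_genotypes`: the path, invisibly. `read_genotypes`: a
#'   `genotype_matrix` validated against `map`.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  writeLines(.header_lines(
    "genotype matrix (rows = markers, columns = clones)",
    c(paste0("#founder\t", paste(gm$clones$founder, collapse = "\t")),
      paste0("#generations\t",
             paste(gm$clones$generations, collapse = "\t")))
  ), con)
  tab <- cbind(marker_table(gm$map), as.data.frame(gm$calls))
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_genotypes
#' @param dialect Input format: "tsv" (the native matrix layout) or "vcf"
#'   (GT fields: 0/1 -> HET, 0/0 -> HOM_P1, 1/1 -> HOM_P2, ./. ->
#'   MISSING; requires the vcfR package).
#' @export
read_genotypes <- function(path, map, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    lines <- readLines(path)
    founders <- generations <- NULL
    meta <- grep("^#(founder|generations)\t", lines, value = TRUE)
    for (m in meta) {
      parts <- strsplit(m, "\t")[[1]]
      if (parts[1] == "#founder") founders <- parts[-1]
      if (parts[1] == "#generations") generations <- as.numeric(parts[-1])
    }
    tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (nrow(tab) != n_markers(map)) {
      stop("file has ", nrow(tab), " marker rows but the map has ",
           n_markers(map))
    }
    mt <- marker_table(map)
    if (!all(tab$chrom == mt$chrom & tab$pos == mt$pos)) {
      stop("marker coordinates in ", path, " do not match the map")
    }
    calls <- as.matrix(tab[, -(1:2), drop = FALSE])
    bad <- which(!calls %in% GENOTYPE_LEVELS)
    if (length(bad)) {
      stop("unknown genotype symbols at cells: ",
           paste(head(bad, 10), collapse = ", "))
    }
    clones <- data.frame(clone = colnames(calls),
                         founder = founders %||% NA_character_,
                         generations = generations %||% NA_real_,
                         stringsAsFactors = FALSE)
    genotype_matrix(map, calls, clones)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF genotypes requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- vcfR::getFIX(v)
    mt <- marker_table(map)
    key_vcf <- paste(fix[, "CHROM"], fix[, "POS"])
    key_map <- paste(mt$chrom, mt$pos)
    idx <- match(key_map, key_vcf)
    if (anyNA(idx)) stop("VCF is missing ", sum(is.na(idx)), " marker sites")
    gt <- gt[idx, , drop = FALSE]
    conv <- c("0/1" = "HET", "1/0" = "HET", "0|1" = "HET", "1|0" = "HET",
              "0/0" = "HOM_P1", "0|0" = "HOM_P1",
              "1/1" = "HOM_P2", "1|1" = "HOM_P2")
    calls <- matrix(conv[gt], nrow = nrow(gt),
                    dimnames = list(NULL, colnames(gt)))
    calls[is.na(calls)] <- "MISSING"
    clones <- data.frame(clone = colnames(calls), founder = NA_character_,
                         generations = NA_real_, stringsAsFactors = FALSE)
    genotype_matrix(map, calls, clones)
  }
}

#' Export a genotype matrix as VCF
#'
#' Minimal VCF 4.2 with GT fields: HET -> 0/1, HOM_P1 -> 0/0, HOM_P2 ->
#' 1/1, MISSING -> ./. . REF/ALT are placeholders (the marker alleles are
#' not modelled), so the file is a genotype container, not a sequence
#' record.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  conv <- c(HET = "0/1", HOM_P1 = "0/0", HOM_P2 = "1/1", MISSING = "./.")
  mt <- marker_table(gm$map)
  gt <- matrix(conv[gm$calls], nrow = nrow(gm$calls))
  body <- cbind(mt$chrom, mt$pos, ".", "A", "T", ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lohdrive (marker genotypes; REF/ALT are placeholders)",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s,length=%d>", gm$map$chromosomes$name,
            as.integer(gm$map$chromosomes$length)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gm$calls)), collapse = "\t")
  ), con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}

#' Write / read LOH events as BED-like TSV
#'
#' On disk the interval columns follow the BED convention (0-based,
#' half-open: `start = left - 1`, `end = right`); extra columns carry
#' clone, class, homolog, breakpoint (1-based) and marker counts. Because
#' midpoint-extrapolated boundaries fall between markers, start/end may be
#' half-integers (BED-like rather than strict BED); this keeps the round
#' trip back to internal 1-based closed intervals lossless.
#'
#' @param events Event data.frame (from [call_loh()]).
#' @param path Output path.
#' @return `write_events_bed`: the path, invisibly; `read_events_bed`: the
#'   event data.frame in internal coordinates.
#' @export
write_events_bed <- function(events, path) {
  con <- file(path, "w")
  writeLines(c("# lohdrive LOH events",
               "# coordinates: BED 0-based half-open (start = left-1, end = right)",
               paste("#chrom", "start", "end", "clone", "class", "homolog",
                     "breakpoint", "n_markers", "n_tracts",
                     "possible_aneuploidy", sep = "\t")), con)
  if (nrow(events)) {
    # midpoint-extrapolated boundaries are half-integers, so start/end are
    # written as-is (BED-like, not strict BED) to keep the round trip
    # lossless
    bed <- data.frame(
      chrom = events$chrom,
      start = events$left - 1, end = events$right,
      clone = events$clone, class = events$class, homolog = events$homolog,
      breakpoint = events$breakpoint, n_markers = events$n_markers,
      n_tracts = events$n_tracts,
      possible_aneuploidy = events$possible_aneuploidy
    )
    write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  close(con)
  invisible(path)
}

#' @rdname write_events_bed
#' @export
read_events_bed <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  cols <- c("chrom", "start", "end", "clone", "class", "homolog",
            "breakpoint", "n_markers", "n_tracts", "possible_aneuploidy")
  if (!length(body)) {
    ev <- .empty_events()
    return(ev)
  }
  tab <- tryCatch(
    read.table(text = body, sep = "\t", col.names = cols,
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed BED line(s) in ", path, ": ",
                             conditionMessage(e))
  )
  nf <- vapply(strsplit(body, "\t"), length, 1L)
  if (any(nf != length(cols))) {
    stop("malformed BED line(s) at file line(s): ",
         paste(which(grepl("^#", lines) == FALSE)[nf != length(cols)] +
                 0, collapse = ", "))
  }
  data.frame(
    clone = tab$clone, chrom = tab$chrom,
    left = tab$start + 1, right = tab$end,
    length = tab$end - (tab$start + 1),
    homolog = tab$homolog, n_markers = tab$n_markers,
    n_tracts = tab$n_tracts, class = tab$class,
    possible_aneuploidy = as.logical(tab$possible_aneuploidy),
    breakpoint = tab$breakpoint, stringsAsFactors = FALSE
  )
}
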