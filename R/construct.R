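# Closed-form expectations for de novo mutations arising inside the
# integrated constructs, and the fraction expected to deactivate the
# drive components.

#' Specification of an integrated construct
#'
#' Describes a cassette integrated (homozygously, hence `copies = 2`) into
#' the genome: its total length, the lengths of its functional drive
#' components (e.g. the gRNA cassette and the Cas9 gene, promoters and
#' terminators included), and the number of end-point clones carrying it.
#'
#' @param name Construct label.
#' @param length_bp Total construct length in bp.
#' @param components Named numeric vector of drive-component lengths in bp
#'   (may be empty for a payload-free control cassette).
#' @param copies Copies per genome (default 2, a homozygous diploid
#'   integration).
#' @param n_clones End-point clones of this strain.
#' @return A `construct_spec` object.
#' @export
#' @examples
#' construct_spec("D", 7999, c(gRNA = 388, Cas9 = 4890), n_clones = 67)
construct_spec <- function(name, length_bp, components = numeric(),
                           copies = 2, n_clones = 0) {
  stopifnot(length_bp > 0, all(components > 0),
            sum(components) <= length_bp, copies >= 1, n_clones >= 0)
  structure(list(name = name, length_bp = length_bp,
                 components = components, copies = copies,
                 n_clones = n_clones),
            class = "construct_spec")
}

#' Default construct specifications
#'
#' Reads the construct table shipped with the package
#' (`inst/extdata/constructs.yaml`): the drive (D, 7999 bp, gRNA + Cas9),
#' Cas9-only (C, 7601 bp) and control (W, 2770 bp) cassettes with their
#' retained end-point clone counts.
#'
#' @param path YAML file to read (default: the shipped table).
#' @return Named list of [construct_spec()] objects.
#' @export
#' @examples
#' default_constructs()$D$length_bp
default_constructs <- function(path = system.file("extdata",
                                                  "constructs.yaml",
                                                  package = "lohdrive")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(x) {
    construct_spec(x$name, x$length_bp,
                   components = unlist(x$components %||% list()),
                   copies = x$copies %||% 2,
                   n_clones = x$n_clones %||% 0)
  })
  stats::setNames(out, vapply(out, function(x) x$name, ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected construct mutations per end-point clone
#'
#' Mutations hit either copy of the construct at the combined SNM + indel
#' per-bp per-generation rate, so a clone is expected to carry
#' `copies * (snm_rate + indel_rate) * length * T` construct mutations
#' after `T` generations.
#'
#' @param spec A [construct_spec()].
#' @param snm_rate Single-nucleotide mutation rate per bp per generation
#'   (default 1.67e-10).
#' @param indel_rate Indel rate per bp per generation (default 7.5e-12).
#' @param T_gen Number of generations (default 800).
#' @return Expected mutations per clone.
#' @export
#' @examples
#' d <- construct_spec("D", 7999, c(gRNA = 388, Cas9 = 4890), n_clones = 67)
#' expected_construct_mutations(d)  # 2.23e-3
expected_construct_mutations <- function(spec, snm_rate = 1.67e-10,
                                         indel_rate = 7.5e-12,
                                         T_gen = 800) {
  stopifnot(inherits(spec, "construct_spec"),
            snm_rate >= 0, indel_rate >= 0, T_gen >= 0)
  spec$copies * (snm_rate + indel_rate) * spec$length_bp * T_gen
}

#' Expected number of clones carrying a construct mutation
#'
#' @param per_clone Expected construct mutations per clone (from
#'   [expected_construct_mutations()]).
#' @param n_clones Number of end-point clones.
#' @return Expected mutant clones across the experiment.
#' @export
#' @examples
#' expected_mutant_clones(2.23e-3, 67)  # ~0.15
expected_mutant_clones <- function(per_clone, n_clones) {
  stopifnot(per_clone >= 0, n_clones >= 0)
  per_clone * n_clones
}

#' Fraction of construct mutations expected to deactivate the drive
#'
#' A conservative length-proportional estimate: the summed length of the
#' drive components divided by the total construct length (every mutation
#' inside a component is assumed deactivating).
#'
#' @param spec A [construct_spec()] with components set.
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' d <- construct_spec("D", 7999, c(gRNA = 388, Cas9 = 4890))
#' deactivating_fraction(d)  # 0.660
deactivating_fraction <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  if (!length(spec$components)) {
    stop("construct '", spec$name, "' has no drive components")
  }
  sum(spec$components) / spec$length_bp
}

#' Uncertainty band from local mutation-rate variation
#'
#' Genome-wide average mutation rates hide up to ~6-fold variation across
#' genomic locations, so a point expectation based on the average rate is
#' bracketed by multiplying with a fold range (default 1/6 to 6).
#'
#' @param expectation Point expectation(s).
#' @param fold_range Length-2 multiplier range, `fold_range[1] <= 1 <=
#'   fold_range[2]`.
#' @return Named vector `lower`, `upper` (or a 2-column matrix for vector
#'   input).
#' @export
#' @examples
#' uncertainty_band(0.39)  # ~0.065 .. 2.3
uncertainty_band <- function(expectation, fold_range = c(1 / 6, 6)) {
  stopifnot(length(fold_range) == 2, fold_range[1] <= 1,
            fold_range[2] >= 1, all(expectation >= 0))
  if (length(expectation) == 1) {
    c(lower = expectation * fold_range[1],
      upper = expectation * fold_range[2])
  } else {
    cbind(lower = expectation * fold_range[1],
          upper = expectation * fold_range[2])
  }
}
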