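#' Kinetic rate parameters
#'
#' Collects the rate constants of the replication kinetics: per-monomer
#' elongation constants (keyed by the identity of the inserted monomer),
#' zeroth-order monomer influx, first-order monomer decay, and first-order
#' degradation rates for the replication intermediates. Intermediate decay is
#' either a single value (uniform-decay mode, required by the analytic
#' theory) or a vector that is assigned to intermediates per (pair, strand,
#' stage) in canonical order when a system is built.
#'
#' @param alphabet a [monomer_alphabet()].
#' @param elongation per-monomer elongation rate constants; scalar or named
#'   vector over the alphabet symbols (concentration^-1 time^-1).
#' @param monomer_influx per-monomer constant influx; scalar or named vector
#'   (concentration time^-1).
#' @param monomer_decay per-monomer decay rate; scalar or named vector
#'   (time^-1).
#' @param intermediate_decay scalar (uniform) or numeric vector of
#'   intermediate degradation rates (time^-1), consumed in canonical order
#'   (pair, then strand, then stage) by [replicator_system()].
#' @return An object of class `rate_parameters`.
#' @examples
#' rate_parameters(binary_alphabet(), intermediate_decay = 0.01)
#' @export
rate_parameters <- function(alphabet,
                            elongation = 1,
                            monomer_influx = 1,
                            monomer_decay = 1,
                            intermediate_decay = 0.01) {
  per_monomer <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(as.numeric(x), alphabet$size), alphabet$symbols)
    x <- x[alphabet$symbols]
    if (anyNA(x)) stop("'", what, "' must cover every alphabet symbol")
    if (any(x <= 0)) stop("'", what, "' rates must be strictly positive")
    stats::setNames(as.numeric(x), alphabet$symbols)
  }
  intermediate_decay <- as.numeric(intermediate_decay)
  if (any(intermediate_decay <= 0))
    stop("'intermediate_decay' rates must be strictly positive")
  structure(
    list(alphabet = alphabet,
         elongation = per_monomer(elongation, "elongation"),
         monomer_influx = per_monomer(monomer_influx, "monomer_influx"),
         monomer_decay = per_monomer(monomer_decay, "monomer_decay"),
         intermediate_decay = intermediate_decay),
    class = "rate_parameters"
  )
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Rate parameters over alphabet {",
      paste(x$alphabet$symbols, collapse = " "), "}\n", sep = "")
  cat("  elongation:        ", paste(signif(x$elongation, 4), collapse = " "), "\n")
  cat("  monomer influx:    ", paste(signif(x$monomer_influx, 4), collapse = " "), "\n")
  cat("  monomer decay:     ", paste(signif(x$monomer_decay, 4), collapse = " "), "\n")
  if (length(x$intermediate_decay) == 1L)
    cat("  intermediate decay:", signif(x$intermediate_decay, 4), "(uniform)\n")
  else
    cat("  intermediate decay:", length(x$intermediate_decay),
        "values in [", signif(min(x$intermediate_decay), 4), ",",
        signif(max(x$intermediate_decay), 4), "]\n")
  invisible(x)
}

#' Is the intermediate decay uniform?
#' @param params a [rate_parameters()] object.
#' @return Logical scalar.
#' @export
uniform_decay <- function(params) {
  length(unique(params$intermediate_decay)) == 1L
}

#' Sampling distributions for rate parameters
#'
#' Each rate family is drawn from a uniform distribution on
#' `[mean * (1 - width), mean * (1 + width)]`; `width = 0` reproduces the
#' mean deterministically. The defaults are the study conditions used by the
#' survey protocols: order-1 elongation, influx and monomer decay (held at
#' their means) and intermediate degradation drawn from a narrow (+/-10%)
#' distribution around 0.01.
#'
#' @param elongation_mean,elongation_width mean and relative width of the
#'   per-monomer elongation constants.
#' @param influx_mean,influx_width monomer influx.
#' @param monomer_decay_mean,monomer_decay_width monomer decay.
#' @param intermediate_decay_mean,intermediate_decay_width intermediate
#'   degradation rates.
#' @return An object of class `rate_distribution`.
#' @export
rate_distribution <- function(elongation_mean = 1, elongation_width = 0,
                              influx_mean = 1, influx_width = 0,
                              monomer_decay_mean = 1, monomer_decay_width = 0,
                              intermediate_decay_mean = 0.01,
                              intermediate_decay_width = 0.1) {
  fam <- function(mean, width, what) {
    if (mean <= 0) stop("'", what, "' mean must be strictly positive")
    if (width < 0 || width >= 1)
      stop("'", what, "' relative width must lie in [0, 1) for positive support")
    list(mean = mean, width = width)
  }
  structure(
    list(elongation = fam(elongation_mean, elongation_width, "elongation"),
         influx = fam(influx_mean, influx_width, "influx"),
         monomer_decay = fam(monomer_decay_mean, monomer_decay_width,
                             "monomer_decay"),
         intermediate_decay = fam(intermediate_decay_mean,
                                  intermediate_decay_width,
                                  "intermediate_decay")),
    class = "rate_distribution"
  )
}

#' Draw a rate-parameter set from a distribution
#'
#' Reproducible under a fixed seed. `n_intermediates` intermediate decay
#' rates are drawn so that a survey can assign them to intermediates in
#' canonical order, always in the same order within a set.
#'
#' @param dist a [rate_distribution()].
#' @param alphabet a [monomer_alphabet()].
#' @param n_intermediates how many per-intermediate decay rates to draw
#'   (use 1 for uniform-decay mode).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A [rate_parameters()] object.
#' @export
sample_parameters <- function(dist, alphabet, n_intermediates = 1L,
                              seed = NULL) {
  draw <- function(fam, n) {
    if (fam$width == 0) rep(fam$mean, n)
    else stats::runif(n, fam$mean * (1 - fam$width), fam$mean * (1 + fam$width))
  }
  do_draw <- function() {
    m <- alphabet$size
    rate_parameters(
      alphabet,
      elongation = stats::setNames(draw(dist$elongation, m), alphabet$symbols),
      monomer_influx = stats::setNames(draw(dist$influx, m), alphabet$symbols),
      monomer_decay = stats::setNames(draw(dist$monomer_decay, m),
                                      alphabet$symbols),
      intermediate_decay = draw(dist$intermediate_decay, n_intermediates)
    )
  }
  if (is.null(seed)) do_draw() else withr::with_seed(seed, do_draw())
}
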