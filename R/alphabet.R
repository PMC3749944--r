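#' Monomer alphabets
#'
#' A monomer alphabet is an ordered set of single-character monomer labels,
#' optionally equipped with a complement map (an involution on the symbols).
#' The complement map is only required for complementary pairing schemes.
#'
#' @param symbols character vector of distinct single-character monomer labels
#'   (at least two).
#' @param complement named character vector mapping each symbol to its
#'   complement, or `NULL` if the alphabet is only used with homologous
#'   pairing. Must be an involution: `complement[complement[x]] == x`.
#' @return An object of class `monomer_alphabet` with elements `symbols`,
#'   `complement` and `size`.
#' @examples
#' monomer_alphabet(c("A", "B"), complement = c(A = "B", B = "A"))
#' rna_alphabet()
#' @export
monomer_alphabet <- function(symbols, complement = NULL) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L)
    stop("an alphabet needs at least two monomer types")
  if (anyDuplicated(symbols))
    stop("alphabet symbols must be distinct")
  if (any(nchar(symbols) != 1L))
    stop("monomer labels must be single characters")
  if (!is.null(complement)) {
    complement <- complement[symbols]
    if (anyNA(complement) || !all(names(complement) == symbols))
      stop("'complement' must be named and cover every symbol")
    if (!all(unname(complement[unname(complement)]) == symbols))
      stop("'complement' must be an involution on the symbols")
  }
  structure(
    list(symbols = symbols, complement = complement, size = length(symbols)),
    class = "monomer_alphabet"
  )
}

#' @describeIn monomer_alphabet Two-letter alphabet A/B with A-B complement.
#' @export
binary_alphabet <- function() {
  monomer_alphabet(c("A", "B"), complement = c(A = "B", B = "A"))
}

#' @describeIn monomer_alphabet RNA alphabet A/C/G/U with Watson-Crick pairs.
#' @export
rna_alphabet <- function() {
  monomer_alphabet(c("A", "C", "G", "U"),
                   complement = c(A = "U", C = "G", G = "C", U = "A"))
}

#' @export
print.monomer_alphabet <- function(x, ...) {
  cat("Monomer alphabet:", paste(x$symbols, collapse = " "), "\n")
  if (!is.null(x$complement))
    cat("Complement map: ",
        paste(names(x$complement), x$complement, sep = "-", collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' Pairing scheme of template replication
#'
#' Declares how the copy strand relates to its template: whether the inserted
#' monomer is the complement of, or identical to, the template monomer
#' (`pairing`), and whether the finished copy is written in reversed order
#' relative to the template (`polarity`). All four combinations are
#' representable.
#'
#' @param pairing `"complementary"` or `"homologous"`.
#' @param polarity `"antiparallel"` or `"parallel"`.
#' @return An object of class `pairing_scheme`.
#' @examples
#' pairing_scheme("complementary", "antiparallel")  # RNA-like
#' pairing_scheme("homologous", "parallel")         # template == copy
#' @export
pairing_scheme <- function(pairing = c("complementary", "homologous"),
                           polarity = c("antiparallel", "parallel")) {
  pairing <- match.arg(pairing)
  polarity <- match.arg(polarity)
  structure(list(pairing = pairing, polarity = polarity),
            class = "pairing_scheme")
}

#' @export
print.pairing_scheme <- function(x, ...) {
  cat("Pairing scheme:", x$pairing, "pairing,", x$polarity, "polarity\n")
  invisible(x)
}
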