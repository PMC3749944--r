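#' @keywords internal
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' @keywords internal
check_sequence <- function(seq, alphabet) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("a sequence must be a single character string")
  ch <- seq_chars(seq)
  if (length(ch) < 2L)
    stop("sequences must have length at least 2")
  bad <- setdiff(ch, alphabet$symbols)
  if (length(bad))
    stop("symbol(s) outside alphabet: ", paste(unique(bad), collapse = ", "))
  ch
}

#' Copy strand of a template under a pairing scheme
#'
#' Returns the finished copy strand produced when `seq` is used as a
#' template. Monomers are incorporated in ascending template position order
#' for every scheme; the polarity only determines what the finished copy
#' strand reads as: for antiparallel polarity the copy is written in reversed
#' order relative to the template. Hence homologous+parallel returns the
#' sequence itself, complementary+antiparallel the reverse complement,
#' homologous+antiparallel the reversal, and complementary+parallel the
#' position-wise complement. The operation is an involution.
#'
#' @param seq character scalar, the template strand (written 5'->3').
#' @param scheme a [pairing_scheme()].
#' @param alphabet a [monomer_alphabet()]; complementary pairing requires its
#'   complement map.
#' @return The copy strand as a character scalar.
#' @examples
#' copy_strand("GAAU", pairing_scheme("complementary", "antiparallel"), rna_alphabet())
#' copy_strand("AAB", pairing_scheme("homologous", "parallel"), binary_alphabet())
#' @export
copy_strand <- function(seq, scheme, alphabet) {
  ch <- check_sequence(seq, alphabet)
  if (scheme$pairing == "complementary") {
    if (is.null(alphabet$complement))
      stop("complementary pairing requires an alphabet with a complement map")
    ch <- unname(alphabet$complement[ch])
  }
  if (scheme$polarity == "antiparallel")
    ch <- rev(ch)
  paste(ch, collapse = "")
}

#' Is a sequence its own copy strand?
#'
#' A sequence is self-paired when template and copy are identical, so the
#' sequence pair consists of two copies of one strand. Under homologous
#' pairing with parallel polarity every sequence is self-paired; under
#' complementary pairing with antiparallel polarity exactly the reverse
#' palindromes are.
#'
#' @inheritParams copy_strand
#' @return Logical scalar.
#' @examples
#' is_self_paired("GAUC", pairing_scheme("complementary", "antiparallel"), rna_alphabet())
#' @export
is_self_paired <- function(seq, scheme, alphabet) {
  identical(copy_strand(seq, scheme, alphabet), seq)
}

#' Monomer composition of a sequence
#'
#' @inheritParams copy_strand
#' @return Named integer vector of monomer counts, in alphabet order,
#'   summing to the sequence length.
#' @examples
#' seq_composition("AABB", binary_alphabet())
#' @export
seq_composition <- function(seq, alphabet) {
  ch <- check_sequence(seq, alphabet)
  counts <- table(factor(ch, levels = alphabet$symbols))
  stats::setNames(as.integer(counts), alphabet$symbols)
}

#' Do two sequences have identical monomer composition?
#'
#' Compositionally identical sequences consume the monomer pools in the same
#' overall proportions; under uniform degradation their coexistence is
#' neutral and structurally unstable.
#'
#' @param seq1,seq2 character scalars over `alphabet`.
#' @inheritParams copy_strand
#' @return Logical scalar.
#' @export
compositionally_identical <- function(seq1, seq2, alphabet) {
  identical(seq_composition(seq1, alphabet), seq_composition(seq2, alphabet))
}

#' Canonical representative strand of a sequence pair
#'
#' A pair is represented by the lexicographically smaller of its two strands,
#' which deduplicates (pair, reversed-pair) bookkeeping when rates are keyed
#' to a pair.
#'
#' @inheritParams copy_strand
#' @return Character scalar: the canonical strand.
#' @export
canonical_strand <- function(seq, scheme, alphabet) {
  other <- copy_strand(seq, scheme, alphabet)
  if (other < seq) other else seq
}

#' Enumerate an ordered sequence space
#'
#' Generates all `m^L` sequences of length `L` over the alphabet, in either
#' plain lexicographic order or ordered first by Hamming distance from the
#' all-first-symbol sequence and then lexicographically (the ordering used
#' for coexistence heatmaps).
#'
#' @param L sequence length (>= 2).
#' @param alphabet a [monomer_alphabet()].
#' @param order `"lexicographic"` or `"hamming_then_lex"`.
#' @param cap refuse to enumerate spaces larger than this many sequences.
#' @return Character vector of `m^L` distinct sequences.
#' @examples
#' sequence_space(2, binary_alphabet())
#' @export
sequence_space <- function(L, alphabet,
                           order = c("lexicographic", "hamming_then_lex"),
                           cap = 1e6) {
  order <- match.arg(order)
  L <- as.integer(L)
  if (L < 2L) stop("sequences must have length at least 2")
  m <- alphabet$size
  if (m^L > cap)
    stop("sequence space of size ", m, "^", L, " exceeds the enumeration cap")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet$symbols), L),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; lexicographic order needs the
  # last position to vary fastest, so build columns in reverse.
  seqs <- do.call(paste0, rev(grid))
  seqs <- sort(seqs)
  if (order == "hamming_then_lex") {
    ref <- strrep(alphabet$symbols[1L], L)
    hd <- vapply(seqs, function(s) hamming_distance(s, ref), integer(1L))
    seqs <- seqs[order(hd, seqs)]
  }
  unname(seqs)
}

#' Hamming distance between two equal-length sequences
#'
#' @param seq1,seq2 character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming_distance <- function(seq1, seq2) {
  a <- seq_chars(seq1); b <- seq_chars(seq2)
  if (length(a) != length(b)) stop("sequences must have equal length")
  sum(a != b)
}

#' Read sequences from FASTA or plain text
#'
#' Accepts FASTA files (via \pkg{seqinr}) or one-sequence-per-line plain
#' text. Sequences are upper-cased.
#'
#' @param path file path.
#' @param format `"auto"` (FASTA if the first non-blank character is `>`),
#'   `"fasta"`, or `"lines"`.
#' @return Character vector of sequences (named for FASTA input).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && startsWith(trimws(first[1L]), ">"))
      "fasta" else "lines"
  }
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
    out <- toupper(vapply(recs, function(r) as.character(r)[1L], character(1L)))
    names(out) <- names(recs)
  } else {
    out <- toupper(trimws(readLines(path, warn = FALSE)))
    out <- out[nzchar(out)]
  }
  out
}

#' Guess the smallest standard alphabet covering a set of sequences
#'
#' @param sequences character vector.
#' @return [binary_alphabet()] if only A/B occur, [rna_alphabet()] if only
#'   A/C/G/U occur; otherwise an alphabet of the observed symbols with no
#'   complement map.
#' @export
detect_alphabet <- function(sequences) {
  ch <- sort(unique(unlist(strsplit(sequences, "", fixed = TRUE))))
  if (all(ch %in% c("A", "B"))) return(binary_alphabet())
  if (all(ch %in% c("A", "C", "G", "U"))) return(rna_alphabet())
  monomer_alphabet(ch)
}
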