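#' Compile sequence pairs into a mass-action replicator system
#'
#' Builds the ODE system of competing template replicators feeding on shared
#' monomer pools. Each input sequence defines a sequence pair (the template
#' plus its scheme-derived copy strand). For every strand of every pair the
#' state carries one variable per elongation stage r in 0..L-1, where r
#' is the number of monomers already incorporated into the nascent copy and
#' stage 0 is the free single strand; the monomer concentrations follow. A
#' self-paired sequence (template == copy) contributes a single strand block
#' whose completion flux feeds its own free-strand variable twice, which is
#' dynamically equivalent to the corresponding two-identical-strand system.
#'
#' Intermediate degradation rates from `params$intermediate_decay` are
#' assigned per (pair, strand, stage) in canonical order (pair, then plus
#' before minus strand, then stage), recycling the vector if needed, so that
#' within a survey the same rates always go to the same slots.
#'
#' @param sequences character vector of template strands (one per pair), all
#'   of the same length, over `alphabet`.
#' @param scheme a [pairing_scheme()].
#' @param alphabet a [monomer_alphabet()].
#' @param params a [rate_parameters()] object for the same alphabet.
#' @return An object of class `replicator_system` with the pair table,
#'   state-variable layout and the packed descriptor used by the compiled
#'   right-hand side.
#' @examples
#' sys <- replicator_system(c("AAAA", "BBBB"),
#'                          pairing_scheme("homologous", "parallel"),
#'                          binary_alphabet(),
#'                          rate_parameters(binary_alphabet()))
#' sys
#' @export
replicator_system <- function(sequences, scheme, alphabet, params) {
  if (!identical(params$alphabet$symbols, alphabet$symbols))
    stop("'params' were built for a different alphabet")
  n_pairs <- length(sequences)
  if (n_pairs == 0L) {
    # degenerate system: just the monomer pools at their influx/decay balance
    L <- 0L
  } else {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("all sequences must have the same length")
    L <- as.integer(lens[1L])
  }

  pairs <- data.frame(
    plus = as.character(sequences),
    minus = vapply(sequences, copy_strand, character(1L),
                   scheme = scheme, alphabet = alphabet),
    stringsAsFactors = FALSE
  )
  pairs$self_paired <- pairs$plus == pairs$minus

  # strand blocks: plus strand always; minus strand only if distinct
  blocks <- data.frame(
    pair = integer(0), strand = character(0), template = character(0),
    stringsAsFactors = FALSE
  )
  for (p in seq_len(n_pairs)) {
    blocks <- rbind(blocks, data.frame(
      pair = p, strand = "plus", template = pairs$plus[p],
      stringsAsFactors = FALSE))
    if (!pairs$self_paired[p])
      blocks <- rbind(blocks, data.frame(
        pair = p, strand = "minus", template = pairs$minus[p],
        stringsAsFactors = FALSE))
  }
  S <- nrow(blocks)
  # partner block: the block whose stage-0 variable receives the finished copy
  partner <- integer(S)
  for (b in seq_len(S)) {
    p <- blocks$pair[b]
    partner[b] <- if (pairs$self_paired[p]) b
      else which(blocks$pair == p & blocks$strand != blocks$strand[b])
  }
  blocks$partner <- partner

  sym_index <- stats::setNames(seq_along(alphabet$symbols) - 1L,
                               alphabet$symbols)
  homologous <- scheme$pairing == "homologous"
  ins <- matrix(0L, nrow = S, ncol = L)  # 0-based inserted-monomer index
  for (b in seq_len(S)) {
    tmpl <- seq_chars(blocks$template[b])
    inserted <- if (homologous) tmpl else unname(alphabet$complement[tmpl])
    ins[b, ] <- unname(sym_index[inserted])
  }

  # canonical intermediate-decay assignment
  idec <- matrix(rep_len(params$intermediate_decay, S * L),
                 nrow = S, ncol = L, byrow = TRUE)

  var_names <- c(
    unlist(lapply(seq_len(S), function(b)
      paste0("p", blocks$pair[b], ".", blocks$strand[b], ".r",
             seq_len(L) - 1L))),
    paste0("mono.", alphabet$symbols)
  )

  parms <- c(alphabet$size, S, L,
             blocks$partner - 1L,
             as.numeric(t(ins)),
             as.numeric(t(idec)),
             unname(params$elongation),
             unname(params$monomer_influx),
             unname(params$monomer_decay))

  structure(
    list(pairs = pairs, blocks = blocks, scheme = scheme, alphabet = alphabet,
         params = params, L = L, n_pairs = n_pairs, n_blocks = S,
         n_vars = S * L + alphabet$size, var_names = var_names,
         ins = ins, idec = idec, parms = parms),
    class = "replicator_system"
  )
}

#' @export
print.replicator_system <- function(x, ...) {
  cat("Replicator system:", x$n_pairs, "sequence pair(s) of length", x$L,
      "over {", paste(x$alphabet$symbols, collapse = " "), "}\n")
  cat("  ", x$scheme$pairing, "pairing,", x$scheme$polarity, "polarity;",
      x$n_vars, "state variables\n")
  for (p in seq_len(x$n_pairs)) {
    cat(sprintf("  pair %d: %s / %s%s\n", p, x$pairs$plus[p], x$pairs$minus[p],
                if (x$pairs$self_paired[p]) " (self-paired)" else ""))
  }
  invisible(x)
}

#' Monomer inserted at a given elongation stage
#'
#' The elongation step from stage r to stage r+1 incorporates the pairing
#' image (complement for complementary pairing, identity for homologous) of
#' the template symbol at copy-order position r+1.
#'
#' @param template character scalar, the template strand.
#' @param stage integer stage `r` in `0 .. L-1`.
#' @param scheme a [pairing_scheme()].
#' @param alphabet a [monomer_alphabet()].
#' @return The inserted monomer symbol (character scalar).
#' @examples
#' inserted_monomer("GAAU", 0, pairing_scheme("complementary", "antiparallel"),
#'                  rna_alphabet())
#' @export
inserted_monomer <- function(template, stage, scheme, alphabet) {
  ch <- check_sequence(template, alphabet)
  stage <- as.integer(stage)
  if (any(stage < 0L) || any(stage > length(ch) - 1L))
    stop("stage must lie in 0 .. L-1")
  sym <- ch[stage + 1L]
  if (scheme$pairing == "complementary") {
    if (is.null(alphabet$complement))
      stop("complementary pairing requires an alphabet with a complement map")
    sym <- unname(alphabet$complement[sym])
  }
  sym
}

#' Mass-action derivative of a replicator system
#'
#' Evaluates the right-hand side of the system's ODEs at a state: elongation
#' fluxes between consecutive stages, release of template and copy on
#' completion, first-order degradation of every intermediate, and monomer
#' influx/decay/consumption. Degraded material is not recycled.
#'
#' @param system a [replicator_system()].
#' @param state numeric vector of concentrations matching the system layout
#'   (all entries must be non-negative).
#' @return Named numeric derivative vector.
#' @export
system_rhs <- function(system, state) {
  state <- check_state(system, state)
  out <- .Call(rx_rhs, system$parms, state)
  stats::setNames(out, system$var_names)
}

#' Analytic Jacobian of a replicator system
#'
#' Closed-form partial derivatives of the mass-action right-hand side
#' (polynomial in the state). When `at_steady_state` is `TRUE` (the default
#' for stability analysis) the derivative residual at `state` is checked
#' first.
#'
#' @inheritParams system_rhs
#' @param at_steady_state require `state` to be (numerically) a fixed point.
#' @param residual_tol maximum permitted `max(abs(rhs))` when
#'   `at_steady_state` is `TRUE`.
#' @return Square numeric matrix of dimension `system$n_vars`.
#' @export
system_jacobian <- function(system, state, at_steady_state = FALSE,
                            residual_tol = 1e-6) {
  state <- check_state(system, state)
  if (at_steady_state) {
    res <- max(abs(.Call(rx_rhs, system$parms, state)))
    if (res > residual_tol)
      stop("state is not a steady state (rhs residual ", signif(res, 3),
           " > ", residual_tol, ")")
  }
  J <- .Call(rx_jacobian, system$parms, state)
  dimnames(J) <- list(system$var_names, system$var_names)
  J
}

#' @keywords internal
check_state <- function(system, state) {
  state <- as.numeric(state)
  if (length(state) != system$n_vars)
    stop("state has length ", length(state), " but the system layout has ",
         system$n_vars, " variables")
  if (any(state < 0))
    stop("concentrations must be non-negative")
  state
}

#' Default initial state of a system
#'
#' Every free strand (stage 0) starts at the same small concentration, all
#' partial intermediates at zero, and the monomers at their influx/decay
#' balance. Neutral coexistence depends on initial conditions, so the strand
#' concentration is configurable.
#'
#' @param system a [replicator_system()].
#' @param strand_conc initial concentration of each free strand.
#' @return Named numeric state vector.
#' @export
initial_state <- function(system, strand_conc = 0.1) {
  y <- numeric(system$n_vars)
  names(y) <- system$var_names
  S <- system$n_blocks; L <- system$L
  y[(seq_len(S) - 1L) * L + 1L] <- strand_conc
  y[S * L + seq_len(system$alphabet$size)] <-
    system$params$monomer_influx / system$params$monomer_decay
  y
}

#' Indices of the state variables belonging to one pair
#' @keywords internal
pair_var_index <- function(system, pair) {
  b <- which(system$blocks$pair == pair)
  unlist(lapply(b, function(s) (s - 1L) * system$L + seq_len(system$L)))
}
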