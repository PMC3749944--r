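#' @keywords internal
check_analytic_regime <- function(params, need_binary = TRUE) {
  if (!uniform_decay(params))
    stop("the closed-form theory requires uniform intermediate decay")
  if (need_binary && params$alphabet$size != 2L)
    stop("the closed-form theory requires a two-monomer alphabet")
  invisible(params)
}

#' Per-stage survival ratio and monomer level pinned by steady-state growth
#'
#' For a self-copying sequence (template == copy) with uniform intermediate
#' decay, a free strand completes a copy with probability
#' `q = prod(k_i / (k_i + delta))` per attempt and then returns to the free
#' pool, so its expected lifetime output is `q / (1 - q)` new strands.
#' Steady state therefore requires `prod(1 + delta / k_i) = 2`. When the
#' per-step rates are equal (`k_i = k`), this pins `k` to
#' `kappa = delta / (2^(1/L) - 1)` and the stage-cascade ratio
#' `k / (k + delta)` to exactly `2^(-1/L)`, independent of the rate values.
#' @keywords internal
pinned_monomer_level <- function(L, params) {
  delta <- params$intermediate_decay[1L]
  kappa <- delta / (2^(1 / L) - 1)
  kappa / params$elongation  # named per-monomer steady concentrations
}

#' Cascade weights of sequence positions
#'
#' During replication, earlier intermediates are present in larger
#' concentrations than intermediates closer to the final step, so monomers
#' incorporated early (the head) are consumed in larger fluxes than monomers
#' incorporated late (the tail). The weight of position `i` is the
#' steady-state elongation flux through that position relative to position
#' 1: each step multiplies the flux by `k / (k + delta)`, the ratio of
#' elongation flux to elongation-plus-decay flux.
#'
#' With `monomer_conc` given, the weights are evaluated at that monomer
#' level (`k = elongation * monomer_conc`); in the zero-decay limit all
#' weights are equal. By default the weights are evaluated at the
#' steady-state monomer level pinned by the growth-balance condition, where
#' the per-step ratio is exactly `2^(-1/L)` whatever the rates are.
#'
#' @param L sequence length.
#' @param params a [rate_parameters()] with uniform intermediate decay and
#'   identical elongation constants.
#' @param monomer_conc optional common monomer concentration at which to
#'   evaluate the weights; `NULL` uses the growth-pinned steady level.
#' @return Numeric vector of `L` strictly positive, strictly decreasing
#'   weights with `w[1] = 1`.
#' @examples
#' cascade_weights(4, rate_parameters(binary_alphabet()))
#' @export
cascade_weights <- function(L, params, monomer_conc = NULL) {
  check_analytic_regime(params, need_binary = FALSE)
  L <- as.integer(L)
  if (L < 2L) stop("sequences must have length at least 2")
  if (is.null(monomer_conc)) {
    rho <- 2^(-1 / L)
  } else {
    cs <- unique(params$elongation)
    if (length(cs) != 1L)
      stop("weights at a given monomer level require identical elongation constants")
    k <- cs * monomer_conc
    rho <- k / (k + params$intermediate_decay[1L])
  }
  rho^(seq_len(L) - 1L)
}

#' Weighted-composition statistic of a sequence
#'
#' The signed scalar that decides coexistence in the homologous two-monomer
#' uniform-decay regime. Each position contributes its cascade weight with
#' sign +1 for the first alphabet symbol (A) and -1 for the second (B);
#' unequal elongation constants or monomer supply tilt the comparison
#' through a rate ratio, giving
#' `statistic = alpha_A - rate_ratio * alpha_B`, where `alpha_X` is the
#' power sum of the cascade weights over the positions holding monomer X
#' and `rate_ratio = g_A / g_B` is the ratio of the monomer supply surpluses
#' `g_X = (influx_X - decay_X * pinned_level_X) / kappa` at the pinned
#' steady state (the ratio is 1 when the two elongation constants and the
#' two monomer supplies are identical). A sequence with a positive statistic
#' behaves as A-limited, one with a negative statistic as B-limited.
#'
#' @param seq character scalar over the two-monomer alphabet.
#' @param params a [rate_parameters()] in the analytic regime (uniform
#'   intermediate decay, two monomers).
#' @return An object of class `weighted_composition` with `weights`,
#'   `alpha` (per-monomer power sums), `rate_ratio` and `statistic`.
#' @examples
#' sequence_statistic("AABB", rate_parameters(binary_alphabet()))$statistic
#' @export
sequence_statistic <- function(seq, params) {
  check_analytic_regime(params)
  alphabet <- params$alphabet
  ch <- check_sequence(seq, alphabet)
  L <- length(ch)
  w <- cascade_weights(L, params)
  alpha <- vapply(alphabet$symbols, function(s) sum(w[ch == s]), numeric(1L))
  delta <- params$intermediate_decay[1L]
  kappa <- delta / (2^(1 / L) - 1)
  level <- kappa / params$elongation
  g <- (params$monomer_influx - params$monomer_decay * level) / kappa
  if (any(g <= 0))
    stop("monomer influx cannot counter degradation at the pinned steady state")
  r <- g[[1L]] / g[[2L]]
  structure(
    list(weights = w, alpha = alpha, rate_ratio = unname(r),
         statistic = unname(alpha[[1L]] - r * alpha[[2L]])),
    class = "weighted_composition"
  )
}

#' @export
print.weighted_composition <- function(x, ...) {
  cat("Weighted composition: statistic", signif(x$statistic, 6),
      "(rate ratio", signif(x$rate_ratio, 6), ")\n")
  cat("  alpha:", paste(names(x$alpha), signif(x$alpha, 5),
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Closed-form concentration of the last replication intermediate
#'
#' Given steady-state monomer concentrations, the stage cascade gives every
#' intermediate concentration relative to the free strand, and the total
#' monomer balance (influx surplus equals total incorporation flux) sets the
#' absolute scale. Returns the concentration of the last intermediate (the
#' complex one elongation step short of completion).
#'
#' @param seq character scalar over the alphabet of `params`.
#' @param params a [rate_parameters()] with uniform intermediate decay.
#' @param monomer_concs named numeric vector of steady-state monomer
#'   concentrations.
#' @return Positive concentration of the stage `L-1` intermediate.
#' @export
last_intermediate_concentration <- function(seq, params, monomer_concs) {
  check_analytic_regime(params, need_binary = FALSE)
  alphabet <- params$alphabet
  ch <- check_sequence(seq, alphabet)
  monomer_concs <- monomer_concs[alphabet$symbols]
  if (anyNA(monomer_concs) || any(monomer_concs <= 0))
    stop("'monomer_concs' must be positive and cover every symbol")
  delta <- params$intermediate_decay[1L]
  k <- unname(params$elongation[ch] * monomer_concs[ch])
  # u_i = flux through position i per unit free strand
  u <- numeric(length(ch))
  u[1L] <- k[1L]
  for (i in seq_along(ch)[-1L])
    u[i] <- u[i - 1L] * k[i] / (k[i] + delta)
  surplus <- sum(params$monomer_influx - params$monomer_decay * monomer_concs)
  if (surplus <= 0)
    stop("monomer influx does not exceed decay at these concentrations")
  x0 <- surplus / sum(u)
  x_last <- x0 * u[length(u)] / k[length(k)]
  unname(x_last)
}

#' Single-resident steady state in the analytic regime
#'
#' Solves the steady state of one self-copying sequence alone on the two
#' monomer pools: monomer concentrations on the sequence's growth-balance
#' curve `n_A log(1 + delta/(c_A a)) + n_B log(1 + delta/(c_B b)) = log 2`,
#' located where the two per-monomer balance equations yield the same free
#' strand concentration.
#'
#' @inheritParams sequence_statistic
#' @return List with `mono` (named steady concentrations), `x0` (free strand
#'   concentration) and `viable` (`FALSE` if the sequence cannot persist
#'   alone under these rates).
#' @export
resident_equilibrium <- function(seq, params) {
  check_analytic_regime(params)
  alphabet <- params$alphabet
  ch <- check_sequence(seq, alphabet)
  L <- length(ch)
  syms <- alphabet$symbols
  n <- seq_composition(seq, alphabet)
  cc <- params$elongation; FF <- params$monomer_influx
  dd <- params$monomer_decay; delta <- params$intermediate_decay[1L]

  consumption <- function(mono) {
    # per-unit-free-strand flux through each position, split by monomer
    k <- unname(cc[ch] * mono[ch])
    u <- numeric(L); u[1L] <- k[1L]
    for (i in seq_len(L)[-1L]) u[i] <- u[i - 1L] * k[i] / (k[i] + delta)
    vapply(syms, function(s) sum(u[ch == s]), numeric(1L))
  }

  if (n[[2L]] == 0L || n[[1L]] == 0L) {
    # homopolymer: growth balance pins its own monomer, the other is unused
    used <- if (n[[2L]] == 0L) 1L else 2L
    other <- 3L - used
    a <- delta / (cc[[used]] * (2^(1 / L) - 1))
    mono <- numeric(2L); names(mono) <- syms
    mono[used] <- a
    mono[other] <- FF[[other]] / dd[[other]]
    if (FF[[used]] <= dd[[used]] * a)
      return(list(mono = mono, x0 = 0, viable = FALSE))
    u <- consumption(mono)
    x0 <- (FF[[used]] - dd[[used]] * a) / u[[used]]
    return(list(mono = mono, x0 = unname(x0), viable = TRUE))
  }

  # b on the growth-balance curve as a function of a
  b_of_a <- function(a) {
    target <- (log(2) - n[[1L]] * log1p(delta / (cc[[1L]] * a))) / n[[2L]]
    if (target <= 0) return(NA_real_)
    delta / (cc[[2L]] * (expm1(target)))
  }
  a_min <- delta / (cc[[1L]] * (2^(1 / n[[1L]]) - 1))  # b -> Inf here
  a_sup <- FF[[1L]] / dd[[1L]]                          # influx exhausted
  if (a_sup <= a_min * (1 + 1e-12))
    return(list(mono = stats::setNames(c(NA, NA), syms), x0 = 0,
                viable = FALSE))
  gap <- function(a) {
    b <- b_of_a(a)
    if (!is.finite(b) || b <= 0) return(NA_real_)
    mono <- stats::setNames(c(a, b), syms)
    u <- consumption(mono)
    x0A <- (FF[[1L]] - dd[[1L]] * a) / u[[1L]]
    x0B <- (FF[[2L]] - dd[[2L]] * b) / u[[2L]]
    x0A - x0B
  }
  lo <- a_min * (1 + 1e-9); hi <- a_sup * (1 - 1e-9)
  glo <- gap(lo); ghi <- gap(hi)
  # near a_min, b is huge so the B-balance may be violated (x0B < 0)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
    # scan for a sign change; the balance gap is continuous on the curve
    grid <- exp(seq(log(lo), log(hi), length.out = 200L))
    vals <- vapply(grid, gap, numeric(1L))
    ok <- which(is.finite(vals))
    sw <- ok[which(diff(sign(vals[ok])) != 0)]
    if (!length(sw))
      return(list(mono = stats::setNames(c(NA, NA), syms), x0 = 0,
                  viable = FALSE))
    lo <- grid[sw[1L]]; hi <- grid[sw[1L] + 1L]
  }
  root <- stats::uniroot(gap, c(lo, hi), tol = 1e-14)$root
  b <- b_of_a(root)
  mono <- stats::setNames(c(root, b), syms)
  u <- consumption(mono)
  x0 <- (FF[[1L]] - dd[[1L]] * root) / u[[1L]]
  list(mono = mono, x0 = unname(x0), viable = x0 > 0)
}

#' Can a sequence invade a resident's steady state?
#'
#' A rare self-copying invader grows if and only if its expected lifetime
#' output exceeds one strand, i.e. `prod(1 + delta/k_i) < 2` at the
#' resident's monomer concentrations -- a purely compositional condition.
#'
#' @param invader character scalar.
#' @param resident_eq result of [resident_equilibrium()].
#' @inheritParams sequence_statistic
#' @return Logical scalar.
#' @export
can_invade <- function(invader, resident_eq, params) {
  check_analytic_regime(params)
  ch <- check_sequence(invader, params$alphabet)
  delta <- params$intermediate_decay[1L]
  k <- unname(params$elongation[ch] * resident_eq$mono[ch])
  sum(log1p(delta / k)) < log(2)
}

#' Closed-form coexistence criterion for two sequences
#'
#' In the homologous two-monomer uniform-decay regime the verdict follows
#' from the weighted-composition statistics: compositionally identical
#' sequences share a growth-balance curve and coexist only neutrally (a line
#' of fixed points, destroyed by any perturbation of the degradation rates);
#' otherwise the sequences coexist exactly when their statistics have
#' opposite signs (different effective limiting resources); with statistics
#' of the same sign one sequence excludes the other. The winner of exclusion
#' is determined by mutual invasibility of the single-resident steady
#' states; if neither resident can be invaded the outcome depends on initial
#' conditions and the winner is reported as `NA`.
#'
#' @param seq1,seq2 character scalars of equal length over the two-monomer
#'   alphabet.
#' @inheritParams sequence_statistic
#' @return An object of class `coexistence_verdict` with `verdict`
#'   (`"coexist"`, `"exclude"` or `"neutral_structurally_unstable"`),
#'   `winner` (1, 2 or `NA`), and `statistics` of both sequences.
#' @examples
#' p <- rate_parameters(binary_alphabet())
#' coexistence_criterion("AAAA", "BBBB", p)$verdict
#' coexistence_criterion("ABBA", "BABA", p)$verdict
#' @export
coexistence_criterion <- function(seq1, seq2, params) {
  check_analytic_regime(params)
  if (nchar(seq1) != nchar(seq2))
    stop("the two sequences must have equal length")
  s1 <- sequence_statistic(seq1, params)
  s2 <- sequence_statistic(seq2, params)
  stats2 <- c(s1$statistic, s2$statistic)
  if (compositionally_identical(seq1, seq2, params$alphabet)) {
    verdict <- "neutral_structurally_unstable"; winner <- NA_integer_
  } else if (sign(stats2[1L]) != sign(stats2[2L]) && all(stats2 != 0)) {
    verdict <- "coexist"; winner <- NA_integer_
  } else {
    verdict <- "exclude"
    eq1 <- resident_equilibrium(seq1, params)
    eq2 <- resident_equilibrium(seq2, params)
    inv21 <- eq1$viable && can_invade(seq2, eq1, params)
    inv12 <- eq2$viable && can_invade(seq1, eq2, params)
    winner <- if (!eq1$viable && !eq2$viable) NA_integer_
      else if (!eq1$viable) 2L
      else if (!eq2$viable) 1L
      else if (!inv21 && inv12) 1L
      else if (!inv12 && inv21) 2L
      else NA_integer_  # bistable or mutually invasible
  }
  structure(
    list(verdict = verdict, winner = winner, statistics = stats2,
         sequences = c(seq1, seq2)),
    class = "coexistence_verdict"
  )
}

#' @export
print.coexistence_verdict <- function(x, ...) {
  cat(x$sequences[1L], "vs", x$sequences[2L], "->", x$verdict)
  if (!is.na(x$winner)) cat(" (winner: sequence", x$winner, ")")
  cat("\n  statistics:", paste(signif(x$statistics, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Minimal homogeneous head block conferring effective A-majority
#'
#' The smallest `h` such that a sequence beginning with `h` A's followed by
#' B's has a positive (A-side) statistic -- and hence coexists with any
#' sequence of explicit B-majority -- regardless of its own overall
#' composition. Because the cascade ratio at the pinned steady state is
#' `2^(-1/L)`, with identical elongation constants the threshold is the
#' smallest integer exceeding `L * log2(4/3)`.
#'
#' @param L sequence length.
#' @inheritParams sequence_statistic
#' @return Integer head-block size `h`.
#' @examples
#' head_block_threshold(10, rate_parameters(binary_alphabet()))
#' @export
head_block_threshold <- function(L, params) {
  check_analytic_regime(params)
  A <- params$alphabet$symbols[1L]; B <- params$alphabet$symbols[2L]
  for (h in seq_len(L)) {
    seq <- paste0(strrep(A, h), strrep(B, L - h))
    if (sequence_statistic(seq, params)$statistic > 0) return(h)
  }
  stop("no head block of length <= L yields an A-side statistic")
}

#' Asymptotic head-block fraction
#'
#' The head-block threshold grows linearly with `L`; this returns the
#' empirical slope `h(L)/L` at a large length, the constant appearing in the
#' homogeneous-head coexistence rule (`log2(4/3)` = 0.41504 for identical
#' elongation constants).
#'
#' @inheritParams sequence_statistic
#' @param L_ref large reference length at which to evaluate the slope.
#' @return Numeric scalar in (0, 1).
#' @export
head_block_constant <- function(params, L_ref = 1000L) {
  # the slope depends only on the cascade-weight geometry, not on the decay
  # rate; rescale the (uniform) decay so the pinned monomer level stays
  # below the influx ceiling even at the large reference length
  ceiling_level <- min(params$elongation * params$monomer_influx /
                         params$monomer_decay)
  params$intermediate_decay <- 0.1 * ceiling_level * (2^(1 / L_ref) - 1)
  head_block_threshold(L_ref, params) / L_ref
}

#' Upper bound on structurally stable coexistence
#'
#' Gause's principle for template replicators: template and copy are
#' stoichiometrically coupled and count as one species, so at a stable fixed
#' point there cannot be more coexisting sequence pairs than monomer types.
#' The corresponding strand count is `m` when template and copy are
#' identical (homologous pairing with parallel polarity) and `2 m`
#' otherwise.
#'
#' @param m number of monomer types (>= 2).
#' @param scheme optional [pairing_scheme()] used to report the strand
#'   count.
#' @return List with `max_pairs` and (when `scheme` is given)
#'   `max_strands`.
#' @examples
#' gause_bound(4, pairing_scheme("complementary", "antiparallel"))
#' @export
gause_bound <- function(m, scheme = NULL) {
  m <- as.integer(m)
  if (m < 2L) stop("'m' must be at least 2")
  out <- list(max_pairs = m)
  if (!is.null(scheme)) {
    self_paired_scheme <- scheme$pairing == "homologous" &&
      scheme$polarity == "parallel"
    out$max_strands <- if (self_paired_scheme) m else 2L * m
  }
  out
}
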