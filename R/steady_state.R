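#' Integrate a replicator system to steady state
#'
#' Stiff implicit integration (lsoda, via \pkg{deSolve}'s compiled-code
#' interface) over geometrically growing checkpoint windows until the system
#' converges, every pair is extinct, or `t_max` is reached. At each
#' checkpoint a pair whose intermediate concentrations have all fallen below
#' `eps_ext` is flagged extinct and its variables are clamped to zero while
#' integration of the rest continues (the layout stays fixed, which keeps
#' Jacobian bookkeeping simple and is dynamically equivalent since every
#' term of a clamped block is proportional to its own concentrations).
#'
#' Convergence requires both a window test and a pointwise test: the maximum
#' absolute concentration change per unit model time across the checkpoint
#' window must fall below `eps_conv`, and the instantaneous relative rate
#' `|rhs| / max(conc, eps_ext)` must fall below `eps_conv_rel` for every
#' variable. The second test prevents a slowly excluding competitor (small
#' negative eigenvalue) from being mistaken for coexistence while its
#' concentration is still drifting towards zero.
#'
#' @param system a [replicator_system()].
#' @param init initial state; defaults to [initial_state()].
#' @param eps_conv absolute convergence threshold (concentration per unit
#'   model time) for the checkpoint-window test.
#' @param eps_conv_rel relative convergence threshold for the instantaneous
#'   derivative test.
#' @param eps_ext extinction threshold: a pair is extinct when all of its
#'   intermediates are below this concentration.
#' @param t_max integration horizon in model-time units; reaching it without
#'   convergence yields an unconverged result, never an error.
#' @param t_first first checkpoint time.
#' @param rtol,atol solver tolerances passed to [deSolve::lsoda()].
#' @return An object of class `steady_state` with elements `final_state`
#'   (named, non-negative), `converged`, `per_pair_status`
#'   (`"persist"`/`"extinct"` per pair), `time_elapsed` and `system`.
#' @examples
#' alpha <- binary_alphabet()
#' sys <- replicator_system(c("AAA", "BBB"),
#'                          pairing_scheme("homologous", "parallel"),
#'                          alpha, rate_parameters(alpha))
#' ss <- steady_state(sys)
#' ss$per_pair_status
#' @export
steady_state <- function(system, init = initial_state(system),
                         eps_conv = 1e-9, eps_conv_rel = 1e-6,
                         eps_ext = 1e-8, t_max = 1e7, t_first = 10,
                         rtol = 1e-8, atol = 1e-12) {
  stopifnot(eps_conv > 0, eps_conv_rel > 0, eps_ext > 0, t_max > 0)
  y <- check_state(system, init)
  extinct <- rep(FALSE, system$n_pairs)
  pair_idx <- lapply(seq_len(system$n_pairs), pair_var_index, system = system)

  # lsoda's work-limit notices are printed straight to stdout by the
  # compiled core; divert them (early returns are handled below)
  null_con <- file(nullfile(), open = "w")
  sink(null_con)
  on.exit({ sink(); close(null_con) }, add = TRUE)

  t_now <- 0
  t_next <- t_first
  converged <- FALSE
  repeat {
    t_next <- min(t_next, t_max)
    sol <- suppressWarnings(deSolve::lsoda(
      y = y, times = c(t_now, t_next), func = "rx_deriv",
      parms = system$parms, dllname = "replicoex", initfunc = "rx_init",
      rtol = rtol, atol = atol, maxsteps = 100000
    ))
    if (anyNA(sol[nrow(sol), ]))
      stop("stiff integrator failed at model time ", t_now)
    # lsoda may return early (work limit); accept the state it reached
    t_reached <- sol[nrow(sol), 1L]
    if (t_reached <= t_now)
      stop("stiff integrator made no progress at model time ", t_now)
    t_next <- t_reached
    y_new <- pmax(sol[nrow(sol), -1L], 0)

    newly <- which(!extinct & vapply(
      pair_idx, function(ix) max(y_new[ix]) < eps_ext, logical(1L)))
    if (length(newly)) {
      extinct[newly] <- TRUE
      for (p in newly) y_new[pair_idx[[p]]] <- 0
    }

    window_rate <- max(abs(y_new - y)) / (t_next - t_now)
    rhs_now <- .Call(rx_rhs, system$parms, y_new)
    rel_rate <- max(abs(rhs_now) / pmax(y_new, eps_ext))
    y <- y_new
    t_now <- t_next
    if (!length(newly) && window_rate < eps_conv && rel_rate < eps_conv_rel) {
      converged <- TRUE
      break
    }
    if (t_now >= t_max) break
    t_next <- t_now * 2
  }

  structure(
    list(final_state = stats::setNames(y, system$var_names),
         converged = converged,
         per_pair_status = ifelse(extinct, "extinct", "persist"),
         time_elapsed = t_now,
         system = system),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Steady-state run:",
      if (x$converged) "converged" else "NOT converged",
      "at model time", format(x$time_elapsed, scientific = TRUE), "\n")
  for (p in seq_along(x$per_pair_status))
    cat(sprintf("  pair %d (%s): %s\n", p, x$system$pairs$plus[p],
                x$per_pair_status[p]))
  invisible(x)
}

#' Classify the outcome of a steady-state run
#'
#' Coexistence requires a converged run in which every pair persists; any
#' extinct pair yields exclusion; an unconverged run is reported as such and
#' must be excluded from coexistence fractions.
#'
#' @param result a [steady_state()] result.
#' @return A list with `outcome` (`"coexistence"`, `"exclusion"` or
#'   `"unconverged"`) and `extinct` (integer indices of extinct pairs).
#' @export
classify_coexistence <- function(result) {
  stopifnot(inherits(result, "steady_state"))
  extinct <- which(result$per_pair_status == "extinct")
  outcome <- if (length(extinct)) "exclusion"
    else if (!result$converged) "unconverged"
    else "coexistence"
  list(outcome = outcome, extinct = extinct)
}

#' Leading eigenvalue and local stability classification
#'
#' The leading eigenvalue is the largest real part over the spectrum of the
#' Jacobian at a fixed point. Classification: stable if it is below
#' `-tol_neutral`, neutral if its magnitude is at most `tol_neutral`
#' (compositionally identical competitors under uniform degradation sit on a
#' line of fixed points with an exactly zero eigenvalue), unstable
#' otherwise. The default tolerance separates that exact zero from the small
#' negative leading eigenvalues of long sequences.
#'
#' @param J square numeric matrix (a Jacobian), or a [steady_state()] result
#'   whose Jacobian is then computed at its final state.
#' @param tol_neutral half-width of the neutral band around zero.
#' @return An object of class `stability_result` with `leading_eigenvalue`
#'   and `classification`.
#' @examples
#' leading_eigenvalue(diag(c(-1, -2)))
#' @export
leading_eigenvalue <- function(J, tol_neutral = 1e-6) {
  if (inherits(J, "steady_state"))
    J <- system_jacobian(J$system, J$final_state, at_steady_state = TRUE)
  if (!is.matrix(J) || nrow(J) != ncol(J))
    stop("'J' must be a square matrix")
  ev <- eigen(J, only.values = TRUE)$values
  lead <- max(Re(ev))
  classification <- if (lead < -tol_neutral) "stable"
    else if (abs(lead) <= tol_neutral) "neutral"
    else "unstable"
  structure(list(leading_eigenvalue = lead, classification = classification),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Leading eigenvalue:", signif(x$leading_eigenvalue, 6),
      "->", x$classification, "\n")
  invisible(x)
}

#' Simulate one competition experiment
#'
#' High-level wrapper: compiles the sequences into a system, integrates to
#' steady state, classifies the outcome and (for coexistence) assesses local
#' stability from the Jacobian's leading eigenvalue.
#'
#' @inheritParams replicator_system
#' @param ... passed on to [steady_state()].
#' @return An object of class `competition_run` bundling the system, the
#'   steady-state result, the outcome classification and, when all pairs
#'   coexist, the `stability_result`.
#' @examples
#' run <- simulate_competition(c("AAAA", "BBBB"),
#'                             pairing_scheme("homologous", "parallel"),
#'                             binary_alphabet(),
#'                             rate_parameters(binary_alphabet()))
#' run
#' @export
simulate_competition <- function(sequences, scheme, alphabet, params, ...) {
  system <- replicator_system(sequences, scheme, alphabet, params)
  ss <- steady_state(system, ...)
  cls <- classify_coexistence(ss)
  stab <- if (cls$outcome == "coexistence") leading_eigenvalue(ss) else NULL
  structure(
    list(system = system, steady_state = ss, outcome = cls$outcome,
         extinct = cls$extinct, stability = stab),
    class = "competition_run"
  )
}

#' @export
print.competition_run <- function(x, digits = 4, ...) {
  print(x$system)
  cat("Outcome:", x$outcome)
  if (length(x$extinct))
    cat(" (extinct pair(s):", paste(x$extinct, collapse = ", "), ")")
  cat("\n")
  if (!is.null(x$stability))
    cat("Leading eigenvalue:", signif(x$stability$leading_eigenvalue, digits),
        "->", x$stability$classification, "\n")
  cat("Final free-strand and monomer concentrations:\n")
  st <- x$steady_state$final_state
  show <- st[grepl("\\.r0$|^mono\\.", names(st))]
  print(signif(show, digits))
  invisible(x)
}

#' @export
summary.competition_run <- function(object, ...) {
  cat("Sequences:", paste(object$system$pairs$plus, collapse = ", "), "\n")
  print(object$steady_state)
  cat("Outcome:", object$outcome, "\n")
  if (!is.null(object$stability)) print(object$stability)
  invisible(object)
}
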