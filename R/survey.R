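#' Configuration of a sequence-space coexistence scan
#'
#' @param scheme a [pairing_scheme()].
#' @param alphabet a [monomer_alphabet()].
#' @param L sequence length.
#' @param n_pairs number of competing sequence pairs per scanned group.
#' @param sample_size `NULL` to scan the full combined sequence space
#'   exhaustively, or the number of groups to draw uniformly at random (with
#'   replacement; duplicates are logged in the result).
#' @param replicates number of random degradation-rate sets per group (1 for
#'   fixed-parameter protocols).
#' @param dist a [rate_distribution()] that supplies the rates: elongation,
#'   influx and monomer decay are drawn once per scan, intermediate decay
#'   once per scan for fixed-parameter protocols or freshly per replicate
#'   for randomized-degradation protocols.
#' @param seed integer seed; together with the configuration it fully
#'   determines the scan.
#' @param space_cap refuse combined spaces larger than this in exhaustive
#'   mode.
#' @param steady_args list of overrides passed to [steady_state()].
#' @return An object of class `survey_config`.
#' @export
survey_config <- function(scheme, alphabet, L, n_pairs = 2L,
                          sample_size = NULL, replicates = 1L,
                          dist = rate_distribution(), seed = 1L,
                          space_cap = 1e6, steady_args = list()) {
  stopifnot(replicates >= 1L, n_pairs >= 1L)
  structure(
    list(scheme = scheme, alphabet = alphabet, L = as.integer(L),
         n_pairs = as.integer(n_pairs),
         sample_size = if (is.null(sample_size)) NULL else as.integer(sample_size),
         replicates = as.integer(replicates), dist = dist,
         seed = as.integer(seed), space_cap = space_cap,
         steady_args = steady_args),
    class = "survey_config"
  )
}

#' @keywords internal
survey_cells <- function(config) {
  space <- sequence_space(config$L, config$alphabet, cap = config$space_cap)
  n_space <- length(space)
  N <- config$n_pairs
  if (is.null(config$sample_size)) {
    if (n_space^N > config$space_cap)
      stop("combined space of size ", n_space, "^", N,
           " exceeds the cap; give 'sample_size'")
    idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(n_space)), N)))
    idx <- idx[, rev(seq_len(N)), drop = FALSE]  # first sequence varies slowest
  } else {
    idx <- matrix(sample.int(n_space, config$sample_size * N, replace = TRUE),
                  ncol = N)
  }
  colnames(idx) <- paste0("seq", seq_len(N))
  list(space = space, idx = idx)
}

#' @keywords internal
run_survey_engine <- function(config, randomize_decay) {
  set.seed(config$seed)
  cells <- survey_cells(config)
  space <- cells$space; idx <- cells$idx
  n_cells <- nrow(idx)
  N <- config$n_pairs
  n_intermediates <- 2L * N * config$L

  base_params <- sample_parameters(config$dist, config$alphabet,
                                   n_intermediates = n_intermediates)
  run_one <- function(seqs, params) {
    sys <- replicator_system(seqs, config$scheme, config$alphabet, params)
    ss <- do.call(steady_state, c(list(system = sys), config$steady_args))
    cls <- classify_coexistence(ss)
    lead <- NA_real_
    if (cls$outcome == "coexistence")
      lead <- leading_eigenvalue(ss)$leading_eigenvalue
    list(outcome = cls$outcome, leading = lead)
  }
  redraw_decay <- function(params) {
    fam <- config$dist$intermediate_decay
    params$intermediate_decay <-
      if (fam$width == 0) rep(fam$mean, n_intermediates)
      else stats::runif(n_intermediates, fam$mean * (1 - fam$width),
                        fam$mean * (1 + fam$width))
    params
  }

  per_cell <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    seqs <- space[idx[i, ]]
    if (config$replicates == 1L && !randomize_decay) {
      per_cell[[i]] <- run_one(seqs, base_params)
    } else {
      reps <- replicate(config$replicates, {
        run_one(seqs, redraw_decay(base_params))
      }, simplify = FALSE)
      outs <- vapply(reps, `[[`, character(1L), "outcome")
      leads <- vapply(reps, `[[`, numeric(1L), "leading")
      conv <- outs != "unconverged"
      per_cell[[i]] <- list(
        outcome = NA_character_,
        n_converged = sum(conv),
        n_coexist = sum(outs == "coexistence"),
        coex_prob = if (any(conv)) mean(outs[conv] == "coexistence") else NA_real_,
        leading = if (any(outs == "coexistence"))
          mean(leads[outs == "coexistence"]) else NA_real_
      )
    }
  }

  cells_df <- as.data.frame(matrix(space[idx], ncol = N,
                                   dimnames = list(NULL, colnames(idx))),
                            stringsAsFactors = FALSE)
  if (config$replicates == 1L && !randomize_decay) {
    cells_df$outcome <- vapply(per_cell, `[[`, character(1L), "outcome")
    cells_df$leading_eigenvalue <- vapply(per_cell, `[[`, numeric(1L), "leading")
    converged <- cells_df$outcome != "unconverged"
    fraction <- mean(cells_df$outcome[converged] == "coexistence")
    n_coex <- sum(cells_df$outcome == "coexistence")
    n_unconv <- sum(!converged)
    n_runs <- n_cells
  } else {
    cells_df$n_converged <- vapply(per_cell, `[[`, numeric(1L), "n_converged")
    cells_df$n_coexist <- vapply(per_cell, `[[`, numeric(1L), "n_coexist")
    cells_df$coex_prob <- vapply(per_cell, `[[`, numeric(1L), "coex_prob")
    cells_df$leading_eigenvalue <- vapply(per_cell, `[[`, numeric(1L), "leading")
    fraction <- sum(cells_df$n_coexist) / sum(cells_df$n_converged)
    n_coex <- sum(cells_df$n_coexist)
    n_unconv <- n_cells * config$replicates - sum(cells_df$n_converged)
    n_runs <- n_cells * config$replicates
  }

  dup <- sum(duplicated(apply(idx, 1L, paste, collapse = " ")))
  structure(
    list(config = config, params = base_params, cells = cells_df,
         fraction_coexisting = fraction,
         mean_leading_eigenvalue =
           mean(cells_df$leading_eigenvalue, na.rm = TRUE),
         n_scanned = n_cells, n_runs = n_runs, n_coexisting = n_coex,
         n_unconverged = n_unconv, n_duplicate_cells = dup),
    class = "replicator_survey"
  )
}

#' @export
print.replicator_survey <- function(x, ...) {
  cat("Coexistence scan:", x$n_scanned, "group(s) of", x$config$n_pairs,
      "pair(s), L =", x$config$L, "\n")
  cat("  scheme:", x$config$scheme$pairing, "/", x$config$scheme$polarity,
      "; alphabet size", x$config$alphabet$size, "; seed", x$config$seed, "\n")
  cat(sprintf("  fraction coexisting: %.1f%% (%d of %d runs; %d unconverged)\n",
              100 * x$fraction_coexisting, x$n_coexisting, x$n_runs,
              x$n_unconverged))
  if (is.finite(x$mean_leading_eigenvalue))
    cat("  mean leading eigenvalue over coexisting cells:",
        signif(x$mean_leading_eigenvalue, 4), "\n")
  invisible(x)
}

#' Scan protocols over combined sequence spaces
#'
#' The four scan protocols over combined sequence spaces. `run_m1` scans
#' groups of `n_pairs` complementary sequence pairs with one fixed parameter
#' set and reports the fraction of coexisting groups plus the mean leading
#' eigenvalue over coexisting groups; `run_m2` repeats each scanned group
#' under `replicates` freshly drawn random degradation-rate sets and reports
#' the mean coexistence fraction. `run_m3` and `run_m4` are the homologous
#' two-monomer counterparts, scanning ordered pairs of self-copying
#' sequences. The distinction is enforced only through the configuration
#' preconditions; the engine is shared.
#'
#' @param config a [survey_config()].
#' @return A `replicator_survey` object; see [survey_config()].
#' @seealso [survey_config()], [coexistence_matrix()]
#' @export
run_m1 <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  if (config$scheme$pairing != "complementary")
    stop("M1 scans complementary sequence pairs")
  config$replicates <- 1L
  run_survey_engine(config, randomize_decay = FALSE)
}

#' @rdname run_m1
#' @export
run_m2 <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  if (config$scheme$pairing != "complementary")
    stop("M2 scans complementary sequence pairs")
  run_survey_engine(config, randomize_decay = TRUE)
}

#' @rdname run_m1
#' @export
run_m3 <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  if (config$scheme$pairing != "homologous" || config$alphabet$size != 2L)
    stop("M3 scans pairs of homologous two-monomer sequences")
  if (config$n_pairs != 2L) stop("M3 scans ordered pairs (n_pairs = 2)")
  config$replicates <- 1L
  run_survey_engine(config, randomize_decay = FALSE)
}

#' @rdname run_m1
#' @export
run_m4 <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  if (config$scheme$pairing != "homologous" || config$alphabet$size != 2L)
    stop("M4 scans pairs of homologous two-monomer sequences")
  if (config$n_pairs != 2L) stop("M4 scans ordered pairs (n_pairs = 2)")
  run_survey_engine(config, randomize_decay = TRUE)
}

#' Pairwise coexistence matrix over an ordered sequence space
#'
#' Builds the square matrix whose cell (i, j) records the outcome of
#' competition between sequences i and j of the ordered space. Two engines
#' are available: the `analytic` engine applies the closed-form
#' [coexistence_criterion()] (homologous two-monomer uniform-decay regime)
#' and yields a tri-state map (coexist / neutral on compositionally
#' identical cells / none); the `ode` engine integrates every cell to steady
#' state and records the outcome, the leading eigenvalue where there is
#' coexistence, and -- with `replicates > 1` -- the per-cell coexistence
#' probability over random degradation-rate sets.
#'
#' @param config a [survey_config()] with `n_pairs = 2`.
#' @param engine `"analytic"` or `"ode"`.
#' @param order axis ordering of the sequence space.
#' @return An object of class `coexistence_matrix` with the axis sequences
#'   and an `outcome` character matrix, plus (ode engine) an `eigenvalue`
#'   matrix and (replicated) a `probability` matrix.
#' @export
coexistence_matrix <- function(config,
                               engine = c("analytic", "ode"),
                               order = c("lexicographic", "hamming_then_lex")) {
  engine <- match.arg(engine)
  order <- match.arg(order)
  stopifnot(inherits(config, "survey_config"), config$n_pairs == 2L)
  seqs <- sequence_space(config$L, config$alphabet, order = order,
                         cap = config$space_cap)
  n <- length(seqs)
  outcome <- matrix(NA_character_, n, n, dimnames = list(seqs, seqs))
  eigmat <- matrix(NA_real_, n, n, dimnames = list(seqs, seqs))
  probmat <- NULL

  if (engine == "analytic") {
    set.seed(config$seed)
    params <- sample_parameters(config$dist, config$alphabet,
                                n_intermediates = 1L)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      v <- coexistence_criterion(seqs[i], seqs[j], params)
      outcome[i, j] <- switch(v$verdict,
        coexist = "coexist",
        neutral_structurally_unstable = "neutral",
        exclude = if (is.na(v$winner)) "exclude"
          else if (v$winner == 1L) "exclude_second" else "exclude_first")
    }
  } else {
    survey <- run_survey_engine_matrix(config, seqs)
    outcome <- survey$outcome
    eigmat <- survey$eigenvalue
    probmat <- survey$probability
  }
  structure(
    list(sequences = seqs, engine = engine, order = order, config = config,
         outcome = outcome, eigenvalue = eigmat, probability = probmat),
    class = "coexistence_matrix"
  )
}

#' @keywords internal
run_survey_engine_matrix <- function(config, seqs) {
  set.seed(config$seed)
  n <- length(seqs)
  n_intermediates <- 4L * config$L
  params <- sample_parameters(config$dist, config$alphabet,
                              n_intermediates = n_intermediates)
  outcome <- matrix(NA_character_, n, n, dimnames = list(seqs, seqs))
  eig <- matrix(NA_real_, n, n, dimnames = list(seqs, seqs))
  prob <- if (config$replicates > 1L)
    matrix(NA_real_, n, n, dimnames = list(seqs, seqs)) else NULL
  fam <- config$dist$intermediate_decay
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (config$replicates == 1L) {
      sys <- replicator_system(c(seqs[i], seqs[j]), config$scheme,
                               config$alphabet, params)
      ss <- do.call(steady_state, c(list(system = sys), config$steady_args))
      cls <- classify_coexistence(ss)
      outcome[i, j] <- switch(cls$outcome,
        coexistence = "coexist",
        unconverged = "unconverged",
        exclusion = if (identical(cls$extinct, 1L)) "exclude_first"
          else if (identical(cls$extinct, 2L)) "exclude_second" else "exclude")
      if (cls$outcome == "coexistence")
        eig[i, j] <- leading_eigenvalue(ss)$leading_eigenvalue
    } else {
      outs <- character(config$replicates)
      for (r in seq_len(config$replicates)) {
        params$intermediate_decay <-
          if (fam$width == 0) rep(fam$mean, n_intermediates)
          else stats::runif(n_intermediates, fam$mean * (1 - fam$width),
                            fam$mean * (1 + fam$width))
        sys <- replicator_system(c(seqs[i], seqs[j]), config$scheme,
                                 config$alphabet, params)
        ss <- do.call(steady_state, c(list(system = sys), config$steady_args))
        outs[r] <- classify_coexistence(ss)$outcome
      }
      conv <- outs != "unconverged"
      prob[i, j] <- if (any(conv)) mean(outs[conv] == "coexistence") else NA_real_
      outcome[i, j] <- if (isTRUE(prob[i, j] > 0.5)) "coexist" else "exclude"
    }
  }
  list(outcome = outcome, eigenvalue = eig, probability = prob)
}

#' @export
print.coexistence_matrix <- function(x, ...) {
  n <- length(x$sequences)
  cat("Coexistence matrix:", n, "x", n, "cells (", x$engine, "engine,",
      x$order, "ordering )\n")
  tab <- table(x$outcome)
  cat("  outcomes:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Heatmap of a coexistence matrix
#'
#' For outcome matrices, a tri-state map (green = coexist, grey = neutral /
#' compositionally identical, pink = exclusion, white = unconverged). For
#' the ode engine a split plot is drawn: outcomes in the lower-left
#' triangle, leading eigenvalues (or coexistence probabilities when
#' replicated) in the upper-right triangle.
#'
#' @param x a [coexistence_matrix()].
#' @param main plot title.
#' @param ... ignored.
#' @export
plot.coexistence_matrix <- function(x, main = NULL, ...) {
  n <- length(x$sequences)
  code <- matrix(0L, n, n)
  code[x$outcome == "coexist"] <- 1L
  code[x$outcome == "neutral"] <- 2L
  code[x$outcome %in% c("exclude", "exclude_first", "exclude_second")] <- 3L
  upper <- upper.tri(code)
  if (x$engine == "ode" && !is.null(x$probability)) {
    z <- x$probability
  } else if (x$engine == "ode") {
    z <- x$eigenvalue
  } else z <- NULL
  graphics::image(seq_len(n), seq_len(n), t(code[n:1, , drop = FALSE]),
                  col = c("white", "#2e9e4f", "grey70", "#f4a6c0"),
                  zlim = c(0, 3), axes = FALSE, xlab = "sequence 2",
                  ylab = "sequence 1",
                  main = main %||% "pairwise coexistence")
  graphics::box()
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Constructive search for a locally stable multi-pair coexisting set
#'
#' Searches for the largest set of `n_pairs` sequence pairs that coexist at
#' a locally asymptotically stable fixed point (strictly negative leading
#' Jacobian eigenvalue). Candidate groups are composition-partitioned: the
#' template strand of pair `i` is drawn with its symbol probabilities biased
#' towards monomer `i` (probability `bias`, remainder spread evenly), so
#' that each pair leans on a different limiting resource. For every
#' candidate group a fresh degradation-rate set is drawn from `dist`, the
#' system is integrated to steady state, and a group is *verified* only if
#' every pair persists, the run converged, and the leading eigenvalue at the
#' fixed point is below the stability tolerance.
#'
#' @param scheme a [pairing_scheme()].
#' @param alphabet a [monomer_alphabet()]; `n_pairs` must not exceed its
#'   size (one bias direction per monomer type).
#' @param L sequence length.
#' @param n_pairs number of sequence pairs per candidate group.
#' @param n_trials maximum number of candidate groups to test.
#' @param bias probability mass on the focal monomer when drawing a
#'   template strand (must exceed the uniform share).
#' @param dist a [rate_distribution()] used to draw one degradation-rate
#'   set per candidate.
#' @param seed integer seed; the search is fully reproducible.
#' @param stop_at_strands stop early once a verified set with at least this
#'   many distinct strands is found (`NULL` to always run all trials).
#' @param ... passed on to [steady_state()].
#' @return An object of class `stable_set_search` with `best` (the verified
#'   group with the most distinct strands: sequences, strand count, leading
#'   eigenvalue, the drawn rate set it is stable under, trial index) or
#'   `NULL` if none verified, `n_verified`, `n_trials_run` and the search
#'   settings.
#' @examples
#' res <- find_stable_set(pairing_scheme("complementary", "antiparallel"),
#'                        rna_alphabet(), L = 4, n_pairs = 2,
#'                        n_trials = 20, seed = 1)
#' res
#' @export
find_stable_set <- function(scheme, alphabet, L, n_pairs,
                            n_trials = 400, bias = 0.7,
                            dist = rate_distribution(), seed = 1,
                            stop_at_strands = 2L * n_pairs, ...) {
  stopifnot(n_pairs >= 1, n_pairs <= alphabet$size,
            bias > 1 / alphabet$size, bias <= 1, n_trials >= 1)
  m <- alphabet$size
  best <- NULL
  n_verified <- 0L
  trial <- 0L
  withr::with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      seqs <- vapply(seq_len(n_pairs), function(i) {
        pr <- rep((1 - bias) / (m - 1), m)
        pr[i] <- bias
        paste(sample(alphabet$symbols, L, replace = TRUE, prob = pr),
              collapse = "")
      }, character(1L))
      params <- sample_parameters(dist, alphabet,
                                  n_intermediates = 2L * n_pairs * L)
      run <- simulate_competition(seqs, scheme, alphabet, params, ...)
      if (run$outcome == "coexistence" && !is.null(run$stability) &&
          run$stability$classification == "stable") {
        n_verified <- n_verified + 1L
        strands <- unique(c(run$system$pairs$plus, run$system$pairs$minus))
        if (is.null(best) || length(strands) > best$n_strands) {
          best <- list(sequences = seqs, n_strands = length(strands),
                       leading_eigenvalue =
                         run$stability$leading_eigenvalue,
                       params = params, trial = trial)
        }
        if (!is.null(stop_at_strands) && best$n_strands >= stop_at_strands)
          break
      }
    }
  })
  structure(
    list(best = best, n_verified = n_verified, n_trials_run = trial,
         scheme = scheme, alphabet = alphabet, L = L, n_pairs = n_pairs,
         bias = bias, seed = seed),
    class = "stable_set_search"
  )
}

#' @export
print.stable_set_search <- function(x, ...) {
  cat("Stable-set search:", x$n_pairs, "pair(s), L =", x$L, ",",
      x$n_trials_run, "trial(s), seed", x$seed, "\n")
  if (is.null(x$best)) {
    cat("  no locally stable all-pairs coexistence verified\n")
  } else {
    cat("  best verified set (trial", x$best$trial, "):",
        paste(x$best$sequences, collapse = " "), "\n")
    cat("  distinct strands:", x$best$n_strands,
        "; leading eigenvalue:", signif(x$best$leading_eigenvalue, 4), "\n")
  }
  invisible(x)
}
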