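bin <- binary_alphabet()
rna <- rna_alphabet()
hp <- pairing_scheme("homologous", "parallel")
ca <- pairing_scheme("complementary", "antiparallel")

# Newton iteration with finite-difference Jacobian: an integration-free
# oracle for algebraic steady states of small systems.
newton_root <- function(f, x0, tol = 1e-13, maxit = 200) {
  x <- x0
  n <- length(x)
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) return(x)
    J <- matrix(0, n, n)
    h <- pmax(1e-8, 1e-8 * abs(x))
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- x[j] + h[j]
      J[, j] <- (f(xp) - fx) / h[j]
    }
    step <- solve(J, fx)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      if (all(xn > 0) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- pmax(xn, 1e-300)
  }
  stop("Newton oracle did not converge")
}

test_that("single-pair steady state matches the root-finding oracle", {
  params <- rate_parameters(bin)
  sys <- replicator_system("AB", hp, bin, params)  # 4 variables
  ss <- steady_state(sys)
  expect_true(ss$converged)
  # start the oracle away from the integrator's answer (and from the trivial
  # extinction root); Newton must land on the same nontrivial fixed point
  root <- newton_root(function(x) unname(system_rhs(sys, x)),
                      unname(ss$final_state) * c(1.5, 0.6, 1.4, 0.7))
  expect_equal(unname(ss$final_state), root, tolerance = 1e-8)

  # and a non-self-paired complementary pair, non-uniform decay
  params4 <- sample_parameters(
    rate_distribution(intermediate_decay_width = 0.3),
    rna, n_intermediates = 8, seed = 21)
  sys4 <- replicator_system("GGAU", ca, rna, params4)
  ss4 <- steady_state(sys4)
  expect_true(ss4$converged)
  root4 <- newton_root(function(x) unname(system_rhs(sys4, x)),
                       pmax(unname(ss4$final_state), 1e-6))
  expect_equal(unname(ss4$final_state), root4, tolerance = 1e-8)
})

test_that("different limiting resources let two sequences coexist", {
  run <- simulate_competition(c("AAAA", "BBBB"), hp, bin,
                              rate_parameters(bin))
  expect_identical(run$outcome, "coexistence")
  expect_identical(run$stability$classification, "stable")
  expect_lt(run$stability$leading_eigenvalue, 0)
})

test_that("exclusion flags the extinct pairs and keeps state non-negative", {
  # same limiting resource, different lengths of head start: homopolymer A
  # against an A-majority sequence -> one of them must go extinct
  params <- rate_parameters(bin)
  run <- simulate_competition(c("AAAA", "AAAB"), hp, bin, params)
  expect_identical(run$outcome, "exclusion")
  expect_length(run$extinct, 1L)
  expect_true(all(run$steady_state$final_state >= 0))
  cls <- classify_coexistence(run$steady_state)
  expect_identical(cls$outcome, "exclusion")
})

test_that("hitting t_max yields an unconverged result, not an error", {
  params <- rate_parameters(bin)
  sys <- replicator_system(c("AAB", "ABB"), hp, bin, params)
  ss <- steady_state(sys, t_max = 20)
  expect_false(ss$converged)
  expect_identical(classify_coexistence(ss)$outcome, "unconverged")
})

test_that("leading_eigenvalue classifies stable/neutral/unstable", {
  r <- leading_eigenvalue(diag(c(-1, -2)))
  expect_equal(r$leading_eigenvalue, -1)
  expect_identical(r$classification, "stable")
  expect_identical(leading_eigenvalue(diag(c(1e-9, -1)))$classification,
                   "neutral")
  expect_identical(leading_eigenvalue(diag(c(0.1, -1)))$classification,
                   "unstable")
  expect_error(leading_eigenvalue(matrix(1, 2, 3)), "square")
})

test_that("jacobian at a non-steady state is refused when required", {
  params <- rate_parameters(bin)
  sys <- replicator_system("AB", hp, bin, params)
  y <- initial_state(sys)
  expect_error(system_jacobian(sys, y, at_steady_state = TRUE),
               "not a steady state")
  expect_silent(system_jacobian(sys, y))
})

test_that("stable coexistence attracts a 1% perturbed state back", {
  run <- simulate_competition(c("AAAB", "ABBB"), hp, bin,
                              rate_parameters(bin))
  expect_identical(run$outcome, "coexistence")
  expect_identical(run$stability$classification, "stable")
  fixed <- run$steady_state$final_state
  set.seed(2)
  perturbed <- fixed * runif(length(fixed), 0.99, 1.01)
  ss2 <- steady_state(run$system, init = perturbed)
  expect_true(ss2$converged)
  expect_equal(unname(ss2$final_state), unname(fixed), tolerance = 1e-4)
})

test_that("outcome is invariant under pair order and monomer relabeling", {
  params <- rate_parameters(bin)
  r12 <- simulate_competition(c("AAAB", "ABBB"), hp, bin, params)
  r21 <- simulate_competition(c("ABBB", "AAAB"), hp, bin, params)
  expect_identical(r12$outcome, r21$outcome)
  expect_equal(r12$stability$leading_eigenvalue,
               r21$stability$leading_eigenvalue, tolerance = 1e-6)

  swap <- function(s) chartr("AB", "BA", s)
  rsw <- simulate_competition(swap(c("AAAB", "ABBB")), hp, bin, params)
  expect_identical(r12$outcome, rsw$outcome)
  expect_equal(r12$stability$leading_eigenvalue,
               rsw$stability$leading_eigenvalue, tolerance = 1e-6)
})

test_that("qualitative outcomes are threshold-insensitive", {
  params <- rate_parameters(bin)
  for (seqs in list(c("AAAB", "ABBB"), c("AAAA", "AAAB"))) {
    strict <- simulate_competition(seqs, hp, bin, params,
                                   eps_conv = 1e-10, eps_ext = 1e-9)
    loose <- simulate_competition(seqs, hp, bin, params,
                                  eps_conv = 1e-8, eps_ext = 1e-7)
    expect_identical(strict$outcome, loose$outcome)
  }
})

test_that("simulate_competition prints a readable run record", {
  run <- simulate_competition(c("AAAA", "BBBB"), hp, bin,
                              rate_parameters(bin))
  out <- capture.output(print(run))
  expect_true(any(grepl("coexistence", out)))
  expect_true(any(grepl("Leading eigenvalue", out)))
  out2 <- capture.output(summary(run))
  expect_true(any(grepl("Outcome", out2)))
})
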