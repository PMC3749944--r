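bin <- binary_alphabet()
rna <- rna_alphabet()
hp <- pairing_scheme("homologous", "parallel")
ca <- pairing_scheme("complementary", "antiparallel")

# Independent reference implementation of the mass-action right-hand side,
# written directly from the model definition (stage fluxes keyed by the
# inserted monomer, completion releasing template and copy, per-intermediate
# decay, monomer influx/decay/consumption, no recycling).
reference_rhs <- function(sys, y) {
  m <- sys$alphabet$size; S <- sys$n_blocks; L <- sys$L
  elong <- unname(sys$params$elongation)
  infl <- unname(sys$params$monomer_influx)
  mdec <- unname(sys$params$monomer_decay)
  dy <- numeric(length(y))
  mono <- y[S * L + seq_len(m)]
  dmono <- infl - mdec * mono
  for (b in seq_len(S)) {
    base <- (b - 1L) * L
    x <- y[base + seq_len(L)]
    for (r in 0:(L - 1L)) {
      mi <- sys$ins[b, r + 1L] + 1L  # monomer inserted in step r -> r+1
      flux <- elong[mi] * mono[mi] * x[r + 1L]
      dy[base + r + 1L] <- dy[base + r + 1L] - flux
      if (r < L - 1L) {
        dy[base + r + 2L] <- dy[base + r + 2L] + flux
      } else {
        # completion: free template back to its own stage 0, finished copy
        # to the partner's stage 0 (the same block when self-paired)
        dy[base + 1L] <- dy[base + 1L] + flux
        pb <- sys$blocks$partner[b]
        dy[(pb - 1L) * L + 1L] <- dy[(pb - 1L) * L + 1L] + flux
      }
      dmono[mi] <- dmono[mi] - flux
    }
    dy[base + seq_len(L)] <- dy[base + seq_len(L)] - sys$idec[b, ] * x
  }
  dy[S * L + seq_len(m)] <- dmono
  dy
}

test_that("state layout matches the pair/strand/stage arithmetic", {
  p4 <- rate_parameters(rna)
  sys <- replicator_system("GGAU", ca, rna, p4)
  expect_identical(sys$n_vars, 2L * 4L + 4L)  # one non-self-paired pair
  sys <- replicator_system("AABB", hp, bin, rate_parameters(bin))
  expect_identical(sys$n_vars, 4L + 2L)       # self-paired single block
  sys <- replicator_system(c("GGAU", "ACGG", "AAAA", "CCCC", "GAGA"),
                           ca, rna, p4)
  expect_identical(sys$n_vars, 44L)           # 5 pairs * 2L + 4 monomers
  # a reverse palindrome collapses its pair to a single block
  sys <- replicator_system(c("GGAU", "ACGU"), ca, rna, p4)
  expect_identical(sys$n_vars, (2L + 1L) * 4L + 4L)
})

test_that("inserted_monomer returns the pairing image in copy order", {
  expect_identical(inserted_monomer("AB", 0, hp, bin), "A")
  expect_identical(inserted_monomer("GAAU", 0, ca, rna), "C")
  expect_error(inserted_monomer("GAAU", 4, ca, rna), "stage")
  # stoichiometry: inserted monomers over all stages = copy composition
  for (s in c("GGAU", "ACGU", "UUCG")) {
    inserted <- vapply(0:3, inserted_monomer, character(1),
                       template = s, scheme = ca, alphabet = rna)
    expect_identical(
      seq_composition(paste(inserted, collapse = ""), rna),
      seq_composition(copy_strand(s, ca, rna), rna))
  }
})

test_that("compiled rhs agrees with the reference implementation", {
  set.seed(11)
  cases <- list(
    list(seqs = c("AAB", "ABB"), scheme = hp, alpha = bin),       # self-paired
    list(seqs = c("GGAU", "ACGU"), scheme = ca, alpha = rna),     # two-strand
    list(seqs = c("GAUC", "AAAA"), scheme = ca, alpha = rna),     # mixed self
    list(seqs = c("ABBA", "AABB"),
         scheme = pairing_scheme("homologous", "antiparallel"), alpha = bin)
  )
  for (case in cases) {
    params <- sample_parameters(
      rate_distribution(elongation_width = 0.3, influx_width = 0.3,
                        monomer_decay_width = 0.3,
                        intermediate_decay_width = 0.5),
      case$alpha, n_intermediates = 2L * length(case$seqs) * nchar(case$seqs[1]))
    sys <- replicator_system(case$seqs, case$scheme, case$alpha, params)
    for (i in 1:5) {
      y <- runif(sys$n_vars, 0, 2)
      expect_equal(unname(system_rhs(sys, y)), reference_rhs(sys, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("rhs boundary cases: zero state and zero monomers", {
  params <- rate_parameters(bin, monomer_influx = c(A = 2, B = 3))
  sys <- replicator_system(c("AAB", "ABB"), hp, bin, params)
  d0 <- system_rhs(sys, numeric(sys$n_vars))
  expect_equal(unname(d0[1:(sys$n_vars - 2)]), rep(0, sys$n_vars - 2))
  expect_equal(unname(d0[sys$n_vars - 1:0]), c(2, 3))

  # zero monomers, one free strand at c: only decay acts on it
  params <- rate_parameters(bin, intermediate_decay = 0.05)
  sys <- replicator_system("AAB", hp, bin, params)
  y <- numeric(sys$n_vars)
  y[1] <- 0.7
  d <- system_rhs(sys, y)
  expect_equal(unname(d[1]), -0.05 * 0.7)
  expect_equal(unname(d[2:3]), c(0, 0))
  expect_error(system_rhs(sys, y - 1), "non-negative")
})

test_that("with zero influx every trajectory decays to extinction", {
  params <- rate_parameters(bin, monomer_influx = 1e-300)
  sys <- replicator_system(c("AAB", "ABB"), hp, bin, params)
  set.seed(3)
  init <- runif(sys$n_vars, 0.1, 1)
  ss <- steady_state(sys, init = init)
  expect_true(all(ss$final_state < 1e-6))
  expect_identical(unname(ss$per_pair_status), c("extinct", "extinct"))
})

test_that("steady-state monomer balance: influx = decay + incorporation", {
  params <- rate_parameters(bin)
  sys <- replicator_system(c("AAB", "ABB"), hp, bin, params)
  ss <- steady_state(sys)
  expect_true(ss$converged)
  y <- ss$final_state
  mono <- y[c("mono.A", "mono.B")]
  # incorporation flux per monomer from the reference rhs decomposition
  S <- sys$n_blocks; L <- sys$L
  incorporation <- c(A = 0, B = 0)
  for (b in seq_len(S)) {
    x <- y[(b - 1L) * L + seq_len(L)]
    for (r in 0:(L - 1L)) {
      msym <- sys$alphabet$symbols[sys$ins[b, r + 1L] + 1L]
      incorporation[msym] <- incorporation[msym] +
        params$elongation[msym] * mono[paste0("mono.", msym)] * x[r + 1L]
    }
  }
  lhs <- unname(params$monomer_influx)
  rhs <- unname(params$monomer_decay) * unname(mono) + unname(incorporation)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("rhs is invariant under relabeling monomers with their rates", {
  params <- rate_parameters(bin, elongation = c(A = 1.3, B = 0.8),
                            monomer_influx = c(A = 2, B = 1),
                            monomer_decay = c(A = 0.9, B = 1.1),
                            intermediate_decay = 0.02)
  swapped <- rate_parameters(bin, elongation = c(A = 0.8, B = 1.3),
                             monomer_influx = c(A = 1, B = 2),
                             monomer_decay = c(A = 1.1, B = 0.9),
                             intermediate_decay = 0.02)
  relabel <- function(s) chartr("AB", "BA", s)
  seqs <- c("AAB", "ABB")
  sys1 <- replicator_system(seqs, hp, bin, params)
  sys2 <- replicator_system(relabel(seqs), hp, bin, swapped)
  set.seed(5)
  for (i in 1:5) {
    y <- runif(sys1$n_vars, 0, 1)
    # same strand stages; monomer entries swap places
    y2 <- y
    nm <- sys1$n_vars
    y2[(nm - 1):nm] <- y[c(nm, nm - 1)]
    d1 <- unname(system_rhs(sys1, y))
    d2 <- unname(system_rhs(sys2, y2))
    expect_equal(d1[1:(nm - 2)], d2[1:(nm - 2)], tolerance = 1e-12)
    expect_equal(d1[(nm - 1):nm], d2[c(nm, nm - 1)], tolerance = 1e-12)
  }
})

test_that("self-paired doubling equals the explicit two-strand system", {
  # integrate the packaged self-paired system against a hand-written ODE for
  # two identical strands of the same template and compare trajectories
  params <- rate_parameters(bin, intermediate_decay = 0.05)
  sys <- replicator_system("AB", hp, bin, params)  # self-paired, L = 2
  elong <- unname(params$elongation)
  infl <- unname(params$monomer_influx)
  mdec <- unname(params$monomer_decay)
  delta <- 0.05
  two_strand <- function(t, y, p) {
    # y = (x0, x1, x0', x1', a, b): two identical "AB" strand blocks
    a <- y[5]; b <- y[6]
    k1 <- elong[1] * a   # step 0 -> 1 inserts A
    k2 <- elong[2] * b   # completion step inserts B
    J1 <- k2 * y[2]; J2 <- k2 * y[4]
    dx0  <- -k1 * y[1] - delta * y[1] + J1 + J2  # own completion + partner's
    dx1  <-  k1 * y[1] - k2 * y[2] - delta * y[2]
    dx0p <- -k1 * y[3] - delta * y[3] + J2 + J1
    dx1p <-  k1 * y[3] - k2 * y[4] - delta * y[4]
    da <- infl[1] - mdec[1] * a - k1 * (y[1] + y[3])
    db <- infl[2] - mdec[2] * b - k2 * (y[2] + y[4])
    list(c(dx0, dx1, dx0p, dx1p, da, db))
  }
  times <- c(0, 1, 5, 20, 100)
  y_self <- initial_state(sys)                     # strand at 0.1
  y_two <- c(0.05, 0, 0.05, 0, 1, 1)               # split over two strands
  sol_self <- deSolve::lsoda(unname(y_self), times, func = "rx_deriv",
                             parms = sys$parms, dllname = "replicoex",
                             initfunc = "rx_init", rtol = 1e-10, atol = 1e-12)
  sol_two <- deSolve::lsoda(y_two, times, two_strand, parms = NULL,
                            rtol = 1e-10, atol = 1e-12)
  for (i in seq_along(times)) {
    expect_equal(sol_self[i, 2], sol_two[i, 2] + sol_two[i, 4],
                 tolerance = 1e-7)                  # stage-0 pool
    expect_equal(sol_self[i, 3], sol_two[i, 3] + sol_two[i, 5],
                 tolerance = 1e-7)                  # stage-1 pool
    expect_equal(unname(sol_self[i, 4:5]), unname(sol_two[i, 6:7]),
                 tolerance = 1e-7)                  # monomers
  }
})

test_that("analytic Jacobian matches central finite differences", {
  params <- sample_parameters(
    rate_distribution(elongation_width = 0.2, intermediate_decay_width = 0.5),
    rna, n_intermediates = 16L, seed = 9)
  sys <- replicator_system(c("GGAU", "ACGU"), ca, rna, params)
  set.seed(13)
  y <- runif(sys$n_vars, 0.05, 1)
  J <- system_jacobian(sys, y)
  h <- 1e-6
  Jfd <- matrix(0, sys$n_vars, sys$n_vars)
  for (j in seq_len(sys$n_vars)) {
    yp <- y; ym <- y
    yp[j] <- y[j] + h; ym[j] <- y[j] - h
    Jfd[, j] <- (system_rhs(sys, yp) - system_rhs(sys, ym)) / (2 * h)
  }
  expect_equal(unname(J), Jfd, tolerance = 1e-5)
})

test_that("parameter sampling is reproducible and respects the support", {
  dist <- rate_distribution(intermediate_decay_width = 0.1)
  p1 <- sample_parameters(dist, bin, n_intermediates = 100, seed = 42)
  p2 <- sample_parameters(dist, bin, n_intermediates = 100, seed = 42)
  expect_identical(p1, p2)
  # width-0 families collapse to the mean
  expect_equal(unname(p1$elongation), c(1, 1))
  expect_equal(unname(p1$monomer_influx), c(1, 1))
  # narrow distribution stays within +/-10% of the mean
  expect_true(all(p1$intermediate_decay >= 0.009))
  expect_true(all(p1$intermediate_decay <= 0.011))
  expect_gt(length(unique(p1$intermediate_decay)), 1)
  expect_error(rate_distribution(elongation_mean = -1), "positive")
  expect_error(rate_distribution(influx_width = 1), "width")
  expect_error(rate_parameters(bin, elongation = c(A = 0, B = 1)), "positive")
})

test_that("a zero-pair system reduces to the monomer pools", {
  sys <- replicator_system(character(0), hp, bin, rate_parameters(bin))
  expect_identical(sys$n_vars, 2L)
  ss <- steady_state(sys)
  expect_true(ss$converged)
  expect_equal(unname(ss$final_state), c(1, 1))  # influx / decay
  J <- system_jacobian(sys, ss$final_state, at_steady_state = TRUE)
  expect_equal(unname(diag(J)), c(-1, -1))
})
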