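test_that("closed-form 15N frequencies match independent 2x2 diagonalization", {
  nuc <- nucleus("15N")
  nz <- abs(nuc$gamma_MHz_T) * 3316 * 1e-4
  ## study-condition example: Fig-3-style couplings at theta = 45 deg
  fr <- n15_frequencies(hyperfine(2.8, -0.4), pi / 4, nuc, fld3316)
  expected <- oracle_freqs_12(2.8, -0.4, pi / 4, nz)
  expect_equal(c(fr$nu_alpha, fr$nu_beta), expected, tolerance = 1e-12)
  expect_equal(fr$nu_alpha, 0.327, tolerance = 2e-3)
  expect_equal(fr$nu_beta, 2.747, tolerance = 2e-3)

  ## random sweep: closed form vs diagonalization to < 1e-9 MHz
  set.seed(11)
  for (i in 1:100) {
    A <- runif(1, -5, 5); Td <- runif(1, -2, 2); th <- runif(1, 0, pi / 2)
    fr <- n15_frequencies(hyperfine(A, Td), th, nuc, fld3316)
    ex <- oracle_freqs_12(A, Td, th, nz)
    expect_lt(max(abs(c(fr$nu_alpha, fr$nu_beta) - ex)), 1e-9)
    expect_lte(fr$nu_alpha, fr$nu_beta)
    ## depth identity k (nu_a nu_b)^2 = (B nu_nz)^2
    B <- 3 * Td * sin(th) * cos(th)
    expect_equal(fr$k * (fr$nu_alpha * fr$nu_beta)^2, (B * nz)^2,
                 tolerance = 1e-9)
  }
})

test_that("axial limits of the 15N closed forms", {
  nuc <- nucleus("15N")
  nz <- abs(nuc$gamma_MHz_T) * 3316 * 1e-4
  ## theta = 0: B vanishes, frequencies are |nu_nz -+ A_zz/2|, depth 0
  fr0 <- n15_frequencies(hyperfine(2.8, -0.4), 0, nuc, fld3316)
  Azz <- 2.8 + 2 * (-0.4)
  expect_equal(sort(c(abs(nz - Azz / 2), nz + Azz / 2)),
               c(fr0$nu_alpha, fr0$nu_beta), tolerance = 1e-12)
  expect_equal(fr0$k, 0)
  ## isotropic coupling: no theta dependence
  fr1 <- n15_frequencies(hyperfine(2.8, 0), 0.3, nuc, fld3316)
  fr2 <- n15_frequencies(hyperfine(2.8, 0), 1.2, nuc, fld3316)
  expect_equal(fr1, fr2)
  expect_error(n15_frequencies(hyperfine(1), 0, nucleus("14N"), fld3316),
               "I = 1/2")
})

test_that("14N exact-cancellation closed forms and the triplet identity", {
  nuc <- nucleus("14N")
  fr <- n14_cancellation_frequencies(quadrupole(0.4167, 0.6),
                                     hyperfine(1.85), nuc, fld3316)
  expect_equal(fr$nu_0, 0.50004, tolerance = 1e-6)
  expect_equal(fr$nu_minus, 1.00008, tolerance = 1e-6)
  expect_equal(fr$nu_plus, 1.50012, tolerance = 1e-6)
  expect_equal(fr$nu_dq, 4.18, tolerance = 1e-2)
  ## nu_0 + nu_minus = nu_plus exactly for random (K, eta)
  set.seed(5)
  for (i in 1:50) {
    K <- runif(1, 0, 2); eta <- runif(1, 0, 1)
    f <- n14_cancellation_frequencies(quadrupole(K, eta), hyperfine(2),
                                      nuc, fld3316)
    expect_equal(f$nu_0 + f$nu_minus, f$nu_plus, tolerance = 1e-12)
  }
  ## degenerate limits
  f0 <- n14_cancellation_frequencies(quadrupole(0.5, 0), hyperfine(2), nuc, fld3316)
  expect_equal(f0$nu_0, 0)
  expect_equal(f0$nu_minus, f0$nu_plus)
  fK <- n14_cancellation_frequencies(quadrupole(0, 0), hyperfine(2), nuc, fld3316)
  nz <- abs(nuc$gamma_MHz_T) * 3316 * 1e-4
  expect_equal(fK$nu_dq, 2 * (nz + 1))
  expect_error(n14_cancellation_frequencies(quadrupole(1), hyperfine(1),
                                            nucleus("15N"), fld3316), "I = 1")
})

test_that("sublevel Hamiltonians reproduce the closed forms", {
  ## I = 1/2 gaps match n15_frequencies over random orientations
  nuc <- nucleus("15N")
  set.seed(3)
  for (i in 1:20) {
    A <- runif(1, 0, 4); Td <- runif(1, -1, 1); th <- runif(1, 0, pi / 2)
    e <- nucleus_entry(nuc, hyperfine(A, Td))
    H <- sublevel_hamiltonians(e, orientation(th), fld3316)
    gaps <- sort(c(diff(range(eigen(H$H_alpha, symmetric = TRUE)$values)),
                   diff(range(eigen(H$H_beta, symmetric = TRUE)$values))))
    fr <- n15_frequencies(hyperfine(A, Td), th, nuc, fld3316)
    expect_lt(max(abs(gaps - c(fr$nu_alpha, fr$nu_beta))), 1e-9)
  }

  ## I = 1 at the exact-cancellation point: cancelled-manifold gaps are the
  ## pure NQI triplet
  nuc14 <- nucleus("14N")
  nz <- abs(nuc14$gamma_MHz_T) * 3316 * 1e-4
  e <- nucleus_entry(nuc14, hyperfine(2 * nz), quadrupole(0.4167, 0.6))
  H <- sublevel_hamiltonians(e, orientation(0), fld3316)
  spread <- function(M) diff(range(eigen(M, symmetric = TRUE)$values))
  cancelled <- if (spread(H$H_alpha) < spread(H$H_beta)) H$H_alpha else H$H_beta
  ev <- sort(eigen(cancelled, symmetric = TRUE)$values)
  gaps <- c(diff(ev), ev[3] - ev[1])
  fr <- n14_cancellation_frequencies(quadrupole(0.4167, 0.6),
                                     hyperfine(2 * nz), nuc14, fld3316)
  expect_lt(max(abs(sort(gaps) - sort(c(fr$nu_0, fr$nu_minus, fr$nu_plus)))),
            1e-6)

  ## zero couplings: both manifolds are the bare nuclear Zeeman term
  nz15 <- abs(nuc$gamma_MHz_T) * 3316 * 1e-4
  e0 <- nucleus_entry(nuc, hyperfine(0, 0))
  H0 <- sublevel_hamiltonians(e0, orientation(0.7, 0.2), fld3316)
  expect_equal(H0$H_alpha, H0$H_beta, tolerance = 1e-12)
  expect_equal(diff(range(eigen(H0$H_alpha, symmetric = TRUE)$values)), nz15,
               tolerance = 1e-12)
})

test_that("type invariants are enforced", {
  expect_error(nucleus("13C"), "unknown isotope")
  expect_error(nucleus("15N", count = 0), NULL)
  expect_error(quadrupole(-1, 0.5), NULL)
  expect_error(quadrupole(1, 1.5), NULL)
  expect_error(field_conditions(-10), NULL)
  expect_error(nucleus_entry(nucleus("15N"), hyperfine(1), quadrupole(1)),
               "I >= 1")
  ## powder weights sum to one
  g <- powder_grid(50, 4)
  expect_equal(sum(g$weight), 1, tolerance = 1e-12)
})
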