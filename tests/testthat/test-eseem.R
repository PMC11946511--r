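test_that("trivial envelopes: no coupled nuclei or zero couplings give E = 1", {
  o <- orientation(pi / 4)
  tr <- eseem_analytic(spin_system(), tim_short, o, fld3316)
  expect_equal(tr$values, rep(1, 64))
  sys0 <- spin_system(list(nucleus_entry(nucleus("15N"), hyperfine(0, 0))))
  expect_equal(eseem_analytic(sys0, tim_short, o, fld3316)$values, rep(1, 64))
  expect_equal(eseem_matrix(sys0, tim_short, o, fld3316)$values, rep(1, 64),
               tolerance = 1e-12)
})

test_that("analytic, matrix and brute-force engines agree on I = 1/2 systems", {
  set.seed(21)
  for (i in 1:5) {
    sys <- spin_system(list(nucleus_entry(
      nucleus("15N", count = sample(1:2, 1)),
      hyperfine(runif(1, 0.5, 4), runif(1, -1, 0.2)))))
    o <- orientation(runif(1, 0.1, 1.4), runif(1, 0, pi / 2))
    a <- eseem_analytic(sys, tim_short, o, fld3316)$values
    m <- eseem_matrix(sys, tim_short, o, fld3316)$values
    expect_lt(rel_rms(a, m), 1e-8)
  }
  ## brute-force density-matrix oracle, including a two-entry mixed system
  sys <- spin_system(list(
    nucleus_entry(nucleus("15N", count = 2), hyperfine(2.8, -0.4)),
    nucleus_entry(nucleus("15N"), hyperfine(1.1, -0.2))))
  o <- orientation(0.7, 0.3)
  a <- eseem_analytic(sys, tim_short, o, fld3316)$values
  b <- eseem_brute_force(sys, tim_short, o, fld3316)$values
  expect_lt(rel_rms(a, b), 1e-6)
})

test_that("matrix engine matches the brute-force oracle for 14N at cancellation", {
  tim <- pulse_timing_3p(210, 12, 16, 48)
  o <- orientation(0.9, 0.5)
  m <- eseem_matrix(sys_14N(), tim, o, fld3316)$values
  b <- eseem_brute_force(sys_14N(), tim, o, fld3316)$values
  expect_lt(rel_rms(m, b), 1e-6)
})

test_that("envelope is bounded and invariant under nucleus permutation", {
  set.seed(31)
  e1 <- nucleus_entry(nucleus("15N"), hyperfine(2.8, -0.4))
  e2 <- nucleus_entry(nucleus("15N"), hyperfine(1.3, -0.1))
  o <- orientation(0.8, 0.1)
  t12 <- eseem_analytic(spin_system(list(e1, e2)), tim_short, o, fld3316)
  t21 <- eseem_analytic(spin_system(list(e2, e1)), tim_short, o, fld3316)
  expect_identical(t12$values, t21$values)
  for (i in 1:5) {
    sys <- spin_system(list(nucleus_entry(
      nucleus("15N", count = sample(1:3, 1)),
      hyperfine(runif(1, 0, 4), runif(1, -1, 1)))))
    v <- eseem_analytic(sys, tim_short, orientation(runif(1, 0, pi / 2)),
                        fld3316)$values
    expect_true(all(v >= -1e-9 & v <= 1 + 1e-9))
  }
  ## count field is exactly equivalent to repeated identical entries
  sc <- spin_system(list(nucleus_entry(nucleus("15N", count = 2),
                                       hyperfine(2.8, -0.4))))
  sr <- spin_system(list(e1, e1))
  expect_identical(eseem_analytic(sc, tim_short, o, fld3316)$values,
                   eseem_analytic(sr, tim_short, o, fld3316)$values)
})

test_that("tau blind spot suppresses the nu_alpha line", {
  nuc <- nucleus("15N")
  fr <- n15_frequencies(hyperfine(2.8, -0.4), pi / 4, nuc, fld3316)
  h_alpha_at <- function(tau) {
    tim <- pulse_timing_3p(tau, 12, 16, 512)
    tr <- eseem_analytic(sys_15N(1), tim, orientation(pi / 4), fld3316)
    peak_height_at(process_1d(tr, window = "hamming"), fr$nu_alpha,
                   box = 0.1)$height
  }
  tau_bs <- 1000 / fr$nu_beta  # nu_beta * tau = 1 cycle
  expect_lt(h_alpha_at(tau_bs), 0.01 * h_alpha_at(210))
})

test_that("powder averaging: single-point grid, isotropic systems, convergence", {
  ## grid_size 1 evaluates theta = 45 degrees
  p1 <- eseem_powder(sys_15N(1), tim_short, 1, "analytic", fld3316)
  a45 <- eseem_analytic(sys_15N(1), tim_short, orientation(pi / 4), fld3316)
  expect_equal(p1$values, a45$values, tolerance = 1e-12)
  ## isotropic coupling: powder equals single crystal
  sysi <- spin_system(list(nucleus_entry(nucleus("15N"), hyperfine(1.7, 0))))
  pp <- eseem_powder(sysi, tim_short, 50, "analytic", fld3316)
  ss <- eseem_analytic(sysi, tim_short, orientation(0.3), fld3316)
  expect_equal(pp$values, ss$values, tolerance = 1e-10)
  ## doubling the grid changes the trace by < 0.5% RMS at 200+ nodes
  tim <- pulse_timing_3p(210, 12, 16, 128)
  g200 <- eseem_powder(sys_15N(2), tim, 200, "analytic", fld3316)$values
  g400 <- eseem_powder(sys_15N(2), tim, 400, "analytic", fld3316)$values
  expect_lt(rel_rms(g400, g200), 0.005)
})

test_that("powder nu_alpha line lies at its depth-weighted position", {
  tim <- pulse_timing_3p(210, 12, 16, 602)
  sp <- process_1d(eseem_powder(sys_15N(1), tim, 200, "analytic", fld3316))
  pk <- pick_peaks(sp, 0.1)
  expect_equal(pk$nu1[which.max(pk$height)], 0.33, tolerance = 0.1)
})

test_that("two equivalent 15N create a combination line absent for one nucleus", {
  ## single orientation: the line at 2 nu_alpha appears only for count >= 2.
  ## A long record keeps the nearby fundamental's mainlobe out of the
  ## combination band so the comparison reflects line content, not leakage.
  fr <- n15_frequencies(hyperfine(2.8, -0.4), pi / 4, nucleus("15N"), fld3316)
  tim <- pulse_timing_3p(210, 12, 16, 2048)
  sp1 <- process_1d(eseem_analytic(sys_15N(1), tim, orientation(pi / 4),
                                   fld3316), window = "hamming", zerofill = 4096)
  sp2 <- process_1d(eseem_analytic(sys_15N(2), tim, orientation(pi / 4),
                                   fld3316), window = "hamming", zerofill = 4096)
  h1 <- peak_height_at(sp1, 2 * fr$nu_alpha, box = 0.08)$height
  h2 <- peak_height_at(sp2, 2 * fr$nu_alpha, box = 0.08)$height
  expect_gt(h2, 5 * h1)
})

test_that("engine preconditions are enforced", {
  expect_error(eseem_analytic(sys_14N(), tim_short, orientation(0.5), fld3316),
               "eseem_matrix")
  sysBig <- spin_system(rep(list(nucleus_entry(nucleus("14N"), hyperfine(1),
                                               quadrupole(0.4, 0.5))), 4))
  expect_error(eseem_brute_force(sysBig, tim_short, orientation(0.5), fld3316),
               "dimension cap")
})
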