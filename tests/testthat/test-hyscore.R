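tim_hy <- pulse_timing_4p(210, 40, 32, 64, 64)

test_that("engine matches a brute-force 4-pulse density-matrix propagation", {
  tim <- pulse_timing_4p(210, 40, 32, 10, 10)
  o <- orientation(0.7, 0.4)
  for (cnt in 1:2) {
    sys <- sys_15N(cnt)
    b <- brute_hyscore(sys, tim, o, fld3316)
    m <- hyscore_single(sys, tim, o, fld3316)$values
    expect_lt(rel_rms(b, m), 1e-6)
  }
  ## and for a 14N nucleus with quadrupole coupling
  b <- brute_hyscore(sys_14N(), tim, o, fld3316)
  m <- hyscore_single(sys_14N(), tim, o, fld3316)$values
  expect_lt(rel_rms(b, m), 1e-6)
})

test_that("zero couplings give a featureless constant signal", {
  sys0 <- spin_system(list(nucleus_entry(nucleus("15N"), hyperfine(0, 0))))
  tr <- hyscore_single(sys0, tim_hy, orientation(0.5), fld3316)
  expect_lt(diff(range(tr$values)), 1e-10)
})

test_that("processed spectra are symmetric across the diagonal", {
  tr <- hyscore_powder(sys_15N(2), tim_hy, 30, fld3316)
  sp <- process_2d(tr, zerofill = 256)
  expect_lt(max(abs(sp$magnitude - t(sp$magnitude))) / max(sp$magnitude), 1e-6)
})

test_that("a single coupled 15N at tau = 210 ns gives one cross-peak pair", {
  tim <- pulse_timing_4p(210, 40, 32, 256, 256)
  tr <- hyscore_powder(sys_15N(1), tim, 60, fld3316)
  cp <- hyscore_cross_peaks(process_2d(tr), 0.10)
  expect_equal(nrow(cp), 2)  # the peak and its mirror image
  expect_equal(sort(c(cp$nu1[1], cp$nu2[1])), sort(c(cp$nu2[2], cp$nu1[2])))
  expect_equal(min(cp$nu1[1], cp$nu2[1]), 0.33, tolerance = 0.1)
  expect_equal(max(cp$nu1[1], cp$nu2[1]), 2.75, tolerance = 0.15)
})

test_that("cross-peak positions match the closed-form frequencies", {
  ## random single-crystal draws in the weak-to-intermediate coupling
  ## regime (A_iso < 2 nu_nz, where the cross peaks live in the reported
  ## (+,+) quadrant), constrained away from the spectral origin where
  ## mirror-lobe overlap biases magnitude-spectrum positions
  set.seed(42)
  n_ok <- 0
  while (n_ok < 8) {
    A <- runif(1, 1.0, 1.9); Td <- runif(1, -0.6, -0.1); th <- runif(1, 0.4, 1.1)
    fr <- n15_frequencies(hyperfine(A, Td), th, nucleus("15N"), fld3316)
    if (fr$nu_alpha < 0.5 || fr$nu_beta - fr$nu_alpha < 0.5 ||
        fr$k < 0.15 || fr$nu_beta > 7) next
    n_ok <- n_ok + 1
    sys <- spin_system(list(nucleus_entry(nucleus("15N"), hyperfine(A, Td))))
    ## 192 points with Hamming apodization: mainlobe narrow enough that
    ## neither the mirror line nor truncation sidelobes bias the position
    tim <- pulse_timing_4p(210, 40, 32, 192, 192)
    tr <- hyscore_single(sys, tim, orientation(th), fld3316)
    cp <- hyscore_cross_peaks(process_2d(tr, window = "hamming"), 0.2,
                              min_freq_MHz = 0.3)
    expect_gte(nrow(cp), 2)
    expect_lt(abs(min(cp$nu1[1], cp$nu2[1]) - fr$nu_alpha), 0.02)
    expect_lt(abs(max(cp$nu1[1], cp$nu2[1]) - fr$nu_beta), 0.02)
  }
})

test_that("tau blind spots suppress cross peaks and tau-summing removes them", {
  fr <- n15_frequencies(hyperfine(2.8, -0.4), pi / 4, nucleus("15N"), fld3316)
  o <- orientation(pi / 4)
  h_at <- function(tau) {
    tr <- hyscore_single(sys_15N(1), pulse_timing_4p(tau, 40, 32, 128, 128),
                         o, fld3316)
    peak_height_at(process_2d(tr), fr$nu_alpha, fr$nu_beta, box = 0.12)$height
  }
  h210 <- h_at(210)
  h_bs <- h_at(1000 / fr$nu_alpha)  # exact nu_alpha blind spot
  expect_lt(h_bs, 0.01 * h210)
  ## averaging spectra over the paper's tau sweep restores the peak
  sp_sum <- hyscore_tau_sum(sys_15N(1), pulse_timing_4p(210, 40, 32, 64, 64),
                            tau_list_ns = c(1000 / fr$nu_alpha, 210, 150),
                            grid_size = 1, field = fld3316, zerofill = 512)
  h_sum <- peak_height_at(sp_sum, fr$nu_alpha, fr$nu_beta, box = 0.15)$height
  expect_gt(h_sum, 0.1 * max(sp_sum$magnitude))
})

test_that("tau-summing a single tau equals the single-tau spectrum", {
  tim <- pulse_timing_4p(210, 40, 32, 32, 32)
  sp1 <- hyscore_tau_sum(sys_15N(1), tim, 210, grid_size = 10,
                         field = fld3316, zerofill = 256)
  sp2 <- process_2d(hyscore_powder(sys_15N(1), tim, 10, fld3316),
                    zerofill = 256)
  expect_equal(sp1$magnitude, sp2$magnitude, tolerance = 1e-12)
})

test_that("weak couplings collapse onto the diagonal at the Larmor frequency", {
  sysw <- spin_system(list(nucleus_entry(nucleus("15N"),
                                         hyperfine(0.05, -0.01))))
  tr <- hyscore_powder(sysw, pulse_timing_4p(210, 40, 32, 128, 128), 20,
                       fld3316)
  sp <- process_2d(tr)
  ij <- which(sp$magnitude == max(sp$magnitude), arr.ind = TRUE)[1, ]
  nz <- abs(nucleus("15N")$gamma_MHz_T) * 3316 * 1e-4
  expect_equal(sp$f1_MHz[ij[1]], nz, tolerance = 0.05)
  expect_equal(sp$f2_MHz[ij[2]], nz, tolerance = 0.05)
})

test_that("combination cross peaks appear only for strong dipolar coupling", {
  tim <- pulse_timing_4p(210, 40, 32, 128, 128)
  peaks_for <- function(Td, grid = 80) {
    sp <- process_2d(hyscore_powder(sys_15N(2, T_dip = Td), tim, grid, fld3316))
    fr <- n15_frequencies(hyperfine(2.8, Td), pi / 4, nucleus("15N"), fld3316)
    cp <- hyscore_cross_peaks(sp, 0.05)
    list(spec = sp, fr = fr, cp = cp)
  }
  ## T = -0.4: a (2 nu_alpha, nu_beta) cross peak is resolved
  r4 <- peaks_for(-0.4)
  near_comb <- abs(r4$cp$nu1 - 2 * r4$fr$nu_alpha) < 0.15 &
    abs(r4$cp$nu2 - r4$fr$nu_beta) < 0.3
  expect_true(any(near_comb))
  ## T = -0.1: no separate combination peak is resolved
  r1 <- peaks_for(-0.1)
  near_comb1 <- abs(r1$cp$nu1 - 2 * r1$fr$nu_alpha) < 0.15 &
    abs(r1$cp$nu2 - r1$fr$nu_beta) < 0.3
  expect_false(any(near_comb1))
  ## T = -1.2: a third cross peak near (2 nu_alpha, 2 nu_beta) rises above
  ## the 5%-of-maximum contour
  r12 <- peaks_for(-1.2)
  h <- peak_height_at(r12$spec, 2 * r12$fr$nu_alpha, 2 * r12$fr$nu_beta,
                      box = 0.25)$height
  expect_gt(h, 0.05 * max(r12$spec$magnitude))
})
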