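## 4-pulse HYSCORE engine (Mims trace formalism, ideal pulses, echo-pathway
## selection), powder averaging, and tau-summed blind-spot suppression.

#' 4-pulse HYSCORE timing
#'
#' Timing of the sequence pi/2 - tau - pi/2 - t1 - pi - t2 - pi/2 - tau -
#' echo.  Defaults mirror a typical X-band acquisition: tau = 210 ns, t1
#' and t2 from 40 ns in 32 ns steps for 256 points each.
#'
#' @param tau_ns Fixed interpulse delay tau, ns (> 0).
#' @param t_start_ns Initial t1/t2 value, ns (> 0).
#' @param dt_ns t1/t2 increment, ns (> 0).
#' @param n1,n2 Number of points along t1 and t2.
#' @return An object of class `pulse_timing_4p`.
#' @export
pulse_timing_4p <- function(tau_ns = 210, t_start_ns = 40, dt_ns = 32,
                            n1 = 256, n2 = 256) {
  stopifnot(tau_ns > 0, t_start_ns > 0, dt_ns > 0, n1 >= 2, n2 >= 2)
  structure(list(tau_ns = tau_ns, t_start_ns = t_start_ns, dt_ns = dt_ns,
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "pulse_timing_4p")
}

#' 2D echo-envelope time trace
#'
#' @param t1_ns,t2_ns Time axes (ns).
#' @param values Real matrix of echo amplitudes, `length(t1_ns)` rows by
#'   `length(t2_ns)` columns.
#' @param meta List of metadata.
#' @return An object of class `time_trace_2d`.
#' @export
time_trace_2d <- function(t1_ns, t2_ns, values, meta = list()) {
  stopifnot(is.matrix(values), nrow(values) == length(t1_ns),
            ncol(values) == length(t2_ns), all(is.finite(values)))
  structure(list(t1_ns = as.numeric(t1_ns), t2_ns = as.numeric(t2_ns),
                 values = values, meta = meta), class = "time_trace_2d")
}

#' @export
print.time_trace_2d <- function(x, ...) {
  cat(sprintf("2D time trace: %d x %d points\n",
              length(x$t1_ns), length(x$t2_ns)))
  invisible(x)
}

## One coherence-transfer pathway for one nucleus: nuclear coherence evolves
## in manifold `b` (eigenvalues lb) during t1 and in manifold `a` (la)
## during t2, with M the a->b manifold overlap matrix.  Returns the complex
## trace on the (t1, t2) grid, normalized to N at zero coupling.
hyscore_pathway <- function(la, lb, M, tau, t1, t2) {
  N <- length(la)
  pa <- exp(1i * .PH * la * tau)
  pb <- exp(1i * .PH * lb * tau)
  G <- Conj(t(M)) %*% (pa * M)          # G_km = sum_l conj(M_lk) e^{i la_l tau} M_lm
  F <- M %*% (pb * Conj(t(M)))          # F_nj = sum_p M_np e^{i lb_p tau} conj(M_jp)
  ## coefficient tensor over alpha pairs (j,n) x beta pairs (k,m)
  jn <- expand.grid(j = 1:N, n = 1:N)
  km <- expand.grid(k = 1:N, m = 1:N)
  C <- matrix(0i, N * N, N * N)
  for (r in seq_len(N * N)) {
    j <- jn$j[r]; n <- jn$n[r]
    C[r, ] <- M[j, km$k] * Conj(M[n, km$m]) * G[cbind(km$k, km$m)] *
      F[n, j] * exp(-1i * .PH * (la[j] + lb[km$k]) * tau)
  }
  W1 <- exp(-1i * .PH * outer(lb[km$k] - lb[km$m], t1))  # (km) x t1
  W2 <- exp(-1i * .PH * outer(la[jn$j] - la[jn$n], t2))  # (jn) x t2
  t(t(W2) %*% C %*% W1)  # t1 x t2
}

#' Single-orientation 4-pulse HYSCORE envelope
#'
#' 2D stimulated-echo envelope computed from the per-nucleus
#' sub-Hamiltonian eigen-decompositions with ideal pulses and the
#' phase-cycled echo pathway: during t1 the nuclear coherence evolves in
#' one electron manifold and the mixing pi pulse transfers it to the other
#' for t2, correlating the two manifolds' nuclear frequencies as cross
#' peaks.  The fixed tau delays supply the blind-spot amplitude factors
#' that vanish when `nu alpha tau` or `nu beta tau` is an integer.
#' Factors multiply across nuclei (raised to the equivalence count) and
#' the two transfer pathways average.
#'
#' @param system A [spin_system()] with I = 1/2 and/or I = 1 nuclei.
#' @param timing A [pulse_timing_4p()].
#' @param orient An [orientation()].
#' @param field [field_conditions()].
#' @return A [time_trace_2d()].
#' @export
hyscore_single <- function(system, timing, orient, field = field_conditions()) {
  for (e in system$nuclei)
    if (e$nucleus$I > 1 + 1e-12)
      stop("hyscore_single supports I <= 1 nuclei", call. = FALSE)
  t1 <- timing$t_start_ns + timing$dt_ns * (0:(timing$n1 - 1))
  t2 <- timing$t_start_ns + timing$dt_ns * (0:(timing$n2 - 1))
  VA <- matrix(1 + 0i, length(t1), length(t2))
  VB <- matrix(1 + 0i, length(t1), length(t2))
  for (e in system$nuclei) {
    me <- manifold_eigen(e, orient, field)
    TA <- hyscore_pathway(me$la, me$lb, me$M, timing$tau_ns, t1, t2) / me$d
    TB <- hyscore_pathway(me$lb, me$la, Conj(t(me$M)), timing$tau_ns, t1, t2) / me$d
    VA <- VA * TA^e$nucleus$count
    VB <- VB * TB^e$nucleus$count
  }
  time_trace_2d(t1, t2, Re(VA + VB) / 2,
                meta = list(timing = timing, orientation = orient,
                            normalized_first_point = FALSE))
}

#' Powder-averaged HYSCORE
#'
#' @inheritParams hyscore_single
#' @param grid_size Number of theta nodes (default 100 for 2D runs).
#' @param n_phi Number of phi nodes for non-axial systems (automatic when
#'   `NULL`).
#' @return A [time_trace_2d()].
#' @export
hyscore_powder <- function(system, timing, grid_size = 100,
                           field = field_conditions(), n_phi = NULL) {
  axial <- system_is_axial(system)
  if (is.null(n_phi)) n_phi <- if (axial) 1L else 8L
  grid <- powder_grid(grid_size, n_phi)
  t1 <- timing$t_start_ns + timing$dt_ns * (0:(timing$n1 - 1))
  t2 <- timing$t_start_ns + timing$dt_ns * (0:(timing$n2 - 1))
  acc <- matrix(0, length(t1), length(t2))
  for (i in seq_len(nrow(grid))) {
    tr <- hyscore_single(system, timing,
                         orientation(grid$theta[i], grid$phi[i]), field)
    acc <- acc + grid$weight[i] * tr$values
  }
  time_trace_2d(t1, t2, acc,
                meta = list(timing = timing, powder = TRUE,
                            grid_size = grid_size, n_phi = n_phi,
                            normalized_first_point = FALSE))
}

#' Tau-summed HYSCORE spectrum
#'
#' Averages processed magnitude spectra (not time traces) across a list of
#' tau values, the standard strategy for suppressing tau blind spots: no
#' nuclear frequency below Nyquist is simultaneously blind at every tau of
#' a sufficiently fine sweep.
#'
#' @inheritParams hyscore_powder
#' @param tau_list_ns Nonempty vector of tau values, ns.
#' @param grid_size Powder grid size passed to [hyscore_powder()].
#' @param window,zerofill Processing options passed to [to_spectrum()].
#' @param background Background model passed to [subtract_background()].
#' @return A `spectrum_2d` (see [to_spectrum()]) averaged across tau.
#' @export
hyscore_tau_sum <- function(system, timing, tau_list_ns, grid_size = 100,
                            field = field_conditions(), window = "chebyshev",
                            zerofill = 1024, background = "polynomial") {
  stopifnot(length(tau_list_ns) >= 1)
  acc <- NULL
  for (tau in tau_list_ns) {
    tim <- pulse_timing_4p(tau, timing$t_start_ns, timing$dt_ns,
                           timing$n1, timing$n2)
    tr <- hyscore_powder(system, tim, grid_size, field)
    sp <- to_spectrum(subtract_background(normalize_trace(tr),
                                          model = background),
                      window = window, zerofill = zerofill)
    if (is.null(acc)) acc <- sp
    else acc$magnitude <- acc$magnitude + sp$magnitude
  }
  acc$magnitude <- acc$magnitude / length(tau_list_ns)
  acc$provenance$tau_list_ns <- tau_list_ns
  acc
}
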