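## 3-pulse ESEEM engines: analytic manifold product rule (I = 1/2, any
## number of equivalent nuclei), general Mims-trace engine (I = 1/2 and
## I = 1), powder averaging, and a full density-matrix brute-force oracle.

.PH <- 2e-3 * pi  # radians per (MHz * ns)

#' 3-pulse ESEEM timing
#'
#' Timing of the stimulated-echo sequence pi/2 - tau - pi/2 - T - pi/2 -
#' tau - echo.  Defaults mirror a typical X-band acquisition: tau = 210 ns,
#' T from 12 ns in 16 ns steps for 602 points.
#'
#' @param tau_ns Fixed interpulse delay tau, ns (> 0).
#' @param T_start_ns Initial T value, ns.
#' @param dT_ns T increment, ns (> 0).
#' @param n_points Number of T points (>= 2).
#' @return An object of class `pulse_timing_3p`.
#' @export
pulse_timing_3p <- function(tau_ns = 210, T_start_ns = 12, dT_ns = 16,
                            n_points = 602) {
  stopifnot(tau_ns > 0, dT_ns > 0, n_points >= 2)
  structure(list(tau_ns = tau_ns, T_start_ns = T_start_ns, dT_ns = dT_ns,
                 n_points = as.integer(n_points)), class = "pulse_timing_3p")
}

#' 1D echo-envelope time trace
#'
#' @param t_ns Time axis (ns).
#' @param values Echo amplitudes (dimensionless).
#' @param meta List of metadata (timing, system description, flags).
#' @return An object of class `time_trace_1d`.
#' @export
time_trace_1d <- function(t_ns, values, meta = list()) {
  stopifnot(length(t_ns) == length(values), all(is.finite(values)))
  structure(list(t_ns = as.numeric(t_ns), values = as.numeric(values),
                 meta = meta), class = "time_trace_1d")
}

#' @export
print.time_trace_1d <- function(x, ...) {
  cat(sprintf("1D time trace: %d points, t = %g..%g ns\n",
              length(x$t_ns), min(x$t_ns), max(x$t_ns)))
  invisible(x)
}

## Per-nucleus manifold frequencies without the alpha/beta sort: the
## m_S = +1/2 manifold has frequency sqrt((nz - A/2)^2 + (B/2)^2).  Keeping
## the physical manifold identity is what makes the product rule valid for
## nuclei with different couplings.
manifold_freqs_12 <- function(hf, theta, nuc, field) {
  nz <- nuclear_zeeman(nuc, field)
  A <- hf$A_iso + hf$T_dip * (3 * cos(theta)^2 - 1)
  B <- 3 * hf$T_dip * sin(theta) * cos(theta)
  f_p <- sqrt((nz - A / 2)^2 + (B / 2)^2)
  f_m <- sqrt((nz + A / 2)^2 + (B / 2)^2)
  k <- if (f_p * f_m > 0) min((B * nz / (f_p * f_m))^2, 1) else 0
  list(f_plus = f_p, f_minus = f_m, k = k)
}

t_axis_3p <- function(timing) timing$T_start_ns + timing$dT_ns * (0:(timing$n_points - 1))

#' Analytic 3-pulse ESEEM (I = 1/2 product rule)
#'
#' Stimulated-echo envelope from the closed-form manifold product rule,
#' `E = (prod_i E+_i^c_i + prod_i E-_i^c_i) / 2` with
#' `E+ = 1 - (k/2) (1 - cos 2 pi nu- tau)(1 - cos 2 pi nu+ (tau + T))`
#' and the manifold swap for `E-`; the equivalence count `c_i` raises the
#' per-manifold factor to the c-th power.  For `c >= 2` the expanded
#' product contains combination terms oscillating at `2 nu_alpha` (and
#' `2 nu_beta`), the signature of multiple equivalent coupled nuclei.
#'
#' @param system A [spin_system()] whose nuclei are all I = 1/2.
#' @param timing A [pulse_timing_3p()].
#' @param orient An [orientation()] (single crystal orientation).
#' @param field [field_conditions()].
#' @return A [time_trace_1d()].
#' @export
eseem_analytic <- function(system, timing, orient, field = field_conditions()) {
  for (e in system$nuclei)
    if (abs(e$nucleus$I - 0.5) > 1e-12)
      stop("eseem_analytic requires I = 1/2 nuclei only; use eseem_matrix ",
           "for systems containing I = 1", call. = FALSE)
  tt <- t_axis_3p(timing)
  Ep <- rep(1, length(tt)); Em <- rep(1, length(tt))
  for (e in system$nuclei) {
    fr <- manifold_freqs_12(e$hyperfine, orient$theta, e$nucleus, field)
    c_p <- 1 - (fr$k / 2) * (1 - cos(.PH * fr$f_minus * timing$tau_ns)) *
      (1 - cos(.PH * fr$f_plus * (timing$tau_ns + tt)))
    c_m <- 1 - (fr$k / 2) * (1 - cos(.PH * fr$f_plus * timing$tau_ns)) *
      (1 - cos(.PH * fr$f_minus * (timing$tau_ns + tt)))
    Ep <- Ep * c_p^e$nucleus$count
    Em <- Em * c_m^e$nucleus$count
  }
  time_trace_1d(tt, (Ep + Em) / 2,
                meta = list(timing = timing, engine = "analytic",
                            orientation = orient, normalized_first_point = FALSE))
}

## Eigen-decomposition bundle for one nucleus at one orientation.
manifold_eigen <- function(entry, orient, field) {
  H <- sublevel_hamiltonians(entry, orient, field)
  ea <- eigen(H$H_alpha, symmetric = TRUE)
  eb <- eigen(H$H_beta, symmetric = TRUE)
  list(la = ea$values, lb = eb$values,
       M = Conj(t(ea$vectors)) %*% eb$vectors, d = length(ea$values))
}

## Per-manifold Mims factor: E(T) = sum_jl |Q_jl|^2/N cos(w_jl (tau+T)) with
## Q = M diag(exp(-i w_beta tau)) M^dagger and w_jl the alpha-manifold gaps.
mims_factor <- function(l_this, l_other, M, tau, tpt) {
  Q <- M %*% (exp(-1i * .PH * l_other * tau) * Conj(t(M)))
  amp <- as.vector(Mod(Q)^2) / length(l_this)
  frq <- as.vector(outer(l_this, l_this, "-"))
  as.vector(amp %*% cos(.PH * outer(frq, tau + tpt)))
}

#' General 3-pulse ESEEM engine (Mims trace formalism)
#'
#' Computes the stimulated-echo envelope from the eigen-decompositions of
#' the per-nucleus sub-Hamiltonians: with `M = U_alpha' U_beta` the
#' manifold overlap matrix, the alpha-manifold factor is
#' `sum_jl |Q_jl|^2 / N cos(2 pi (l_j - l_l)(tau + T))` where
#' `Q = M diag(e^{-i 2 pi l_beta tau}) M'`; factors multiply across nuclei
#' within each manifold (raised to the equivalence count) and the two
#' manifolds average.  Valid for any mixture of I = 1/2 and I = 1 nuclei
#' and identical to [eseem_analytic()] for pure I = 1/2 systems.
#'
#' @inheritParams eseem_analytic
#' @return A [time_trace_1d()].
#' @export
eseem_matrix <- function(system, timing, orient, field = field_conditions()) {
  for (e in system$nuclei)
    if (e$nucleus$I > 1 + 1e-12)
      stop("eseem_matrix supports I <= 1 nuclei", call. = FALSE)
  tt <- t_axis_3p(timing)
  Ep <- rep(1, length(tt)); Em <- rep(1, length(tt))
  for (e in system$nuclei) {
    me <- manifold_eigen(e, orient, field)
    fa <- mims_factor(me$la, me$lb, me$M, timing$tau_ns, tt)
    fb <- mims_factor(me$lb, me$la, Conj(t(me$M)), timing$tau_ns, tt)
    Ep <- Ep * fa^e$nucleus$count
    Em <- Em * fb^e$nucleus$count
  }
  time_trace_1d(tt, (Ep + Em) / 2,
                meta = list(timing = timing, engine = "matrix",
                            orientation = orient, normalized_first_point = FALSE))
}

#' Powder-averaged 3-pulse ESEEM
#'
#' Weighted average of single-orientation envelopes over a
#' Gauss-Legendre-in-cos(theta) grid (theta-only for axial collinear
#' systems; crossed with a phi grid otherwise).
#'
#' @inheritParams eseem_analytic
#' @param grid_size Number of theta nodes (>= 1); `grid_size = 1` evaluates
#'   the single orientation theta = 45 degrees.
#' @param engine `"analytic"` (I = 1/2 only) or `"matrix"`.
#' @param n_phi Number of phi nodes for non-axial systems; chosen
#'   automatically when `NULL`.
#' @return A [time_trace_1d()].
#' @export
eseem_powder <- function(system, timing, grid_size = 200,
                         engine = c("analytic", "matrix"),
                         field = field_conditions(), n_phi = NULL) {
  engine <- match.arg(engine)
  axial <- system_is_axial(system)
  if (is.null(n_phi)) n_phi <- if (axial) 1L else 12L
  grid <- powder_grid(grid_size, n_phi)
  fun <- if (engine == "analytic") eseem_analytic else eseem_matrix
  tt <- t_axis_3p(timing)
  acc <- rep(0, length(tt))
  for (i in seq_len(nrow(grid))) {
    tr <- fun(system, timing, orientation(grid$theta[i], grid$phi[i]), field)
    acc <- acc + grid$weight[i] * tr$values
  }
  time_trace_1d(tt, acc,
                meta = list(timing = timing, engine = engine, powder = TRUE,
                            grid_size = grid_size, n_phi = n_phi,
                            normalized_first_point = FALSE))
}

## -- brute-force density-matrix oracle -------------------------------------

## Kronecker product over a list (electron first, then nuclei in order).
kron_list <- function(mats) Reduce(kronecker, mats)

## Operator acting on slot `pos` of the product space with dims `dims`.
embed_op <- function(op, pos, dims) {
  mats <- lapply(seq_along(dims), function(j)
    if (j == pos) op else diag(dims[j]) + 0i)
  kron_list(mats)
}

#' Brute-force density-matrix 3-pulse ESEEM oracle
#'
#' Propagates the full electron (x) nuclear density matrix from thermal S_z
#' through three ideal instantaneous pi/2 pulses and free evolution under
#' the rotating-frame Hamiltonian (S_z-conditioned hyperfine, nuclear
#' Zeeman, quadrupole), with a four-step pulse phase cycle and a four-point
#' electron-offset comb that together select the stimulated-echo pathway
#' exactly.  The echo amplitude is normalized against the uncoupled system.
#' Intended as an independent cross-check of the fast engines; the total
#' Hilbert dimension `2 * prod(2 I_i + 1)` must not exceed 64 (equivalence
#' counts expand into explicit copies).
#'
#' @inheritParams eseem_analytic
#' @return A [time_trace_1d()].
#' @export
eseem_brute_force <- function(system, timing, orient,
                              field = field_conditions()) {
  entries <- list()
  for (e in system$nuclei)
    for (i in seq_len(e$nucleus$count))
      entries <- c(entries, list(e))
  dims <- c(2L, vapply(entries, function(e) as.integer(2 * e$nucleus$I + 1),
                       integer(1)))
  D <- prod(dims)
  if (D > 64) stop("Hilbert dimension cap (64) exceeded", call. = FALSE)

  es <- spin_ops(0.5)
  Sx <- embed_op(es$x, 1, dims); Sy <- embed_op(es$y, 1, dims)
  Sz <- embed_op(es$z, 1, dims)
  Sp <- Sx + 1i * Sy
  n <- c(sin(orient$theta) * cos(orient$phi),
         sin(orient$theta) * sin(orient$phi), cos(orient$theta))

  build_H <- function(zero_couplings) {
    H <- matrix(0i, D, D)
    for (j in seq_along(entries)) {
      e <- entries[[j]]
      ops <- spin_ops(e$nucleus$I)
      Ix <- embed_op(ops$x, j + 1, dims); Iy <- embed_op(ops$y, j + 1, dims)
      Iz <- embed_op(ops$z, j + 1, dims)
      nz <- nuclear_zeeman(e$nucleus, field)
      H <- H - nz * (n[1] * Ix + n[2] * Iy + n[3] * Iz)
      if (!zero_couplings) {
        a <- as.numeric(n %*% hyperfine_tensor(e$hyperfine))
        ## S_z-conditioned hyperfine (secular in the electron spin)
        H <- H + (a[1] * Ix + a[2] * Iy + a[3] * Iz) %*% Sz
        q <- e$quadrupole
        if (!is.null(q) && q$K > 0) {
          R <- euler_rotation(q$euler)
          Iq <- lapply(1:3, function(m)
            R[1, m] * Ix + R[2, m] * Iy + R[3, m] * Iz)
          H <- H + q$K * (3 * Iq[[3]] %*% Iq[[3]] -
                            e$nucleus$I * (e$nucleus$I + 1) * diag(D) +
                            q$eta * (Iq[[1]] %*% Iq[[1]] - Iq[[2]] %*% Iq[[2]]))
        }
      }
    }
    H
  }

  pulse <- function(angle, phase) {
    G <- angle * (Sx * cos(phase) + Sy * sin(phase))
    eg <- eigen(G, symmetric = TRUE)
    eg$vectors %*% (exp(-1i * eg$values) * Conj(t(eg$vectors)))
  }

  tau <- timing$tau_ns
  tt <- t_axis_3p(timing)
  offsets <- (0:3) / (8e-3 * tau)  # MHz; e^{+-2 i dw tau} sums to zero
  Px <- pulse(pi / 2, 0); Pmx <- pulse(pi / 2, pi)
  run <- function(H_nuc) {
    sig <- rep(0i, length(tt))
    for (off in offsets) {
      H <- H_nuc + off * Sz
      eg <- eigen(H, symmetric = TRUE)
      V <- eg$vectors; lam <- eg$values
      Ut <- V %*% (exp(-1i * .PH * lam * tau) * Conj(t(V)))
      K <- Conj(t(Px)) %*% Conj(t(Ut)) %*% Sp %*% Ut %*% Px
      Kp <- Conj(t(V)) %*% K %*% V
      frq <- as.vector(outer(lam, lam, function(a, b) b - a))
      phmat <- exp(1i * .PH * outer(frq, tt))
      for (i1 in 1:2) for (i2 in 1:2) {
        rec <- if (i1 == i2) 1 else -1
        P1 <- if (i1 == 1) Px else Pmx
        P2 <- if (i2 == 1) Px else Pmx
        rho2 <- P2 %*% Ut %*% P1 %*% Sz %*% Conj(t(P1)) %*% Conj(t(Ut)) %*% Conj(t(P2))
        r2 <- Conj(t(V)) %*% rho2 %*% V
        cf <- as.vector(r2 * t(Kp))
        sig <- sig + rec * as.vector(cf %*% phmat)
      }
    }
    sig
  }
  s <- run(build_H(FALSE))
  s0 <- run(build_H(TRUE))  # uncoupled reference, constant in T
  time_trace_1d(tt, Re(s / s0),
                meta = list(timing = timing, engine = "brute_force",
                            orientation = orient,
                            normalized_first_point = FALSE))
}
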