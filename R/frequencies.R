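## Nuclear spin matrices and analytic transition frequencies.

## Spin operators for arbitrary spin I: list(x =, y =, z =), dim 2I+1.
spin_ops <- function(I) {
  d <- as.integer(round(2 * I + 1))
  m <- seq(I, -I, by = -1)
  Iz <- diag(m)
  Ip <- matrix(0, d, d)
  for (j in seq_len(d - 1)) {
    ## I+ |I, m[j+1]> = sqrt(I(I+1) - m(m+1)) |I, m[j]>
    mm <- m[j + 1]
    Ip[j, j + 1] <- sqrt(I * (I + 1) - mm * (mm + 1))
  }
  Im <- t(Ip)
  list(x = (Ip + Im) / 2, y = (Ip - Im) / (2i), z = Iz + 0i, d = d)
}

## ZYZ Euler rotation matrix (active rotation of the principal frame).
euler_rotation <- function(euler) {
  a <- euler[1]; b <- euler[2]; g <- euler[3]
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

## Hyperfine tensor (3x3, molecular frame) from axial principal values.
hyperfine_tensor <- function(hf) {
  Apv <- diag(c(hf$A_iso - hf$T_dip, hf$A_iso - hf$T_dip, hf$A_iso + 2 * hf$T_dip))
  if (all(hf$euler == 0)) return(Apv)
  R <- euler_rotation(hf$euler)
  R %*% Apv %*% t(R)
}

#' Orientation of the static field in the molecular frame
#'
#' @param theta,phi Polar and azimuthal angles, radians.
#' @param weight Powder weight (dimensionless).
#' @return An object of class `orientation`.
#' @export
orientation <- function(theta, phi = 0, weight = 1) {
  stopifnot(all(is.finite(c(theta, phi, weight))))
  structure(list(theta = theta, phi = phi, weight = weight),
            class = "orientation")
}

#' Powder orientation grid
#'
#' Gauss-Legendre nodes in cos(theta) on `[0, 1]` (the upper hemisphere
#' suffices for the inversion-symmetric tensors handled here), optionally
#' crossed with a uniform phi grid on `[0, pi/2]` for systems that are not
#' axially symmetric about the molecular z axis (nonzero quadrupole
#' asymmetry or tilted tensor frames).  Weights sum to one.
#'
#' @param n_theta Number of theta nodes (>= 1).
#' @param n_phi Number of phi nodes (1 for axial systems).
#' @return A data frame with columns `theta`, `phi`, `weight`.
#' @export
powder_grid <- function(n_theta = 200, n_phi = 1) {
  stopifnot(n_theta >= 1, n_phi >= 1)
  if (n_theta == 1) {
    ct <- list(x = cos(pi / 4), w = 1)  # single representative orientation
  } else {
    ct <- pracma::gaussLegendre(n_theta, 0, 1)
  }
  theta <- acos(ct$x)
  wt <- ct$w / sum(ct$w)
  phi <- (seq_len(n_phi) - 0.5) * (pi / 2) / n_phi
  g <- expand.grid(theta = theta, phi = phi)
  g$weight <- rep(wt, times = n_phi) / n_phi
  g
}

## TRUE when every tensor is axial about molecular z -> theta-only powder.
system_is_axial <- function(system) {
  for (e in system$nuclei) {
    if (any(e$hyperfine$euler != 0)) return(FALSE)
    q <- e$quadrupole
    if (!is.null(q) && q$K > 0 && (q$eta > 0 || any(q$euler != 0))) return(FALSE)
  }
  TRUE
}

#' Analytic I = 1/2 nuclear transition frequencies
#'
#' Closed-form ESEEM frequencies for an I = 1/2 nucleus with an axial
#' hyperfine tensor: with `A = A_iso + T (3 cos^2 theta - 1)` and
#' `B = 3 T sin theta cos theta`, the two manifold frequencies are
#' `nu = sqrt((nu_nz -/+ A/2)^2 + (B/2)^2)`, reported sorted so that
#' `nu_alpha < nu_beta`.  The modulation depth is
#' `k = (B nu_nz / (nu_alpha nu_beta))^2`.
#'
#' @param hf A [hyperfine()] coupling (axial; Euler angles ignored here,
#'   `theta` is measured from the hyperfine symmetry axis).
#' @param theta Angle between the field and the hyperfine axis, radians.
#' @param nuc A [nucleus()] with I = 1/2.
#' @param field [field_conditions()].
#' @return A list with `nu_alpha`, `nu_beta` (MHz) and depth `k`.
#' @examples
#' n15_frequencies(hyperfine(2.8, -0.4), pi / 4, nucleus("15N"),
#'                 field_conditions(3316))
#' @export
n15_frequencies <- function(hf, theta, nuc, field) {
  if (abs(nuc$I - 0.5) > 1e-12)
    stop("n15_frequencies supports I = 1/2 nuclei only", call. = FALSE)
  nz <- nuclear_zeeman(nuc, field)
  A <- hf$A_iso + hf$T_dip * (3 * cos(theta)^2 - 1)
  B <- 3 * hf$T_dip * sin(theta) * cos(theta)
  nus <- sort(c(sqrt((nz - A / 2)^2 + (B / 2)^2),
                sqrt((nz + A / 2)^2 + (B / 2)^2)))
  k <- if (nus[1] * nus[2] > 0) (B * nz / (nus[1] * nus[2]))^2 else 0
  list(nu_alpha = nus[1], nu_beta = nus[2], k = min(k, 1))
}

#' 14N exact-cancellation frequencies
#'
#' Closed-form frequencies for an I = 1 nucleus at (or near) the exact
#' cancellation condition `A_iso ~ 2 nu_nz`: the cancelled manifold shows
#' the pure nuclear-quadrupole triplet `nu_0 = 2 K eta`,
#' `nu_minus = K (3 - eta)`, `nu_plus = K (3 + eta)` (so
#' `nu_0 + nu_minus = nu_plus` exactly), and the other manifold shows the
#' double-quantum line
#' `nu_dq = 2 sqrt((nu_nz + A_iso/2)^2 + K^2 (3 + eta^2))`.
#'
#' @param q A [quadrupole()] coupling.
#' @param hf A [hyperfine()] coupling.
#' @param nuc A [nucleus()] with I = 1.
#' @param field [field_conditions()].
#' @return A list with `nu_0`, `nu_minus`, `nu_plus`, `nu_dq` in MHz.
#' @export
n14_cancellation_frequencies <- function(q, hf, nuc, field) {
  if (abs(nuc$I - 1) > 1e-12)
    stop("n14_cancellation_frequencies supports I = 1 nuclei only", call. = FALSE)
  nz <- nuclear_zeeman(nuc, field)
  list(nu_0 = 2 * q$K * q$eta,
       nu_minus = q$K * (3 - q$eta),
       nu_plus = q$K * (3 + q$eta),
       nu_dq = 2 * sqrt((nz + hf$A_iso / 2)^2 + q$K^2 * (3 + q$eta^2)))
}

#' Electron-manifold nuclear sub-Hamiltonians
#'
#' For one nucleus entry and one field orientation, builds the two nuclear
#' sub-Hamiltonians `H_alpha` (m_S = +1/2) and `H_beta` (m_S = -1/2), in MHz:
#' `H_mS = mS * (n' A) . I - nu_nz (n . I) + H_Q`, where `n` is the field
#' direction in the molecular frame, `A` the hyperfine tensor and `H_Q` the
#' quadrupole term in its (rotated) principal frame.  Eigenvalue differences
#' of each matrix are the nuclear transition frequencies of that manifold.
#'
#' @param entry A [nucleus_entry()].
#' @param orient An [orientation()].
#' @param field [field_conditions()].
#' @return A list with complex Hermitian matrices `H_alpha`, `H_beta`.
#' @export
sublevel_hamiltonians <- function(entry, orient, field) {
  nuc <- entry$nucleus
  if (!(abs(nuc$I - 0.5) < 1e-12 || abs(nuc$I - 1) < 1e-12))
    stop("simulation engines support I = 1/2 and I = 1 only", call. = FALSE)
  ops <- spin_ops(nuc$I)
  n <- c(sin(orient$theta) * cos(orient$phi),
         sin(orient$theta) * sin(orient$phi),
         cos(orient$theta))
  A <- hyperfine_tensor(entry$hyperfine)
  a <- as.numeric(n %*% A)                    # hyperfine field on the nucleus
  h_hf <- a[1] * ops$x + a[2] * ops$y + a[3] * ops$z
  nz <- nuclear_zeeman(nuc, field)
  h_z <- nz * (n[1] * ops$x + n[2] * ops$y + n[3] * ops$z)
  h_q <- matrix(0, ops$d, ops$d)
  q <- entry$quadrupole
  if (!is.null(q) && q$K > 0) {
    R <- euler_rotation(q$euler)
    ## principal-axis operators: columns of R are the PAS axes
    Iq <- lapply(1:3, function(j)
      R[1, j] * ops$x + R[2, j] * ops$y + R[3, j] * ops$z)
    Isq <- nuc$I * (nuc$I + 1) * diag(ops$d)
    h_q <- q$K * (3 * Iq[[3]] %*% Iq[[3]] - Isq +
                    q$eta * (Iq[[1]] %*% Iq[[1]] - Iq[[2]] %*% Iq[[2]]))
  }
  list(H_alpha = 0.5 * h_hf - h_z + h_q,
       H_beta = -0.5 * h_hf - h_z + h_q)
}
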