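#' @keywords internal
"_PACKAGE"

## Nuclear gyromagnetic ratios, MHz per tesla (signed, standard tables).
.GYROMAGNETIC <- c("1H" = 42.5775, "14N" = 3.0777, "15N" = -4.3157)
.NUCLEAR_SPIN <- c("1H" = 0.5, "14N" = 1, "15N" = 0.5)

#' Nucleus descriptor
#'
#' Describes one (set of) magnetically equivalent nuclei coupled to the
#' electron: isotope, nuclear spin, gyromagnetic ratio and the number of
#' equivalent copies (identical coupling tensors in collinear frames).
#'
#' @param isotope Isotope label, one of `"1H"`, `"14N"`, `"15N"`, or any
#'   label if `I` and `gamma_MHz_T` are given explicitly.
#' @param count Number of equivalent copies (positive integer).
#' @param I Nuclear spin quantum number; looked up from `isotope` if missing.
#'   The simulation engines support I = 1/2 and I = 1.
#' @param gamma_MHz_T Gyromagnetic ratio in MHz/T (signed); looked up from
#'   `isotope` if missing.
#' @return An object of class `nucleus`.
#' @examples
#' nucleus("15N", count = 2)
#' @export
nucleus <- function(isotope, count = 1L, I = NULL, gamma_MHz_T = NULL) {
  if (is.null(I)) {
    if (!isotope %in% names(.NUCLEAR_SPIN))
      stop("unknown isotope '", isotope, "'; supply I and gamma_MHz_T", call. = FALSE)
    I <- .NUCLEAR_SPIN[[isotope]]
  }
  if (is.null(gamma_MHz_T)) gamma_MHz_T <- .GYROMAGNETIC[[isotope]]
  count <- as.integer(count)
  stopifnot(count >= 1L, is.finite(I), I > 0)
  if (gamma_MHz_T == 0) stop("gyromagnetic ratio must be nonzero", call. = FALSE)
  if (abs(2 * I - round(2 * I)) > 1e-12)
    stop("I must be a half-integer or integer multiple of 1/2", call. = FALSE)
  structure(list(isotope = isotope, I = I, gamma_MHz_T = gamma_MHz_T,
                 count = count), class = "nucleus")
}

#' Hyperfine coupling (axial)
#'
#' Axial hyperfine tensor parameterized by the isotropic part `A_iso` and the
#' dipolar part `T_dip`, with principal values
#' `A_xx = A_yy = A_iso - T_dip` and `A_zz = A_iso + 2*T_dip`.
#'
#' @param A_iso Isotropic hyperfine coupling, MHz.
#' @param T_dip Axial dipolar coupling, MHz (signed).
#' @param euler Euler angles (radians, ZYZ) of the hyperfine principal frame
#'   in the molecular frame; defaults to collinear.
#' @return An object of class `hyperfine`.
#' @export
hyperfine <- function(A_iso, T_dip = 0, euler = c(0, 0, 0)) {
  stopifnot(is.finite(A_iso), is.finite(T_dip), length(euler) == 3,
            all(is.finite(euler)))
  structure(list(A_iso = A_iso, T_dip = T_dip, euler = as.numeric(euler)),
            class = "hyperfine")
}

#' Nuclear quadrupole coupling
#'
#' Quadrupole interaction for I >= 1 nuclei, parameterized by
#' `K = e^2 q Q / 4h` (for I = 1) and the asymmetry `eta`.
#'
#' @param K Quadrupole coupling constant, MHz (nonnegative).
#' @param eta Asymmetry parameter in `[0, 1]`.
#' @param euler Euler angles (radians) of the quadrupole principal frame in
#'   the molecular frame.
#' @return An object of class `quadrupole`.
#' @export
quadrupole <- function(K, eta = 0, euler = c(0, 0, 0)) {
  stopifnot(is.finite(K), K >= 0, is.finite(eta), eta >= 0, eta <= 1,
            length(euler) == 3, all(is.finite(euler)))
  structure(list(K = K, eta = eta, euler = as.numeric(euler)),
            class = "quadrupole")
}

#' Spin system
#'
#' An S = 1/2 electron (isotropic g) coupled to an ordered list of nuclei.
#' Each entry pairs a [nucleus()] with its [hyperfine()] coupling and, for
#' I >= 1, a [quadrupole()] coupling.
#'
#' @param nuclei A list of entries created by [nucleus_entry()].
#' @param g_iso Isotropic electron g value (informational).
#' @return An object of class `spin_system`.
#' @examples
#' sys <- spin_system(list(nucleus_entry(nucleus("15N", count = 2),
#'                                       hyperfine(2.8, -0.4))))
#' @export
spin_system <- function(nuclei = list(), g_iso = 2.06) {
  stopifnot(is.list(nuclei))
  for (e in nuclei) {
    if (!inherits(e, "nucleus_entry"))
      stop("each element of `nuclei` must be a nucleus_entry()", call. = FALSE)
  }
  structure(list(g_iso = g_iso, nuclei = nuclei), class = "spin_system")
}

#' Couple a nucleus to the electron
#'
#' @param nuc A [nucleus()].
#' @param hf A [hyperfine()] coupling.
#' @param quad A [quadrupole()] coupling, or `NULL` for I = 1/2.
#' @return An object of class `nucleus_entry`.
#' @export
nucleus_entry <- function(nuc, hf, quad = NULL) {
  stopifnot(inherits(nuc, "nucleus"), inherits(hf, "hyperfine"))
  if (nuc$I >= 1 && is.null(quad)) quad <- quadrupole(0, 0)
  if (nuc$I < 1 && !is.null(quad))
    stop("quadrupole coupling requires I >= 1", call. = FALSE)
  structure(list(nucleus = nuc, hyperfine = hf, quadrupole = quad),
            class = "nucleus_entry")
}

#' Static field conditions
#'
#' @param B0_gauss Static field in gauss (positive).
#' @param mw_freq_GHz Microwave frequency in GHz (informational).
#' @return An object of class `field_conditions`.
#' @export
field_conditions <- function(B0_gauss = 3316, mw_freq_GHz = 9.7) {
  stopifnot(is.finite(B0_gauss), B0_gauss > 0)
  structure(list(B0_gauss = B0_gauss, mw_freq_GHz = mw_freq_GHz),
            class = "field_conditions")
}

## Nuclear Zeeman frequency in MHz (magnitude; sign dropped by convention).
nuclear_zeeman <- function(nuc, field) {
  abs(nuc$gamma_MHz_T) * field$B0_gauss * 1e-4
}

#' @export
print.spin_system <- function(x, ...) {
  cat("Spin system: S = 1/2 electron, g_iso =", x$g_iso, "\n")
  if (!length(x$nuclei)) cat("  (no coupled nuclei)\n")
  for (e in x$nuclei) {
    n <- e$nucleus; h <- e$hyperfine
    cat(sprintf("  %s x%d  I = %g  A_iso = %g MHz  T = %g MHz",
                n$isotope, n$count, n$I, h$A_iso, h$T_dip))
    if (!is.null(e$quadrupole) && e$quadrupole$K > 0)
      cat(sprintf("  K = %g MHz  eta = %g", e$quadrupole$K, e$quadrupole$eta))
    cat("\n")
  }
  invisible(x)
}

## -- convenience constructors for the canonical histidine systems ----------

#' Canonical coupled-nitrogen systems
#'
#' `his_15N_system()` builds the remote-nitrogen system of `n` equivalent
#' 15N-labeled histidine imidazoles coupled to Cu2+ (defaults
#' A_iso = 2.8 MHz, T = -0.4 MHz).  `his_14N_system()` builds a single
#' natural-abundance remote 14N near exact cancellation
#' (K = 0.4167 MHz, eta = 0.6, A_iso = 1.85 MHz).
#'
#' @param count Number of equivalent 15N nuclei.
#' @param A_iso,T_dip Hyperfine parameters, MHz.
#' @param K,eta Quadrupole parameters for the 14N system.
#' @return A [spin_system()].
#' @export
his_15N_system <- function(count = 1, A_iso = 2.8, T_dip = -0.4) {
  spin_system(list(nucleus_entry(nucleus("15N", count = count),
                                 hyperfine(A_iso, T_dip))))
}

#' @rdname his_15N_system
#' @export
his_14N_system <- function(A_iso = 1.85, T_dip = 0.1, K = 0.4167, eta = 0.6) {
  spin_system(list(nucleus_entry(nucleus("14N"),
                                 hyperfine(A_iso, T_dip),
                                 quadrupole(K, eta))))
}
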