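## Acquisition-parameter design: proton blind-spot tau, per-transition
## intensity-vs-tau curves, and joint 14N/15N recommendations.

#' Proton blind-spot tau
#'
#' The tau values at which the (1 - cos 2 pi nu_H tau) factor suppresses
#' the 1H matrix line: `tau = harmonic / nu_H` with `nu_H = gamma_H B0`.
#'
#' @param field [field_conditions()].
#' @param harmonic Positive integer harmonic.
#' @return tau in ns.
#' @examples
#' proton_blindspot_tau(field_conditions(3316), 3)  # ~212 ns
#' @export
proton_blindspot_tau <- function(field, harmonic = 3) {
  stopifnot(harmonic >= 1)
  nu_H <- .GYROMAGNETIC[["1H"]] * field$B0_gauss * 1e-4  # MHz
  1000 * harmonic / nu_H
}

## Fourier coefficient of cos(m x) in (1 - d + d cos x)^c, computed by a
## discrete cosine transform exact for polynomial degree c < n_fft.
combination_coefficient <- function(d, c, m, n_fft = 64) {
  x <- 2 * pi * (0:(n_fft - 1)) / n_fft
  g <- outer(d, cos(x), function(dd, cx) (1 - dd + dd * cx)^c)
  if (m == 0) rowMeans(g)
  else 2 * as.vector(g %*% cos(m * x)) / n_fft
}

#' Transition intensity as a function of tau
#'
#' For I = 1/2 systems, the powder-averaged amplitude prefactor of the
#' named spectral line in the analytic 3-pulse ESEEM expression: the
#' fundamental `nu_alpha` (`nu_beta`) lines carry the per-nucleus depth
#' prefactor `d = (k/2)(1 - cos 2 pi nu_other tau)`, and the `2nu_alpha`
#' combination line carries the expanded-product prefactor (the
#' coefficient of `cos(2 x)` in the c-th power of the manifold factor,
#' `d^2/2` for two equivalent nuclei), defined only for counts
#' `c >= 2`.  For `transition = "nu_dq"` (I = 1 systems) the curve is the
#' tau-dependent Mims amplitude of the double-quantum transition of the
#' non-cancelled manifold, from the matrix engine's eigen-decomposition.
#' Curve maxima identify optimal tau values; zeros are blind spots.
#'
#' @param system A [spin_system()] with a single nucleus entry.
#' @param transition One of `"nu_alpha"`, `"nu_beta"`, `"2nu_alpha"`,
#'   `"nu_dq"`.
#' @param tau_range_ns Vector of tau values, ns.
#' @param powder_grid_size Number of theta nodes.
#' @param field [field_conditions()].
#' @return A data frame with columns `tau_ns`, `intensity` (nonnegative).
#' @export
tau_intensity_curve <- function(system, transition, tau_range_ns,
                                powder_grid_size = 100,
                                field = field_conditions()) {
  stopifnot(length(system$nuclei) == 1)
  e <- system$nuclei[[1]]
  taus <- as.numeric(tau_range_ns)
  if (transition %in% c("nu_alpha", "nu_beta", "2nu_alpha")) {
    if (abs(e$nucleus$I - 0.5) > 1e-12)
      stop("transition '", transition, "' requires an I = 1/2 nucleus", call. = FALSE)
    grid <- powder_grid(powder_grid_size, 1)
    acc <- numeric(length(taus))
    m <- if (transition == "2nu_alpha") 2 else 1
    if (m == 2 && e$nucleus$count < 2)
      stop("2nu_alpha requires at least two equivalent nuclei", call. = FALSE)
    for (i in seq_len(nrow(grid))) {
      fr <- manifold_freqs_12(e$hyperfine, grid$theta[i], e$nucleus, field)
      nus <- sort(c(fr$f_plus, fr$f_minus))
      other <- if (transition == "nu_beta") nus[1] else nus[2]
      d <- (fr$k / 2) * (1 - cos(.PH * other * taus))
      acc <- acc + grid$weight[i] *
        (if (m == 1) d else abs(combination_coefficient(d, e$nucleus$count, m)))
    }
    return(data.frame(tau_ns = taus, intensity = acc))
  }
  if (transition == "nu_dq") {
    if (abs(e$nucleus$I - 1) > 1e-12)
      stop("nu_dq requires an I = 1 nucleus", call. = FALSE)
    n_phi <- if (system_is_axial(system)) 1L else 8L
    grid <- powder_grid(powder_grid_size, n_phi)
    acc <- numeric(length(taus))
    for (i in seq_len(nrow(grid))) {
      me <- manifold_eigen(e, orientation(grid$theta[i], grid$phi[i]), field)
      ## non-cancelled manifold = the one with the larger total spread
      use_a <- diff(range(me$la)) >= diff(range(me$lb))
      l_this <- if (use_a) me$la else me$lb
      l_other <- if (use_a) me$lb else me$la
      M <- if (use_a) me$M else Conj(t(me$M))
      jh <- which.max(l_this); jl <- which.min(l_this)
      ## |Q_jl(tau)|^2 for the DQ pair, vectorized over tau
      cks <- M[jh, ] * Conj(M[jl, ])
      q <- exp(-1i * .PH * outer(taus, l_other)) %*% cks
      acc <- acc + grid$weight[i] * 2 * Mod(as.vector(q))^2 / me$d
    }
    return(data.frame(tau_ns = taus, intensity = acc))
  }
  stop("unknown transition '", transition, "'", call. = FALSE)
}

#' Joint 14N/15N acquisition recommendation
#'
#' Picks the tau that maximizes the minimum normalized amplitude across
#' the 14N double-quantum line and the 15N nu_alpha, nu_beta and (when two
#' or more equivalent nuclei are present) 2 nu_alpha lines, restricted to
#' tau values within `blindspot_window_ns` of a proton blind spot so the
#' 1H matrix line stays suppressed.  Recommends the smallest offered
#' initial T, which keeps broad components (the multi-histidine
#' signatures) in the detected envelope.
#'
#' @param system14 A [spin_system()] with one I = 1 nucleus, or `NULL`.
#' @param system15 A [spin_system()] with one I = 1/2 entry, or `NULL`.
#' @param tau_range_ns Vector of candidate tau values, ns.
#' @param T_options_ns Candidate initial T values, ns.
#' @param field [field_conditions()].
#' @param powder_grid_size Theta nodes for the intensity curves.
#' @param blindspot_window_ns Half-width of the allowed window around each
#'   proton blind spot, ns.
#' @return An `acquisition_plan`: recommended tau and T_start, the
#'   per-transition intensity curves, and notes.
#' @export
recommend_acquisition <- function(system14, system15, tau_range_ns,
                                  T_options_ns = c(12, 400),
                                  field = field_conditions(),
                                  powder_grid_size = 100,
                                  blindspot_window_ns = 5) {
  taus <- as.numeric(tau_range_ns)
  curves <- list()
  if (!is.null(system14))
    curves$nu_dq <- tau_intensity_curve(system14, "nu_dq", taus,
                                        powder_grid_size, field)$intensity
  if (!is.null(system15)) {
    curves$nu_alpha <- tau_intensity_curve(system15, "nu_alpha", taus,
                                           powder_grid_size, field)$intensity
    curves$nu_beta <- tau_intensity_curve(system15, "nu_beta", taus,
                                          powder_grid_size, field)$intensity
    if (system15$nuclei[[1]]$nucleus$count >= 2)
      curves$`2nu_alpha` <- tau_intensity_curve(system15, "2nu_alpha", taus,
                                                powder_grid_size, field)$intensity
  }
  if (!length(curves)) stop("at least one system must be supplied", call. = FALSE)
  norm <- lapply(curves, function(v) if (max(v) > 0) v / max(v) else v)
  score <- do.call(pmin, norm)
  nu_H <- .GYROMAGNETIC[["1H"]] * field$B0_gauss * 1e-4
  harmonics <- seq_len(ceiling(max(taus) * nu_H / 1000) + 1)
  bs <- 1000 * harmonics / nu_H
  feasible <- vapply(taus, function(tau)
    any(abs(tau - bs) <= blindspot_window_ns), logical(1))
  notes <- character(0)
  if (!any(feasible)) {
    warning("no tau in range lies near a proton blind spot; returning the ",
            "best-effort unconstrained optimum")
    notes <- c(notes, "proton blind-spot constraint infeasible in scanned range")
    feasible <- rep(TRUE, length(taus))
  }
  sc <- ifelse(feasible, score, -Inf)
  best <- which.max(sc)
  plan <- list(tau_ns = taus[best],
               T_start_ns = min(T_options_ns),
               curves = data.frame(tau_ns = taus, as.data.frame(norm),
                                   check.names = FALSE),
               score = score,
               proton_blindspots_ns = bs[bs >= min(taus) & bs <= max(taus)],
               notes = notes)
  class(plan) <- "acquisition_plan"
  plan
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("Acquisition plan: tau = %g ns, initial T = %g ns\n",
              x$tau_ns, x$T_start_ns))
  cat("Proton blind spots in range (ns):",
      paste(sprintf("%.1f", x$proton_blindspots_ns), collapse = ", "), "\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
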