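## Post-acquisition processing: normalization, background subtraction,
## apodization + zero-fill + magnitude FFT, peak picking and ratios.

#' 1D magnitude spectrum
#' @param freq_MHz Frequency axis, MHz (0 to Nyquist).
#' @param magnitude Nonnegative magnitudes.
#' @param provenance List recording the processing chain.
#' @return An object of class `spectrum_1d`.
#' @export
spectrum_1d <- function(freq_MHz, magnitude, provenance = list()) {
  stopifnot(length(freq_MHz) == length(magnitude), all(magnitude >= 0))
  structure(list(freq_MHz = freq_MHz, magnitude = magnitude,
                 provenance = provenance), class = "spectrum_1d")
}

#' 2D magnitude spectrum
#' @param f1_MHz,f2_MHz Frequency axes, MHz.
#' @param magnitude Nonnegative magnitude matrix.
#' @param provenance List recording the processing chain.
#' @return An object of class `spectrum_2d`.
#' @export
spectrum_2d <- function(f1_MHz, f2_MHz, magnitude, provenance = list()) {
  stopifnot(is.matrix(magnitude), nrow(magnitude) == length(f1_MHz),
            ncol(magnitude) == length(f2_MHz), all(magnitude >= 0))
  structure(list(f1_MHz = f1_MHz, f2_MHz = f2_MHz, magnitude = magnitude,
                 provenance = provenance), class = "spectrum_2d")
}

#' @export
print.spectrum_1d <- function(x, ...) {
  cat(sprintf("1D spectrum: %d bins, 0..%.3f MHz\n",
              length(x$freq_MHz), max(x$freq_MHz)))
  invisible(x)
}

#' @export
print.spectrum_2d <- function(x, ...) {
  cat(sprintf("2D spectrum: %d x %d bins, 0..%.3f x 0..%.3f MHz\n",
              length(x$f1_MHz), length(x$f2_MHz),
              max(x$f1_MHz), max(x$f2_MHz)))
  invisible(x)
}

#' Normalize a trace to its first point
#'
#' Divides the envelope by the amplitude at the first time point (echo
#' intensity at the initial T), so the trace starts at 1.  Idempotent.
#'
#' @param trace A [time_trace_1d()] or [time_trace_2d()].
#' @return The normalized trace.
#' @export
normalize_trace <- function(trace) {
  v0 <- if (inherits(trace, "time_trace_2d")) trace$values[1, 1]
        else trace$values[1]
  if (!is.finite(v0) || v0 == 0)
    stop("degenerate trace: first-point amplitude is zero", call. = FALSE)
  trace$values <- trace$values / v0
  trace$meta$normalized_first_point <- TRUE
  trace
}

## Exponential decay fit y ~ a exp(-t/tc) + c; returns fitted values or NULL.
fit_exponential <- function(t, y) {
  rng <- diff(range(y))
  c0 <- min(y); a0 <- max(y) - c0
  if (a0 <= 0 || rng == 0) return(rep(mean(y), length(t)))
  tc0 <- diff(range(t)) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / tc) + c,
                      start = list(a = a0, tc = tc0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.numeric(stats::fitted(fit))
}

## Polynomial background for all rows of Y at once via the hat matrix.
poly_rows <- function(Y, t, order) {
  X <- stats::poly(t, degree = order, raw = FALSE)
  X <- cbind(1, X)
  H <- X %*% solve(crossprod(X), t(X))
  Y %*% t(H)
}

#' Background subtraction
#'
#' Least-squares fit of a slowly varying envelope model (`"exponential"`:
#' `a exp(-t/tc) + c`; `"polynomial"`: degree-`order` polynomial) which is
#' subtracted to leave the oscillating modulation.  For 2D traces the fit
#' is applied along each dimension in turn, which also removes the
#' axis ridges of separable 1D modulation.  An exponential fit that fails
#' to converge falls back to a polynomial fit of order 3 with a message.
#'
#' @param trace A [time_trace_1d()] or [time_trace_2d()].
#' @param model `"exponential"` or `"polynomial"`.
#' @param order Polynomial order (default 3).
#' @return The background-subtracted trace; the fitted background of a 1D
#'   trace is kept in `meta$background`.
#' @export
subtract_background <- function(trace, model = c("exponential", "polynomial"),
                                order = 3) {
  model <- match.arg(model)
  if (inherits(trace, "time_trace_1d")) {
    if (length(trace$t_ns) < 8) stop("need >= 8 points", call. = FALSE)
    bg <- if (model == "exponential") fit_exponential(trace$t_ns, trace$values)
          else NULL
    if (is.null(bg)) {
      if (model == "exponential")
        message("exponential background fit failed; falling back to polynomial order 3")
      bg <- as.vector(poly_rows(matrix(trace$values, nrow = 1), trace$t_ns, order))
    }
    trace$meta$background <- bg
    trace$values <- trace$values - bg
    return(trace)
  }
  stopifnot(inherits(trace, "time_trace_2d"))
  V <- trace$values
  strip <- function(V, t) {
    if (model == "polynomial") return(V - poly_rows(V, t, order))
    out <- V
    for (i in seq_len(nrow(V))) {
      bg <- fit_exponential(t, V[i, ])
      if (is.null(bg)) bg <- as.vector(poly_rows(V[i, , drop = FALSE], t, order))
      out[i, ] <- V[i, ] - bg
    }
    out
  }
  V <- strip(V, trace$t2_ns)           # along t2 for each t1 row
  V <- t(strip(t(V), trace$t1_ns))     # along t1 for each t2 column
  trace$values <- V
  trace
}

## Decaying apodization window: second half of a symmetric window of
## length 2n, so the t = 0 end of the envelope is not attenuated.
apod_window <- function(n, window, at = 100) {
  switch(window,
         none = rep(1, n),
         hamming = signal::hamming(2 * n)[(n + 1):(2 * n)],
         chebyshev = as.numeric(signal::chebwin(2 * n, at))[(n + 1):(2 * n)],
         stop("unknown window '", window, "'", call. = FALSE))
}

#' Magnitude spectrum of a (background-subtracted) trace
#'
#' Removes the residual mean, applies the apodization window, zero-fills
#' and Fourier-transforms, returning the magnitude over `[0, Nyquist]`
#' (both axes for 2D).  Defaults follow common ESEEM/HYSCORE practice:
#' Chebyshev (Dolph-Chebyshev, 100 dB) apodization, zero-fill to 2048
#' points in 1D and 1024 x 1024 in 2D.
#'
#' @param trace A [time_trace_1d()] or [time_trace_2d()].
#' @param window `"chebyshev"`, `"hamming"` or `"none"`.
#' @param zerofill Transform length (>= trace length); default 2048 for 1D
#'   and 1024 for 2D.
#' @param chebyshev_at Chebyshev sidelobe attenuation, dB.
#' @return A [spectrum_1d()] or [spectrum_2d()].
#' @export
to_spectrum <- function(trace, window = c("chebyshev", "hamming", "none"),
                        zerofill = NULL, chebyshev_at = 100) {
  window <- match.arg(window)
  prov <- list(window = window, chebyshev_at = chebyshev_at)
  if (inherits(trace, "time_trace_1d")) {
    n <- length(trace$t_ns)
    if (is.null(zerofill)) zerofill <- 2048
    if (zerofill < n) stop("zerofill smaller than trace length", call. = FALSE)
    dt <- trace$t_ns[2] - trace$t_ns[1]
    y <- (trace$values - mean(trace$values)) * apod_window(n, window, chebyshev_at)
    y <- c(y, rep(0, zerofill - n))
    mag <- Mod(stats::fft(y))[1:(zerofill %/% 2 + 1)]
    f <- (0:(zerofill %/% 2)) * 1000 / (zerofill * dt)
    prov$zerofill <- zerofill; prov$dt_ns <- dt
    return(spectrum_1d(f, mag, prov))
  }
  stopifnot(inherits(trace, "time_trace_2d"))
  n1 <- length(trace$t1_ns); n2 <- length(trace$t2_ns)
  if (is.null(zerofill)) zerofill <- 1024
  if (zerofill < max(n1, n2)) stop("zerofill smaller than trace length", call. = FALSE)
  dt1 <- trace$t1_ns[2] - trace$t1_ns[1]
  dt2 <- trace$t2_ns[2] - trace$t2_ns[1]
  V <- trace$values - mean(trace$values)
  V <- V * outer(apod_window(n1, window, chebyshev_at),
                 apod_window(n2, window, chebyshev_at))
  Z <- matrix(0, zerofill, zerofill)
  Z[1:n1, 1:n2] <- V
  mag <- Mod(stats::fft(Z))[1:(zerofill %/% 2 + 1), 1:(zerofill %/% 2 + 1)]
  f1 <- (0:(zerofill %/% 2)) * 1000 / (zerofill * dt1)
  f2 <- (0:(zerofill %/% 2)) * 1000 / (zerofill * dt2)
  prov$zerofill <- zerofill; prov$dt_ns <- c(dt1, dt2)
  spectrum_2d(f1, f2, mag, prov)
}

## 3-point parabolic refinement; returns c(offset_in_bins, refined_height).
parab_refine <- function(ym, y0, yp) {
  denom <- ym - 2 * y0 + yp
  if (denom >= 0) return(c(0, y0))  # not a proper maximum
  d <- 0.5 * (ym - yp) / denom
  d <- max(-0.5, min(0.5, d))
  c(d, y0 - 0.25 * (ym - yp) * d)
}

#' Peak picking
#'
#' Finds local maxima above a height threshold, refines positions and
#' heights by 3-point (1D) or separable 3x3 (2D) parabolic interpolation,
#' and orders the result deterministically by descending height with ties
#' broken by ascending first frequency.
#'
#' @param spec A [spectrum_1d()] or [spectrum_2d()].
#' @param min_height_frac Threshold as a fraction of the spectrum maximum.
#' @return A `peak_list`: a data frame with columns `nu1`, `nu2` (NA for
#'   1D), `height`, `label`.
#' @export
pick_peaks <- function(spec, min_height_frac = 0.05) {
  if (inherits(spec, "spectrum_1d")) {
    y <- spec$magnitude; f <- spec$freq_MHz
    n <- length(y)
    thr <- min_height_frac * max(y)
    out <- list()
    if (n >= 3 && max(y) > 0) for (i in 2:(n - 1)) {
      if (y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] >= thr) {
        r <- parab_refine(y[i - 1], y[i], y[i + 1])
        out[[length(out) + 1]] <- c(f[i] + r[1] * (f[2] - f[1]), NA, r[2])
      }
    }
    return(peak_list_from(out))
  }
  stopifnot(inherits(spec, "spectrum_2d"))
  M <- spec$magnitude
  thr <- min_height_frac * max(M)
  out <- list()
  nr <- nrow(M); nc <- ncol(M)
  df1 <- spec$f1_MHz[2] - spec$f1_MHz[1]; df2 <- spec$f2_MHz[2] - spec$f2_MHz[1]
  if (nr >= 3 && nc >= 3 && max(M) > 0) {
    ## strict maximum against the 3x3 neighborhood (ties to lower index)
    cand <- which(M >= thr, arr.ind = TRUE)
    cand <- cand[cand[, 1] > 1 & cand[, 1] < nr & cand[, 2] > 1 & cand[, 2] < nc, ,
                 drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      nb <- M[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (M[i, j] < max(nb)) next
      nb[2, 2] <- -Inf
      if (M[i, j] <= max(nb) &&
          !(M[i, j] > M[i - 1, j] && M[i, j] > M[i, j - 1])) next
      r1 <- parab_refine(M[i - 1, j], M[i, j], M[i + 1, j])
      r2 <- parab_refine(M[i, j - 1], M[i, j], M[i, j + 1])
      out[[length(out) + 1]] <- c(spec$f1_MHz[i] + r1[1] * df1,
                                  spec$f2_MHz[j] + r2[1] * df2,
                                  max(r1[2], r2[2]))
    }
  }
  peak_list_from(out)
}

peak_list_from <- function(entries) {
  if (!length(entries)) {
    df <- data.frame(nu1 = numeric(0), nu2 = numeric(0),
                     height = numeric(0), label = character(0))
  } else {
    m <- do.call(rbind, entries)
    df <- data.frame(nu1 = m[, 1], nu2 = m[, 2], height = m[, 3],
                     label = "")
    df <- df[order(-df$height, df$nu1), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Peak height near a predicted position
#'
#' Maximum magnitude within a box of half-width `box` MHz around the
#' predicted position, with parabolic position refinement — the standard
#' way peak heights are read off for intensity-ratio comparisons.
#'
#' @param spec A [spectrum_1d()] or [spectrum_2d()].
#' @param nu1,nu2 Predicted position, MHz (`nu2` ignored for 1D).
#' @param box Half-width of the search box, MHz.
#' @return A list with `height`, `nu1` and (2D) `nu2` of the local maximum.
#' @export
peak_height_at <- function(spec, nu1, nu2 = NULL, box = 0.15) {
  if (inherits(spec, "spectrum_1d")) {
    sel <- which(abs(spec$freq_MHz - nu1) <= box)
    if (!length(sel)) return(list(height = 0, nu1 = NA_real_))
    i <- sel[which.max(spec$magnitude[sel])]
    h <- spec$magnitude[i]; pos <- spec$freq_MHz[i]
    if (i > 1 && i < length(spec$magnitude)) {
      r <- parab_refine(spec$magnitude[i - 1], h, spec$magnitude[i + 1])
      pos <- pos + r[1] * (spec$freq_MHz[2] - spec$freq_MHz[1]); h <- r[2]
    }
    return(list(height = h, nu1 = pos))
  }
  i1 <- which(abs(spec$f1_MHz - nu1) <= box)
  i2 <- which(abs(spec$f2_MHz - nu2) <= box)
  if (!length(i1) || !length(i2)) return(list(height = 0, nu1 = NA_real_, nu2 = NA_real_))
  sub <- spec$magnitude[i1, i2, drop = FALSE]
  ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  i <- i1[ij[1]]; j <- i2[ij[2]]
  h <- spec$magnitude[i, j]
  p1 <- spec$f1_MHz[i]; p2 <- spec$f2_MHz[j]
  if (i > 1 && i < nrow(spec$magnitude) && j > 1 && j < ncol(spec$magnitude)) {
    r1 <- parab_refine(spec$magnitude[i - 1, j], h, spec$magnitude[i + 1, j])
    r2 <- parab_refine(spec$magnitude[i, j - 1], h, spec$magnitude[i, j + 1])
    p1 <- p1 + r1[1] * (spec$f1_MHz[2] - spec$f1_MHz[1])
    p2 <- p2 + r2[1] * (spec$f2_MHz[2] - spec$f2_MHz[1])
    h <- max(r1[2], r2[2])
  }
  list(height = h, nu1 = p1, nu2 = p2)
}

#' Peak-height ratios against a reference peak
#'
#' @param peaks A `peak_list` from [pick_peaks()].
#' @param reference Row index or label of the reference peak.
#' @param others Row indices or labels of the peaks to ratio (default: all).
#' @return Numeric vector of `height / reference height`; the reference
#'   maps to 1.
#' @export
peak_height_ratio <- function(peaks, reference = 1, others = NULL) {
  idx <- function(x) {
    if (is.character(x)) {
      m <- match(x, peaks$label)
      if (anyNA(m)) stop("peak label(s) not found: ",
                         paste(x[is.na(m)], collapse = ", "), call. = FALSE)
      m
    } else {
      if (any(x < 1 | x > nrow(peaks))) stop("peak index out of range", call. = FALSE)
      x
    }
  }
  if (!nrow(peaks)) stop("empty peak list", call. = FALSE)
  r <- idx(reference)
  o <- if (is.null(others)) seq_len(nrow(peaks)) else idx(others)
  peaks$height[o] / peaks$height[r]
}

#' Off-diagonal HYSCORE cross peaks
#'
#' Picks peaks of a 2D spectrum and removes the diagonal ridge and the
#' near-axis region, leaving the cross peaks ordered by descending height.
#'
#' @param spec A [spectrum_2d()].
#' @param min_height_frac Threshold fraction passed to [pick_peaks()].
#' @param diagonal_margin_MHz Exclusion half-width around `nu1 = nu2`.
#' @param min_freq_MHz Exclusion band along each axis.
#' @return A `peak_list` of cross peaks.
#' @export
hyscore_cross_peaks <- function(spec, min_height_frac = 0.05,
                                diagonal_margin_MHz = 0.25,
                                min_freq_MHz = 0.15) {
  pk <- pick_peaks(spec, min_height_frac)
  keep <- abs(pk$nu1 - pk$nu2) > diagonal_margin_MHz &
    pk$nu1 > min_freq_MHz & pk$nu2 > min_freq_MHz
  out <- pk[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' @export
print.peak_list <- function(x, ...) {
  cat("Peak list (", nrow(x), " peaks)\n", sep = "")
  NextMethod()
}
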