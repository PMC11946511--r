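## Configuration, trace file I/O (ASCII/CSV/minimal Bruker BES3T) and the
## seeded synthetic fixture generator.

.CONFIG_KEYS <- list(
  top = c("field", "system", "timing_3p", "timing_4p", "processing", "seed",
          "output"),
  field = c("B0_gauss", "mw_freq_GHz"),
  system = c("g_iso", "nuclei"),
  nucleus = c("isotope", "count", "A_iso_MHz", "T_dip_MHz", "K_MHz", "eta",
              "hf_euler_rad", "q_euler_rad"),
  timing_3p = c("tau_ns", "T_start_ns", "dT_ns", "n_points"),
  timing_4p = c("tau_ns", "t_start_ns", "dt_ns", "n1", "n2"),
  processing = c("window", "zerofill_1d", "zerofill_2d", "background",
                 "chebyshev_at_dB"),
  output = c("trace_path", "spectrum_path", "peaks_path"))

check_keys <- function(x, allowed, where, errs) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    errs <- c(errs, paste0("unknown key(s) in ", where, ": ",
                           paste(bad, collapse = ", ")))
  errs
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing the spin system, field, pulse
#' timings and processing options.  Keys carry explicit units
#' (`tau_ns`, `B0_gauss`, ...).  Unknown keys and missing required fields
#' are rejected with a message naming every violation.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config` with elements `field`
#'   ([field_conditions()]), `system` ([spin_system()]), `timing_3p`,
#'   `timing_4p`, `processing`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  errs <- check_keys(cfg, .CONFIG_KEYS$top, "top level", errs)
  if (is.null(cfg$field) || is.null(cfg$field$B0_gauss))
    errs <- c(errs, "missing required field: field$B0_gauss")
  if (is.null(cfg$system) || is.null(cfg$system$nuclei))
    errs <- c(errs, "missing required field: system$nuclei")
  if (!is.null(cfg$field))
    errs <- check_keys(cfg$field, .CONFIG_KEYS$field, "field", errs)
  if (!is.null(cfg$system)) {
    errs <- check_keys(cfg$system, .CONFIG_KEYS$system, "system", errs)
    for (i in seq_along(cfg$system$nuclei)) {
      nu <- cfg$system$nuclei[[i]]
      errs <- check_keys(nu, .CONFIG_KEYS$nucleus,
                         paste0("system$nuclei[[", i, "]]"), errs)
      if (is.null(nu$isotope))
        errs <- c(errs, paste0("system$nuclei[[", i, "]]: missing isotope"))
      if (is.null(nu$A_iso_MHz))
        errs <- c(errs, paste0("system$nuclei[[", i, "]]: missing A_iso_MHz"))
    }
  }
  for (blk in c("timing_3p", "timing_4p", "processing"))
    if (!is.null(cfg[[blk]]))
      errs <- check_keys(cfg[[blk]], .CONFIG_KEYS[[blk]], blk, errs)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)

  field <- field_conditions(cfg$field$B0_gauss,
                            cfg$field$mw_freq_GHz %||% 9.7)
  entries <- lapply(cfg$system$nuclei, function(nu) {
    n <- nucleus(nu$isotope, nu$count %||% 1L)
    hf <- hyperfine(nu$A_iso_MHz, nu$T_dip_MHz %||% 0,
                    nu$hf_euler_rad %||% c(0, 0, 0))
    quad <- NULL
    if (!is.null(nu$K_MHz) && n$I >= 1)
      quad <- quadrupole(nu$K_MHz, nu$eta %||% 0, nu$q_euler_rad %||% c(0, 0, 0))
    nucleus_entry(n, hf, quad)
  })
  t3 <- cfg$timing_3p %||% list()
  t4 <- cfg$timing_4p %||% list()
  pr <- cfg$processing %||% list()
  out <- list(
    field = field,
    system = spin_system(entries, cfg$system$g_iso %||% 2.06),
    timing_3p = pulse_timing_3p(t3$tau_ns %||% 210, t3$T_start_ns %||% 12,
                                t3$dT_ns %||% 16, t3$n_points %||% 602),
    timing_4p = pulse_timing_4p(t4$tau_ns %||% 210, t4$t_start_ns %||% 40,
                                t4$dt_ns %||% 32, t4$n1 %||% 256,
                                t4$n2 %||% 256),
    processing = list(window = pr$window %||% "chebyshev",
                      zerofill_1d = pr$zerofill_1d %||% 2048,
                      zerofill_2d = pr$zerofill_2d %||% 1024,
                      background = pr$background %||% "exponential",
                      chebyshev_at_dB = pr$chebyshev_at_dB %||% 100),
    seed = cfg$seed %||% 1L,
    output = cfg$output %||% list())
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a time trace to disk
#'
#' 1D traces are written as two-column ASCII (t_ns, amplitude); 2D traces
#' as a matrix CSV plus `<path>_t1.csv` / `<path>_t2.csv` axis files.
#'
#' @param trace A [time_trace_1d()] or [time_trace_2d()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "time_trace_1d")) {
    utils::write.table(data.frame(t_ns = trace$t_ns, value = trace$values),
                       path, sep = " ", row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(trace$values, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    base <- sub("\\.[^.]*$", "", path)
    writeLines(format(trace$t1_ns, scientific = FALSE), paste0(base, "_t1.csv"))
    writeLines(format(trace$t2_ns, scientific = FALSE), paste0(base, "_t2.csv"))
  }
  invisible(path)
}

#' Read a time trace
#'
#' Supported formats: two-column ASCII / CSV (1D), matrix CSV with axis
#' side files (2D, as written by [write_trace()]), and minimal Bruker
#' BES3T (`.DSC` descriptor + big-endian float64 `.DTA`, 1D and 2D).
#'
#' @param path Input path (for BES3T, either the `.DSC` or `.DTA` file).
#' @param format `"auto"`, `"ascii"`, `"csv2d"` or `"bes3t"`.
#' @return A [time_trace_1d()] or [time_trace_2d()].
#' @export
read_trace <- function(path, format = c("auto", "ascii", "csv2d", "bes3t")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(dsc|dta)$", tolower(path))) "bes3t"
    else if (file.exists(sub("\\.[^.]*$", "_t1.csv", path))) "csv2d"
    else "ascii"
  }
  if (format == "bes3t") return(read_bes3t(path))
  if (format == "csv2d") {
    base <- sub("\\.[^.]*$", "", path)
    V <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(V) <- NULL
    t1 <- as.numeric(readLines(paste0(base, "_t1.csv")))
    t2 <- as.numeric(readLines(paste0(base, "_t2.csv")))
    return(time_trace_2d(t1, t2, V, meta = list(source = path)))
  }
  d <- utils::read.table(path, header = FALSE,
                         sep = if (grepl("\\.csv$", tolower(path))) "," else "")
  time_trace_1d(d[[1]], d[[2]], meta = list(source = path))
}

## -- minimal Bruker BES3T --------------------------------------------------

parse_dsc <- function(dsc_path) {
  lines <- readLines(dsc_path, warn = FALSE)
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "*") || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s+(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("BES3T descriptor parse error at line ", i, " of ", dsc_path,
           call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

dsc_num <- function(kv, key, dsc_path, default = NULL) {
  if (is.null(kv[[key]])) {
    if (!is.null(default)) return(default)
    stop("BES3T descriptor missing required key ", key, " in ", dsc_path,
         call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(kv[[key]]))
  if (!is.finite(v))
    stop("BES3T descriptor key ", key, " is not numeric in ", dsc_path,
         call. = FALSE)
  v
}

read_bes3t <- function(path) {
  base <- sub("\\.[Dd][SsTt][CcAa]$", "", path)
  dsc <- paste0(base, if (file.exists(paste0(base, ".DSC"))) ".DSC" else ".dsc")
  dta <- paste0(base, if (file.exists(paste0(base, ".DTA"))) ".DTA" else ".dta")
  if (!file.exists(dsc)) stop("missing BES3T descriptor ", dsc, call. = FALSE)
  if (!file.exists(dta)) stop("missing BES3T data file ", dta, call. = FALSE)
  kv <- parse_dsc(dsc)
  irfmt <- kv[["IRFMT"]] %||% "D"
  if (!identical(irfmt, "D"))
    stop("unsupported BES3T IRFMT '", irfmt,
         "' (only D, float64, is supported)", call. = FALSE)
  endian <- if (identical(kv[["BSEQ"]], "LIT")) "little" else "big"
  xpts <- as.integer(dsc_num(kv, "XPTS", dsc))
  xmin <- dsc_num(kv, "XMIN", dsc)
  xwid <- dsc_num(kv, "XWID", dsc)
  ypts <- as.integer(dsc_num(kv, "YPTS", dsc, default = 0))
  n <- xpts * max(1L, ypts)
  raw <- readBin(dta, what = "double", n = n + 1L, size = 8, endian = endian)
  if (length(raw) < n)
    stop("BES3T data file ", dta, " holds ", length(raw),
         " points, descriptor promises ", n, call. = FALSE)
  raw <- raw[seq_len(n)]
  x <- xmin + xwid * (0:(xpts - 1)) / max(1L, xpts - 1L)
  if (ypts <= 1L)
    return(time_trace_1d(x, raw, meta = list(source = path, format = "bes3t")))
  ymin <- dsc_num(kv, "YMIN", dsc)
  ywid <- dsc_num(kv, "YWID", dsc)
  y <- ymin + ywid * (0:(ypts - 1)) / (ypts - 1L)
  ## DTA stores the X sweep contiguously for each Y slice
  V <- t(matrix(raw, nrow = xpts, ncol = ypts))
  time_trace_2d(y, x, V, meta = list(source = path, format = "bes3t"))
}

#' Write a minimal BES3T pair
#'
#' Writes `<base>.DSC` / `<base>.DTA` (big-endian float64) for a 1D or 2D
#' trace; the counterpart of the subset of BES3T that [read_trace()]
#' understands.  Useful for round-trip tests and for feeding the
#' processing chain with spectrometer-like files.
#'
#' @param trace A [time_trace_1d()] or [time_trace_2d()].
#' @param base Output path without extension.
#' @export
write_bes3t <- function(trace, base) {
  dsc <- paste0(base, ".DSC"); dta <- paste0(base, ".DTA")
  if (inherits(trace, "time_trace_1d")) {
    x <- trace$t_ns
    lines <- c("*", "* minimal BES3T descriptor", "*",
               "BSEQ BIG", "IRFMT D",
               paste("XPTS", length(x)),
               paste("XMIN", format(x[1], scientific = FALSE)),
               paste("XWID", format(x[length(x)] - x[1], scientific = FALSE)),
               "XUNI 'ns'")
    writeLines(lines, dsc)
    writeBin(as.numeric(trace$values), dta, size = 8, endian = "big")
  } else {
    x <- trace$t2_ns; y <- trace$t1_ns
    lines <- c("*", "* minimal BES3T descriptor", "*",
               "BSEQ BIG", "IRFMT D",
               paste("XPTS", length(x)),
               paste("XMIN", format(x[1], scientific = FALSE)),
               paste("XWID", format(x[length(x)] - x[1], scientific = FALSE)),
               paste("YPTS", length(y)),
               paste("YMIN", format(y[1], scientific = FALSE)),
               paste("YWID", format(y[length(y)] - y[1], scientific = FALSE)),
               "XUNI 'ns'", "YUNI 'ns'")
    writeLines(lines, dsc)
    writeBin(as.numeric(t(trace$values)), dta, size = 8, endian = "big")
  }
  invisible(base)
}

#' Synthetic experimental-like fixture
#'
#' Simulates a powder 3-pulse ESEEM envelope, multiplies it by an
#' exponential relaxation decay, and adds seeded white Gaussian noise of
#' standard deviation `1/snr` relative to the unit first-point amplitude.
#' Regeneration from the same parameters and seed is bit-identical.
#'
#' @param system A [spin_system()].
#' @param timing A [pulse_timing_3p()].
#' @param decay_tau_ns Relaxation decay constant, ns.
#' @param snr Signal-to-noise ratio (> 0); `Inf` for noiseless.
#' @param seed Integer random seed.
#' @param field [field_conditions()].
#' @param grid_size Powder grid size.
#' @param engine Simulation engine for [eseem_powder()].
#' @return An object of class `fixture`: `trace_noiseless`, `trace_noisy`
#'   (both [time_trace_1d()]), `ground_truth` (predicted transition
#'   frequencies, MHz) and `params`.
#' @export
make_fixture <- function(system, timing, decay_tau_ns = 3000, snr = 20,
                         seed = 1L, field = field_conditions(),
                         grid_size = 100,
                         engine = if (system_is_axial(system)) "analytic" else "matrix") {
  stopifnot(snr > 0)
  clean <- eseem_powder(system, timing, grid_size, engine, field)
  decay <- exp(-(clean$t_ns - clean$t_ns[1]) / decay_tau_ns)
  noiseless <- time_trace_1d(clean$t_ns, clean$values * decay,
                             meta = c(clean$meta, list(decay_tau_ns = decay_tau_ns)))
  noisy <- noiseless
  if (is.finite(snr)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    noisy$values <- noisy$values + stats::rnorm(length(noisy$values), sd = 1 / snr)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  gt <- fixture_ground_truth(system, field)
  structure(list(trace_noiseless = noiseless, trace_noisy = noisy,
                 ground_truth = gt,
                 params = list(decay_tau_ns = decay_tau_ns, snr = snr,
                               seed = seed, grid_size = grid_size)),
            class = "fixture")
}

## Predicted transition table: I = 1/2 lines at the powder-modal
## orientation (theta = 45 deg, where the modulation depth peaks), the
## combination line for counts >= 2, and 14N cancellation lines.
fixture_ground_truth <- function(system, field) {
  rows <- list()
  for (e in system$nuclei) {
    if (abs(e$nucleus$I - 0.5) < 1e-12) {
      fr <- n15_frequencies(e$hyperfine, pi / 4, e$nucleus, field)
      rows[[length(rows) + 1]] <-
        data.frame(label = c("nu_alpha", "nu_beta"),
                   freq_MHz = c(fr$nu_alpha, fr$nu_beta))
      if (e$nucleus$count >= 2)
        rows[[length(rows) + 1]] <-
          data.frame(label = "2nu_alpha", freq_MHz = 2 * fr$nu_alpha)
    } else {
      fr <- n14_cancellation_frequencies(e$quadrupole, e$hyperfine,
                                         e$nucleus, field)
      rows[[length(rows) + 1]] <-
        data.frame(label = c("nu_0", "nu_minus", "nu_plus", "nu_dq"),
                   freq_MHz = unlist(fr, use.names = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("ESEEM fixture: %d points, decay %g ns, SNR %g, seed %d\n",
              length(x$trace_noisy$t_ns), x$params$decay_tau_ns,
              x$params$snr, x$params$seed))
  invisible(x)
}
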