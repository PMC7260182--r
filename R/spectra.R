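# Spectrum container and the spectral operations of the IR workflow:
# frequency scaling, Gaussian broadening, Boltzmann ensemble averaging,
# similarity scoring, and diagnostic-band classification.

#' Spectrum container
#'
#' Either a vibrational line list (stick spectrum) or a continuous trace on
#' a wavenumber grid. The default working range, 700-1850 cm^-1, is the
#' region of the infrared ion-spectroscopy experiments this pipeline
#' emulates.
#'
#' @param positions wavenumbers, cm^-1 (strictly increasing for traces).
#' @param intensities non-negative intensities, arbitrary units.
#' @param kind `"lines"` or `"trace"`.
#' @param range working range `c(lo, hi)` in cm^-1.
#' @return object of class `spectrum_ir`.
#' @export
spectrum_ir <- function(positions, intensities, kind = c("lines", "trace"),
                        range = c(700, 1850)) {
  kind <- match.arg(kind)
  positions <- as.numeric(positions); intensities <- as.numeric(intensities)
  if (length(positions) != length(intensities))
    stop("positions and intensities must have equal length")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (kind == "trace" && any(diff(positions) <= 0))
    stop("trace positions must be strictly increasing")
  if (kind == "lines" && is.unsorted(positions)) {
    o <- order(positions); positions <- positions[o]; intensities <- intensities[o]
  }
  structure(list(kind = kind, positions = positions,
                 intensities = intensities, range = range),
            class = "spectrum_ir")
}

#' @export
print.spectrum_ir <- function(x, ...) {
  cat(sprintf("%s spectrum: %d points in [%.0f, %.0f] cm^-1, max intensity %.3g\n",
              x$kind, length(x$positions), min(x$positions), max(x$positions),
              if (length(x$intensities)) max(x$intensities) else 0))
  invisible(x)
}

#' Read and write two-column spectrum files
#'
#' Plain TSV (wavenumber, intensity); line lists carry the header comment
#' `# kind: lines`, traces `# kind: trace`.
#'
#' @param path file path.
#' @param spec a [spectrum_ir] (for writing).
#' @return `read_spectrum` returns a [spectrum_ir]; `write_spectrum`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1)
  kind <- if (grepl("^#\\s*kind:\\s*lines", first)) "lines" else "trace"
  d <- utils::read.table(path, comment.char = "#", col.names = c("nu", "i"))
  spectrum_ir(d$nu, d$i, kind = kind)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spec, path) {
  writeLines(c(sprintf("# kind: %s", spec$kind),
               sprintf("%.6f\t%.8g", spec$positions, spec$intensities)), path)
  invisible(path)
}

#' Scale vibrational line positions
#'
#' Multiplies every line position by the empirical harmonic scaling factor
#' (default 0.975, the value used for the ion spectra this pipeline
#' emulates); intensities are untouched.
#'
#' @param lines a line-list [spectrum_ir].
#' @param factor dimensionless scale factor.
#' @return the scaled line list.
#' @export
scale_frequencies <- function(lines, factor = 0.975) {
  if (lines$kind != "lines") stop("scale_frequencies expects a line list")
  if (factor <= 0 || factor > 1.2) stop("scale factor outside (0, 1.2]")
  spectrum_ir(lines$positions * factor, lines$intensities, kind = "lines",
              range = lines$range)
}

#' Gaussian broadening of a line list
#'
#' Convolves the stick spectrum with unit-area Gaussian kernels: the trace
#' is the sum over lines of `intensity * N(position, sigma)` sampled on the
#' grid, with `width` interpreted as the full width at half maximum by
#' default (the convention of the ion-spectroscopy literature; set
#' `width_is_fwhm = FALSE` for sigma). Integrated intensity is conserved up
#' to grid truncation.
#'
#' @param lines a line-list [spectrum_ir].
#' @param width broadening width in cm^-1 (default 20).
#' @param grid wavenumber grid; default 1 cm^-1 spacing over the working
#'   range.
#' @param width_is_fwhm interpret `width` as FWHM (default) or as sigma.
#' @return a trace [spectrum_ir] on `grid`.
#' @export
broaden <- function(lines, width = 20, grid = NULL, width_is_fwhm = TRUE) {
  if (lines$kind != "lines") stop("broaden expects a line list")
  if (width <= 0) stop("width must be > 0")
  if (is.null(grid)) grid <- seq(lines$range[1], lines$range[2], by = 1)
  sigma <- if (width_is_fwhm) width / (2 * sqrt(2 * log(2))) else width
  y <- numeric(length(grid))
  for (k in seq_along(lines$positions))
    y <- y + lines$intensities[k] * stats::dnorm(grid, lines$positions[k], sigma)
  spectrum_ir(grid, y, kind = "trace", range = lines$range)
}

# linear resampling of a trace onto a grid (zero outside its support)
resample_trace <- function(spec, grid) {
  y <- stats::approx(spec$positions, spec$intensities, xout = grid,
                     yleft = 0, yright = 0)$y
  spectrum_ir(grid, pmax(y, 0), kind = "trace", range = range(grid))
}

#' Boltzmann-weighted ensemble spectrum
#'
#' Combines per-conformer broadened traces into one composite, weighted by
#' Boltzmann factors of their Gibbs energies at temperature `T`, or by
#' explicit mixture fractions (for two-species mixing analyses). Traces on
#' differing grids are resampled onto the first trace's grid.
#'
#' @param traces list of trace [spectrum_ir] objects.
#' @param gibbs free energies in kJ/mol, one per trace (ignored when
#'   `fractions` given).
#' @param T temperature in Kelvin.
#' @param fractions explicit non-negative mixture fractions (normalized
#'   internally).
#' @return a trace [spectrum_ir].
#' @export
ensemble_spectrum <- function(traces, gibbs = NULL, T = 298, fractions = NULL) {
  if (!length(traces)) stop("at least one trace required")
  if (is.null(fractions)) {
    if (is.null(gibbs) || length(gibbs) != length(traces))
      stop("supply one Gibbs energy per trace, or explicit fractions")
    w <- boltzmann_weights(gibbs, T)
  } else {
    if (length(fractions) != length(traces) || any(fractions < 0))
      stop("fractions must be non-negative, one per trace")
    w <- fractions / sum(fractions)
  }
  grid <- traces[[1]]$positions
  y <- numeric(length(grid))
  for (k in seq_along(traces)) {
    tk <- traces[[k]]
    if (length(tk$positions) != length(grid) ||
        any(abs(tk$positions - grid) > 1e-9)) tk <- resample_trace(tk, grid)
    y <- y + w[k] * tk$intensities
  }
  spectrum_ir(grid, y, kind = "trace", range = traces[[1]]$range)
}

#' Similarity score between two spectra
#'
#' Cosine similarity of max-normalized traces resampled onto a common
#' 1 cm^-1 grid over the overlap of `range` with both spectra; invariant to
#' uniform intensity scaling of either input and symmetric in its
#' arguments. Pearson correlation is available as an alternative metric.
#'
#' @param computed,experimental trace [spectrum_ir] objects (line lists are
#'   broadened with defaults first).
#' @param range comparison window in cm^-1 (default the working range
#'   700-1850).
#' @param method `"cosine"` (default) or `"pearson"`.
#' @return score in [-1, 1] (non-negative traces give [0, 1] for cosine).
#' @export
match_score <- function(computed, experimental, range = c(700, 1850),
                        method = c("cosine", "pearson")) {
  method <- match.arg(method)
  if (computed$kind == "lines") computed <- broaden(computed)
  if (experimental$kind == "lines") experimental <- broaden(experimental)
  lo <- max(range[1], min(computed$positions), min(experimental$positions))
  hi <- min(range[2], max(computed$positions), max(experimental$positions))
  if (hi <= lo) stop("empty overlap range between the spectra")
  grid <- seq(lo, hi, by = 1)
  a <- resample_trace(computed, grid)$intensities
  b <- resample_trace(experimental, grid)$intensities
  if (max(a) > 0) a <- a / max(a)
  if (max(b) > 0) b <- b / max(b)
  if (method == "cosine") {
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(0)
    sum(a * b) / den
  } else {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
}

#' Default diagnostic band table
#'
#' The diagnostic infrared windows for glycosyl cation assignment: the
#' oxocarbenium C1=O5+ stretch near 1600 cm^-1, the intact acetyl C=O
#' stretch near 1800 cm^-1, the dioxolenium O-C=O+ stretch (~1550) and bend
#' (~1500), and the carbonyl of ring-opened species (1730-1790 cm^-1).
#'
#' @return data.frame: `band`, `lo`, `hi` (cm^-1).
#' @export
diagnostic_bands <- function() {
  data.frame(
    band = c("oxocarbenium_1600", "ester_1800", "dioxolenium_1550",
             "dioxolenium_1500", "ring_opened_carbonyl"),
    lo = c(1575, 1770, 1525, 1475, 1730),
    hi = c(1625, 1830, 1575, 1525, 1790))
}

# peaks of a trace: strict local maxima above a relative threshold
find_peaks <- function(spec, rel_threshold = 0.05) {
  y <- spec$intensities; x <- spec$positions
  if (length(y) < 3) return(data.frame(position = numeric(), height = numeric()))
  thr <- rel_threshold * max(y)
  i <- which(y[-c(1, length(y))] > y[-c(length(y) - 1, length(y))] &
               y[-c(1, length(y))] >= y[-(1:2)]) + 1
  i <- i[y[i] >= thr]
  data.frame(position = x[i], height = y[i])
}

#' Classify an ion spectrum by its diagnostic bands
#'
#' Detects peaks (local maxima above `rel_threshold` of the trace maximum)
#' inside each diagnostic window and applies the band rules:
#' ring-opened = dioxolenium 1550 stretch plus a 1730-1790 cm^-1 carbonyl;
#' oxocarbenium = 1600 stretch plus intact 1800 ester and no 1550;
#' dioxolenium = 1550 stretch plus 1500 bend and no 1800 ester; anything
#' else is reported `"mixed/indeterminate"`. Rules are evaluated in that
#' order.
#'
#' @param trace a trace [spectrum_ir] covering the diagnostic windows.
#' @param band_table window table as from [diagnostic_bands()].
#' @param rel_threshold peak detection threshold relative to the trace
#'   maximum (default 0.05).
#' @return object of class `ion_assignment`: `label` (one of
#'   `"oxocarbenium"`, `"dioxolenium"`, `"ring-opened"`,
#'   `"mixed/indeterminate"`) and `evidence` (per-band presence calls with
#'   peak positions).
#' @export
classify_ion_type <- function(trace, band_table = diagnostic_bands(),
                              rel_threshold = 0.05) {
  if (trace$kind != "trace") stop("classify_ion_type expects a broadened trace")
  if (min(trace$positions) > min(band_table$lo) ||
      max(trace$positions) < max(band_table$hi))
    stop("trace does not cover the diagnostic windows")
  peaks <- find_peaks(trace, rel_threshold)
  ev <- band_table
  ev$present <- FALSE; ev$position <- NA_real_; ev$height <- NA_real_
  for (r in seq_len(nrow(ev))) {
    inw <- peaks[peaks$position >= ev$lo[r] & peaks$position <= ev$hi[r], ]
    if (nrow(inw)) {
      top <- which.max(inw$height)
      ev$present[r] <- TRUE
      ev$position[r] <- inw$position[top]; ev$height[r] <- inw$height[top]
    }
  }
  has <- function(b) ev$present[ev$band == b]
  label <- if (has("dioxolenium_1550") && has("ring_opened_carbonyl"))
    "ring-opened"
  else if (has("oxocarbenium_1600") && has("ester_1800") &&
             !has("dioxolenium_1550")) "oxocarbenium"
  else if (has("dioxolenium_1550") && has("dioxolenium_1500") &&
             !has("ester_1800")) "dioxolenium"
  else "mixed/indeterminate"
  structure(list(label = label, evidence = ev), class = "ion_assignment")
}

#' @export
print.ion_assignment <- function(x, ...) {
  cat(sprintf("ion assignment: %s\n", x$label))
  for (r in seq_len(nrow(x$evidence)))
    cat(sprintf("  %-22s [%4.0f-%4.0f] %s%s\n", x$evidence$band[r],
                x$evidence$lo[r], x$evidence$hi[r],
                if (x$evidence$present[r]) "peak" else "-",
                if (x$evidence$present[r])
                  sprintf(" at %.0f", x$evidence$position[r]) else ""))
  invisible(x)
}
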