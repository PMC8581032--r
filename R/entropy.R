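# Entropy measures of gaze signals: sample entropy of 1-D series, Shannon
# entropy of 2-D occupancy (histogram or kernel-density), and spectral
# entropy of a 2-D difference signal.

#' Entropy configuration
#'
#' @param m Sample-entropy template length (default 2).
#' @param r_factor Sample-entropy tolerance as a fraction of the series SD
#'   (default 0.2).
#' @param spatial_bins Histogram cells per axis for the gaze spatial
#'   distribution (default 100).
#' @param kde_grid Kernel-density grid cells per axis for the
#'   gaze-to-stimulus difference (default 50).
#' @param nperseg Welch segment length for spectral entropy (default 32).
#' @return An `entropy_config` list.
#' @export
entropy_config <- function(m = 2, r_factor = 0.2, spatial_bins = 100,
                           kde_grid = 50, nperseg = 32) {
  if (m < 1) abort("`m` must be >= 1")
  if (r_factor <= 0) abort("`r_factor` must be > 0")
  structure(
    list(m = m, r_factor = r_factor, spatial_bins = spatial_bins,
         kde_grid = kde_grid, nperseg = nperseg),
    class = "entropy_config"
  )
}

#' Sample entropy
#'
#' Negative natural log of the conditional probability that two subsequences
#' similar over `m` points (Chebyshev distance at most `r`) stay similar at
#' the next point. Self-matches are excluded. Lower values mean a more
#' predictable series; a constant series has sample entropy 0.
#'
#' @param series Numeric vector, length > `m + 1`.
#' @param m Template length (default 2).
#' @param r Similarity tolerance; when `NULL` (default) it is
#'   `r_factor * sd(series)`.
#' @param r_factor Tolerance as a fraction of the series SD (default 0.2).
#' @return Non-negative entropy, or `NA` when no template pair matches (the
#'   conditional probability is undefined).
#' @export
#' @examples
#' sample_entropy(rep(1, 50))             # 0: perfectly predictable
#' sample_entropy(sin(seq(0, 20, 0.1)))
sample_entropy <- function(series, m = 2, r = NULL, r_factor = 0.2) {
  series <- as.numeric(series)
  if (length(series) <= m + 1) {
    abort(sprintf("series must be longer than m + 1 = %d", m + 1))
  }
  r <- r %||% (r_factor * sd(series))
  out <- .sampen_cpp(series, as.integer(m), r)
  if (is.na(out)) {
    inform("sample entropy undefined (no matching template pairs); returning NA")
  }
  out
}

#' Shannon entropy of a 2-D histogram
#'
#' Bins the points on a `bins x bins` grid and returns the Shannon entropy
#' of the cell occupancy distribution (`0 * log 0 := 0`), optionally
#' normalized by the maximum possible entropy `log2(bins^2)` so the result
#' lies in `[0, 1]`.
#'
#' @param x,y Point coordinates.
#' @param bins Cells per axis (default 100).
#' @param normalize Divide by `log2(bins^2)`? Default `TRUE`.
#' @param range_x,range_y Binning ranges; default the data range (use
#'   `c(0, 1)` for normalized gaze coordinates).
#' @return Entropy in bits, or in `[0, 1]` when normalized.
#' @export
histogram_entropy_2d <- function(x, y, bins = 100, normalize = TRUE,
                                 range_x = NULL, range_y = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  counts <- bin_counts_2d(x, y, bins, range_x, range_y)
  shannon_bits(counts / sum(counts)) / if (normalize) log2(bins^2) else 1
}

bin_counts_2d <- function(x, y, bins, range_x = NULL, range_y = NULL) {
  rng <- function(v, r) {
    r <- r %||% range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)  # all mass in one cell
    r
  }
  rx <- rng(x, range_x)
  ry <- rng(y, range_y)
  ix <- pmin(pmax(findInterval(x, seq(rx[1], rx[2], length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, seq(ry[1], ry[2], length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  tabulate((iy - 1L) * bins + ix, nbins = bins^2)
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Kernel-density entropy of a 2-D difference signal
#'
#' Estimates the density of the points with a Gaussian product kernel
#' (Scott's-rule bandwidth per axis) evaluated on a `grid x grid` lattice
#' over the data range, converts the lattice values to a probability vector,
#' and returns its Shannon entropy normalized by `log2(grid^2)`.
#'
#' @param dx,dy Difference coordinates.
#' @param grid Lattice cells per axis (default 50).
#' @return Normalized entropy in `[0, 1]`; 0 by convention when all points
#'   coincide.
#' @export
kde_entropy <- function(dx, dy, grid = 50) {
  stopifnot(length(dx) == length(dy))
  if (length(dx) < 2) abort("need at least 2 points")
  n <- length(dx)
  sx <- sd(dx)
  sy <- sd(dy)
  if (sx == 0 && sy == 0) {
    inform("degenerate (point-mass) difference distribution; entropy 0")
    return(0)
  }
  # Scott's rule per axis; MASS::kde2d uses h/4 as the Gaussian SD
  scott <- function(s) 4 * max(s, 1e-6) * n^(-1 / 6)
  hx <- scott(sx)
  hy <- scott(sy)
  lims <- c(range(dx) + c(-1, 1) * hx / 4, range(dy) + c(-1, 1) * hy / 4)
  k <- MASS::kde2d(dx, dy, h = c(hx, hy), n = grid, lims = lims)
  p <- k$z / sum(k$z)
  shannon_bits(p) / log2(grid^2)
}

#' Spectral entropy of a 2-D difference signal
#'
#' Welch power spectral densities of the x and y components (Hann window,
#' 50% overlap, per-segment mean removal) are summed per frequency bin,
#' normalized to a probability vector, and the Shannon entropy of that
#' vector is normalized by `log2` of the number of frequency bins
#' (`floor(nperseg / 2) + 1`). Values near 1 indicate an unstructured, flat
#' spectrum.
#'
#' @param dx,dy Difference coordinates, uniformly sampled.
#' @param nperseg Welch segment length (default 32); shrunk to the series
#'   length (with a message) when the series is shorter.
#' @return Normalized entropy in `[0, 1]`; `NA` for series shorter than 4
#'   samples; 0 by convention for a spectrally empty (constant) signal.
#' @export
spectral_entropy <- function(dx, dy, nperseg = 32) {
  stopifnot(length(dx) == length(dy))
  n <- length(dx)
  if (n < 4) {
    inform("series shorter than 4 samples; spectral entropy missing")
    return(NA_real_)
  }
  if (n < nperseg) {
    inform(sprintf("series length %d < nperseg %d; shrinking segment", n,
                   nperseg))
    nperseg <- n
  }
  p <- welch_psd(dx, nperseg) + welch_psd(dy, nperseg)
  if (sum(p) == 0) {
    inform("spectrally empty signal; entropy 0")
    return(0)
  }
  p <- p / sum(p)
  shannon_bits(p) / log2(length(p))
}

# Welch average periodogram, one-sided, Hann (periodic) window, 50% overlap,
# per-segment mean detrend. Absolute scale is irrelevant downstream (the PSD
# is renormalized to a probability vector).
welch_psd <- function(x, nperseg) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    pg <- Mod(fft(seg))^2
    acc <- acc + pg[seq_len(nf)]
  }
  acc / length(starts)
}
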