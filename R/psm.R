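# ---- dimensionality of the phase space -------------------------------------

#' Correlation-scale PCA eigenspectrum of a micro-stage matrix
#'
#' Runs a principal component analysis with the micro-stage columns as
#' variables and the neurons (rows) as observations, on the correlation
#' matrix (every column standardized) — the scale presupposed by the
#' eigenvalue-greater-than-1 retention rule. Columns with (numerically)
#' zero variance carry no correlation information; they are dropped with a
#' warning and the explained proportions are renormalized over the
#' retained columns.
#'
#' @param m Numeric matrix, observations x variables (for micro-stage
#'   matrices: neurons x micro-stages).
#' @param tol Variance tolerance below which a column counts as constant.
#' @return An object of class `eigen_spectrum`: `eigenvalues`
#'   (non-increasing, correlation scale), `explained` (proportions summing
#'   to 1), `n_components`, `n_dropped`, and the provenance attributes of
#'   `m` if present.
#' @export
pca_eigenspectrum <- function(m, tol = 1e-12) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  v <- apply(m, 2, stats::var)
  keep <- v > tol
  if (sum(keep) < 2L) {
    stop("fewer than 2 non-constant columns; eigenspectrum is degenerate")
  }
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance column(s) dropped before PCA")
    m <- m[, keep, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  structure(
    list(eigenvalues = ev, explained = ev / sum(ev),
         n_components = length(ev), n_dropped = sum(!keep),
         letter = attr(m, "letter"), network_id = attr(m, "network_id")),
    class = "eigen_spectrum"
  )
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf(
    "<eigen_spectrum> %d components; PC1-2 explain %.1f%%, eigenvalues > 1: %d\n",
    x$n_components, 100 * sum(x$explained[1:2]), sum(x$eigenvalues > 1)))
  invisible(x)
}

#' @export
plot.eigen_spectrum <- function(x, n = 10, ...) {
  k <- seq_len(min(n, x$n_components))
  graphics::plot(k, x$eigenvalues[k], type = "b", xlab = "component",
                 ylab = "eigenvalue", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Weight of the primary and secondary dimensions
#'
#' Condenses an eigenspectrum into the two dimensionality indicators of
#' the phase-space-of-meaning analysis: `wght_pd`, the proportion of
#' variance explained jointly by the first two principal components (the
#' primary, affect-like dimensions), and `wght_sd`, the variance explained
#' by components 3 through 6 (the secondary, information-oriented
#' dimensions; the upper index follows the Kaiser-like median cutoff, see
#' [kaiser_median_cutoff()]). Spectra with fewer than 6 components are
#' padded with zero explained variance.
#'
#' @param spectrum An `eigen_spectrum`.
#' @param primary,secondary Component index ranges (defaults 1:2 and 3:6).
#' @return A list of class `dim_indicators` with `wght_pd`, `wght_sd`,
#'   `n_eigen_gt1`, and provenance (`letter`, `network_id`).
#' @export
dimensionality_indicators <- function(spectrum, primary = 1:2,
                                      secondary = 3:6) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  ex <- spectrum$explained
  pad <- max(primary, secondary) - length(ex)
  if (pad > 0) ex <- c(ex, numeric(pad))
  structure(
    list(wght_pd = sum(ex[primary]), wght_sd = sum(ex[secondary]),
         n_eigen_gt1 = sum(spectrum$eigenvalues > 1),
         letter = spectrum$letter, network_id = spectrum$network_id),
    class = "dim_indicators"
  )
}

#' @export
print.dim_indicators <- function(x, ...) {
  cat(sprintf("<dim_indicators> wght_pd %.3f, wght_sd %.3f (eigenvalues > 1: %d)\n",
              x$wght_pd, x$wght_sd, x$n_eigen_gt1))
  invisible(x)
}

#' Kaiser-like median cutoff over a collection of eigenspectra
#'
#' For each spectrum, counts the components whose correlation-scale
#' eigenvalue exceeds 1; returns the median count over the collection —
#' the last factor with an eigenvalue above 1 in at least half of the
#' PCAs. For even-length collections the lower median is taken, so the
#' cutoff is always one of the observed counts.
#'
#' @param spectra A list of `eigen_spectrum` objects.
#' @return Integer component index.
#' @export
kaiser_median_cutoff <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  counts <- vapply(spectra, function(s) {
    stopifnot(inherits(s, "eigen_spectrum"))
    sum(s$eigenvalues > 1)
  }, integer(1))
  sorted <- sort(counts)
  sorted[floor((length(sorted) + 1) / 2)]       # lower median
}

#' Lower quantile of the two-component explained variance
#'
#' Computes `wght_pd` (variance explained by the first two components)
#' for every spectrum and returns its `q`-th quantile with linear
#' interpolation — e.g. `q = 0.05` gives the level that 95% of the PCAs
#' reach or exceed, the robust floor used to justify the primary-dimension
#' indices.
#'
#' @param spectra A list of `eigen_spectrum` objects.
#' @param q Quantile level (default 0.05).
#' @return The quantile of `wght_pd`, a proportion in [0, 1].
#' @export
quantile_profile <- function(spectra, q = 0.05) {
  stopifnot(length(spectra) >= 1L, q >= 0, q <= 1)
  wpd <- vapply(spectra, function(s) {
    dimensionality_indicators(s)$wght_pd
  }, numeric(1))
  unname(stats::quantile(wpd, probs = q, type = 7))
}
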