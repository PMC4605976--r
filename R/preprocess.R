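#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution in a set of spectra. Following the standard
#' dialect, each spectrum is first normalized to a common total integral,
#' the reference is taken as the pointwise median (or mean) of the
#' integral-normalized set, and each spectrum is then divided by the median
#' of its pointwise quotients against that reference. The factor returned
#' per sample is the combined divisor, so
#' `out$intensities[i, ] == in$intensities[i, ] / out$factors[i]`.
#'
#' Because both set-level constants (the median total and the pointwise
#' reference) are robust statistics of the input set, rescaling a single
#' spectrum leaves its corrected output exactly unchanged as long as the
#' rescaling does not move the spectrum across the median total; crossing
#' it perturbs the reference slightly, as with any data-driven PQN
#' reference.
#'
#' @param spectra a [generate_spectra()] `spectrum_set`, or a plain numeric
#'   matrix of non-negative intensities (samples in rows).
#' @param reference `"median"` (default) or `"mean"` reference spectrum.
#' @return A `spectrum_set` (or matrix, matching the input) with an added
#'   `factors` element of per-sample quotient factors.
#' @export
pqn_normalize <- function(spectra, reference = c("median", "mean")) {
  reference <- match.arg(reference)
  mat_in <- !inherits(spectra, "spectrum_set")
  X <- if (mat_in) as.matrix(spectra) else spectra$intensities
  if (nrow(X) < 2L) stop("PQN needs at least two spectra", call. = FALSE)
  if (any(X < 0)) stop("intensities must be non-negative", call. = FALSE)
  totals <- rowSums(X)
  if (any(totals <= 0)) {
    stop("all-zero spectrum: quotients undefined for sample(s) ",
         paste(which(totals <= 0), collapse = ", "), call. = FALSE)
  }
  t_ref <- median(totals)
  Xi <- X * (t_ref / totals)          # total-integral normalization
  ref <- if (reference == "median") apply(Xi, 2, median) else colMeans(Xi)
  use <- ref > 0
  if (!any(use)) {
    stop("reference spectrum has no positive entries", call. = FALSE)
  }
  q <- apply(Xi[, use, drop = FALSE], 1, function(s) median(s / ref[use]))
  factors <- (totals / t_ref) * q
  Xout <- X / factors
  if (mat_in) {
    attr(Xout, "factors") <- factors
    return(Xout)
  }
  out <- spectra
  out$intensities <- Xout
  out$factors <- factors
  out
}

#' Equal-width spectral binning
#'
#' Reduces a spectrum (or a set of spectra sharing one axis) to contiguous
#' equal-width bins; each bin value is the sum of the intensities of the
#' points falling in it, so the total integral is conserved exactly. Bins
#' are anchored at the maximum ppm of the axis and the last (possibly
#' partial) bin is kept, giving `ceiling(range / width)` bins.
#'
#' @param ppm chemical-shift axis, strictly monotone (either direction).
#' @param intensities numeric vector (one spectrum) or matrix with
#'   `length(ppm)` columns.
#' @param bin_width bin width in ppm, `0 < bin_width <= range(ppm)`.
#' @return A vector (or matrix) of bin integrals, names giving bin centers,
#'   ordered from high to low ppm.
#' @export
bin_spectrum <- function(ppm, intensities, bin_width) {
  stopifnot(is.numeric(ppm), length(ppm) >= 2L, bin_width > 0)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  rng <- max(ppm) - min(ppm)
  if (bin_width > rng) {
    stop("bin_width exceeds the axis range", call. = FALSE)
  }
  nb <- ceiling(rng / bin_width)
  # bin k (1-based) covers (max - k*w, max - (k-1)*w]; anchor at max ppm.
  # The 1e-9 guard keeps points lying exactly on a bin edge (up to float
  # rounding) in the bin whose closed upper edge they sit on.
  k <- floor((max(ppm) - ppm) / bin_width + 1e-9) + 1L
  k[k > nb] <- nb  # the point at min ppm lands in the last bin
  centers <- max(ppm) - (seq_len(nb) - 0.5) * bin_width
  one <- function(s) {
    out <- vapply(seq_len(nb), function(j) sum(s[k == j]), numeric(1))
    names(out) <- sprintf("%.4f", centers)
    out
  }
  if (is.matrix(intensities)) {
    stopifnot(ncol(intensities) == length(ppm))
    t(apply(intensities, 1, one))
  } else {
    stopifnot(length(intensities) == length(ppm))
    one(intensities)
  }
}

#' Autoscale a matrix or metabolite table
#'
#' Centers every variable to mean zero and scales it to unit standard
#' deviation. Without `params` the means and SDs are estimated on the given
#' rows (the model set) and returned; with `params` the stored statistics
#' are applied unchanged, which is how test-set and out-of-bag samples must
#' be projected to avoid information leakage.
#'
#' @param x numeric matrix or [metabolite_table()].
#' @param params a `scaling_params` object from a previous fit, or `NULL`
#'   to fit on `x`.
#' @return A list with `values` (scaled matrix, or `metab_table` when the
#'   input was one) and `params` (`scaling_params`: `mean`, `sd` per
#'   variable).
#' @export
autoscale <- function(x, params = NULL) {
  is_mt <- inherits(x, "metab_table")
  X <- if (is_mt) x$values else as.matrix(x)
  if (is.null(params)) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    zero <- sdev < 1e-12
    if (any(zero)) {
      stop("zero-variance variable(s) on fit: ",
           paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
    }
    params <- structure(list(mean = mu, sd = sdev),
                        class = "scaling_params")
  } else {
    stopifnot(inherits(params, "scaling_params"))
    if (!identical(colnames(X), names(params$mean))) {
      if (!all(colnames(X) %in% names(params$mean))) {
        stop("variables of `x` do not match the scaling parameters",
             call. = FALSE)
      }
      params <- structure(list(mean = params$mean[colnames(X)],
                               sd = params$sd[colnames(X)]),
                          class = "scaling_params")
    }
  }
  Z <- sweep(sweep(X, 2, params$mean), 2, params$sd, `/`)
  if (is_mt) {
    out <- x
    out$values <- Z
    list(values = out, params = params)
  } else {
    list(values = Z, params = params)
  }
}

#' Invert autoscaling
#'
#' @param z scaled matrix.
#' @param params the `scaling_params` used to scale.
#' @return The matrix on the original scale.
#' @export
unscale <- function(z, params) {
  stopifnot(inherits(params, "scaling_params"))
  sweep(sweep(as.matrix(z), 2, params$sd, `*`), 2, params$mean, `+`)
}
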