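# Raw images -> illuminance maps.  The radiometric calibration experiment
# itself is out of scope; this module consumes its result (a monotone
# camera response) and inverts it, then optionally pre-filters the maps
# (Gaussian for white noise, median for salt-and-pepper), mirroring the
# image post-processing of the physical rig.  The synthetic pipeline uses
# the linear response: simulated pixel intensity is proportional to
# illuminance by construction.

#' Camera radiometric response model
#'
#' Maps linear illuminance in \[0, 1\] to encoded pixel values in \[0, 1\].
#' `to_illuminance()` applies the inverse.
#'
#' @param kind `"linear"`, `"gamma"` (encoded = linear^(1/gamma)) or `"lut"`.
#' @param gamma Exponent for the gamma kind (display-style, e.g. 2.2).
#' @param lut For the lut kind, a data frame or list with numeric `linear`
#'   and `encoded`, both strictly increasing (a sampled forward response).
#' @return An object of class `response_model`.
#' @export
response_model <- function(kind = c("linear", "gamma", "lut"), gamma = 2.2,
                           lut = NULL) {
  kind <- match.arg(kind)
  if (kind == "gamma") stopifnot(gamma > 0)
  if (kind == "lut") {
    stopifnot(!is.null(lut), length(lut$linear) == length(lut$encoded))
    if (any(diff(lut$linear) <= 0) || any(diff(lut$encoded) <= 0)) {
      stop("non-monotone LUT rejected: response must be strictly increasing")
    }
  }
  structure(list(kind = kind, gamma = gamma, lut = lut),
            class = "response_model")
}

#' Invert the camera response: raw image to illuminance map
#'
#' @param raw Matrix or array of raw pixel values.  Values are normalised by
#'   `2^bit_depth - 1` when `bit_depth` is given, otherwise assumed already
#'   in \[0, 1\].
#' @param model A [response_model()].
#' @param bit_depth Integer bit depth of `raw` (e.g. 8 or 16), or `NULL`.
#' @return Float illuminance map, same shape as `raw`.  The mapping is
#'   monotone, so pixel ordering is preserved.
#' @export
to_illuminance <- function(raw, model = response_model("linear"),
                           bit_depth = NULL) {
  v <- if (is.null(bit_depth)) raw else raw / (2^bit_depth - 1)
  out <- switch(model$kind,
    linear = v,
    gamma = sign(v) * abs(v)^model$gamma,
    lut = {
      z <- stats::approx(model$lut$encoded, model$lut$linear, xout = as.vector(v),
                         rule = 2)$y
      array(z, dim = dim(v) %||% length(v))
    }
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a matrix by (dr, dc) with replicate padding.
shift_pad <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1), w)
  m[ri, ci, drop = FALSE]
}

#' Gaussian blur with a sampled separable kernel
#'
#' Replicate padding at the borders; the kernel is `dnorm` sampled on
#' integer offsets within 3 sigma and renormalised, so a constant image is
#' unchanged.
#'
#' @param img Float matrix.
#' @param sigma Standard deviation in pixels.
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  out <- img * 0
  for (i in seq_along(k)) out <- out + k[i] * shift_pad(img, i - r - 1L, 0L)
  out2 <- out * 0
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_pad(out, 0L, i - r - 1L)
  out2
}

#' Square median filter
#'
#' @param img Float matrix.
#' @param size Odd window size (default 3).
#' @return Filtered matrix (replicate padding at the borders).
#' @export
median_filter <- function(img, size = 3) {
  stopifnot(size %% 2 == 1)
  r <- (size - 1L) / 2L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  stk <- array(NA_real_, c(nrow(img), ncol(img), nrow(offs)))
  for (i in seq_len(nrow(offs))) {
    stk[, , i] <- shift_pad(img, offs$dr[i], offs$dc[i])
  }
  apply(stk, c(1, 2), stats::median)
}

#' Denoise an illuminance map
#'
#' Gaussian blur (white noise) followed by a median filter (salt-and-pepper
#' noise), the pre-filtering used before the photometric computations.  The
#' order and defaults are package choices; both stages are configurable and
#' either can be disabled.
#'
#' @param img Float illuminance matrix.
#' @param sigma Gaussian sigma in pixels (0 disables). Default 1.
#' @param median_size Median window (0 or 1 disables). Default 3.
#' @return Filtered matrix.
#' @export
denoise_illuminance <- function(img, sigma = 1, median_size = 3) {
  out <- gaussian_blur(img, sigma)
  if (median_size >= 3) out <- median_filter(out, median_size)
  out
}
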