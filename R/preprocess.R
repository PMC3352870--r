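#' Denoising parameters
#'
#' OCT B-scans carry strong multiplicative speckle noise; before layer
#' detection each B-scan is cleaned with a median filter (impulse/speckle
#' suppression) followed by Gaussian smoothing. Both stages are optional and
#' parameter-light.
#'
#' @param median_window odd window width in pixels (default 3).
#' @param gaussian_sigma Gaussian smoothing scale in pixels (default 1.5).
#' @param stages ordered subset of `c("median", "gaussian")`.
#' @return A list of class `denoise_params`.
#' @export
denoise_params <- function(median_window = 3L, gaussian_sigma = 1.5,
                           stages = c("median", "gaussian")) {
  median_window <- as.integer(median_window)
  if (median_window < 1L || median_window %% 2L == 0L) {
    onh_error("onhquant_parameter_error", "median_window must be odd and >= 1")
  }
  if (gaussian_sigma < 0) {
    onh_error("onhquant_parameter_error", "gaussian_sigma must be >= 0")
  }
  stages <- intersect(stages, c("median", "gaussian"))
  structure(list(median_window = median_window,
                 gaussian_sigma = gaussian_sigma,
                 stages = stages), class = "denoise_params")
}

# Separable Gaussian convolution with reflect padding. Kernel truncated at
# 3 sigma and renormalized, so output is a convex combination of inputs and
# stays inside the input range.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  sep_conv_cpp(img, k)
}

#' Denoise one B-scan
#'
#' Applies the enabled stages of `params` in order: median filtering with
#' reflect border padding, then Gaussian smoothing. Shape and the \[0, 1\]
#' intensity range are preserved; with all stages disabled the input is
#' returned unchanged.
#'
#' @param bscan numeric matrix with intensities in \[0, 1\].
#' @param params a [denoise_params] object.
#' @return A matrix of the same shape.
#' @export
denoise_bscan <- function(bscan, params = denoise_params()) {
  stopifnot(is.matrix(bscan), is.numeric(bscan))
  if (!inherits(params, "denoise_params")) {
    params <- do.call(denoise_params, params)
  }
  out <- bscan
  for (stage in params$stages) {
    if (stage == "median" && params$median_window > 1L) {
      out <- median_filter_cpp(out, params$median_window)
    } else if (stage == "gaussian" && params$gaussian_sigma > 0) {
      out <- gaussian_blur(out, params$gaussian_sigma)
    }
  }
  pmin(pmax(out, 0), 1)
}
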