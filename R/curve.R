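#' Construct a reflectivity curve
#'
#' A specular reflectivity measurement or simulation: vertical momentum
#' transfer `qz`, the reflected intensity ratio `reflectivity` (either raw R
#' or Fresnel-normalized R/R_F), and its one-standard-deviation uncertainty
#' `sigma`.
#'
#' @param qz momentum transfer, inverse Angstrom; strictly increasing, > 0
#' @param reflectivity intensity ratio per point, > 0
#' @param sigma 1-sigma uncertainty per point, > 0
#' @param normalized logical; `TRUE` if values are R/R_F
#' @param wavelength X-ray wavelength, Angstrom (metadata)
#' @param sample optional sample label (metadata)
#' @param seed optional generator seed (metadata)
#' @return an object of class `xr_curve`
#' @export
reflectivity_curve <- function(qz, reflectivity, sigma,
                               normalized = FALSE, wavelength = 1.24,
                               sample = NULL, seed = NULL) {
    qz <- as.numeric(qz); reflectivity <- as.numeric(reflectivity)
    sigma <- as.numeric(sigma)
    n <- length(qz)
    if (length(reflectivity) != n || length(sigma) != n)
        stop("qz, reflectivity and sigma must have equal length")
    if (n < 1 || any(!is.finite(qz)) || any(qz <= 0))
        stop("`qz` must be finite and > 0")
    if (any(diff(qz) <= 0))
        stop("`qz` must be strictly increasing")
    if (any(!is.finite(reflectivity)) || any(reflectivity <= 0))
        stop("`reflectivity` must be finite and > 0")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
        stop("`sigma` must be finite and > 0")
    structure(list(qz = qz, reflectivity = reflectivity, sigma = sigma,
                   normalized = isTRUE(normalized),
                   wavelength = wavelength, sample = sample,
                   seed = if (is.null(seed)) NULL else as.integer(seed)),
              class = "xr_curve")
}

#' @export
print.xr_curve <- function(x, ...) {
    cat(sprintf("<xr_curve> %d points, qz %.4g..%.4g A^-1, %s%s\n",
                length(x$qz), min(x$qz), max(x$qz),
                if (x$normalized) "R/R_F (Fresnel-normalized)" else "raw R",
                if (!is.null(x$sample)) paste0(", sample ", x$sample) else ""))
    invisible(x)
}

#' @export
as.data.frame.xr_curve <- function(x, ...) {
    data.frame(qz = x$qz, reflectivity = x$reflectivity, sigma = x$sigma)
}

#' @export
length.xr_curve <- function(x) length(x$qz)

#' Fresnel-normalize a reflectivity curve
#'
#' Divides reflectivity and its uncertainty pointwise by the Fresnel
#' reflectivity of the ideal sharp fronting/backing interface (air/water by
#' default). Round-trips with [denormalize_from_fresnel()] to machine
#' precision.
#'
#' @param curve an [reflectivity_curve()] with `normalized = FALSE`
#' @param backing_sld,fronting_sld SLDs of the bounding media
#' @return the normalized curve (`normalized = TRUE`)
#' @export
normalize_to_fresnel <- function(curve,
                                 backing_sld = xr_constants$sld_water,
                                 fronting_sld = 0) {
    stopifnot(inherits(curve, "xr_curve"))
    if (curve$normalized)
        stop("curve is already Fresnel-normalized")
    rf <- fresnel_reflectivity(curve$qz, backing_sld, fronting_sld)
    out <- curve
    out$reflectivity <- curve$reflectivity / rf
    out$sigma <- curve$sigma / rf
    out$normalized <- TRUE
    out
}

#' Undo Fresnel normalization
#'
#' @inheritParams normalize_to_fresnel
#' @export
denormalize_from_fresnel <- function(curve,
                                     backing_sld = xr_constants$sld_water,
                                     fronting_sld = 0) {
    stopifnot(inherits(curve, "xr_curve"))
    if (!curve$normalized)
        stop("curve is not Fresnel-normalized")
    rf <- fresnel_reflectivity(curve$qz, backing_sld, fronting_sld)
    out <- curve
    out$reflectivity <- curve$reflectivity * rf
    out$sigma <- curve$sigma * rf
    out$normalized <- FALSE
    out
}

#' @export
plot.xr_curve <- function(x, ..., main = NULL) {
    ylab <- if (x$normalized) expression(R / R[F]) else "R"
    graphics::plot(x$qz, x$reflectivity, log = if (x$normalized) "" else "y",
                   xlab = expression(q[z] ~ (ring(A)^-1)), ylab = ylab,
                   pch = 16, cex = 0.6, main = main, ...)
    graphics::segments(x$qz, x$reflectivity - x$sigma,
                       x$qz, x$reflectivity + x$sigma, col = "grey50")
    invisible(x)
}
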