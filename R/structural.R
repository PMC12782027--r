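# Structural metrics derived from fitted monolayer models: oxidation-
# induced tail shortening, headgroup density change, and electron-counting
# consistency checks.

fit_or_model <- function(x) {
    if (inherits(x, "xr_slab_fit")) x$model
    else if (inherits(x, "slab_model")) x
    else stop("expected an xr_slab_fit or slab_model")
}

param_error_of <- function(x, name) {
    if (inherits(x, "xr_slab_fit") && name %in% names(x$param_errors))
        x$param_errors[[name]]
    else NA_real_
}

#' Compare before/after monolayer structures
#'
#' Computes the oxidation metrics from two fitted two-layer models: tail
#' shortening (before minus after tail thickness, in Angstrom and as a
#' percentage of the before value), headgroup density change, and subphase
#' roughness change. When fit objects are supplied, uncertainties are
#' propagated in quadrature from the per-parameter errors.
#'
#' @param before,after `xr_slab_fit` or [slab_model()] objects with the
#'   same number of layers (tails first, heads second)
#' @param labels optional character pair naming the two states
#' @return an object of class `xr_structural_comparison`
#' @examples
#' compare_models(reference_model("SAPC"), reference_model("SAPC+15-LOX-2"))
#' @export
compare_models <- function(before, after, labels = NULL) {
    mb <- fit_or_model(before); ma <- fit_or_model(after)
    if (length(mb$layers) != length(ma$layers))
        stop("models have different layer counts")
    if (length(mb$layers) < 2)
        stop("comparison needs two-layer (tails/heads) models")
    tb <- mb$layers[[1]]$thickness; ta <- ma$layers[[1]]$thickness
    shortening <- tb - ta
    pct <- 100 * shortening / tb
    se_tb <- param_error_of(before, "tails.thickness")
    se_ta <- param_error_of(after, "tails.thickness")
    se_short <- sqrt(se_tb^2 + se_ta^2)
    # d(pct)/d(tb) = 100*ta/tb^2 ; d(pct)/d(ta) = -100/tb
    se_pct <- sqrt((100 * ta / tb^2 * se_tb)^2 + (100 / tb * se_ta)^2)
    hb <- mb$layers[[2]]$rho_rel; ha <- ma$layers[[2]]$rho_rel
    se_h <- sqrt(param_error_of(before, "heads.rho_rel")^2 +
                     param_error_of(after, "heads.rho_rel")^2)
    sr <- ma$subphase_roughness - mb$subphase_roughness
    se_sr <- sqrt(param_error_of(before, "subphase.roughness")^2 +
                      param_error_of(after, "subphase.roughness")^2)
    if (is.null(labels)) {
        lb <- if (inherits(before, "xr_slab_fit")) before$curve$sample else NULL
        la <- if (inherits(after, "xr_slab_fit")) after$curve$sample else NULL
        labels <- c(if (is.null(lb)) "before" else lb,
                    if (is.null(la)) "after" else la)
    }
    structure(list(tail_shortening_A = shortening,
                   tail_shortening_pct = pct,
                   head_rho_change = ha - hb,
                   subphase_roughness_change = sr,
                   se = c(tail_shortening_A = se_short,
                          tail_shortening_pct = se_pct,
                          head_rho_change = se_h,
                          subphase_roughness_change = se_sr),
                   labels = labels,
                   tail_before = tb, tail_after = ta),
              class = "xr_structural_comparison")
}

#' @export
print.xr_structural_comparison <- function(x, ...) {
    fmt <- function(v, e) if (is.na(e)) sprintf("%.3g", v)
                          else sprintf("%.3g +/- %.2g", v, e)
    cat(sprintf("<xr_structural_comparison> %s -> %s\n",
                x$labels[1], x$labels[2]))
    cat("  tail shortening:  ",
        fmt(x$tail_shortening_A, x$se[["tail_shortening_A"]]), "A  (",
        fmt(x$tail_shortening_pct, x$se[["tail_shortening_pct"]]), "% )\n",
        sep = "")
    cat("  headgroup rho/rho_water change: ",
        fmt(x$head_rho_change, x$se[["head_rho_change"]]), "\n", sep = "")
    cat("  subphase roughness change:      ",
        fmt(x$subphase_roughness_change,
            x$se[["subphase_roughness_change"]]), " A\n", sep = "")
    invisible(x)
}

#' Relative electron density from an electron count
#'
#' Converts the number of electrons per molecule in a layer, the area per
#' molecule and the layer thickness into electron density relative to
#' water: `(n_electrons / (area * thickness)) / 0.334`.
#'
#' @param n_electrons electrons per molecule in the layer
#' @param area_per_molecule square Angstrom
#' @param layer_thickness Angstrom
#' @return rho/rho_water (dimensionless)
#' @examples
#' rho_from_electron_count(10, 1, 29.94)   # bulk water, ~1
#' @export
rho_from_electron_count <- function(n_electrons, area_per_molecule,
                                    layer_thickness) {
    if (any(n_electrons <= 0) || any(area_per_molecule <= 0) ||
        any(layer_thickness <= 0))
        stop("all inputs must be > 0")
    (n_electrons / (area_per_molecule * layer_thickness)) /
        xr_constants$rho_water_abs
}

#' Tail/headgroup layer distinction of a density profile
#'
#' Measures how clearly the headgroup density maximum stands out from the
#' lipid-tail plateau: `(head peak rho - tail plateau mean rho) / head peak
#' rho`. The head peak is the profile maximum within +/-10 Angstrom of
#' z = 0 (the headgroup center); the tail plateau mean is taken over the
#' central half of the tail layer, located either from `tail_bounds` or
#' automatically from the two steepest descents on the air side of the
#' peak.
#'
#' @param profile a [density_profile()]
#' @param tail_bounds optional `c(z_lower, z_upper)` of the tail layer,
#'   Angstrom; when `NULL` the bounds are detected from the profile
#' @return scalar in \[0, 1\] for physical monolayer profiles
#' @export
layer_distinction <- function(profile, tail_bounds = NULL) {
    stopifnot(inherits(profile, "density_profile"))
    z <- profile$z; rho <- profile$rho_rel
    win <- which(abs(z) <= 10)
    if (length(win) < 3) stop("profile does not cover the headgroup region")
    ipk <- win[which.max(rho[win])]
    pk <- rho[ipk]
    # a real head maximum must rise above both neighbours of the window
    if (pk - max(rho[min(win)], rho[max(win)]) < 1e-3 ||
        diff(range(rho)) < 1e-6)
        stop("no detectable headgroup maximum (degenerate profile)")
    if (is.null(tail_bounds)) {
        up <- which(z > z[ipk])
        if (length(up) < 5) stop("no tail region above the headgroup peak")
        d <- diff(rho[up]) / (z[2] - z[1])
        # local minima of the derivative = interface descents
        locmin <- which(diff(sign(diff(d))) > 0) + 1
        locmin <- locmin[d[locmin] < 0.2 * min(d)]
        if (length(locmin) >= 2) {
            z_ht <- z[up[locmin[1]]]
            z_ta <- z[up[locmin[length(locmin)]]]
        } else if (length(locmin) == 1) {
            z_ht <- z[ipk]
            z_ta <- z[up[locmin[1]]]
        } else stop("could not locate tail-layer interfaces")
        tail_bounds <- c(z_ht, z_ta)
    }
    w <- diff(tail_bounds)
    mid <- mean(tail_bounds)
    sel <- z >= mid - w / 4 & z <= mid + w / 4
    if (!any(sel)) stop("tail bounds select no grid points")
    (pk - mean(rho[sel])) / pk
}
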