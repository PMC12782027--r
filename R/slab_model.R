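#' Define a slab (box) layer
#'
#' One homogeneous layer of a slab model: its thickness, its electron
#' density relative to water, and the error-function roughness of its upper
#' (air-side) interface.
#'
#' @param thickness layer thickness, Angstrom, >= 0
#' @param rho_rel electron density relative to water, >= 0
#' @param roughness error-function width (Gaussian sigma) of the layer's
#'   air-side interface, Angstrom, >= 0
#' @param fixed character vector of fields held constant during fitting;
#'   subset of `c("thickness", "rho_rel", "roughness")`
#' @return an object of class `xr_layer`
#' @export
layer <- function(thickness, rho_rel, roughness, fixed = character()) {
    if (thickness < 0 || rho_rel < 0 || roughness < 0)
        stop("layer thickness, rho_rel and roughness must be >= 0")
    bad <- setdiff(fixed, c("thickness", "rho_rel", "roughness"))
    if (length(bad))
        stop("unknown fixed field(s): ", paste(bad, collapse = ", "))
    structure(list(thickness = thickness, rho_rel = rho_rel,
                   roughness = roughness, fixed = fixed),
              class = "xr_layer")
}

#' Construct a slab model of an interfacial film
#'
#' An ordered stack: semi-infinite fronting medium (air), N layers with the
#' first adjacent to air, and a semi-infinite subphase (water) whose
#' interface with the deepest layer carries its own roughness.
#'
#' @param layers list of [layer()] objects, index 1 adjacent to air
#' @param subphase_roughness Angstrom; roughness of the deepest
#'   layer/subphase interface
#' @param layer_names optional names (e.g. `c("tails", "heads")`); defaults
#'   to `tails`/`heads` for two-layer models, `layer1..N` otherwise
#' @param fronting_rho_rel relative density of the fronting medium (air = 0)
#' @param subphase_rho_rel relative density of the subphase (water = 1)
#' @param scale multiplicative intensity factor (default 1)
#' @param background additive constant reflectivity (default 0)
#' @return an object of class `slab_model`
#' @export
slab_model <- function(layers, subphase_roughness, layer_names = NULL,
                       fronting_rho_rel = 0, subphase_rho_rel = 1,
                       scale = 1, background = 0) {
    if (inherits(layers, "xr_layer")) layers <- list(layers)
    stopifnot(all(vapply(layers, inherits, TRUE, "xr_layer")))
    if (subphase_roughness < 0) stop("subphase_roughness must be >= 0")
    if (fronting_rho_rel < 0 || subphase_rho_rel < 0)
        stop("bounding medium densities must be >= 0")
    n <- length(layers)
    if (is.null(layer_names))
        layer_names <- if (n == 2) c("tails", "heads")
                       else if (n == 0) character(0)
                       else paste0("layer", seq_len(n))
    if (length(layer_names) != n || anyDuplicated(layer_names))
        stop("layer_names must be unique and match the number of layers")
    names(layers) <- layer_names
    structure(list(layers = layers,
                   subphase_roughness = subphase_roughness,
                   fronting_rho_rel = fronting_rho_rel,
                   subphase_rho_rel = subphase_rho_rel,
                   scale = scale, background = background),
              class = "slab_model")
}

#' @export
print.slab_model <- function(x, ...) {
    cat(sprintf("<slab_model> %d layer(s), fronting rho %.3g, subphase rho %.3g\n",
                length(x$layers), x$fronting_rho_rel, x$subphase_rho_rel))
    for (nm in names(x$layers)) {
        l <- x$layers[[nm]]
        cat(sprintf("  %-8s d = %6.2f A  rho/rho_w = %5.3f  sigma = %5.2f A%s\n",
                    nm, l$thickness, l$rho_rel, l$roughness,
                    if (length(l$fixed))
                        paste0("  [fixed: ", paste(l$fixed, collapse = ","), "]")
                    else ""))
    }
    cat(sprintf("  subphase roughness = %.2f A; scale = %g, background = %g\n",
                x$subphase_roughness, x$scale, x$background))
    invisible(x)
}

# Interface geometry in depth coordinates (s increasing from air into the
# subphase, s = 0 at the air/layer-1 interface). Returns positions,
# roughnesses and the densities above/below each interface.
slab_interfaces <- function(model) {
    th <- vapply(model$layers, `[[`, 0, "thickness")
    n <- length(th)
    s <- c(0, cumsum(th))                       # n + 1 interfaces
    rho <- c(model$fronting_rho_rel,
             vapply(model$layers, `[[`, 0, "rho_rel"),
             model$subphase_rho_rel)
    sig <- c(vapply(model$layers, `[[`, 0, "roughness"),
             model$subphase_roughness)
    list(s = s, sigma = sig, rho_above = rho[seq_len(n + 1)],
         rho_below = rho[seq_len(n + 1) + 1])
}

#' Electron-density profile of a slab model
#'
#' Smears each interface of the stack with an error function of its
#' roughness and sums the steps into a continuous relative electron-density
#' profile rho(z)/rho_water. The depth axis has air at large positive z,
#' subphase at large negative z, and z = 0 at the midpoint of the headgroup
#' layer (the deepest layer by default).
#'
#' @param model a [slab_model()]
#' @param dz grid step, Angstrom
#' @param pad Angstrom of bulk medium kept on each side of the film; should
#'   be at least 3 times the largest roughness
#' @param center_layer index or name of the layer whose midpoint defines
#'   z = 0; default the deepest (headgroup) layer
#' @return an object of class `density_profile` with fields `z`, `rho_rel`
#' @export
slab_to_profile <- function(model, dz = 0.25, pad = 20,
                            center_layer = length(model$layers)) {
    stopifnot(inherits(model, "slab_model"), dz > 0, pad > 0)
    ifc <- slab_interfaces(model)
    maxsig <- max(ifc$sigma)
    if (pad < 3 * maxsig)
        warning("pad < 3 * max roughness; profile may not reach bulk density",
                call. = FALSE)
    n <- length(model$layers)
    if (is.character(center_layer))
        center_layer <- match(center_layer, names(model$layers))
    if (n > 0) {
        if (is.na(center_layer) || center_layer < 1 || center_layer > n)
            stop("invalid center_layer")
        s_mid <- (ifc$s[center_layer] + ifc$s[center_layer + 1]) / 2
    } else s_mid <- 0
    s_total <- ifc$s[length(ifc$s)]
    # z = s_mid - s: air side positive, subphase negative
    z <- seq(s_mid - s_total - pad, s_mid + pad, by = dz)
    rho <- rep(model$fronting_rho_rel, length(z))
    zi <- s_mid - ifc$s
    for (i in seq_along(zi)) {
        step <- ifc$rho_below[i] - ifc$rho_above[i]
        if (ifc$sigma[i] == 0) {
            rho <- rho + step * (z <= zi[i])
        } else {
            rho <- rho + step / 2 *
                (1 + erf((zi[i] - z) / (sqrt(2) * ifc$sigma[i])))
        }
    }
    density_profile(z, rho)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Construct a density profile
#'
#' @param z uniform increasing depth grid, Angstrom (air at positive z,
#'   subphase at negative z, z = 0 at the headgroup center)
#' @param rho_rel relative electron density at each z
#' @return object of class `density_profile`
#' @export
density_profile <- function(z, rho_rel) {
    z <- as.numeric(z); rho_rel <- as.numeric(rho_rel)
    if (length(z) != length(rho_rel)) stop("z and rho_rel length mismatch")
    if (length(z) > 2) {
        dd <- diff(z)
        if (any(dd <= 0)) stop("z must be strictly increasing")
        if (max(dd) - min(dd) > 1e-8 * mean(dd))
            stop("z grid must be uniform")
    }
    structure(list(z = z, rho_rel = rho_rel), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
    cat(sprintf("<density_profile> %d points, z %.4g..%.4g A, rho %.3g..%.3g\n",
                length(x$z), min(x$z), max(x$z),
                min(x$rho_rel), max(x$rho_rel)))
    invisible(x)
}

#' @export
as.data.frame.density_profile <- function(x, ...) {
    data.frame(z = x$z, rho_rel = x$rho_rel)
}

#' @export
plot.density_profile <- function(x, ..., xlab = "z (A)",
                                 ylab = expression(rho / rho[water])) {
    graphics::plot(x$z, x$rho_rel, type = "l", xlab = xlab, ylab = ylab, ...)
    invisible(x)
}
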