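#' Fresnel reflectivity of an ideal sharp interface
#'
#' Reflectivity of an infinitely sharp interface between two non-absorbing
#' media, used to normalize measured curves. Below the critical edge the
#' reflectivity is exactly 1 (total external reflection).
#'
#' @param qz momentum transfer, inverse Angstrom, > 0
#' @param backing_sld,fronting_sld SLD of the two media, inverse square
#'   Angstrom; defaults describe the bare air/water interface
#' @return reflectivity in (0, 1]
#' @export
fresnel_reflectivity <- function(qz, backing_sld = xr_constants$sld_water,
                                 fronting_sld = 0) {
    if (any(!is.finite(qz)) || any(qz <= 0))
        stop("`qz` must be finite and > 0")
    k0 <- qz / 2
    k1 <- sqrt(as.complex(k0^2 - 4 * pi * (backing_sld - fronting_sld)))
    Mod((k0 - k1) / (k0 + k1))^2
}

#' Construct a micro-slab stack
#'
#' Uniform discretization of a continuous SLD profile into thin slabs, the
#' carrier for the Parratt recursion. Slabs are ordered from the fronting
#' (air) side down to the backing (subphase).
#'
#' @param slab_sld SLD per micro-slab, inverse square Angstrom
#' @param slab_thickness slab thickness, Angstrom (scalar, uniform)
#' @param fronting_sld,backing_sld SLD of the semi-infinite media
#' @return object of class `microslab_stack`
#' @export
microslab_stack <- function(slab_sld, slab_thickness, fronting_sld,
                            backing_sld) {
    if (slab_thickness <= 0) stop("slab_thickness must be > 0")
    n <- length(slab_sld)
    if (n > 0) {
        contrast <- abs(backing_sld - fronting_sld)
        tol <- max(0.01 * contrast, 1e-12)
        if (abs(slab_sld[1] - fronting_sld) > tol ||
            abs(slab_sld[n] - backing_sld) > tol)
            stop("stack ends must be within 1% of the bounding media SLDs")
    }
    structure(list(slab_sld = as.numeric(slab_sld),
                   slab_thickness = slab_thickness,
                   fronting_sld = fronting_sld, backing_sld = backing_sld),
              class = "microslab_stack")
}

#' Parratt reflectivity of a micro-slab stack
#'
#' Exact specular reflectivity of a stratified medium by the recursive
#' Parratt scheme, evaluated from the backing upward. With no absorption,
#' R = 1 below the backing critical edge and 0 <= R <= 1 everywhere.
#'
#' @param stack a [microslab_stack()], or a list with fields `slab_sld`,
#'   `slab_thickness`, `fronting_sld`, `backing_sld`
#' @param qz momentum transfer, inverse Angstrom, > 0
#' @return reflectivity at each `qz`
#' @export
parratt_reflectivity <- function(stack, qz) {
    if (any(!is.finite(qz)) || any(qz <= 0))
        stop("`qz` must be finite and > 0")
    n <- length(stack$slab_sld)
    if (n == 0 && isTRUE(all.equal(stack$fronting_sld, stack$backing_sld))) {
        message("empty stack with no fronting/backing contrast: R = 0")
        return(rep(0, length(qz)))
    }
    d <- rep(stack$slab_thickness, length.out = n)
    .parratt_cpp(qz, stack$slab_sld, d, stack$fronting_sld, stack$backing_sld)
}

# Micro-slice a density profile into a stack. The profile's z axis has air
# at positive z; the stack is ordered air -> subphase, i.e. decreasing z.
# Leading/trailing slabs indistinguishable from the bulk media are trimmed.
profile_to_stack <- function(profile, fronting_rho = 0, subphase_rho = 1) {
    sld <- rho_rel_to_sld(rev(profile$rho_rel))   # air side first
    dz <- profile$z[2] - profile$z[1]
    f_sld <- rho_rel_to_sld(fronting_rho)
    b_sld <- rho_rel_to_sld(subphase_rho)
    tol <- 1e-9 * max(abs(b_sld - f_sld), 1e-12)
    keep <- which(abs(sld - f_sld) > tol | abs(sld - b_sld) > tol)
    nontrivial <- which(abs(sld - f_sld) > tol & abs(sld - b_sld) > tol)
    if (length(nontrivial) == 0)
        return(microslab_stack(numeric(0), dz, f_sld, b_sld))
    i0 <- max(1, min(nontrivial) - 2)
    i1 <- min(length(sld), max(nontrivial) + 2)
    sld <- sld[i0:i1]
    # force exact bulk termination so the stack invariant holds
    microslab_stack(sld, dz, f_sld, b_sld)
}

#' Reflectivity of a slab model
#'
#' Composes [slab_to_profile()] (error-function roughness), micro-slicing,
#' and [parratt_reflectivity()]; applies the model's intensity scale and
#' additive background. Models with all roughnesses zero are computed on the
#' sharp-interface stack directly (exact limit).
#'
#' @param model a [slab_model()]
#' @param qz momentum transfer grid, inverse Angstrom
#' @param dz micro-slab thickness for roughness discretization, Angstrom
#' @return reflectivity R at each `qz`
#' @export
reflectivity_from_slabs <- function(model, qz, dz = 0.25) {
    stopifnot(inherits(model, "slab_model"))
    ifc <- slab_interfaces(model)
    if (all(ifc$sigma == 0)) {
        th <- vapply(model$layers, `[[`, 0, "thickness")
        sld <- rho_rel_to_sld(vapply(model$layers, `[[`, 0, "rho_rel"))
        r <- .parratt_cpp(qz, sld, th,
                          rho_rel_to_sld(model$fronting_rho_rel),
                          rho_rel_to_sld(model$subphase_rho_rel))
    } else {
        pad <- max(20, 4 * max(ifc$sigma))
        prof <- slab_to_profile(model, dz = dz, pad = pad)
        stack <- profile_to_stack(prof, model$fronting_rho_rel,
                                  model$subphase_rho_rel)
        r <- parratt_reflectivity(stack, qz)
    }
    model$scale * r + model$background
}

#' Gaussian resolution smearing in q
#'
#' Convolves a computed reflectivity curve with a Gaussian of FWHM
#' `dq_over_q * qz` (sigma = FWHM / 2.355), approximating instrumental q
#' resolution. `dq_over_q = 0` is the identity.
#'
#' @param R reflectivity values on `qz`
#' @param qz momentum transfer grid
#' @param dq_over_q fractional FWHM resolution, >= 0
#' @return smeared reflectivity
#' @export
apply_resolution_smearing <- function(R, qz, dq_over_q) {
    if (dq_over_q < 0) stop("dq_over_q must be >= 0")
    if (dq_over_q == 0) return(R)
    out <- numeric(length(qz))
    for (i in seq_along(qz)) {
        s <- dq_over_q * qz[i] / 2.355
        w <- exp(-0.5 * ((qz - qz[i]) / s)^2)
        out[i] <- sum(w * R) / sum(w)
    }
    out
}
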