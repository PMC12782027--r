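# Independent reference implementations used as oracles. All pure R, kept
# deliberately separate from the package's computational path.

# complex vertical wavevector in medium with given SLD (fronting-referenced)
.kz <- function(qz, sld, sld_fronting) {
    sqrt(as.complex((qz / 2)^2 - 4 * pi * (sld - sld_fronting)))
}

# Abeles transfer-matrix reflectivity of a sharp-interface stack.
# sld/d: finite slabs ordered from the fronting side.
abeles_reflectivity <- function(qz, sld, d, sld_fronting, sld_backing) {
    n <- length(sld)
    vapply(qz, function(q) {
        k <- c(.kz(q, sld_fronting, sld_fronting),
               if (n) vapply(seq_len(n), function(j)
                   .kz(q, sld[j], sld_fronting), complex(1)),
               .kz(q, sld_backing, sld_fronting))
        M <- diag(2) + 0i
        for (j in 0:n) {
            rj <- (k[j + 1] - k[j + 2]) / (k[j + 1] + k[j + 2])
            beta <- if (j == 0) 0 + 0i else k[j + 1] * d[j]
            Mj <- matrix(c(exp(1i * beta), rj * exp(-1i * beta),
                           rj * exp(1i * beta), exp(-1i * beta)), 2, 2)
            M <- M %*% Mj
        }
        Mod(M[2, 1] / M[1, 1])^2
    }, 0)
}

# Sharp-interface Parratt with Nevot-Croce roughness damping of each
# interface Fresnel coefficient: r_j -> r_j * exp(-2 k_j k_{j+1} sigma_j^2).
nevot_croce_reflectivity <- function(model, qz) {
    ifc <- lipidxr:::slab_interfaces(model)
    sld_above <- rho_rel_to_sld(ifc$rho_above)
    sld_below <- rho_rel_to_sld(ifc$rho_below)
    f_sld <- rho_rel_to_sld(model$fronting_rho_rel)
    th <- vapply(model$layers, `[[`, 0, "thickness")
    n <- length(th)
    vapply(qz, function(q) {
        kk <- c(.kz(q, f_sld, f_sld),
                vapply(seq_len(n), function(j) .kz(q, rho_rel_to_sld(
                    model$layers[[j]]$rho_rel), f_sld), complex(1)),
                .kz(q, rho_rel_to_sld(model$subphase_rho_rel), f_sld))
        r <- 0 + 0i
        for (j in (n + 1):1) {     # interface index, deepest first
            fr <- (kk[j] - kk[j + 1]) / (kk[j] + kk[j + 1]) *
                exp(-2 * kk[j] * kk[j + 1] * ifc$sigma[j]^2)
            if (j == n + 1) r <- fr
            else {
                ph <- exp(2i * kk[j + 1] * th[j])
                r <- (fr + r * ph) / (1 + fr * r * ph)
            }
        }
        Mod(r)^2
    }, 0)
}

# Kinematic (master-formula) normalized reflectivity: the Fourier transform
# of the density gradient, valid well above the critical edge.
kinematic_rrf <- function(model, qz, dz = 0.05) {
    prof <- slab_to_profile(model, dz = dz, pad = 30)
    drho <- diff(prof$rho_rel) / dz
    zm <- (prof$z[-1] + prof$z[-length(prof$z)]) / 2
    contrast <- model$subphase_rho_rel - model$fronting_rho_rel
    vapply(qz, function(q)
        Mod(sum(drho * exp(1i * q * zm)) * dz / contrast)^2, 0)
}

# literal loop-based reduced chi-square
brute_chi2 <- function(curve, model, p, dz = 0.25) {
    rf <- fresnel_reflectivity(curve$qz)
    mod <- reflectivity_from_slabs(model, curve$qz, dz = dz) / rf
    s <- 0
    for (i in seq_along(curve$qz))
        s <- s + ((mod[i] - curve$reflectivity[i]) / curve$sigma[i])^2
    s / (length(curve$qz) - p)
}

# random sharp slab stack for oracle-equivalence sweeps
random_stack <- function() {
    nl <- sample(1:4, 1)
    list(sld = rho_rel_to_sld(runif(nl, 0, 2)),
         d = runif(nl, 2, 40),
         f = 0, b = xr_constants$sld_water)
}
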