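# Model-independent electron-density inversion: the profile is a cubic
# B-spline on a fixed knot span, pinned to bulk water on the subphase side
# and to air on the air side, refined against R/R_F by constrained least
# squares from many random starts. All models within 20% of the minimum
# chi-square form the reported family; the best model is the smoothest
# profile among those within 1% of the minimum.

spline_basis <- function(z_range, n_knots) {
    knots <- c(rep(z_range[1], 3),
               seq(z_range[1], z_range[2], length.out = n_knots),
               rep(z_range[2], 3))
    list(knots = knots, n_basis = n_knots + 2)
}

eval_spline_profile <- function(coefficients, knots, z) {
    B <- splines::splineDesign(knots, z, ord = 4, outer.ok = TRUE)
    drop(B %*% coefficients)
}

#' Evaluate a spline profile model on a depth grid
#'
#' Returns the full relative electron-density profile, constant at bulk
#' water below the spline support and at air above it.
#'
#' @param model an `xr_spline_profile` (see [fit_spline_profile()])
#' @param z depth grid, Angstrom
#' @return rho/rho_water at each z
#' @export
predict_spline_profile <- function(model, z) {
    shift <- if (is.null(model$z_shift)) 0 else model$z_shift
    zs <- z + shift    # headgroup-centered gauge
    out <- numeric(length(z))
    inside <- zs >= model$z_range[1] & zs <= model$z_range[2]
    out[zs < model$z_range[1]] <- 1     # subphase bulk
    out[zs > model$z_range[2]] <- 0     # air
    if (any(inside))
        out[inside] <- eval_spline_profile(model$coefficients, model$knots,
                                           zs[inside])
    out
}

#' Roughness functional of a density profile
#'
#' Integrated squared second derivative, `integral (d2 rho / dz2)^2 dz`, by
#' second-difference quadrature on the uniform grid. Zero for constant and
#' affine profiles; decreases when interfacial widths grow.
#'
#' @param profile a [density_profile()] (uniform grid, >= 3 points)
#' @return non-negative scalar
#' @export
smoothness <- function(profile) {
    stopifnot(inherits(profile, "density_profile"))
    n <- length(profile$z)
    if (n < 3) stop("smoothness needs at least 3 grid points")
    dz <- profile$z[2] - profile$z[1]
    d2 <- diff(profile$rho_rel, differences = 2) / dz^2
    sum(d2^2) * dz
}

#' Pointwise envelopes of a spline model family
#'
#' @param members list of profiles (numeric vectors) or curves on a shared
#'   grid
#' @return list with `lo`, `hi` pointwise min/max vectors
#' @export
family_envelopes <- function(members) {
    if (length(members) < 1) stop("need at least one member")
    len <- vapply(members, length, 0L)
    if (any(len != len[1])) stop("members must share one grid")
    m <- do.call(rbind, members)
    list(lo = apply(m, 2, min), hi = apply(m, 2, max))
}

#' Model-independent B-spline inversion of a reflectivity curve
#'
#' Fits the relative electron-density profile as a cubic B-spline series by
#' constrained nonlinear least squares against the Fresnel-normalized data,
#' from `n_starts` seeded random coefficient initializations. Boundary
#' behaviour is built in by pinning the two outermost coefficients on each
#' side (bulk water on the subphase side, zero on the air side);
#' non-negativity is enforced by a penalty. All converged models within
#' `chi2 <= 1.2 * chi2_min` form the family; the reported best model is the
#' one minimizing the [smoothness()] functional among models within 1% of
#' the minimum chi-square (ties broken by lower chi-square).
#'
#' @param curve a Fresnel-normalized [reflectivity_curve()]
#' @param n_knots number of spline knots across `z_range` (>= 6)
#' @param n_starts number of random starts (>= 2; use hundreds in earnest)
#' @param seed integer seed
#' @param z_range spline support, Angstrom, `c(subphase_side, air_side)`
#'   in the headgroup-centered z convention
#' @param dz forward-model micro-slab thickness, Angstrom
#' @param penalty_weight weight of the non-negativity penalty residuals
#' @param max_iterations Levenberg-Marquardt cap per start
#' @return an object of class `xr_spline_family`: `best`
#'   (`xr_spline_profile`), `members`, `chi2_min`, `chi2` (per member),
#'   `z_grid`, `band_profile_lo/hi`, `band_refl_lo/hi`
#' @export
fit_spline_profile <- function(curve, n_knots = 12, n_starts = 500, seed = 1,
                               z_range = c(-15, 30), dz = 0.25,
                               penalty_weight = 30, max_iterations = 60) {
    stopifnot(inherits(curve, "xr_curve"))
    if (!curve$normalized) stop("curve must be Fresnel-normalized")
    if (n_knots < 6) stop("n_knots must be >= 6")
    if (n_starts < 2) stop("n_starts must be >= 2")
    bas <- spline_basis(z_range, n_knots)
    nb <- bas$n_basis
    pinned_lo <- 1:2            # subphase side: value and slope of bulk water
    pinned_hi <- (nb - 1):nb    # air side: zero
    free_idx <- setdiff(seq_len(nb), c(pinned_lo, pinned_hi))
    p <- length(free_idx)
    zg <- seq(z_range[1], z_range[2], by = dz)
    B <- splines::splineDesign(bas$knots, zg, ord = 4)
    rf <- fresnel_reflectivity(curve$qz)
    n <- length(curve$qz)
    if (n <= p) stop("more free spline coefficients than data points")
    wt <- 1 / curve$sigma
    f_sld <- 0; b_sld <- xr_constants$sld_water

    full_coef <- function(cf) {
        cc <- numeric(nb); cc[pinned_lo] <- 1; cc[free_idx] <- cf; cc
    }
    model_refl <- function(rho) {
        sld <- rho_rel_to_sld(rev(rho))       # air side first
        .parratt_cpp(curve$qz, sld, rep(dz, length(sld)), f_sld, b_sld) / rf
    }
    resid_fn <- function(cf) {
        rho <- drop(B %*% full_coef(cf))
        c((model_refl(rho) - curve$reflectivity) * wt,
          penalty_weight * pmin(rho, 0))
    }
    data_chi2 <- function(cf) {
        rho <- drop(B %*% full_coef(cf))
        sum(((model_refl(rho) - curve$reflectivity) * wt)^2) / (n - p)
    }

    # baseline: linear descent from bulk water to air across the free range
    base <- seq(1, 0, length.out = p + 2)[2:(p + 1)]
    start_mat <- with_seed(derive_seed(seed, "spline-starts"), {
        t(vapply(seq_len(n_starts), function(k)
            pmax(-0.2, base + runif(p, -0.45, 0.45)), numeric(p)))
    })

    fits <- vector("list", n_starts)
    for (k in seq_len(n_starts)) {
        fit <- tryCatch(
            suppressWarnings(minpack.lm::nls.lm(par = start_mat[k, ], fn = resid_fn,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = max_iterations))),
            error = function(e) NULL)
        if (is.null(fit) || !(fit$info %in% 1:4)) next
        fits[[k]] <- fit$par
    }
    fits <- fits[!vapply(fits, is.null, TRUE)]
    if (length(fits) == 0)
        stop("spline inversion failed: no start converged")

    chis <- vapply(fits, data_chi2, 0)
    chi2_min <- min(chis)
    keep <- chis <= 1.2 * chi2_min
    members_cf <- fits[keep]
    members_chi2 <- chis[keep]

    profile_of <- function(cf) drop(B %*% full_coef(cf))
    smooth_of <- function(cf) smoothness(density_profile(zg, profile_of(cf)))

    # Specular reflectivity is invariant under rigid translation of the
    # profile, so the fit determines rho(z) only up to a z-offset. Fix the
    # gauge to the coordinate convention (headgroup center at z = 0) by
    # re-centering each member at its interior density maximum, refined by
    # parabolic interpolation.
    peak_z <- function(rho) {
        interior <- 4:(length(zg) - 3)
        i <- interior[which.max(rho[interior])]
        # only a genuine headgroup maximum (above both bulk levels) defines
        # the gauge; monotone profiles are left untouched
        if (i == interior[1] || i == interior[length(interior)] ||
            rho[i] < max(rho[1], rho[length(rho)]) + 0.1)
            return(0)
        if (i > 1 && i < length(zg)) {
            y1 <- rho[i - 1]; y2 <- rho[i]; y3 <- rho[i + 1]
            den <- y1 - 2 * y2 + y3
            off <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
            zg[i] + max(-0.5, min(0.5, off)) * dz
        } else zg[i]
    }
    centered_profile <- function(cf) {
        rho <- profile_of(cf)
        s <- peak_z(rho)
        zs <- zg + s
        out <- numeric(length(zg))
        out[zs < z_range[1]] <- 1
        out[zs > z_range[2]] <- 0
        inside <- zs >= z_range[1] & zs <= z_range[2]
        if (any(inside))
            out[inside] <- drop(splines::splineDesign(bas$knots, zs[inside],
                                                      ord = 4) %*% full_coef(cf))
        out
    }

    near <- which(members_chi2 <= 1.01 * chi2_min)
    sm <- vapply(members_cf[near], smooth_of, 0)
    # smoothness values agreeing to 0.1% are numerically tied (converged
    # refinements of one basin differ at that level); break ties by chi2
    cand <- near[sm <= min(sm) * (1 + 1e-3)]
    best_i <- cand[which.min(members_chi2[cand])]

    # reflectivity from the as-fitted profile; reported profiles in the
    # centered gauge
    refl_members <- lapply(lapply(members_cf, profile_of), model_refl)
    prof_members <- lapply(members_cf, centered_profile)
    env_p <- family_envelopes(prof_members)
    env_r <- family_envelopes(refl_members)

    best_model <- structure(list(knots = bas$knots,
                                 coefficients = full_coef(members_cf[[best_i]]),
                                 z_range = z_range,
                                 z_shift = peak_z(profile_of(members_cf[[best_i]]))),
                            class = "xr_spline_profile")
    structure(list(best = best_model, best_index = best_i,
                   members = members_cf, chi2 = members_chi2,
                   chi2_min = chi2_min, z_grid = zg,
                   best_profile = prof_members[[best_i]],
                   profile_members = prof_members,
                   band_profile_lo = env_p$lo, band_profile_hi = env_p$hi,
                   band_refl_lo = env_r$lo, band_refl_hi = env_r$hi,
                   best_refl = refl_members[[best_i]],
                   qz = curve$qz, n_starts = n_starts,
                   n_converged = length(fits), seed = seed,
                   penalty_weight = penalty_weight, dz = dz,
                   curve = curve),
              class = "xr_spline_family")
}

#' @export
print.xr_spline_family <- function(x, ...) {
    cat(sprintf(paste0("<xr_spline_family> %d/%d starts converged, ",
                       "%d members within chi2_min + 20%%, chi2_min = %.4g\n"),
                x$n_converged, x$n_starts, length(x$members), x$chi2_min))
    invisible(x)
}

#' @export
plot.xr_spline_family <- function(x, what = c("profile", "reflectivity"), ...) {
    what <- match.arg(what)
    if (what == "profile") {
        graphics::plot(x$z_grid, x$best_profile, type = "l", col = "red3",
                       lwd = 1.5, xlab = "z (A)",
                       ylab = expression(rho / rho[water]),
                       ylim = range(x$band_profile_lo, x$band_profile_hi), ...)
        graphics::lines(x$z_grid, x$band_profile_lo, lty = 2)
        graphics::lines(x$z_grid, x$band_profile_hi, lty = 2)
    } else {
        plot(x$curve, ...)
        graphics::lines(x$qz, x$best_refl, col = "red3")
        graphics::lines(x$qz, x$band_refl_lo, lty = 2)
        graphics::lines(x$qz, x$band_refl_hi, lty = 2)
    }
    invisible(x)
}

#' Best-fit profile of a spline family as a density profile
#'
#' @param family an `xr_spline_family`
#' @param dz output grid step, Angstrom
#' @param pad Angstrom of bulk appended on each side of the spline support
#' @return a [density_profile()]
#' @export
spline_best_profile <- function(family, dz = 0.25, pad = 10) {
    z <- seq(family$best$z_range[1] - pad, family$best$z_range[2] + pad,
             by = dz)
    density_profile(z, predict_spline_profile(family$best, z))
}
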