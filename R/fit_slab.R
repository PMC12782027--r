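# Model-dependent fitting of slab models to Fresnel-normalized curves.
# Parameters are addressed by name: "<layer>.thickness", "<layer>.rho_rel",
# "<layer>.roughness", "subphase.roughness", plus "scale" and "background"
# (fixed unless explicitly freed).

default_bounds <- function(kind) {
    switch(kind,
           thickness = c(2, 40),
           rho_rel = c(0, 2),
           roughness = c(1, 10),
           scale = c(0.5, 2),
           background = c(0, 1e-6),
           stop("unknown parameter kind: ", kind))
}

param_kind <- function(name) {
    if (name %in% c("scale", "background")) return(name)
    sub("^[^.]+\\.", "", name)
}

# Full parameter table for a model: value, bounds, free flag.
param_table <- function(model, fixed = character(), free_extra = character(),
                        bounds = NULL) {
    nm <- character(0); val <- numeric(0)
    for (ln in names(model$layers)) {
        l <- model$layers[[ln]]
        for (f in c("thickness", "rho_rel", "roughness")) {
            nm <- c(nm, paste0(ln, ".", f)); val <- c(val, l[[f]])
        }
    }
    nm <- c(nm, "subphase.roughness", "scale", "background")
    val <- c(val, model$subphase_roughness, model$scale, model$background)
    layer_fixed <- unlist(lapply(names(model$layers), function(ln)
        paste0(ln, ".", model$layers[[ln]]$fixed)))
    free <- !(nm %in% c(fixed, layer_fixed))
    free[nm %in% c("scale", "background")] <- nm[nm %in% c("scale", "background")] %in% free_extra
    lo <- hi <- numeric(length(nm))
    for (i in seq_along(nm)) {
        b <- default_bounds(param_kind(nm[i]))
        if (!is.null(bounds) && nm[i] %in% names(bounds))
            b <- bounds[[nm[i]]]
        lo[i] <- b[1]; hi[i] <- b[2]
    }
    bad <- which(free & (val < lo | val > hi))
    if (length(bad))
        stop("initial value outside bounds for: ", paste(nm[bad], collapse = ", "))
    data.frame(name = nm, value = val, lower = lo, upper = hi, free = free,
               stringsAsFactors = FALSE)
}

params_to_model <- function(theta, template) {
    m <- template
    for (nm in names(theta)) {
        v <- theta[[nm]]
        if (nm == "subphase.roughness") m$subphase_roughness <- v
        else if (nm == "scale") m$scale <- v
        else if (nm == "background") m$background <- v
        else {
            ln <- sub("\\.[^.]+$", "", nm)
            f <- sub("^.+\\.", "", nm)
            m$layers[[ln]][[f]] <- v
        }
    }
    m
}

#' Reduced chi-square of a slab model against a normalized curve
#'
#' `chi2 = 1/(N - p) * sum(((R/R_F)_model - (R/R_F)_data)^2 / sigma^2)`,
#' with p the number of free parameters of the model (all layer parameters
#' plus the subphase roughness, minus per-layer fixed flags).
#'
#' @param curve a Fresnel-normalized [reflectivity_curve()]
#' @param model a [slab_model()]
#' @param fixed extra parameter names counted as fixed
#' @param dz forward-model discretization, Angstrom
#' @return non-negative scalar; 0 iff the model reproduces the data exactly
#' @export
chi2 <- function(curve, model, fixed = character(), dz = 0.25) {
    stopifnot(inherits(curve, "xr_curve"), inherits(model, "slab_model"))
    if (!curve$normalized) stop("curve must be Fresnel-normalized")
    pt <- param_table(model, fixed = fixed)
    p <- sum(pt$free)
    n <- length(curve$qz)
    if (n <= p) stop("need more data points than free parameters")
    rf <- fresnel_reflectivity(curve$qz)
    mod <- reflectivity_from_slabs(model, curve$qz, dz = dz) / rf
    sum(((mod - curve$reflectivity) / curve$sigma)^2) / (n - p)
}

#' Fit a slab model to a Fresnel-normalized reflectivity curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) over the free parameters of `model0`, repeated from
#' `multistart` perturbed initial guesses (+/-20\% uniform, seeded) to
#' escape local minima in the thickness/roughness trade-off. Parameter
#' uncertainties are estimated from the finite-difference concavity
#' (Hessian) of the chi-square surface at the optimum; see
#' [estimate_parameter_errors()].
#'
#' @param curve a Fresnel-normalized [reflectivity_curve()]
#' @param model0 initial [slab_model()]; per-layer `fixed` flags are honored
#' @param fixed character vector of additional parameter names to hold
#'   constant, e.g. `"tails.roughness"`
#' @param free_extra subset of `c("scale", "background")` to fit (both fixed
#'   by default)
#' @param bounds named list of `c(lower, upper)` overrides; defaults are
#'   thickness \[2, 40\] A, rho_rel \[0, 2\], roughness \[1, 10\] A
#' @param multistart number of restarts (first start = `model0` itself)
#' @param seed integer seed for the restart perturbations
#' @param max_iterations Levenberg-Marquardt iteration cap per start
#' @param dz forward-model discretization, Angstrom
#' @param compute_errors logical; fill covariance/errors at the optimum
#' @param tiebreak_tol two-layer slab models can show distinct chi-square
#'   minima (thickness/roughness trade-offs) that the data cannot
#'   statistically distinguish; restart solutions within this relative
#'   margin of the lowest chi-square are treated as tied, and the tie is
#'   broken in favour of realistic parameter values, i.e. the solution
#'   closest to `model0` in bound-normalized parameter distance
#' @return an object of class `xr_slab_fit` with components `model`
#'   (optimized [slab_model()]), `par` (free parameters), `param_errors`,
#'   `covariance`, `chi2`, `n_points`, `n_free`, and bookkeeping fields
#' @export
fit_slab_model <- function(curve, model0, fixed = character(),
                           free_extra = character(), bounds = NULL,
                           multistart = 8, seed = 1, max_iterations = 200,
                           dz = 0.25, compute_errors = TRUE,
                           tiebreak_tol = 0.02) {
    stopifnot(inherits(curve, "xr_curve"), inherits(model0, "slab_model"))
    if (!curve$normalized) stop("curve must be Fresnel-normalized")
    pt <- param_table(model0, fixed = fixed, free_extra = free_extra,
                      bounds = bounds)
    free <- pt$free
    p <- sum(free)
    n <- length(curve$qz)
    if (n < p + 2) stop("need at least 2 more points than free parameters")
    rf <- fresnel_reflectivity(curve$qz)
    data_n <- curve$reflectivity
    wt <- 1 / curve$sigma
    theta_full <- setNames(pt$value, pt$name)

    resid_fn <- function(theta) {
        th <- theta_full
        th[pt$name[free]] <- theta
        m <- params_to_model(as.list(th), model0)
        mod <- reflectivity_from_slabs(m, curve$qz, dz = dz) / rf
        (mod - data_n) * wt
    }

    lo <- pt$lower[free]; hi <- pt$upper[free]
    th0 <- pt$value[free]
    starts <- list(th0)
    if (multistart > 1) {
        perturb <- with_seed(derive_seed(seed, "slab-multistart"), {
            lapply(seq_len(multistart - 1), function(k)
                pmin(hi, pmax(lo, th0 * runif(p, 0.8, 1.2))))
        })
        starts <- c(starts, perturb)
    }

    sols <- list(); any_conv <- FALSE
    for (st in starts) {
        fit <- tryCatch(
            suppressWarnings(minpack.lm::nls.lm(par = st, lower = lo, upper = hi,
                               fn = resid_fn,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = max_iterations))),
            error = function(e) NULL)
        if (is.null(fit)) next
        any_conv <- any_conv || fit$info %in% 1:4
        sols[[length(sols) + 1]] <- list(par = fit$par, ssr = fit$deviance)
    }
    if (length(sols) == 0)
        stop("slab fit failed: no optimizer start produced a result")
    ssrs <- vapply(sols, `[[`, 0, "ssr")
    best_ssr_all <- min(ssrs)
    # Distinct multistart minima with statistically indistinguishable
    # chi-square (within `tiebreak_tol` of the lowest) are resolved by
    # preferring realistic parameter values, operationalized as the
    # smallest bound-normalized distance from the initial model.
    cand <- which(ssrs <= best_ssr_all * (1 + tiebreak_tol))
    dist0 <- vapply(cand, function(i)
        sqrt(mean(((sols[[i]]$par - th0) / (hi - lo))^2)), 0)
    pick <- cand[order(dist0, ssrs[cand])][1]
    best <- sols[[pick]]
    best_ssr <- best$ssr
    theta_hat <- setNames(best$par, pt$name[free])
    th <- theta_full
    th[names(theta_hat)] <- theta_hat
    model_hat <- params_to_model(as.list(th), model0)
    out <- structure(list(
        model = model_hat, par = theta_hat,
        param_errors = setNames(rep(NA_real_, p), names(theta_hat)),
        covariance = matrix(NA_real_, p, p,
                            dimnames = list(names(theta_hat), names(theta_hat))),
        chi2 = best_ssr / (n - p), n_points = n, n_free = p,
        fixed = pt$name[!free], bounds = cbind(lower = lo, upper = hi),
        curve = curve, dz = dz, seed = seed, multistart = multistart,
        converged = any_conv, resid_fn = resid_fn,
        error_warning = NULL), class = "xr_slab_fit")
    if (!any_conv)
        warning("no optimizer start converged; returning best partial result",
                call. = FALSE)
    if (compute_errors && p > 0)
        out <- estimate_parameter_errors(out)
    out
}

#' Finite-difference covariance errors for a slab fit
#'
#' Measures the concavity of the chi-square surface at the optimum: the
#' Hessian of half the weighted sum of squared residuals is built by
#' central finite differences over the free parameters; its inverse is the
#' parameter covariance and `sqrt(diag)` the 1-sigma errors. Strong
#' parameter interdependence can make these underestimates; a
#' non-positive-definite Hessian is flagged in `$error_warning`.
#'
#' @param fit an `xr_slab_fit`
#' @param rel_step relative finite-difference step
#' @return the fit with `covariance` and `param_errors` filled
#' @export
estimate_parameter_errors <- function(fit, rel_step = 1e-3) {
    stopifnot(inherits(fit, "xr_slab_fit"))
    theta <- fit$par
    p <- length(theta)
    if (p == 0) return(fit)
    S <- function(th) 0.5 * sum(fit$resid_fn(th)^2)
    h <- rel_step * pmax(abs(theta), 1)
    H <- matrix(0, p, p)
    S0 <- S(theta)
    for (i in seq_len(p)) {
        ei <- replace(numeric(p), i, h[i])
        H[i, i] <- (S(theta + ei) - 2 * S0 + S(theta - ei)) / h[i]^2
        if (i > 1) for (j in seq_len(i - 1)) {
            ej <- replace(numeric(p), j, h[j])
            H[i, j] <- H[j, i] <-
                (S(theta + ei + ej) - S(theta + ei - ej) -
                 S(theta - ei + ej) + S(theta - ei - ej)) / (4 * h[i] * h[j])
        }
    }
    ev <- eigen(H, symmetric = TRUE)
    if (min(ev$values) <= 1e-12 * max(abs(ev$values))) {
        v <- ev$vectors[, p]
        pair <- order(abs(v), decreasing = TRUE)[1:min(2, p)]
        stop("singular chi-square Hessian: degenerate parameter direction ",
             "dominated by ", paste(names(theta)[pair], collapse = " / "))
    }
    cov <- solve(H)
    cov <- (cov + t(cov)) / 2
    warn <- NULL
    if (any(diag(cov) < 0)) {
        warn <- "non-positive covariance diagonal; parameter errors unreliable (likely underestimated)"
        warning(warn, call. = FALSE)
    }
    fit$covariance <- cov
    dimnames(fit$covariance) <- list(names(theta), names(theta))
    fit$param_errors <- setNames(sqrt(pmax(diag(cov), 0)), names(theta))
    fit$error_warning <- warn
    fit
}

#' @export
print.xr_slab_fit <- function(x, ...) {
    cat(sprintf("<xr_slab_fit> %d free parameter(s), %d points, reduced chi2 = %.4g\n",
                x$n_free, x$n_points, x$chi2))
    print(x$model)
    invisible(x)
}

#' @export
summary.xr_slab_fit <- function(object, ...) {
    tab <- data.frame(estimate = object$par,
                      std_error = object$param_errors)
    structure(list(coefficients = tab, chi2 = object$chi2,
                   n_points = object$n_points, n_free = object$n_free,
                   fixed = object$fixed, converged = object$converged,
                   error_warning = object$error_warning),
              class = "summary.xr_slab_fit")
}

#' @export
print.summary.xr_slab_fit <- function(x, ...) {
    cat(sprintf("Slab-model fit: %d points, %d free parameters, reduced chi2 = %.4g\n",
                x$n_points, x$n_free, x$chi2))
    print(round(x$coefficients, 5))
    if (length(x$fixed))
        cat("fixed:", paste(x$fixed, collapse = ", "), "\n")
    if (!is.null(x$error_warning)) cat("note:", x$error_warning, "\n")
    invisible(x)
}

#' @export
coef.xr_slab_fit <- function(object, ...) object$par

#' @export
vcov.xr_slab_fit <- function(object, ...) object$covariance

#' @export
predict.xr_slab_fit <- function(object, qz = NULL,
                                type = c("normalized", "reflectivity"), ...) {
    type <- match.arg(type)
    if (is.null(qz)) qz <- object$curve$qz
    r <- reflectivity_from_slabs(object$model, qz, dz = object$dz)
    if (type == "normalized") r / fresnel_reflectivity(qz) else r
}

#' @export
fitted.xr_slab_fit <- function(object, ...) predict(object)

#' @export
residuals.xr_slab_fit <- function(object,
                                  type = c("pearson", "response"), ...) {
    type <- match.arg(type)
    r <- object$curve$reflectivity - predict(object)
    if (type == "pearson") r / object$curve$sigma else r
}

#' @export
plot.xr_slab_fit <- function(x, ...) {
    plot(x$curve, main = "slab-model fit", ...)
    graphics::lines(x$curve$qz, predict(x), col = "red3", lwd = 1.5)
    invisible(x)
}

#' Simulate replicate curves from a fitted slab model
#'
#' Draws `nsim` synthetic curves from the fitted model with the relative
#' noise level implied by the data uncertainties.
#'
#' @param object an `xr_slab_fit`
#' @param nsim number of replicates
#' @param seed integer seed
#' @param ... unused
#' @return list of [reflectivity_curve()] objects (normalized)
#' @export
simulate.xr_slab_fit <- function(object, nsim = 1, seed = 1, ...) {
    rel <- stats::median(object$curve$sigma / object$curve$reflectivity)
    lapply(seq_len(nsim), function(k) {
        cur <- simulate_curve(object$model, qz = object$curve$qz,
                              noise = noise_spec(rel_sigma = rel,
                                                 seed = derive_seed(seed, paste0("sim", k))),
                              dz = object$dz)
        normalize_to_fresnel(cur)
    })
}
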