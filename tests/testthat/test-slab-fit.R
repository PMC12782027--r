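sim_norm <- function(name, seed, rel = 0.02, n = 120) {
    normalize_to_fresnel(simulate_curve(reference_model(name),
                                        default_qz_grid(n),
                                        noise_spec(rel, seed = seed),
                                        sample = name))
}

test_that("reduced chi-square matches its definition", {
    m <- reference_model("DSPC")
    q <- default_qz_grid(60)
    rrf <- reflectivity_from_slabs(m, q) / fresnel_reflectivity(q)
    sig <- 0.02 * rrf
    exact <- reflectivity_curve(q, rrf, sig, normalized = TRUE)
    expect_equal(chi2(exact, m), 0, tolerance = 1e-18)
    # data offset by exactly one sigma at every point
    off <- reflectivity_curve(q, rrf + sig, sig, normalized = TRUE)
    p <- 7   # all slab parameters free for DSPC
    expect_equal(chi2(off, m), 60 / (60 - p), tolerance = 1e-10)
    # literal loop-based recomputation on noisy data and a perturbed model
    pm <- slab_model(list(layer(17, 1.05, 3), layer(8, 1.38, 3.3)),
                     subphase_roughness = 2.8)
    noisy <- sim_norm("DSPC", seed = 21, n = 60)
    expect_equal(chi2(noisy, pm), brute_chi2(noisy, pm, p = 7),
                 tolerance = 1e-12)
    expect_error(chi2(denormalize_from_fresnel(exact), m), "normalized")
    short <- reflectivity_curve(q[1:5], rrf[1:5], sig[1:5], normalized = TRUE)
    expect_error(chi2(short, m), "free parameters")
})

test_that("noise-free fits recover the generating parameters to 0.1%", {
    m0 <- reference_model("SAPC")
    q <- default_qz_grid()
    rrf <- reflectivity_from_slabs(m0, q) / fresnel_reflectivity(q)
    cur <- reflectivity_curve(q, rrf, 1e-6 * rrf, normalized = TRUE)
    # perturbed start
    start <- m0
    start$layers$tails$thickness <- 13
    start$layers$heads$rho_rel <- 1.2
    start$subphase_roughness <- 4.0
    fit <- fit_slab_model(cur, start, multistart = 2, seed = 3,
                          compute_errors = FALSE)
    truth <- coef(fit) * 0 + setNames(
        lipidxr:::param_table(m0)$value,
        lipidxr:::param_table(m0)$name)[names(coef(fit))]
    expect_lt(max(abs(coef(fit) / truth - 1)), 1e-3)
    expect_lt(fit$chi2, chi2(cur, start, fixed = "tails.roughness"))
})

test_that("fluid-monolayer recovery reproduces the published thicknesses", {
    cur <- sim_norm("SAPC", seed = 42)
    fit <- fit_slab_model(cur, reference_model("SAPC"), seed = 7)
    # tails roughness was fixed (3.66 A) in the published fit
    expect_true("tails.roughness" %in% fit$fixed)
    expect_lt(abs(coef(fit)[["tails.thickness"]] - 11.8), 3 * 0.2)
    dcur <- sim_norm("DSPC", seed = 42)
    dfit <- fit_slab_model(dcur, reference_model("DSPC"), seed = 7)
    expect_equal(dfit$n_free, 7)   # all parameters free
    expect_lt(abs(coef(dfit)[["tails.thickness"]] - 18.0), 3 * 0.2)
    expect_lt(abs(coef(dfit)[["tails.rho_rel"]] - 1.00), 3 * 0.01)
})

test_that("finite-difference errors reproduce an analytic quadratic surface", {
    # residual r(x) = (x - a)/s gives S = (x-a)^2/(2 s^2); the 1-sigma
    # error must equal s
    a <- 2.5; s <- 0.37
    fake <- structure(list(par = c(x = a),
                           resid_fn = function(th) (th - a) / s,
                           param_errors = c(x = NA_real_),
                           covariance = matrix(NA, 1, 1)),
                      class = "xr_slab_fit")
    out <- estimate_parameter_errors(fake)
    expect_equal(out$param_errors[["x"]], s, tolerance = 1e-6)
})

test_that("parameter errors are stable under step-size refinement", {
    cur <- sim_norm("SAPC+15-LOX-2", seed = 5, n = 90)
    fit <- fit_slab_model(cur, reference_model("SAPC+15-LOX-2"),
                          multistart = 2, seed = 2)
    e1 <- estimate_parameter_errors(fit, rel_step = 1e-3)$param_errors
    e2 <- estimate_parameter_errors(fit, rel_step = 5e-4)$param_errors
    expect_lt(max(abs(e1 / e2 - 1)), 0.01)
    # covariance is symmetric with non-negative diagonal, errors = sqrt(diag)
    V <- vcov(fit)
    expect_equal(V, t(V), tolerance = 1e-10)
    expect_true(all(diag(V) >= 0))
    expect_equal(fit$param_errors, sqrt(diag(V)), tolerance = 1e-12)
})

test_that("finite-difference errors track the replicate spread of the fit", {
    tails <- vapply(1:20, function(s) {
        cur <- sim_norm("SAPC", seed = 100 + s, n = 90)
        fit <- fit_slab_model(cur, reference_model("SAPC"), multistart = 1,
                              compute_errors = (s <= 8))
        c(coef(fit)[["tails.thickness"]],
          fit$param_errors[["tails.thickness"]])
    }, c(0, 0))
    emp_sd <- sd(tails[1, ])
    mean_err <- mean(tails[2, ], na.rm = TRUE)
    expect_lt(emp_sd / mean_err, 2)
    expect_gt(emp_sd / mean_err, 0.5)
})

test_that("fixing a parameter never lowers the minimized chi-square", {
    cur <- sim_norm("DSPC", seed = 31, n = 80)
    m0 <- reference_model("DSPC")
    free_fit <- fit_slab_model(cur, m0, multistart = 2, seed = 11,
                               compute_errors = FALSE)
    fixables <- c("tails.thickness", "heads.rho_rel", "subphase.roughness",
                  "heads.thickness", "tails.roughness")
    offsets <- c(1.04, 0.95, 1.1, 0.92, 1.06)
    for (i in seq_along(fixables)) {
        m_off <- lipidxr:::params_to_model(
            setNames(list(lipidxr:::param_table(m0)$value[
                match(fixables[i], lipidxr:::param_table(m0)$name)] *
                    offsets[i]), fixables[i]), m0)
        cfit <- fit_slab_model(cur, m_off, fixed = fixables[i],
                               multistart = 2, seed = 11,
                               compute_errors = FALSE)
        expect_gte(cfit$chi2 * (cfit$n_points - cfit$n_free),
                   free_fit$chi2 * (free_fit$n_points - free_fit$n_free) *
                       (1 - 1e-8))
    }
})

test_that("identical inputs give identical fits regardless of assembly order", {
    cur <- sim_norm("PAzePC", seed = 13, n = 70)
    idx <- withr::with_seed(2, sample(70))
    reordered <- reflectivity_curve(cur$qz[idx][order(cur$qz[idx])],
                                    cur$reflectivity[idx][order(cur$qz[idx])],
                                    cur$sigma[idx][order(cur$qz[idx])],
                                    normalized = TRUE)
    f1 <- fit_slab_model(cur, reference_model("PAzePC"), multistart = 2,
                         seed = 4, compute_errors = FALSE)
    f2 <- fit_slab_model(reordered, reference_model("PAzePC"),
                         multistart = 2, seed = 4, compute_errors = FALSE)
    expect_identical(coef(f1), coef(f2))
})

test_that("standard model-object methods are coherent", {
    cur <- sim_norm("DSPC", seed = 8, n = 80)
    fit <- fit_slab_model(cur, reference_model("DSPC"), multistart = 2,
                          seed = 5)
    expect_named(coef(fit))
    expect_length(predict(fit), 80)
    expect_equal(predict(fit), fitted(fit))
    # pearson residuals consistent with chi2
    expect_equal(sum(residuals(fit)^2) / (80 - fit$n_free), fit$chi2,
                 tolerance = 1e-10)
    expect_output(print(summary(fit)), "reduced chi2")
    sims <- simulate(fit, nsim = 2, seed = 3)
    expect_length(sims, 2)
    expect_true(all(vapply(sims, inherits, TRUE, "xr_curve")))
})
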