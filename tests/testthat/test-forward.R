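test_that("Fresnel reflectivity matches closed forms", {
    qc <- critical_qz()
    # total external reflection below the critical edge (cancellation in
    # (q/2)^2 - 4 pi SLD leaves ~1e-8 rounding right at the edge)
    expect_true(all(abs(fresnel_reflectivity(
        seq(0.001, qc, length.out = 20)) - 1) < 1e-6))
    # closed-form value at exactly twice the critical edge
    expect_equal(fresnel_reflectivity(2 * qc),
                 ((2 - sqrt(3)) / (2 + sqrt(3)))^2, tolerance = 1e-12)
    expect_equal(fresnel_reflectivity(2 * qc), 5.155e-3, tolerance = 1e-3)
    # asymptotic (q_c / 2 q)^4 decay within 1% well above 10 q_c
    q <- seq(11 * qc, 0.7, length.out = 50)
    expect_lt(max(abs(fresnel_reflectivity(q) / (qc / (2 * q))^4 - 1)), 0.01)
    expect_error(fresnel_reflectivity(c(0.1, -0.2)), "qz")
})

test_that("Parratt equals the Fresnel solution for the bare interface", {
    st <- microslab_stack(numeric(0), 1, 0, xr_constants$sld_water)
    q <- default_qz_grid(60)
    expect_equal(parratt_reflectivity(st, q), fresnel_reflectivity(q),
                 tolerance = 1e-12)
})

test_that("Parratt agrees with an independent Abeles transfer matrix", {
    q <- seq(0.016, 0.7, length.out = 80)
    withr::with_seed(101, {
        for (k in 1:100) {
            st <- random_stack()
            r_p <- lipidxr:::.parratt_cpp(q, st$sld, st$d, st$f, st$b)
            r_a <- abeles_reflectivity(q, st$sld, st$d, st$f, st$b)
            expect_lt(max(abs(r_p - r_a) / pmax(r_a, 1e-300)), 1e-8)
        }
    })
})

test_that("reflectivity is bounded and unitary below the critical edge", {
    withr::with_seed(7, {
        for (k in 1:20) {
            st <- random_stack()
            q <- default_qz_grid(80)
            r <- lipidxr:::.parratt_cpp(q, st$sld, st$d, st$f, st$b)
            expect_true(all(r >= 0 & r <= 1 + 1e-12))
            qc_b <- critical_qz(st$b, st$f)
            below <- q[q < qc_b]
            if (length(below))
                expect_true(all(abs(lipidxr:::.parratt_cpp(
                    below, st$sld, st$d, st$f, st$b) - 1) < 1e-9))
        }
    })
})

test_that("zero-roughness slab model equals the analytic sharp Parratt", {
    m <- slab_model(list(layer(20, 1.2, 0)), subphase_roughness = 0,
                    layer_names = "film")
    q <- default_qz_grid(60)
    r1 <- reflectivity_from_slabs(m, q)
    r2 <- abeles_reflectivity(q, rho_rel_to_sld(1.2), 20, 0,
                              xr_constants$sld_water)
    expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("rough interfaces agree with the Nevot-Croce approximation", {
    for (nm in reference_sample_names()) {
        m <- reference_model(nm)
        sig_max <- max(lipidxr:::slab_interfaces(m)$sigma)
        q <- seq(0.02, min(0.7, 1 / sig_max), length.out = 40)
        r_micro <- reflectivity_from_slabs(m, q, dz = 0.25)
        r_nc <- nevot_croce_reflectivity(m, q)
        expect_lt(max(abs(r_micro - r_nc) / r_nc), 0.02)
    }
})

test_that("the kinematic master formula holds well above the critical edge", {
    qc <- critical_qz()
    q <- seq(5 * qc, 0.7, length.out = 60)
    # fluid monolayers: no deep Kiessig minima, pointwise 5% agreement
    for (nm in c("SAPC", "SAPC+15-LOX-2")) {
        m <- reference_model(nm)
        rrf <- reflectivity_from_slabs(m, q, dz = 0.1) /
            fresnel_reflectivity(q)
        expect_lt(max(abs(rrf / kinematic_rrf(m, q) - 1)), 0.05)
    }
    # DSPC is a thick, strongly modulated film: the Born approximation
    # errs several percent around its fringe structure and its relative
    # error is unbounded at the near-zero minima. Require close agreement
    # in the median and 10% away from the minima.
    m <- reference_model("DSPC")
    rrf <- reflectivity_from_slabs(m, q, dz = 0.1) / fresnel_reflectivity(q)
    kin <- kinematic_rrf(m, q)
    relerr <- abs(rrf / kin - 1)
    away <- kin > 0.1 * stats::median(kin)
    expect_lt(stats::median(relerr), 0.05)
    expect_lt(max(relerr[away]), 0.1)
})

test_that("the micro-slab discretization converges at second order", {
    m <- reference_model("SAPC")
    q <- default_qz_grid(60)
    r1 <- reflectivity_from_slabs(m, q, dz = 0.25)
    r2 <- reflectivity_from_slabs(m, q, dz = 0.125)
    r3 <- reflectivity_from_slabs(m, q, dz = 0.0625)
    e12 <- max(abs(r1 - r2) / r2)
    e23 <- max(abs(r2 - r3) / r3)
    # staircase error is O((q dz)^2): ~2e-3 at dz = 0.25, q = 0.7 -- far
    # below the 2% counting noise -- and drops ~4x per halving
    expect_lt(e12, 5e-3)
    expect_lt(e23, 0.35 * e12)
    # in the fringe-information region q <= 0.35 the error is an order
    # of magnitude smaller still
    low <- q <= 0.35
    expect_lt(max((abs(r1 - r2) / r2)[low]), 5e-4)
})

test_that("scaling all SLDs by s rescales the critical edge by sqrt(s)", {
    s <- 4
    q <- seq(0.005, 0.1, by = 1e-4)
    r1 <- lipidxr:::.parratt_cpp(q, rho_rel_to_sld(1.3), 15, 0,
                                 xr_constants$sld_water)
    r4 <- lipidxr:::.parratt_cpp(q, s * rho_rel_to_sld(1.3), 15, 0,
                                 s * xr_constants$sld_water)
    edge <- function(r) q[max(which(r > 0.5))]
    expect_equal(edge(r4) / edge(r1), sqrt(s), tolerance = 0.02)
})

test_that("Fresnel normalization round-trips and flags double application", {
    m <- reference_model("DSPC")
    cur <- simulate_curve(m, noise = noise_spec(0.02, seed = 3))
    ncur <- normalize_to_fresnel(cur)
    expect_true(ncur$normalized)
    expect_error(normalize_to_fresnel(ncur), "already")
    back <- denormalize_from_fresnel(ncur)
    expect_equal(back$reflectivity, cur$reflectivity, tolerance = 1e-12)
    expect_equal(back$sigma, cur$sigma, tolerance = 1e-12)
    # bare interface: R/R_F is identically 1
    bare <- slab_model(list(), subphase_roughness = 0)
    q <- default_qz_grid(50)
    flat <- reflectivity_from_slabs(bare, q) / fresnel_reflectivity(q)
    expect_equal(flat, rep(1, 50), tolerance = 1e-10)
})

test_that("Kiessig fringe period reflects the total film thickness", {
    # exact relation for a single uniform film of the DSPC total
    # thickness: fringe minima spaced by 2 pi / D
    single <- slab_model(list(layer(25.7, 1.2, 0)), subphase_roughness = 0,
                         layer_names = "film")
    q <- seq(0.1, 0.7, by = 5e-4)
    rrf <- reflectivity_from_slabs(single, q) / fresnel_reflectivity(q)
    minima <- q[which(diff(sign(diff(rrf))) > 0) + 1]
    expect_equal(mean(diff(minima)), 2 * pi / 25.7, tolerance = 0.05)
    # the two-layer DSPC model beats its 18 / 7.7 / 25.7 A scales, so its
    # deep-minima spacing only approximates 2 pi / D
    m <- reference_model("DSPC")
    rrf2 <- reflectivity_from_slabs(m, q) / fresnel_reflectivity(q)
    minima2 <- q[which(diff(sign(diff(rrf2))) > 0) + 1]
    expect_equal(mean(diff(minima2)), 2 * pi / 25.7, tolerance = 0.2)
})

test_that("resolution smearing behaves as a proper convolution", {
    m <- reference_model("DSPC")
    q <- seq(0.05, 0.7, length.out = 300)
    r <- reflectivity_from_slabs(m, q) / fresnel_reflectivity(q)
    expect_identical(apply_resolution_smearing(r, q, 0), r)
    expect_equal(apply_resolution_smearing(rep(0.7, 300), q, 0.05),
                 rep(0.7, 300), tolerance = 1e-12)
    # fringe contrast decreases monotonically with resolution width
    contrast <- function(dq) {
        rs <- apply_resolution_smearing(r, q, dq)
        win <- q > 0.3 & q < 0.5
        diff(range(log(rs[win])))
    }
    c0 <- contrast(0); c2 <- contrast(0.02); c5 <- contrast(0.05)
    expect_gt(c0, c2)
    expect_gt(c2, c5)
})
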