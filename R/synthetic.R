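# Reference monolayer models and the synthetic-data generator. The five
# named samples are the model-dependent fit parameters of the enzyme
# oxidation study: the arachidonoyl substrate lipid SAPC before and after
# 15-LOX-2 exposure, the oxidized-lipid mimic PAzePC, and the saturated
# negative control DSPC before and after exposure. The tails-layer
# roughness of the three fluid monolayers was held fixed in the original
# fits; those fixed flags are reproduced here.

reference_table <- list(
    "SAPC" = list(tails = c(11.8, 0.96, 3.66), heads = c(6.3, 1.35, 2.7),
                  sub = 4.9, tail_rough_fixed = TRUE),
    "SAPC+15-LOX-2" = list(tails = c(8.64, 0.86, 3.11), heads = c(6.5, 1.48, 3.6),
                           sub = 7.1, tail_rough_fixed = TRUE),
    "PAzePC" = list(tails = c(7.8, 0.86, 3.05), heads = c(6, 1.4, 3.4),
                    sub = 5.1, tail_rough_fixed = TRUE),
    "DSPC" = list(tails = c(18.0, 1.00, 3.06), heads = c(7.7, 1.43, 3.6),
                  sub = 2.5, tail_rough_fixed = FALSE),
    "DSPC+15-LOX-2" = list(tails = c(18.7, 1.03, 3.33), heads = c(7.5, 1.41, 2.5),
                           sub = 2.6, tail_rough_fixed = FALSE))

#' Names of the reference monolayer samples
#' @return character vector of the five sample names
#' @export
reference_sample_names <- function() names(reference_table)

#' Reference slab model for a named monolayer sample
#'
#' Two-layer (tails/headgroups) slab models with the published central
#' parameter values for the five monolayers of the oxidation experiment.
#' For the fluid monolayers (SAPC, SAPC+15-LOX-2, PAzePC) the tails-layer
#' roughness carries a `fixed` flag, mirroring how those fits were run.
#'
#' @param name one of [reference_sample_names()]
#' @return a [slab_model()]
#' @examples
#' reference_model("DSPC")
#' @export
reference_model <- function(name) {
    if (length(name) != 1 || !name %in% names(reference_table))
        stop("unknown sample '", name, "'; valid names: ",
             paste(names(reference_table), collapse = ", "))
    r <- reference_table[[name]]
    slab_model(
        layers = list(
            layer(r$tails[1], r$tails[2], r$tails[3],
                  fixed = if (r$tail_rough_fixed) "roughness" else character()),
            layer(r$heads[1], r$heads[2], r$heads[3])),
        subphase_roughness = r$sub,
        layer_names = c("tails", "heads"))
}

#' Default measurement grid in momentum transfer
#'
#' Log-spaced q_z grid over the measured range of the experiment.
#'
#' @param n number of points
#' @param qmin,qmax range, inverse Angstrom
#' @export
default_qz_grid <- function(n = 120, qmin = 0.016, qmax = 0.7) {
    exp(seq(log(qmin), log(qmax), length.out = n))
}

#' Counting-noise specification for simulated curves
#'
#' Multiplicative Gaussian noise: `R = R_model * (1 + rel_sigma * eps)`,
#' `eps ~ N(0, 1)`, an approximation to counting statistics after
#' normalization. The reported uncertainty is `rel_sigma * R` with an
#' absolute floor.
#'
#' @param rel_sigma fractional noise level (default 0.02)
#' @param sigma_floor absolute uncertainty floor on un-normalized R
#' @param seed integer seed
#' @export
noise_spec <- function(rel_sigma = 0.02, sigma_floor = 1e-10, seed = 1) {
    if (rel_sigma < 0) stop("rel_sigma must be >= 0")
    list(rel_sigma = rel_sigma, sigma_floor = sigma_floor, seed = seed)
}

#' Simulate a specular reflectivity curve
#'
#' Computes the forward reflectivity of `model` on `qz` and applies
#' multiplicative Gaussian counting noise per [noise_spec()]. Points driven
#' non-positive by a noise draw are resampled. Identical seeds reproduce
#' identical curves.
#'
#' @param model a [slab_model()]
#' @param qz momentum transfer grid
#' @param noise a [noise_spec()]
#' @param dz forward-model discretization, Angstrom
#' @param sample optional sample label recorded on the curve
#' @return an un-normalized [reflectivity_curve()]
#' @export
simulate_curve <- function(model, qz = default_qz_grid(),
                           noise = noise_spec(), dz = 0.25, sample = NULL) {
    stopifnot(inherits(model, "slab_model"))
    r0 <- reflectivity_from_slabs(model, qz, dz = dz)
    r <- with_seed(noise$seed, {
        x <- r0 * (1 + noise$rel_sigma * rnorm(length(qz)))
        for (it in 1:100) {
            bad <- which(x <= 0)
            if (!length(bad)) break
            x[bad] <- r0[bad] * (1 + noise$rel_sigma * rnorm(length(bad)))
        }
        x
    })
    if (any(r <= 0)) r[r <= 0] <- noise$sigma_floor
    sigma <- pmax(noise$rel_sigma * r, noise$sigma_floor)
    reflectivity_curve(qz, r, sigma, normalized = FALSE,
                       sample = sample, seed = noise$seed)
}

#' Simulate a paired before/after oxidation experiment
#'
#' Two curves on one shared q-grid with independent noise seeds, emulating
#' measurement of the same monolayer before and after enzyme exposure.
#'
#' @param before,after sample names (see [reference_sample_names()])
#' @param qz shared momentum-transfer grid
#' @param seeds integer vector of two noise seeds
#' @param rel_sigma fractional noise level for both curves
#' @param dz forward-model discretization
#' @return list with elements `before`, `after` ([reflectivity_curve()]s)
#' @export
paired_experiment <- function(before, after, qz = default_qz_grid(),
                              seeds = c(1L, 2L), rel_sigma = 0.02,
                              dz = 0.25) {
    mb <- reference_model(before)
    ma <- reference_model(after)
    list(before = simulate_curve(mb, qz,
                                 noise_spec(rel_sigma, seed = seeds[1]),
                                 dz = dz, sample = before),
         after = simulate_curve(ma, qz,
                                noise_spec(rel_sigma, seed = seeds[2]),
                                dz = dz, sample = after))
}
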