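# Column-text curve files: '#'-prefixed metadata header, then whitespace-
# delimited numeric columns qz, R (or R/R_F), sigma. Locale-independent
# (C-style decimal points); %.17g makes the numeric round trip exact.

#' Write a reflectivity curve to a column-text file
#'
#' @param curve an [reflectivity_curve()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_curve <- function(curve, path) {
    stopifnot(inherits(curve, "xr_curve"))
    hdr <- c("# lipidxr reflectivity curve",
             sprintf("# wavelength: %s", format(curve$wavelength, digits = 12)),
             sprintf("# normalized: %s", if (curve$normalized) "true" else "false"),
             if (!is.null(curve$sample)) sprintf("# sample: %s", curve$sample),
             if (!is.null(curve$seed)) sprintf("# seed: %s", curve$seed),
             "# columns: qz reflectivity sigma")
    rows <- sprintf("%.17g %.17g %.17g", curve$qz, curve$reflectivity,
                    curve$sigma)
    writeLines(c(hdr, rows), path)
    invisible(path)
}

#' Read a reflectivity curve from a column-text file
#'
#' Accepts 3-column files (qz, reflectivity, sigma) or 2-column files, in
#' which case sigma is imputed as 2\% of the reflectivity with a warning.
#' Metadata in `# key: value` header lines (wavelength, normalized, sample,
#' seed) is restored.
#'
#' @param path input file
#' @return an [reflectivity_curve()]
#' @export
read_curve <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    meta <- list(wavelength = 1.24, normalized = FALSE,
                 sample = NULL, seed = NULL)
    is_hdr <- grepl("^\\s*#", lines)
    for (h in lines[is_hdr]) {
        m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
        if (length(m) == 3) {
            key <- m[2]; val <- trimws(m[3])
            if (key == "wavelength") meta$wavelength <- as.numeric(val)
            if (key == "normalized") meta$normalized <- tolower(val) %in% c("true", "yes", "1")
            if (key == "sample") meta$sample <- val
            if (key == "seed") meta$seed <- suppressWarnings(as.integer(val))
        }
    }
    data_idx <- which(!is_hdr & nzchar(trimws(lines)))
    if (length(data_idx) < 1) stop("no data rows in ", path)
    fields <- strsplit(trimws(lines[data_idx]), "\\s+")
    ncol <- length(fields[[1]])
    if (ncol < 2) stop("need at least 2 columns (qz, reflectivity)")
    vals <- lapply(seq_along(fields), function(i) {
        v <- suppressWarnings(as.numeric(fields[[i]]))
        if (length(v) != ncol || any(is.na(v)))
            stop("parse error: non-numeric cell on line ", data_idx[i],
                 " of ", path)
        v
    })
    m <- do.call(rbind, vals)
    qz <- m[, 1]
    if (any(diff(qz) <= 0)) {
        bad <- which(diff(qz) <= 0)[1] + 1
        stop("qz not strictly increasing at line ", data_idx[bad],
             " of ", path)
    }
    refl <- m[, 2]
    if (ncol >= 3) sigma <- m[, 3]
    else {
        warning("2-column file: imputing sigma = 0.02 * reflectivity",
                call. = FALSE)
        sigma <- 0.02 * refl
    }
    reflectivity_curve(qz, refl, sigma, normalized = meta$normalized,
                       wavelength = meta$wavelength, sample = meta$sample,
                       seed = meta$seed)
}

#' Write a density profile as two-column text
#'
#' @param profile a [density_profile()]
#' @param path output file
#' @export
write_profile <- function(profile, path) {
    stopifnot(inherits(profile, "density_profile"))
    writeLines(c("# lipidxr density profile",
                 "# columns: z rho_rel",
                 sprintf("%.17g %.17g", profile$z, profile$rho_rel)), path)
    invisible(path)
}

#' Write a slab fit result as key-value text
#'
#' One `key = value` line per parameter, with `.se` lines for the
#' 1-sigma errors of free parameters, plus `chi2`, `n_points`, `n_free`
#' and the sample label.
#'
#' @param fit an `xr_slab_fit`
#' @param path output file
#' @export
write_fit_result <- function(fit, path) {
    stopifnot(inherits(fit, "xr_slab_fit"))
    pt <- param_table(fit$model)
    out <- c("# lipidxr slab fit result",
             if (!is.null(fit$curve$sample)) sprintf("sample = %s", fit$curve$sample),
             sprintf("%s = %.17g", pt$name, pt$value),
             sprintf("%s.se = %.17g", names(fit$param_errors), fit$param_errors),
             sprintf("chi2 = %.17g", fit$chi2),
             sprintf("n_points = %d", fit$n_points),
             sprintf("n_free = %d", fit$n_free),
             sprintf("fixed = %s", paste(fit$fixed, collapse = ",")))
    writeLines(out, path)
    invisible(path)
}

#' Read a slab fit result written by [write_fit_result()]
#'
#' Reconstructs a minimal `xr_slab_fit` (two-layer model, parameter errors,
#' chi-square) sufficient for [compare_models()].
#'
#' @param path input file
#' @export
read_fit_result <- function(path) {
    lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
    lines <- lines[nzchar(trimws(lines))]
    kv <- strsplit(lines, "\\s*=\\s*")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    get_num <- function(k) as.numeric(vals[match(k, keys)])
    model <- slab_model(
        layers = list(
            layer(get_num("tails.thickness"), get_num("tails.rho_rel"),
                  get_num("tails.roughness")),
            layer(get_num("heads.thickness"), get_num("heads.rho_rel"),
                  get_num("heads.roughness"))),
        subphase_roughness = get_num("subphase.roughness"),
        layer_names = c("tails", "heads"),
        scale = get_num("scale"), background = get_num("background"))
    se_keys <- keys[grepl("\\.se$", keys)]
    pe <- setNames(as.numeric(vals[match(se_keys, keys)]),
                   sub("\\.se$", "", se_keys))
    sample <- if ("sample" %in% keys) vals[match("sample", keys)] else NULL
    structure(list(model = model, par = setNames(numeric(0), character(0)),
                   param_errors = pe, chi2 = get_num("chi2"),
                   n_points = as.integer(get_num("n_points")),
                   n_free = as.integer(get_num("n_free")),
                   curve = list(sample = sample)),
              class = "xr_slab_fit")
}

run_config_keys <- c("sample", "input", "output_dir", "seed", "model",
                     "fit", "simulate")

#' Read a structured run configuration
#'
#' YAML file describing one analysis run: the sample or input path, the
#' slab model (layers, fixed parameters, bounds), fit settings
#' (multistart, seed) and the output directory. Unknown top-level keys are
#' rejected.
#'
#' @param path YAML file
#' @return named list
#' @export
read_run_config <- function(path) {
    cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(cfg), run_config_keys)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg
}

#' Write a resolved run configuration
#'
#' @param cfg named list (subset of the accepted keys)
#' @param path output YAML file
#' @export
write_run_config <- function(cfg, path) {
    unknown <- setdiff(names(cfg), run_config_keys)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    yaml::write_yaml(cfg, path)
    invisible(path)
}
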