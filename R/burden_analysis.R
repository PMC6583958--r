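# Growth-yield and metabolic-burden analysis.
#
# At negligible maintenance, mu = Y_XS * q_S, so the biomass yield is the
# slope of growth rate against substrate uptake rate through the origin —
# estimated over many (q_S, mu) pairs rather than from a single ratio. A
# plasmid-bearing strain reaches lower mu at the same q_S; the extra
# substrate demand of the heterologous load follows from the two yields:
#   q_S,total = q_S,mu + q_S,load
#   q_S,load  = q_S,mu * (Y_WT - Y_loaded) / Y_loaded

#' Assemble a mu-q_S dataset
#'
#' @param q_S substrate uptake rates (mg_S mg_CDW^-1 h^-1), > 0.
#' @param mu matching specific growth rates (h^-1), >= 0.
#' @param strain strain label per record, e.g. `"wildtype"` / `"loaded"`.
#' @return A data.frame of class `mu_qs_dataset` with columns `q_S`, `mu`,
#'   `strain`.
#' @export
mu_qs_dataset <- function(q_S, mu, strain = "wildtype") {
  if (!is.numeric(q_S) || !is.numeric(mu) || length(q_S) != length(mu))
    pf_validation_stop("`q_S` and `mu` must be numeric vectors of equal length")
  if (length(q_S) == 0) pf_validation_stop("empty dataset")
  if (any(!is.finite(q_S)) || any(q_S <= 0))
    pf_validation_stop("`q_S` must be positive")
  if (any(!is.finite(mu)) || any(mu < 0))
    pf_validation_stop("`mu` must be non-negative")
  out <- data.frame(q_S = q_S, mu = mu,
                    strain = rep_len(as.character(strain), length(q_S)))
  class(out) <- c("mu_qs_dataset", "data.frame")
  out
}

#' Estimate a biomass yield from mu-q_S pairs
#'
#' Origin-constrained least squares: `mu = Y * q_S` with no intercept,
#' since maintenance is neglected in this relation. With
#' `intercept = TRUE` an unconstrained line is fitted instead and the
#' (negated, yield-scaled) intercept is reported as an implied maintenance
#' uptake — a sensitivity check, not the default estimator.
#'
#' @param data a [mu_qs_dataset()] (or data.frame with `q_S` and `mu`).
#' @param strain if given, filter `data` to this strain label first.
#' @param intercept fit an unconstrained line instead.
#' @return A list of class `yield_fit`: `yield` (mg_CDW mg_S^-1), `se`,
#'   `n`, `implied_maintenance` (mg_S mg_CDW^-1 h^-1; `NA` for the
#'   origin-constrained fit) and the underlying `lm`.
#' @examples
#' d <- mu_qs_dataset(q_S = c(0.2, 0.5, 1), mu = 0.35 * c(0.2, 0.5, 1))
#' fit_yield(d)$yield # 0.35
#' @export
fit_yield <- function(data, strain = NULL, intercept = FALSE) {
  if (!is.data.frame(data) || !all(c("q_S", "mu") %in% names(data)))
    pf_validation_stop("`data` must have columns `q_S` and `mu`")
  if (!is.null(strain)) {
    if (!"strain" %in% names(data))
      pf_validation_stop("`data` has no `strain` column to filter on")
    data <- data[data$strain == strain, , drop = FALSE]
  }
  if (nrow(data) < 2)
    pf_validation_stop("at least 2 records are required to fit a yield")
  if (intercept) {
    fit <- lm(mu ~ q_S, data = data)
    sl <- summary(fit)$coefficients
    yield <- unname(coef(fit)["q_S"])
    se <- unname(sl["q_S", "Std. Error"])
    maint <- -unname(coef(fit)[1]) / yield
  } else {
    fit <- lm(mu ~ 0 + q_S, data = data)
    sl <- summary(fit)$coefficients
    yield <- unname(coef(fit)["q_S"])
    se <- unname(sl["q_S", "Std. Error"])
    maint <- NA_real_
  }
  structure(list(yield = yield, se = se, n = nrow(data),
                 implied_maintenance = maint, fit = fit),
            class = "yield_fit")
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("<yield_fit> Y_XS = %.4f +/- %.4f mg_CDW/mg_S (n = %d)\n",
              x$yield, x$se, x$n))
  invisible(x)
}

#' Decompose substrate demand into growth and heterologous load
#'
#' From the wildtype and plasmid-bearing yields, the extra substrate uptake
#' the load costs (relative to the growth demand `q_S,mu`) is
#' `(Y_WT - Y_loaded) / Y_loaded`; the loaded strain's total uptake at the
#' same growth rate is `1 +` that fraction of the wildtype's, and the share
#' of total uptake spent on the load is `load / (1 + load)`. Standard
#' errors, if supplied, are propagated to the load fraction by the
#' first-order delta method; a seeded Gaussian bootstrap over the yields is
#' available as a cross-check.
#'
#' @param Y_WT wildtype biomass yield (mg_CDW mg_S^-1), > 0.
#' @param Y_loaded yield of the plasmid-bearing strain, > 0; a value above
#'   `Y_WT` (negative burden) warns but is not an error.
#' @param se_WT,se_loaded optional standard errors of the yields.
#' @param bootstrap number of bootstrap draws (0 to skip).
#' @param seed RNG seed, required when `bootstrap > 0`.
#' @return A list of class `burden_result`: `Y_WT`, `Y_loaded`,
#'   `load_fraction_of_growth`, `total_fraction`, `load_share_of_total`,
#'   `load_fraction_se` (delta method; `NA` without SEs) and, when
#'   bootstrapped, `load_fraction_boot_ci` (2.5/97.5 percentiles).
#' @examples
#' burden_decomposition(0.35, 0.263)
#' @export
burden_decomposition <- function(Y_WT, Y_loaded, se_WT = NA, se_loaded = NA,
                                 bootstrap = 0, seed = NULL) {
  if (!is.numeric(Y_WT) || length(Y_WT) != 1 || !is.finite(Y_WT) || Y_WT <= 0 ||
      !is.numeric(Y_loaded) || length(Y_loaded) != 1 || !is.finite(Y_loaded) ||
      Y_loaded <= 0)
    pf_validation_stop("yields must be single positive numbers")
  if (Y_loaded > Y_WT)
    warning("Y_loaded exceeds Y_WT: negative burden (check strain labels?)",
            call. = FALSE)
  load <- (Y_WT - Y_loaded) / Y_loaded
  res <- list(Y_WT = Y_WT, Y_loaded = Y_loaded,
              load_fraction_of_growth = load,
              total_fraction = 1 + load,
              load_share_of_total = load / (1 + load))
  if (is.finite(se_WT) && is.finite(se_loaded)) {
    # f = (Yw - Yl)/Yl: df/dYw = 1/Yl, df/dYl = -Yw/Yl^2
    res$load_fraction_se <- sqrt((se_WT / Y_loaded)^2 +
                                 (Y_WT * se_loaded / Y_loaded^2)^2)
  } else res$load_fraction_se <- NA_real_
  if (bootstrap > 0) {
    if (!is.finite(se_WT) || !is.finite(se_loaded))
      pf_validation_stop("bootstrap requires `se_WT` and `se_loaded`")
    if (is.null(seed))
      pf_validation_stop("a `seed` is required for the bootstrap")
    draws <- with_seed(seed, {
      yw <- rnorm(bootstrap, Y_WT, se_WT)
      yl <- rnorm(bootstrap, Y_loaded, se_loaded)
      keep <- yw > 0 & yl > 0
      (yw[keep] - yl[keep]) / yl[keep]
    })
    res$load_fraction_boot_ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  structure(res, class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(paste0("<burden_result> Y_WT = %.4f, Y_loaded = %.4f\n",
                     "  load demand  : %.1f%% of growth demand\n",
                     "  total uptake : %.1f%% of wildtype at equal mu\n",
                     "  load share   : %.1f%% of total uptake\n"),
              x$Y_WT, x$Y_loaded, 100 * x$load_fraction_of_growth,
              100 * x$total_fraction, 100 * x$load_share_of_total))
  invisible(x)
}

#' Bead geometry for micro-encapsulation
#'
#' `bead_volume()` is the enclosed sphere volume `pi d^3 / 6` at a given
#' droplet diameter, in microlitres (1 mm^3 = 1 uL). `bead_size_stats()`
#' summarises a measured diameter sample.
#'
#' @param diameter bead diameter(s) in mm, >= 0; vectorised.
#' @param diameters a numeric vector of measured diameters (mm), n >= 2.
#' @return `bead_volume()`: volume(s) in uL. `bead_size_stats()`: a list
#'   with `mean`, `sd` and `n`.
#' @examples
#' bead_volume(2.92) # ~13 uL
#' bead_size_stats(c(2.7, 3.1))
#' @export
bead_volume <- function(diameter) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter < 0))
    pf_validation_stop("`diameter` must be non-negative and finite (mm)")
  pi * diameter^3 / 6
}

#' @rdname bead_volume
#' @export
bead_size_stats <- function(diameters) {
  if (!is.numeric(diameters) || any(!is.finite(diameters)))
    pf_validation_stop("`diameters` must be finite numeric (mm)")
  if (length(diameters) < 2)
    pf_validation_stop("at least 2 diameters are required for a standard deviation")
  list(mean = mean(diameters), sd = sd(diameters), n = length(diameters))
}
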