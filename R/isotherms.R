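# Equilibrium titration isotherms: cooperative (Hill) binding and
# ligand-depletion (tight-binding) models, with least-squares fitters.
#
# Gel-shift and thermophoresis titrations report the fraction of a labelled
# DNA probe bound as protein concentration increases. A sharp sigmoidal
# curve indicates cooperative assembly and is summarised by the Hill
# equation; when the apparent KD approaches the probe concentration the
# free-ligand approximation fails and the quadratic depletion model is
# required.

#' Hill binding isotherm
#'
#' `theta = P^h / (kd_app^h + P^h)`. `kd_app` is the titration midpoint
#' (EC50) of the cooperative curve, an apparent KD rather than a
#' microscopic constant.
#'
#' @param p protein concentration (nM, or any unit shared with `kd_app`).
#' @param kd_app apparent KD / EC50 (same unit as `p`).
#' @param h Hill coefficient.
#' @return fraction bound in `[0, 1]`.
#' @export
hill_model <- function(p, kd_app, h = 1) {
  stopifnot(kd_app > 0, h > 0)
  p^h / (kd_app^h + p^h)
}

#' Ligand-depletion (tight-binding) isotherm
#'
#' Fraction of probe bound when free protein is depleted by binding:
#' `theta = ((P0 + D0 + kd) - sqrt((P0 + D0 + kd)^2 - 4 P0 D0)) / (2 D0)`,
#' the physical root of the binding quadratic.
#'
#' @param p0 total protein concentration (nM).
#' @param d0 total probe concentration (nM), > 0.
#' @param kd dissociation constant (nM).
#' @return fraction of probe bound in `[0, 1]`.
#' @export
depletion_model <- function(p0, d0, kd) {
  if (any(d0 <= 0)) stop("probe concentration d0 must be > 0")
  stopifnot(kd > 0, all(p0 >= 0))
  b <- p0 + d0 + kd
  (b - sqrt(b^2 - 4 * p0 * d0)) / (2 * d0)
}

fit_isotherm_core <- function(conc, theta, model, d0 = NULL) {
  stopifnot(length(conc) == length(theta), length(conc) >= 3L)
  if (all(theta == 0)) stop("all-zero isotherm: nothing to fit")
  pmax_ <- max(conc)
  if (model == "hill") {
    starts <- expand.grid(kd = stats::quantile(conc, c(0.25, 0.5, 0.75),
                                               names = FALSE),
                          h = c(1, 2, 4))
    lower <- c(kd = pmax_ * 1e-6, h = 0.5)
    upper <- c(kd = pmax_ * 10, h = 6)
    pred <- function(kd, h) hill_model(conc, kd, h)
  } else {
    starts <- data.frame(kd = stats::quantile(conc, c(0.1, 0.25, 0.5, 0.75),
                                              names = FALSE))
    lower <- c(kd = pmax_ * 1e-8)
    upper <- c(kd = pmax_ * 10)
    pred <- function(kd) depletion_model(conc, d0, kd)
  }
  best <- NULL
  for (g in seq_len(nrow(starts))) {
    fml <- if (model == "hill") theta ~ pred(kd, h) else theta ~ pred(kd)
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, start = as.list(starts[g, , drop = FALSE]),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(coef = stats::coef(fit), rss = rss, fit = fit)
    }
  }
  if (is.null(best)) stop("isotherm fit failed for all starts")
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(best$coef)))
  list(coef = best$coef, se = se, rss = best$rss)
}

#' Fit the Hill model to a titration isotherm
#'
#' Bounded least squares (`h` in `[0.5, 6]`, `kd` in `(0, 10 * max(P)]`)
#' from a fixed multi-start grid; deterministic.
#'
#' @param iso a `binding_isotherm` (from [simulate_isotherm()]) or a
#'   data.frame with columns `conc_nM` and `fraction_bound`.
#' @return list of class `isotherm_fit`: `kd_app` (nM), `hill_h`,
#'   `model_kind = "hill"`, `rss`, `se` (named standard errors).
#' @export
fit_hill <- function(iso) {
  df <- as.data.frame(iso[c("conc_nM", "fraction_bound")])
  if (nrow(df) == 0L) stop("empty isotherm")
  r <- fit_isotherm_core(df$conc_nM, df$fraction_bound, "hill")
  structure(list(kd_app = unname(r$coef["kd"]),
                 hill_h = unname(r$coef["h"]),
                 model_kind = "hill", rss = r$rss, se = r$se),
            class = "isotherm_fit")
}

#' Fit the depletion model to a titration isotherm
#'
#' @param iso a `binding_isotherm` with known probe concentration, or a
#'   data.frame with `conc_nM`, `fraction_bound` plus `probe_nM` given
#'   explicitly.
#' @param probe_nM total probe concentration (taken from `iso$probe_nM`
#'   when absent).
#' @return list of class `isotherm_fit`: `kd_app` (nM),
#'   `model_kind = "depletion"`, `rss`, `se`.
#' @export
fit_depletion <- function(iso, probe_nM = NULL) {
  df <- as.data.frame(iso[c("conc_nM", "fraction_bound")])
  if (nrow(df) == 0L) stop("empty isotherm")
  d0 <- probe_nM %||% iso$probe_nM
  if (is.null(d0)) stop("probe concentration required for depletion fit")
  r <- fit_isotherm_core(df$conc_nM, df$fraction_bound, "depletion", d0 = d0)
  structure(list(kd_app = unname(r$coef["kd"]), hill_h = NA_real_,
                 model_kind = "depletion", rss = r$rss, se = r$se),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("%s isotherm fit: apparent KD = %.3g nM", x$model_kind,
              x$kd_app))
  if (!is.na(x$hill_h)) cat(sprintf(", h = %.2f", x$hill_h))
  cat(sprintf(" (rss %.3g)\n", x$rss))
  invisible(x)
}
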