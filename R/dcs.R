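# Diffuse correlation spectroscopy: forward model, fitting, relative flow ----

#' Tissue optical properties for the DCS model
#'
#' @param mua absorption coefficient (mm^-1) at the DCS wavelength.
#' @param musp reduced scattering coefficient (mm^-1).
#' @param n_tissue tissue refractive index.
#' @param rho_cm source-detector separation (cm); the handheld probe default
#'   is 2.5 cm.
#' @param wavelength_nm laser wavelength (nm), 786 by default.
#' @param r_eff effective reflection coefficient of the tissue-air boundary
#'   (0.493 for n = 1.4).
#' @return Object of class `tissue_optics`.
#' @export
tissue_optics <- function(mua = 0.005, musp = 0.8, n_tissue = 1.4,
                          rho_cm = 2.5, wavelength_nm = 786, r_eff = 0.493) {
  for (v in c(mua, musp, n_tissue, rho_cm, wavelength_nm)) {
    dh_assert(is_number(v) && v > 0, "dothisto_config",
              "all tissue optics must be positive numbers")
  }
  structure(list(mua = mua, musp = musp, n_tissue = n_tissue,
                 rho_cm = rho_cm, wavelength_nm = wavelength_nm,
                 r_eff = r_eff),
            class = "tissue_optics")
}

#' Intensity autocorrelation model for semi-infinite tissue
#'
#' Forward model for the normalized intensity autocorrelation `g2(tau)`
#' measured by DCS.  The field autocorrelation `g1` is the solution of the
#' correlation diffusion equation in the homogeneous semi-infinite geometry
#' with an extrapolated boundary:
#' \deqn{G1(tau) \propto e^{-K(\tau) r_1}/r_1 - e^{-K(\tau) r_b}/r_b}
#' with `K^2(tau) = 3 mua musp' + 6 musp'^2 k0^2 BFI tau` (Brownian-motion
#' flow model, `BFI = alpha * D_B`), `k0 = 2 pi n / lambda` in tissue,
#' `r1 = sqrt(rho^2 + z0^2)`, `rb = sqrt(rho^2 + (z0 + 2 zb)^2)`,
#' `z0 = 1/musp'`, `zb = 2 (1 + R_eff) / (3 musp' (1 - R_eff))`.
#' `g1` is normalized so `g1(0) = 1` and the Siegert relation gives
#' `g2 = 1 + beta g1^2`.
#'
#' All internal lengths are in mm; `BFI` is accepted in the conventional
#' cm^2/s and converted.
#'
#' @param tau delay times (s), positive.
#' @param bfi blood flow index (cm^2/s), >= 0.
#' @param beta coherence factor in (0, 1].
#' @param optics a [tissue_optics()] object.
#' @return Numeric vector of `g2` values.
#' @export
g2_model <- function(tau, bfi, beta, optics = tissue_optics()) {
  dh_assert(all(tau > 0), "dothisto_config", "delays must be positive")
  dh_assert(is_number(bfi) && bfi >= 0, "dothisto_config", "bfi must be >= 0")
  dh_assert(is_number(beta) && beta > 0 && beta <= 1, "dothisto_config",
            "beta must be in (0, 1]")
  1 + beta * g1_semiinf(tau, bfi, optics)^2
}

g1_semiinf <- function(tau, bfi, optics) {
  mua <- optics$mua; musp <- optics$musp
  rho <- optics$rho_cm * 10                       # cm -> mm
  lambda_mm <- optics$wavelength_nm * 1e-6        # nm -> mm
  k0 <- 2 * pi * optics$n_tissue / lambda_mm      # 1/mm, in tissue
  db <- bfi * 100                                 # cm^2/s -> mm^2/s
  z0 <- 1 / musp
  zb <- 2 * (1 + optics$r_eff) / (3 * musp * (1 - optics$r_eff))
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  K <- sqrt(3 * mua * musp + 6 * musp^2 * k0^2 * db * tau)
  K0 <- sqrt(3 * mua * musp)
  num <- exp(-K * r1) / r1 - exp(-K * rb) / rb
  den <- exp(-K0 * r1) / r1 - exp(-K0 * rb) / rb
  num / den
}

#' A measured (or simulated) autocorrelation curve
#'
#' @param tau strictly increasing positive delays (s).
#' @param g2 intensity autocorrelation values.
#' @param label `"tumor"` or `"normal"` scan position class.
#' @param position_index integer scan position along the probe line.
#' @return Object of class `g2_curve`.
#' @export
g2_curve <- function(tau, g2, label = c("normal", "tumor"),
                     position_index = 1L) {
  label <- match.arg(label)
  dh_assert(length(tau) == length(g2), "dothisto_config",
            "tau and g2 lengths differ")
  dh_assert(all(tau > 0) && !is.unsorted(tau, strictly = TRUE),
            "dothisto_config", "tau must be strictly increasing and positive")
  structure(list(tau = as.numeric(tau), g2 = as.numeric(g2), label = label,
                 position_index = as.integer(position_index)),
            class = "g2_curve")
}

#' Fit the blood flow index to an autocorrelation curve
#'
#' Least-squares fit of [g2_model()] to a measured curve over `(BFI, beta)`,
#' with positivity enforced by fitting `log10(BFI)` and box-bounding `beta`
#' in (0, 1].  Levenberg-Marquardt minimization is multi-started over a
#' log-spaced grid of initial BFI values so the fit cannot be trapped by a
#' poor starting decay rate.
#'
#' A curve that does not decay (early-delay mean indistinguishable from the
#' late-delay tail) is reported as a rejected fit (`converged = FALSE`)
#' rather than an error.  The default fit window runs from the first delay
#' to the first delay at which the curve reaches its noise-floor tail (the
#' mean of the last 10 % of points), so the noise floor itself is not fitted.
#'
#' @param curve a [g2_curve()] (or list with `tau`, `g2`).
#' @param optics a [tissue_optics()] object.
#' @param fit_window optional numeric length-2 `(tau_min, tau_max)` in
#'   seconds overriding the automatic window.
#' @param starts log10 BFI (cm^2/s) multi-start grid.
#' @param min_decay minimum g2 amplitude drop (early mean minus tail mean)
#'   for the curve to count as decaying.
#' @return Object of class `bfi_fit`: `bfi` (cm^2/s), `beta`, `rss`,
#'   `converged`, `n_used`, plus the window and the curve for methods.
#' @export
fit_bfi <- function(curve, optics = tissue_optics(), fit_window = NULL,
                    starts = seq(-9, -7, by = 0.5), min_decay = 0.02) {
  tau <- curve$tau; g2 <- curve$g2
  n <- length(tau)
  dh_assert(n >= 10, "dothisto_insufficient_data",
            "need at least 10 delay points")
  n10 <- max(3L, ceiling(0.1 * n))
  tail_mean <- mean(g2[(n - n10 + 1):n])
  head_mean <- mean(g2[1:n10])
  rejected <- function(reason) {
    structure(list(bfi = NA_real_, beta = NA_real_, rss = NA_real_,
                   converged = FALSE, reason = reason, n_used = 0L,
                   curve = curve, optics = optics),
              class = "bfi_fit")
  }
  if (!is.finite(head_mean - tail_mean) || head_mean - tail_mean < min_decay) {
    return(rejected("non-decaying curve"))
  }
  if (is.null(fit_window)) {
    # stop at the first delay whose g2 has reached the tail level
    reach <- which(g2 <= tail_mean)
    hi <- if (length(reach)) tau[reach[1]] else tau[n]
    fit_window <- c(tau[1], hi)
  }
  use <- tau >= fit_window[1] & tau <= fit_window[2]
  if (sum(use) < 10) use <- seq_len(n) <= max(10, sum(use))
  tu <- tau[use]; gu <- g2[use]

  resid_fn <- function(p) {
    g2_model(tu, 10^p[1], p[2], optics) - gu
  }
  beta0 <- max(min(g2[1] - 1, 1), 1e-2)
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(log10_bfi = s, beta = beta0), fn = resid_fn,
      lower = c(-12, 1e-3), upper = c(-4, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) return(rejected("optimization failed"))
  conv <- best$info %in% 1:3 && is.finite(best$rss)
  structure(list(bfi = 10^best$par[["log10_bfi"]], beta = best$par[["beta"]],
                 rss = best$rss, converged = conv, reason = NULL,
                 n_used = sum(use), fit_window = fit_window,
                 curve = curve, optics = optics),
            class = "bfi_fit")
}

#' @export
print.bfi_fit <- function(x, ...) {
  if (!x$converged) {
    cat("bfi_fit: rejected (", x$reason %||% "not converged", ")\n", sep = "")
  } else {
    cat(sprintf("bfi_fit: BFI = %.3e cm^2/s, beta = %.3f, rss = %.3e (n = %d)\n",
                x$bfi, x$beta, x$rss, x$n_used))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.bfi_fit <- function(object, ...) {
  c(bfi = object$bfi, beta = object$beta)
}

#' @export
predict.bfi_fit <- function(object, tau = NULL, ...) {
  if (is.null(tau)) tau <- object$curve$tau
  if (!object$converged) return(rep(NA_real_, length(tau)))
  g2_model(tau, object$bfi, object$beta, object$optics)
}

#' @export
residuals.bfi_fit <- function(object, ...) {
  object$curve$g2 - predict(object)
}

#' @export
plot.bfi_fit <- function(x, ...) {
  plot(x$curve$tau, x$curve$g2, log = "x", xlab = expression(tau ~ "(s)"),
       ylab = expression(g[2](tau)), pch = 16, cex = 0.6, ...)
  if (x$converged) {
    graphics::lines(x$curve$tau, predict(x), col = 2, lwd = 2)
  }
  invisible(x)
}

#' Relative blood flow from labelled fits
#'
#' Tumor and normal scan positions are averaged separately and the relative
#' blood flow is the ratio of the mean tumor to mean normal blood flow index.
#' Non-converged fits are excluded and counted.
#'
#' @param fits list of `bfi_fit` objects, each carrying its curve's
#'   tumor/normal label (or a list of `list(label=, fit=)` pairs).
#' @return List of class `rbf_result`: `rbf`, `bfi_tumor`, `bfi_normal`,
#'   `n_tumor`, `n_normal`, `n_excluded`.
#' @export
compute_rbf <- function(fits) {
  lab <- vapply(fits, function(f) {
    if (!is.null(f$curve)) f$curve$label else f$label
  }, character(1))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  bfi <- vapply(fits, function(f) f$bfi %||% NA_real_, numeric(1))
  keep_t <- conv & lab == "tumor"
  keep_n <- conv & lab == "normal"
  if (!any(keep_t) || !any(keep_n)) {
    dh_error("dothisto_insufficient_data",
             "need at least one converged tumor and one converged normal fit")
  }
  bt <- mean(bfi[keep_t]); bn <- mean(bfi[keep_n])
  structure(list(rbf = bt / bn, bfi_tumor = bt, bfi_normal = bn,
                 n_tumor = sum(keep_t), n_normal = sum(keep_n),
                 n_excluded = sum(!conv)),
            class = "rbf_result")
}

#' Tabulate a list of blood-flow fits
#'
#' @param fits list of `bfi_fit` objects.
#' @return `data.frame` with `position_index`, `label`, `bfi_cm2_s`,
#'   `beta`, `rss`, `converged` — the flat form written to fit-results CSV.
#' @export
bfi_fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(position_index = f$curve$position_index %||% NA_integer_,
               label = f$curve$label %||% NA_character_,
               bfi_cm2_s = f$bfi %||% NA_real_,
               beta = f$beta %||% NA_real_,
               rss = f$rss %||% NA_real_,
               converged = isTRUE(f$converged))
  }))
}

#' @export
print.rbf_result <- function(x, ...) {
  cat(sprintf(
    "rBF = %.3f (tumor BFI %.3e over %d positions / normal BFI %.3e over %d; %d excluded)\n",
    x$rbf, x$bfi_tumor, x$n_tumor, x$bfi_normal, x$n_normal, x$n_excluded))
  invisible(x)
}
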