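# Venous fraction and relative mammary metabolic rate of oxygen ---------------

#' Venous blood-volume fraction from oxygen saturations
#'
#' Tissue oxygen saturation mixes the arterial and venous compartments,
#' `StO2 = (1 - gamma) SaO2 + gamma SvO2`, where `gamma` is the fraction of
#' blood volume in the venous compartment.  Inverting,
#' `gamma = (SaO2 - StO2) / (SaO2 - SvO2)`.
#'
#' @param sto2 measured tissue saturation (fraction).
#' @param sao2 arterial saturation; 0.98 default when unmeasured.
#' @param svo2 venous saturation; 0.70 default when unmeasured.
#' @return `gamma` in `[0, 1]`.  An `StO2` outside `[SvO2, SaO2]` has no
#'   physical venous fraction and raises an `dothisto_unphysical_gamma`
#'   error carrying the out-of-range value in its `gamma` field.
#' @export
gamma_from_sats <- function(sto2, sao2 = 0.98, svo2 = 0.70) {
  dh_assert(is_number(sao2) && is_number(svo2) && is_number(sto2),
            "dothisto_config", "saturations must be single numbers")
  dh_assert(svo2 < sao2, "dothisto_config", "SvO2 must be below SaO2")
  gamma <- (sao2 - sto2) / (sao2 - svo2)
  if (sto2 < svo2 || sto2 > sao2) {
    dh_error("dothisto_unphysical_gamma",
             sprintf("StO2 = %.3f outside [SvO2, SaO2] = [%.3f, %.3f] gives unphysical gamma = %.3f",
                     sto2, svo2, sao2, gamma),
             gamma = gamma)
  }
  gamma
}

#' Tumor-to-normal relative mammary metabolic rate of oxygen
#'
#' `rMMRO2 = (gamma_N / gamma_T) * (rHb / rTHC) * rBF`, combining the DOT
#' hemoglobin ratios with the DCS relative blood flow.  The venous fractions
#' may be supplied directly, derived from tumor/normal tissue saturations via
#' [gamma_from_sats()], or left at the unity-ratio fallback (gamma_N/gamma_T
#' = 1) when no saturation information is available; the result records which
#' of these was used.
#'
#' @param rhb,rthc,rbf tumor-to-normal deoxyhemoglobin, total hemoglobin and
#'   blood flow ratios (positive).
#' @param gamma_n,gamma_t venous fractions in (0, 1], or `NULL`.
#' @param sto2_t,sto2_n tumor/normal tissue saturations used to derive the
#'   venous fractions when `gamma_*` are not given.
#' @param sao2,svo2 arterial/venous saturations for the derivation.
#' @return Object of class `rmmro2_result`: `rmmro2`, the inputs echoed, and
#'   `gamma_source` (`"supplied"`, `"from_sto2"` or `"unity_ratio"`).
#' @export
compute_rmmro2 <- function(rhb, rthc, rbf, gamma_n = NULL, gamma_t = NULL,
                           sto2_t = NULL, sto2_n = NULL,
                           sao2 = 0.98, svo2 = 0.70) {
  for (v in list(rhb, rthc, rbf)) {
    dh_assert(is_number(v) && v > 0, "dothisto_domain",
              "rHb, rTHC and rBF must all be positive")
  }
  if (!is.null(gamma_n) && !is.null(gamma_t)) {
    gamma_source <- "supplied"
  } else if (!is.null(sto2_t) && !is.null(sto2_n)) {
    gamma_t <- gamma_from_sats(sto2_t, sao2, svo2)
    gamma_n <- gamma_from_sats(sto2_n, sao2, svo2)
    gamma_source <- "from_sto2"
  } else {
    gamma_n <- gamma_t <- 1
    gamma_source <- "unity_ratio"
  }
  for (v in list(gamma_n, gamma_t)) {
    dh_assert(is_number(v) && v > 0 && v <= 1, "dothisto_domain",
              "venous fractions must be in (0, 1]")
  }
  structure(list(rmmro2 = (gamma_n / gamma_t) * (rhb / rthc) * rbf,
                 rhb = rhb, rthc = rthc, rbf = rbf,
                 gamma_n = gamma_n, gamma_t = gamma_t,
                 gamma_source = gamma_source),
            class = "rmmro2_result")
}

#' @export
print.rmmro2_result <- function(x, ...) {
  cat(sprintf("rMMRO2 = %.4f  (gamma_N/gamma_T = %.3f [%s], rHb = %.3f, rTHC = %.3f, rBF = %.3f)\n",
              x$rmmro2, x$gamma_n / x$gamma_t, x$gamma_source,
              x$rhb, x$rthc, x$rbf))
  invisible(x)
}
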