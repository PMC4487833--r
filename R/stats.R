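# Small-sample correlation and group-comparison statistics --------------------

drop_incomplete <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n_dropped = sum(!ok))
}

#' Pearson correlation with t-based (or exact permutation) p-value
#'
#' Sample linear correlation; by default the two-sided p-value uses the
#' classical t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom (the convention of the correlation tables this package
#' reproduces).  `exact = TRUE` enumerates all `n!` pairings instead
#' (n <= 9), giving the distribution-free permutation p-value.  Incomplete
#' pairs are dropped (and counted); zero variance in either variable leaves
#' the correlation undefined.
#'
#' @param x,y paired numeric vectors.
#' @param exact use the exact permutation null (n <= 9 only).
#' @return List of class `assoc_test`: `estimate` (r), `p`, `n`,
#'   `n_dropped`, `method`, `p_method`; `estimate` and `p` carry the
#'   undefined-result signal for degenerate input.
#' @export
cor_pearson <- function(x, y, exact = FALSE) {
  d <- drop_incomplete(x, y)
  n <- length(d$x)
  out <- list(method = "pearson", n = n, n_dropped = d$n_dropped)
  if (n < 3 || var(d$x) == 0 || var(d$y) == 0) {
    out$estimate <- undefined_value("fewer than 3 pairs or zero variance")
    out$p <- undefined_value("fewer than 3 pairs or zero variance")
    out$p_method <- "none"
  } else {
    r <- cor(d$x, d$y)
    out$estimate <- r
    if (isTRUE(exact)) {
      dh_assert(n <= 9, "dothisto_config",
                "exact permutation p is enumerable only up to n = 9")
      out$p <- perm_cor_pvalue(d$x, d$y)
      out$p_method <- "exact"
    } else {
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      out$p <- min(1, 2 * pt(-abs(tt), df = n - 2))
      out$p_method <- "t"
    }
  }
  structure(out, class = "assoc_test")
}

# exact two-sided permutation p-value of a correlation between fixed ranks
# (or values): proportion of permutations with |centered cross-product| at
# least the observed, enumerated with Heap's algorithm
perm_cor_pvalue <- function(x, y) {
  n <- length(x)
  cx <- x - mean(x); cy <- y - mean(y)
  s_obs <- abs(sum(cx * cy))
  count <- 0L
  total <- 0L
  a <- seq_len(n)
  c_idx <- rep(1L, n)
  score <- function(p) abs(sum(cx * cy[p]))
  if (score(a) >= s_obs - 1e-12) count <- count + 1L
  total <- 1L
  i <- 1L
  while (i <= n) {
    if (c_idx[i] < i) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_idx[i]]; a[c_idx[i]] <- a[i]; a[i] <- tmp
      }
      if (score(a) >= s_obs - 1e-12) count <- count + 1L
      total <- total + 1L
      c_idx[i] <- c_idx[i] + 1L
      i <- 1L
    } else {
      c_idx[i] <- 1L
      i <- i + 1L
    }
  }
  count / total
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Pearson correlation of mid-ranks (average ranks on ties).  For `n <= 9`
#' the two-sided p-value is exact, by enumeration of all `n!` orderings
#' (mid-ranks preserved, so ties are handled exactly); for larger samples
#' the t approximation on the rank correlation is used.
#'
#' @param x,y paired numeric vectors.
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   enumerates up to n = 9.
#' @return List of class `assoc_test` with `estimate` (rho), `p`, `n`,
#'   `n_dropped`, `method`, `p_method` (`"exact"` or `"t-approx"`).
#' @export
cor_spearman <- function(x, y, exact = NULL) {
  d <- drop_incomplete(x, y)
  n <- length(d$x)
  out <- list(method = "spearman", n = n, n_dropped = d$n_dropped)
  if (n < 3 || var(d$x) == 0 || var(d$y) == 0) {
    out$estimate <- undefined_value("fewer than 3 pairs or zero variance")
    out$p <- undefined_value("fewer than 3 pairs or zero variance")
    out$p_method <- "none"
    return(structure(out, class = "assoc_test"))
  }
  rx <- rank(d$x); ry <- rank(d$y)
  rho <- cor(rx, ry)
  use_exact <- if (is.null(exact)) n <= 9 else exact
  if (use_exact) {
    out$p <- perm_cor_pvalue(rx, ry)
    out$p_method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    out$p <- min(1, 2 * pt(-abs(tt), df = n - 2))
    out$p_method <- "t-approx"
  }
  out$estimate <- rho
  structure(out, class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s correlation: %s = %.3f, p = %.4g (n = %d%s)\n",
              x$method, if (x$method == "pearson") "r" else "rho",
              as.numeric(x$estimate), as.numeric(x$p), x$n,
              if (x$n_dropped) paste0(", ", x$n_dropped, " dropped") else ""))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test with mid-ranks: exact by
#' enumeration when the combined sample is small (`n_a + n_b <= 12`) and
#' tie-free, otherwise the normal approximation with tie and continuity
#' corrections.  Two identical constant groups are reported as `p = 1`.
#'
#' @param a,b numeric vectors for the two groups (e.g. Ki67-positive and
#'   Ki67-negative subjects' optical parameter).
#' @param exact_max combined size up to which the exact distribution is used.
#' @return List of class `group_comparison`: group sizes, `statistic`
#'   (Mann-Whitney W for group `a`), `p`, group medians, `exact` flag.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  dh_assert(na >= 1 && nb >= 1, "dothisto_insufficient_data",
            "both groups need at least one observation")
  ties <- anyDuplicated(c(a, b)) > 0
  if (diff(range(c(a, b))) == 0) {
    # all observations identical: no evidence of separation
    out <- list(n_a = na, n_b = nb, statistic = na * nb / 2, p = 1,
                median_a = median(a), median_b = median(b), exact = FALSE)
    return(structure(out, class = "group_comparison"))
  }
  use_exact <- (na + nb) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE,
                alternative = "two.sided"))
  structure(list(n_a = na, n_b = nb,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 median_a = median(a), median_b = median(b),
                 exact = use_exact),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.4g (%s; n = %d vs %d; medians %.3g vs %.3g)\n",
              x$statistic, x$p, if (x$exact) "exact" else "normal approx.",
              x$n_a, x$n_b, x$median_a, x$median_b))
  invisible(x)
}

#' Dichotomize a Ki67 percentage
#'
#' Positive when the percentage strictly exceeds the cutoff (a value exactly
#' at the cutoff is negative); 15 % is the common clinical convention,
#' though clinics vary between 10 and 20 %, so the cutoff is a parameter.
#'
#' @param pct Ki67 percentage(s), >= 0.
#' @param cutoff positivity cutoff (percent).
#' @return factor with levels `negative`, `positive`.
#' @export
ki67_group <- function(pct, cutoff = 15) {
  dh_assert(all(pct >= 0, na.rm = TRUE), "dothisto_domain",
            "percentages must be non-negative")
  factor(ifelse(pct > cutoff, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Threshold scan of predictive values
#'
#' For each candidate threshold, calls a subject "proliferative" when its
#' parameter value falls on the configured side of the threshold, compares
#' the call with the true Ki67 group, and tabulates the confusion counts and
#' derived rates.  NPV = TN / (TN + FN); rates with empty denominators are
#' `NA` (undefined), not 0.
#'
#' @param values numeric parameter per subject (e.g. rHb).
#' @param labels factor from [ki67_group()] (`positive` = proliferative).
#' @param thresholds candidate thresholds in the parameter's units.
#' @param direction `"less"` when values below the threshold predict
#'   proliferative (the deoxyhemoglobin convention), `"greater"` for the
#'   opposite.
#' @return `data.frame`: threshold, tp, fp, tn, fn, npv, ppv, sensitivity,
#'   specificity.
#' @export
npv_scan <- function(values, labels, thresholds,
                     direction = c("less", "greater")) {
  direction <- match.arg(direction)
  labels <- factor(labels, levels = c("negative", "positive"))
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  rows <- lapply(thresholds, function(th) {
    call_pos <- if (direction == "less") values < th else values > th
    tp <- sum(call_pos & labels == "positive")
    fp <- sum(call_pos & labels == "negative")
    fn <- sum(!call_pos & labels == "positive")
    tn <- sum(!call_pos & labels == "negative")
    rate <- function(num, den) if (den > 0) num / den else NA_real_
    data.frame(threshold = th, tp = tp, fp = fp, tn = tn, fn = fn,
               npv = rate(tn, tn + fn), ppv = rate(tp, tp + fp),
               sensitivity = rate(tp, tp + fn),
               specificity = rate(tn, tn + fp))
  })
  do.call(rbind, rows)
}

#' Linear fit with a pointwise confidence band for the mean
#'
#' Ordinary least squares of `y` on `x` with the standard
#' `t`-based pointwise confidence band for the mean response,
#' `yhat +/- t_{n-2} * SE(mean)`, evaluated on a grid (the band drawn as
#' dotted lines around a fitted line in a correlation plot).
#'
#' @param x,y paired numeric vectors.
#' @param level confidence level (default 0.95).
#' @param grid_n evaluation grid size across the range of `x`.
#' @return List of class `linear_fit_ci`: `slope`, `intercept`, `band`
#'   (data.frame x, fit, lwr, upr), and the underlying `lm` fit.
#' @export
linear_fit_ci <- function(x, y, level = 0.95, grid_n = 50) {
  d <- drop_incomplete(x, y)
  dh_assert(length(d$x) >= 3, "dothisto_insufficient_data",
            "need at least 3 complete pairs")
  if (var(d$x) == 0) {
    return(structure(list(slope = undefined_value("zero x-variance"),
                          intercept = undefined_value("zero x-variance"),
                          band = NULL, fit = NULL),
                     class = "linear_fit_ci"))
  }
  df <- data.frame(x = d$x, y = d$y)
  fit <- lm(y ~ x, data = df)
  grid <- data.frame(x = seq(min(d$x), max(d$x), length.out = grid_n))
  pr <- predict(fit, newdata = grid, interval = "confidence", level = level)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 band = cbind(grid, as.data.frame(pr)), fit = fit,
                 level = level),
            class = "linear_fit_ci")
}

#' @export
print.linear_fit_ci <- function(x, ...) {
  if (is_undefined(x$slope)) {
    cat("linear fit undefined (zero x-variance)\n")
  } else {
    cat(sprintf("linear fit: y = %.4g + %.4g x with %d%% pointwise mean CI band\n",
                x$intercept, x$slope, round(100 * x$level)))
  }
  invisible(x)
}

#' @export
plot.linear_fit_ci <- function(x, ...) {
  d <- x$fit$model
  plot(d$x, d$y, xlab = "x", ylab = "y", pch = 16, ...)
  graphics::lines(x$band$x, x$band$fit, lwd = 2)
  graphics::lines(x$band$x, x$band$lwr, lty = 3)
  graphics::lines(x$band$x, x$band$upr, lty = 3)
  invisible(x)
}

#' Build the optical-vs-histology association table
#'
#' Pearson and Spearman correlations (with p-values and per-cell n) between
#' each tumor-to-normal optical parameter and each histology biomarker,
#' using pairwise-complete observations per cell — subjects enter exactly
#' the analyses their data support, so n varies across cells (a subject
#' without normal-tissue Ki67 expression contributes to cancer-Ki67 cells
#' but not to relative-Ki67 cells).  Cells with fewer than 3 complete pairs
#' are marked not computable.  No multiple-testing correction is applied by
#' default (exploratory convention); `p_adjust = "BH"` adds
#' Benjamini-Hochberg adjusted columns.
#'
#' @param data data frame of per-subject pipeline outputs.
#' @param optical_vars,histo_vars column names to cross.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return `data.frame` of class `association_table`: one row per cell with
#'   `optical`, `marker`, `n`, `pearson_r`, `p_pearson`, `spearman_rho`,
#'   `p_spearman`, `computable`.
#' @export
build_association_table <- function(data,
                                    optical_vars = c("rStO2", "rTHC", "rHbO2",
                                                     "rHb", "rmusp"),
                                    histo_vars = c("rKi67", "Ki67_T_pct",
                                                   "MVA", "r_compact"),
                                    p_adjust = "none") {
  rows <- list()
  for (h in histo_vars) {
    for (o in optical_vars) {
      x <- data[[o]]; y <- data[[h]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n >= 3 && var(x[ok]) > 0 && var(y[ok]) > 0) {
        pe <- cor_pearson(x[ok], y[ok])
        sp <- cor_spearman(x[ok], y[ok])
        rows[[length(rows) + 1]] <- data.frame(
          optical = o, marker = h, n = n,
          pearson_r = as.numeric(pe$estimate), p_pearson = as.numeric(pe$p),
          spearman_rho = as.numeric(sp$estimate),
          p_spearman = as.numeric(sp$p), computable = TRUE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          optical = o, marker = h, n = n,
          pearson_r = NA_real_, p_pearson = NA_real_,
          spearman_rho = NA_real_, p_spearman = NA_real_,
          computable = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p_pearson_adj <- stats::p.adjust(out$p_pearson, method = p_adjust)
    out$p_spearman_adj <- stats::p.adjust(out$p_spearman, method = p_adjust)
  }
  class(out) <- c("association_table", "data.frame")
  out
}

#' @export
print.association_table <- function(x, digits = 3, ...) {
  cat("optical-histology association table (pairwise-complete n per cell)\n")
  for (h in unique(x$marker)) {
    sub <- x[x$marker == h, ]
    cat("\n--", h, "--\n")
    m <- rbind(`Pearson r` = round(sub$pearson_r, digits),
               `p` = round(sub$p_pearson, digits),
               `Spearman rho` = round(sub$spearman_rho, digits),
               `p ` = round(sub$p_spearman, digits),
               n = sub$n)
    colnames(m) <- sub$optical
    print(m)
  }
  invisible(x)
}
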