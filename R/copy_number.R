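#' Tumour fraction from the maximum somatic VAF
#'
#' Under a heterozygous-truncal, copy-neutral assumption the tumour-derived
#' fraction of plasma DNA is twice the maximum somatic VAF: T = 2 x mVAF /
#' 100 with mVAF in percent. mVAF above 50% implies loss of heterozygosity
#' or copy-number effects the linear model ignores, so T is clamped to 1
#' with a warning.
#'
#' @param mvaf_pct Maximum somatic VAF in percent; must be positive.
#' @return Tumour fraction in (0, 1].
#' @export
#' @examples
#' tumour_fraction(10)  # 0.2
#' tumour_fraction(50)  # 1
tumour_fraction <- function(mvaf_pct) {
  if (any(!is.finite(mvaf_pct)) || any(mvaf_pct <= 0)) {
    stop("mvaf_pct must be > 0: tumour fraction undefined")
  }
  t <- 2 * mvaf_pct / 100
  if (any(t > 1)) {
    warning("mVAF > 50%: tumour fraction clamped to 1")
    t <- pmin(t, 1)
  }
  t
}

#' Purity-adjust a plasma copy number
#'
#' The observed plasma copy number of a gene mixes tumour and normal DNA:
#' observed = 2(1 - T) + T x true. Inverting gives
#' adjusted = (observed - 2(1 - T)) / T. Copy-neutral genes (observed = 2)
#' are a fixed point for every T, and T = 1 returns the observed value
#' unchanged. Negative adjusted values (purity overestimation) are floored
#' at 0 with a warning; the raw value is kept in the `"raw"` attribute.
#'
#' @param observed_pcn Observed plasma copy number, >= 0.
#' @param t Tumour fraction in (0, 1], from [tumour_fraction()].
#' @return Adjusted plasma copy number (>= 0), with attribute `raw` holding
#'   the unfloored values.
#' @export
#' @examples
#' adjust_pcn(3, 0.5)  # 4
#' adjust_pcn(2, 0.2)  # 2: copy-neutral fixed point
adjust_pcn <- function(observed_pcn, t) {
  if (any(!is.finite(t)) || any(t <= 0) || any(t > 1)) {
    stop("t must be in (0, 1]")
  }
  if (any(observed_pcn < 0)) stop("observed_pcn must be >= 0")
  raw <- (observed_pcn - 2 * (1 - t)) / t
  out <- raw
  if (any(raw < 0)) {
    warning("negative adjusted copy number floored at 0")
    out <- pmax(raw, 0)
  }
  attr(out, "raw") <- raw
  out
}

#' Purity-adjust all copy-number calls in a cohort
#'
#' Computes per-patient tumour fractions from mVAF and applies
#' [adjust_pcn()] to every copy-number call. Patients with no computable
#' mVAF (no variants) get `NA` adjusted values.
#'
#' @param cohort A [ctdna_cohort()] (germline-filtered).
#' @param operating_threshold Amplification call threshold on the adjusted
#'   scale (strict `>`).
#' @return The cohort with cn columns `mvaf_pct`, `t`, `adjusted_pcn`,
#'   `adjusted_pcn_raw` and `call_at_threshold` filled in.
#' @export
adjust_cohort_pcn <- function(cohort, operating_threshold = 2.0) {
  if (!nrow(cohort$cn)) {
    return(cohort)
  }
  mv <- compute_mvaf(cohort)
  cn <- cohort$cn
  cn$mvaf_pct <- mv$mvaf_pct[match(cn$patient_id, mv$patient_id)]
  ok <- !is.na(cn$mvaf_pct) & cn$mvaf_pct > 0
  cn$t <- NA_real_
  cn$adjusted_pcn <- NA_real_
  cn$adjusted_pcn_raw <- NA_real_
  if (any(ok)) {
    t <- suppressWarnings(tumour_fraction(cn$mvaf_pct[ok]))
    adj <- suppressWarnings(adjust_pcn(cn$observed_pcn[ok], t))
    cn$t[ok] <- t
    cn$adjusted_pcn[ok] <- as.numeric(adj)
    cn$adjusted_pcn_raw[ok] <- attr(adj, "raw")
  }
  cn$call_at_threshold <- !is.na(cn$adjusted_pcn) &
    cn$adjusted_pcn > operating_threshold
  cohort$cn <- cn
  cohort
}

#' ROC evaluation of an amplification call against tissue labels
#'
#' Classifies amplification as adjusted copy number strictly greater than
#' the threshold, sweeps the threshold over all unique adjusted values to
#' build a full ROC curve (trapezoidal AUC), and reports sensitivity and
#' specificity at the operating threshold with exact Clopper-Pearson 95%
#' confidence intervals.
#'
#' @param adjusted_pcn Numeric vector of adjusted plasma copy numbers.
#' @param tissue_positive Logical vector, `TRUE` for tissue-amplified.
#' @param operating_threshold Operating threshold (strict `>`), default 2.0.
#' @param conf_level Confidence level for the Clopper-Pearson intervals.
#' @return List of class `roc_result`: `curve` (data.frame threshold,
#'   sensitivity, specificity), `auc`, `sensitivity`, `specificity`,
#'   `sens_ci`, `spec_ci`, `n_positive`, `n_negative`, `operating_threshold`,
#'   `ci_method`.
#' @export
amplification_roc <- function(adjusted_pcn, tissue_positive,
                              operating_threshold = 2.0,
                              conf_level = 0.95) {
  keep <- !is.na(adjusted_pcn) & !is.na(tissue_positive)
  x <- adjusted_pcn[keep]
  y <- as.logical(tissue_positive)[keep]
  if (length(unique(y)) < 2) {
    stop("tissue labels contain a single class: ROC undefined")
  }
  np <- sum(y)
  nn <- sum(!y)
  sens_spec <- function(thr) {
    c(sum(x > thr & y) / np, sum(x <= thr & !y) / nn)
  }
  thr_grid <- c(-Inf, sort(unique(x)))
  curve <- t(vapply(thr_grid, sens_spec, numeric(2)))
  curve <- data.frame(
    threshold = thr_grid, sensitivity = curve[, 1], specificity = curve[, 2]
  )
  # trapezoid over (1 - specificity, sensitivity), sorted by FPR
  fpr <- 1 - curve$specificity
  ord <- order(fpr, curve$sensitivity)
  fx <- fpr[ord]
  fy <- curve$sensitivity[ord]
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  op <- sens_spec(operating_threshold)
  sens_ci <- stats::binom.test(sum(x > operating_threshold & y), np,
    conf.level = conf_level
  )$conf.int
  spec_ci <- stats::binom.test(sum(x <= operating_threshold & !y), nn,
    conf.level = conf_level
  )$conf.int
  structure(
    list(
      curve = curve, auc = auc,
      sensitivity = op[1], specificity = op[2],
      sens_ci = as.numeric(sens_ci), spec_ci = as.numeric(spec_ci),
      n_positive = np, n_negative = nn,
      operating_threshold = operating_threshold,
      ci_method = "Clopper-Pearson (exact binomial)"
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f | at threshold > %.2f: sens %.1f%% (%.1f-%.1f), spec %.1f%% (%.1f-%.1f) [%s]\n",
    x$auc, x$operating_threshold,
    100 * x$sensitivity, 100 * x$sens_ci[1], 100 * x$sens_ci[2],
    100 * x$specificity, 100 * x$spec_ci[1], 100 * x$spec_ci[2],
    x$ci_method
  ))
  invisible(x)
}
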