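# ROC / Youden / Wilcoxon diagnostics and the barycentric fraction embedding.
#
# AUC is the Mann-Whitney probability that a value from the designated
# larger-value class exceeds one from the other class (ties counting 1/2),
# which equals the trapezoidal integral of the empirical ROC curve — the test
# suite asserts that identity against an independent trapezoidal oracle.

#' Empirical ROC analysis
#'
#' @param values numeric measurements
#' @param labels binary class labels (logical, or any two-level vector)
#' @param larger the label whose class is expected to have the larger values
#'   (explicit by design: class orientation is never inferred from the data)
#' @return object of class `roc_result`: `thresholds` (midpoints between
#'   consecutive distinct sorted values, plus -Inf/Inf), `sensitivity`,
#'   `specificity`, `auc`, `youden_threshold`, `youden_j`
#' @examples
#' r <- roc(c(1, 2, 3, 4), c("a", "a", "b", "b"), larger = "b")
#' r$auc  # 1
#' @export
roc <- function(values, labels, larger) {
  stopifnot(length(values) == length(labels))
  is_pos <- labels == larger
  if (!any(is_pos) || all(is_pos))
    stop("parameter error: both classes must be non-empty", call. = FALSE)
  pos <- values[is_pos]
  neg <- values[!is_pos]
  auc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  sv <- sort(unique(values))
  thresholds <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  sens <- vapply(thresholds, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg <= t), numeric(1))
  j <- sens + spec - 1
  # ties: prefer higher specificity, then the smaller threshold
  ord <- order(-j, -spec, thresholds)
  best <- ord[1L]
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 youden_threshold = thresholds[best], youden_j = j[best],
                 larger = larger),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f; Youden J %.3f at threshold %.4g\n",
              x$auc, x$youden_j, x$youden_threshold))
  invisible(x)
}

#' Sensitivity and specificity at a fixed threshold
#'
#' Sensitivity is the fraction of the larger-value class strictly above the
#' threshold; specificity the fraction of the other class at or below it.
#'
#' @inheritParams roc
#' @param threshold classification cutoff
#' @return named vector `c(sensitivity, specificity)`
#' @export
sens_spec_at <- function(values, labels, threshold, larger) {
  is_pos <- labels == larger
  if (!any(is_pos) || all(is_pos))
    stop("parameter error: both classes must be non-empty", call. = FALSE)
  c(sensitivity = mean(values[is_pos] > threshold),
    specificity = mean(values[!is_pos] <= threshold))
}

#' Youden-optimal cutoff of an ROC result
#'
#' `J = max_t { sensitivity(t) + specificity(t) - 1 }`; ties resolved to the
#' higher-specificity, then smaller, threshold.
#'
#' @param r a `roc_result`
#' @return named list `threshold`, `j`
#' @export
youden <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  list(threshold = r$youden_threshold, j = r$youden_j)
}

#' Paired Wilcoxon signed-rank test
#'
#' `W` is the smaller of the positive and negative rank sums of the non-zero
#' paired differences (average ranks for tied magnitudes). The two-sided p is
#' exact — full enumeration of the 2^n sign assignments over the observed
#' (possibly tied) ranks — for n <= `exact_max`, otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y paired samples; at least 5 non-zero differences required
#' @param exact_max largest n for exact enumeration
#' @return list `w`, `p`, `n` (non-zero differences), `method`
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate-input error: all differences zero", call. = FALSE)
  if (n < 5) stop("parameter error: fewer than 5 non-zero differences", call. = FALSE)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  tot <- w_pos + w_neg
  if (n <= exact_max) {
    # distribution of the positive rank sum over all sign patterns, by
    # convolution; symmetric about tot/2, so the two-sided p is the mass at
    # least as far from the centre as observed
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)    # 2^n achievable sums
    p <- mean(abs(sums - tot / 2) >= abs(w_pos - tot / 2) - 1e-9)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - 0.5 * sign(w_pos - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal-approximation"
  }
  list(w = w, p = p, n = n, method = method)
}

#' Barycentric embedding of the three volume fractions
#'
#' Maps `(VF_ic, VF_ec, VF_iso)` (non-negative, summing to 1) onto the unit
#' triangle with vertices VF_ic = (0,0), VF_ec = (1,0),
#' VF_iso = (0.5, sqrt(3)/2).
#'
#' @param vf_ic,vf_ec,vf_iso fractions (vectors allowed), each in `[0, 1]`
#' @param tol allowed deviation of the sum from 1
#' @return n x 2 matrix of 2D coordinates
#' @export
ternary_coordinates <- function(vf_ic, vf_ec, vf_iso, tol = 1e-6) {
  s <- vf_ic + vf_ec + vf_iso
  if (any(abs(s - 1) > tol) || any(vf_ic < 0 | vf_ec < 0 | vf_iso < 0))
    stop("validation error: fractions must be non-negative and sum to 1",
         call. = FALSE)
  cbind(x = vf_ec + 0.5 * vf_iso, y = sqrt(3) / 2 * vf_iso)
}

#' Clinical fixture: per-patient edema volume, LTD and motor outcome
#'
#' Loads the packaged 24-patient table (case id, edema volume in mm^3,
#' lesion-to-tract distance in mm, and the motor-decline label, decline
#' meaning MRC muscle-strength grade <= 4). Labels are stored exactly as the
#' seven decline rows of the source table; its accompanying text mentions six
#' decliners, a discrepancy recorded in the file's comment header, as is the
#' misprinted thousands separator in case 19's edema volume.
#'
#' @return `data.frame` with columns `case`, `age`, `sex`, `edema_volume_mm3`,
#'   `ltd_mm`, `motor_decline` ("yes"/"no")
#' @export
read_table1 <- function() {
  path <- system.file("extdata", "table1_patients.tsv", package = "nodditract",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
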