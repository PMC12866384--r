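#' Quantitative early-imaging classification rules
#'
#' `classify_blood_pool_grade()` implements the blood-pool grading rule:
#' myocardial uptake equal to or greater than blood-pool uptake is
#' positive. `classify_pid()` implements the %ID/mL rule-in threshold:
#' values at or above the threshold (default 0.003%) are positive (the
#' boundary itself is classified positive; recorded in provenance).
#'
#' @param suv_myo,suv_bp myocardial and blood-pool SUVmean (> 0).
#' @param subject_id,window optional provenance fields.
#' @return A `diagnosis_record`: list with `subject_id`, `window`, `rule`,
#'   `inputs_used`, `label` (`"positive"`/`"negative"`).
#' @examples
#' classify_blood_pool_grade(3.86, 3.08)$label
#' classify_pid(0.00139)$label
#' @export
classify_blood_pool_grade <- function(suv_myo, suv_bp,
                                      subject_id = NA_character_,
                                      window = NA_character_) {
  if (suv_myo <= 0 || suv_bp <= 0) stop("SUV inputs must be positive")
  structure(list(subject_id = subject_id, window = window,
                 rule = "blood_pool_grade",
                 inputs_used = c(suv_myo = suv_myo, suv_bp = suv_bp),
                 label = if (suv_myo >= suv_bp) "positive" else "negative"),
            class = "diagnosis_record")
}

#' @rdname classify_blood_pool_grade
#' @param pid_percent myocardial %ID/mL (percent; >= 0).
#' @param threshold rule-in threshold, percent (default 0.003).
#' @export
classify_pid <- function(pid_percent, threshold = 0.003,
                         subject_id = NA_character_, window = NA_character_) {
  if (pid_percent < 0) stop("pid_percent must be >= 0")
  structure(list(subject_id = subject_id, window = window,
                 rule = "pid_threshold",
                 inputs_used = c(pid_percent = pid_percent, threshold = threshold),
                 label = if (pid_percent >= threshold) "positive" else "negative"),
            class = "diagnosis_record")
}

#' @export
print.diagnosis_record <- function(x, ...) {
  cat(sprintf("Diagnosis [%s]: %s (%s)\n", x$rule, x$label,
              paste(sprintf("%s=%.4g", names(x$inputs_used), x$inputs_used),
                    collapse = ", ")))
  invisible(x)
}

#' Diagnostic performance against a reference standard
#'
#' @param predicted,truth equal-length vectors of `"positive"`/`"negative"`
#'   labels (or logicals, `TRUE` = positive).
#' @return A `performance_summary`: confusion counts `TP`, `FP`, `TN`, `FN`
#'   and `sensitivity`, `specificity`, `accuracy` in percent (`NA` with an
#'   `undefined` flag when a class is absent).
#' @export
diagnostic_performance <- function(predicted, truth) {
  as_pos <- function(x) {
    if (is.logical(x)) return(x)
    if (!all(x %in% c("positive", "negative")))
      stop("labels must be 'positive'/'negative' or logical")
    x == "positive"
  }
  p <- as_pos(predicted); t <- as_pos(truth)
  if (length(p) == 0L) stop("degenerate input: empty label vectors")
  if (length(p) != length(t)) stop("predicted and truth lengths differ")
  TP <- sum(p & t); FP <- sum(p & !t); TN <- sum(!p & !t); FN <- sum(!p & t)
  sens <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = sens, specificity = spec,
                 accuracy = 100 * (TP + TN) / length(p),
                 undefined = c(sensitivity = TP + FN == 0,
                               specificity = TN + FP == 0)),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Performance: sens %.1f%%, spec %.1f%%, acc %.1f%% (TP %d FP %d TN %d FN %d)\n",
              x$sensitivity, x$specificity, x$accuracy, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Cohen's kappa for two binary readers
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement from the
#' marginal products. When agreement is perfect, kappa is defined as 1
#' even if the marginals are degenerate (all labels identical in both
#' readers); a `degenerate` attribute flags that case.
#'
#' @param labels_a,labels_b equal-length binary label vectors.
#' @return kappa (numeric scalar, in [-1, 1]).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) == 0L) stop("degenerate input: empty label vectors")
  if (length(labels_a) != length(labels_b)) stop("label lengths differ")
  a <- as.character(labels_a); b <- as.character(labels_b)
  lev <- sort(unique(c(a, b)))
  if (length(lev) > 2L) stop("cohen_kappa expects binary labels")
  po <- mean(a == b)
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (pe >= 1) {
    k <- if (po == 1) 1 else 0
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  (po - pe) / (1 - pe)
}

#' Welch's t-test from group summary statistics
#'
#' Two-sided unequal-variance t-test computed from `(mean, sd, n)` per
#' group, with Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (`n >= 2`, `sd > 0`).
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_t_from_summary(30.9, 5.6, 11, 26.4, 3.4, 8)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 <= 0 || sd2 <= 0) stop("need sd > 0 in both groups")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
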