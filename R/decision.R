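#' Organ-at-risk constraint set
#'
#' The clinical planning constraints that drive technique selection:
#' ipsilateral lung V20Gy < 30%, heart V25Gy < 10% and mean heart dose
#' < 3 Gy. All comparisons are strict.
#'
#' @param lung_V20_max maximum ipsilateral-lung V20Gy in percent.
#' @param heart_V25_max maximum heart V25Gy in percent.
#' @param heart_Dmean_max maximum mean heart dose in Gy.
#' @return a `constraint_set`.
#' @export
constraint_set <- function(lung_V20_max = 30, heart_V25_max = 10,
                           heart_Dmean_max = 3) {
  if (any(c(lung_V20_max, heart_V25_max, heart_Dmean_max) <= 0))
    stop("all constraint thresholds must be positive")
  structure(list(lung_V20_max = lung_V20_max, heart_V25_max = heart_V25_max,
                 heart_Dmean_max = heart_Dmean_max),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set> lung V20Gy < %g%%, heart V25Gy < %g%%, heart Dmean < %g Gy\n",
              x$lung_V20_max, x$heart_V25_max, x$heart_Dmean_max))
  invisible(x)
}

#' Check OAR constraints on DVH metrics
#'
#' @param metrics named list with elements `lung` and `heart`, each a
#'   [dvh_metrics][extract_metrics] object (both must be present —
#'   a missing OAR is an error, never a silent pass).
#' @param constraints a [constraint_set()].
#' @return list with `pass` (logical) and `violations` (data.frame of
#'   failed comparisons: `constraint`, `observed`, `threshold`).
#' @export
check_constraints <- function(metrics, constraints = constraint_set()) {
  for (nm in c("lung", "heart")) {
    m <- metrics[[nm]]
    if (is.null(m) || !inherits(m, "dvh_metrics") || !isTRUE(m$present))
      stop(sprintf("'%s' DVH metrics are missing; cannot evaluate constraints", nm))
  }
  checks <- data.frame(
    constraint = c("lung_V20Gy", "heart_V25Gy", "heart_Dmean"),
    observed = c(metrics$lung$V20Gy, metrics$heart$V25Gy, metrics$heart$Dmean),
    threshold = c(constraints$lung_V20_max, constraints$heart_V25_max,
                  constraints$heart_Dmean_max))
  bad <- checks$observed >= checks$threshold  # strict '<' to pass
  list(pass = !any(bad), violations = checks[bad, , drop = FALSE])
}

#' Recommend a treatment technique
#'
#' Applies the default-3D-CRT rule: 3D-CRT is recommended whenever its
#' predicted plan meets all OAR constraints; IMRT is recommended only when
#' 3D-CRT fails. When both techniques fail, IMRT is recommended with
#' `needs_review = TRUE` so the case is escalated to a human planner.
#'
#' @param crt_metrics,imrt_metrics named lists (`lung`, `heart`) of
#'   predicted [dvh_metrics][extract_metrics] for each technique.
#' @param constraints a [constraint_set()].
#' @param case_id case identifier carried into the result.
#' @return a `technique_decision`: `recommended`, `crt_pass`, `imrt_pass`,
#'   `violations` (for the failing techniques) and `needs_review`.
#' @export
recommend <- function(crt_metrics, imrt_metrics,
                      constraints = constraint_set(), case_id = "case") {
  crt <- check_constraints(crt_metrics, constraints)
  imrt <- check_constraints(imrt_metrics, constraints)
  recommended <- if (crt$pass) "3DCRT" else "IMRT"
  needs_review <- !crt$pass && !imrt$pass
  viol <- rbind(
    if (!crt$pass) cbind(technique = "3DCRT", crt$violations),
    if (!imrt$pass) cbind(technique = "IMRT", imrt$violations))
  structure(list(case_id = case_id, recommended = recommended,
                 crt_pass = crt$pass, imrt_pass = imrt$pass,
                 violations = viol, needs_review = needs_review),
            class = "technique_decision")
}

#' @export
print.technique_decision <- function(x, ...) {
  cat(sprintf("<decision> %s: %s (3D-CRT pass: %s, IMRT pass: %s%s)\n",
              x$case_id, x$recommended, x$crt_pass, x$imrt_pass,
              if (x$needs_review) ", NEEDS REVIEW" else ""))
  if (!is.null(x$violations) && nrow(x$violations))
    print(x$violations, row.names = FALSE)
  invisible(x)
}

#' Confusion matrix of technique decisions
#'
#' 2x2 counts of decided vs ground-truth technique with 3D-CRT as the
#' positive class.
#'
#' @param ground_truth,decisions character vectors of `"3DCRT"`/`"IMRT"`
#'   labels over the same cases, in the same order.
#' @return a `technique_confusion`: list with `tp`, `fp`, `fn`, `tn` and
#'   the 2x2 `table` (rows = decision, columns = truth).
#' @export
build_confusion <- function(ground_truth, decisions) {
  lv <- c("3DCRT", "IMRT")
  if (length(ground_truth) != length(decisions))
    stop("ground truth and decisions cover different case sets")
  if (!all(ground_truth %in% lv) || !all(decisions %in% lv))
    stop("labels must be '3DCRT' or 'IMRT'")
  gt <- factor(ground_truth, levels = lv)
  dc <- factor(decisions, levels = lv)
  tab <- table(decision = dc, truth = gt)
  structure(list(tp = tab["3DCRT", "3DCRT"], fp = tab["3DCRT", "IMRT"],
                 fn = tab["IMRT", "3DCRT"], tn = tab["IMRT", "IMRT"],
                 table = tab, positive_class = "3DCRT"),
            class = "technique_confusion")
}

#' Confusion matrix from printed counts
#'
#' Builds a [technique_confusion][build_confusion] directly from the four
#' cell counts (decided 3D-CRT/actually 3D-CRT, decided 3D-CRT/actually
#' IMRT, decided IMRT/actually 3D-CRT, decided IMRT/actually IMRT), e.g.
#' when re-analysing a published confusion table.
#'
#' @param tp,fp,fn,tn non-negative integer counts; positive class 3D-CRT.
#' @return a `technique_confusion`.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  gt <- c(rep("3DCRT", tp), rep("IMRT", fp), rep("3DCRT", fn), rep("IMRT", tn))
  dc <- c(rep("3DCRT", tp + fp), rep("IMRT", fn + tn))
  build_confusion(gt, dc)
}

#' @export
print.technique_confusion <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Classification metrics of a decision confusion matrix
#'
#' Accuracy, recall, precision and F1 in percent with 3D-CRT as the
#' positive class: `accuracy = (TP+TN)/total`, `recall = TP/(TP+FN)`,
#' `precision = TP/(TP+FP)`, `F1 = 2PR/(P+R)`. A metric with a zero
#' denominator is reported as `NA` (undefined), never as 0.
#'
#' @param matrix a [technique_confusion][build_confusion].
#' @return a `classification_report` with `accuracy`, `recall`,
#'   `precision`, `f1` in percent.
#' @export
classification_report <- function(matrix) {
  stopifnot(inherits(matrix, "technique_confusion"))
  tp <- as.numeric(matrix$tp); fp <- as.numeric(matrix$fp)
  fn <- as.numeric(matrix$fn); tn <- as.numeric(matrix$tn)
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- safe(tp, tp + fn)
  precision <- safe(tp, tp + fp)
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = 100 * (tp + tn) / total,
                 recall = 100 * recall, precision = 100 * precision,
                 f1 = 100 * f1), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  recall %.1f%%  precision %.1f%%  F1 %.1f%%\n",
              x$accuracy, x$recall, x$precision, x$f1))
  invisible(x)
}

#' Run the decision framework over a cohort
#'
#' Applies [recommend()] per case from predicted DVH metrics of both
#' techniques, then validates against ground-truth labels with a confusion
#' matrix and classification report.
#'
#' @param case_metrics list over cases; each element a list with `case_id`,
#'   `crt` and `imrt` (each a named list of `lung`/`heart`
#'   [dvh_metrics][extract_metrics]), and optionally `ptv` metrics carried
#'   into the audit output.
#' @param ground_truth character vector of ground-truth labels, same
#'   order as `case_metrics`.
#' @param constraints a [constraint_set()].
#' @return list with `decisions` (per-case objects), `audit` (data.frame
#'   of per-case labels, passes and review flags), `confusion` and
#'   `report`.
#' @export
run_framework <- function(case_metrics, ground_truth,
                          constraints = constraint_set()) {
  if (length(case_metrics) != length(ground_truth))
    stop("ground truth and metrics cover different case sets")
  decisions <- lapply(case_metrics, function(cm)
    recommend(cm$crt, cm$imrt, constraints,
              case_id = if (!is.null(cm$case_id)) cm$case_id else "case"))
  labels <- vapply(decisions, `[[`, character(1), "recommended")
  confusion <- build_confusion(ground_truth, labels)
  audit <- data.frame(
    case_id = vapply(decisions, `[[`, character(1), "case_id"),
    ground_truth = ground_truth,
    recommended = labels,
    crt_pass = vapply(decisions, `[[`, logical(1), "crt_pass"),
    imrt_pass = vapply(decisions, `[[`, logical(1), "imrt_pass"),
    needs_review = vapply(decisions, `[[`, logical(1), "needs_review"))
  list(decisions = decisions, audit = audit, confusion = confusion,
       report = classification_report(confusion))
}
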