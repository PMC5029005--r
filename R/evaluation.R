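# Evaluation statistics: precision/recall/F1 against gold labels, simple
# percent agreement, and Cohen's kappa. Percentages are reported to one
# decimal with round-half-up, matching the conventions of published
# corpus-evaluation tables.

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Compare predicted and gold POS/NEG labels
#'
#' Counts `tp` (both POS), `fp` (predicted POS, gold NEG), `fn` (predicted
#' NEG, gold POS), `tn` (both NEG) and derives precision, recall and F1 as
#' percentages (`P = 100 tp/(tp+fp)`, `R = 100 tp/(tp+fn)`,
#' `F = 2PR/(P+R)`), rounded half-up to one decimal.
#'
#' @param predicted,gold Equal-length aligned character vectors with values
#'   `"POS"`/`"NEG"`.
#' @return An object of class `eval_result`: list with `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`.
#' @export
evaluate_labels <- function(predicted, gold) {
  predicted <- as.character(predicted); gold <- as.character(gold)
  if (length(predicted) != length(gold)) {
    stop("predicted and gold label vectors must have equal length", call. = FALSE)
  }
  ok <- c("POS", "NEG")
  if (!all(predicted %in% ok) || !all(gold %in% ok)) {
    stop("labels must be POS or NEG", call. = FALSE)
  }
  tp <- sum(predicted == "POS" & gold == "POS")
  fp <- sum(predicted == "POS" & gold == "NEG")
  fn <- sum(predicted == "NEG" & gold == "POS")
  tn <- sum(predicted == "NEG" & gold == "NEG")
  p <- if (tp + fp > 0) round_half_up(100 * tp / (tp + fp)) else NA_real_
  r <- if (tp + fn > 0) round_half_up(100 * tp / (tp + fn)) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) prf_from_pr(p, r) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = p, recall = r, f1 = f),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> tp=%d fp=%d fn=%d tn=%d  P=%.1f%% R=%.1f%% F=%.1f%%\n",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' F1 from precision and recall percentages
#'
#' Harmonic mean `2PR/(P+R)` of two percentages, rounded half-up.
#'
#' @param precision_pct,recall_pct Percentages in \[0, 100\].
#' @param digits Decimal places of the half-up rounding (default 1).
#' @return F1 percentage. When both inputs are 0 the result is defined as
#'   `0` with a warning.
#' @export
prf_from_pr <- function(precision_pct, recall_pct, digits = 1L) {
  stopifnot(precision_pct >= 0, precision_pct <= 100,
            recall_pct >= 0, recall_pct <= 100)
  if (precision_pct + recall_pct == 0) {
    warning("precision and recall both zero; F1 defined as 0", call. = FALSE)
    return(0)
  }
  round_half_up(2 * precision_pct * recall_pct / (precision_pct + recall_pct),
                digits)
}

#' Simple percent agreement
#'
#' `100 * agreements / (agreements + disagreements)`, rounded half-up to
#' one decimal.
#'
#' @param agreements,disagreements Non-negative counts, not both zero.
#' @return Agreement percentage.
#' @export
simple_agreement <- function(agreements, disagreements) {
  stopifnot(agreements >= 0, disagreements >= 0)
  if (agreements + disagreements == 0) {
    stop("agreements and disagreements are both zero", call. = FALSE)
  }
  round_half_up(100 * agreements / (agreements + disagreements))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/total` and expected agreement
#' `p_e = sum(row_i * col_i) / total^2`. Works for any square label matrix
#' (the 2x2 POS/NEG case and beyond).
#'
#' @param confusion Square numeric matrix of label co-counts (rows: one
#'   annotator, columns: the other), total > 0.
#' @return Kappa in \[-1, 1\]. Degenerate tables with `p_e = 1` are an
#'   error (kappa undefined).
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square", call. = FALSE)
  total <- sum(confusion)
  if (total <= 0) stop("confusion matrix total must be positive", call. = FALSE)
  p_o <- sum(diag(confusion)) / total
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (isTRUE(all.equal(p_e, 1))) {
    stop("expected agreement is 1; kappa undefined", call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Pairwise annotation agreement between two label vectors
#'
#' @param a,b Equal-length label vectors from two annotators.
#' @return An object of class `agreement_result`: counts of agreements and
#'   disagreements, the simple percent agreement, the label confusion
#'   matrix, and Cohen's kappa (`NA` if undefined).
#' @export
agreement <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop("label vectors must have equal length", call. = FALSE)
  agr <- sum(a == b); dis <- sum(a != b)
  labs <- sort(unique(c(a, b)))
  confusion <- table(factor(a, levels = labs), factor(b, levels = labs))
  kap <- tryCatch(cohens_kappa(unclass(confusion)), error = function(e) NA_real_)
  structure(list(agreements = agr, disagreements = dis,
                 percent = simple_agreement(agr, dis),
                 confusion = confusion, kappa = kap),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %d/%d agreements (%.1f%%), kappa = %s\n",
              x$agreements, x$agreements + x$disagreements, x$percent,
              if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa)))
  invisible(x)
}
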