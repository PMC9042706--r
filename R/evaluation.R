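# final calls from either a cascade_prediction or a plain character vector
.calls_of <- function(predictions) {
  if (is.data.frame(predictions)) as.character(predictions$final_call)
  else as.character(predictions)
}

#' Operational sensitivity and specificity of cascade calls
#'
#' Follows the operational diagnostic-yield convention for a classifier
#' with a rejection option: sensitivity = correct calls / all samples
#' (an "undetermined" call counts against sensitivity), and specificity =
#' correct calls / assigned samples (samples with a non-"undetermined"
#' call). This is NOT the epidemiological true-negative rate: it answers
#' "when the model does commit to an entity, how often is it right".
#'
#' @param predictions a `cascade_prediction` or character vector of final
#'   calls.
#' @param truth character vector of true labels, same length/order.
#' @return list of class `evaluation_report`: `n_total`, `n_assigned`,
#'   `n_correct`, `sensitivity`, `specificity` (NA when nothing was
#'   assigned), their 2-decimal rounding (`sensitivity_2dp`,
#'   `specificity_2dp`), `per_entity` breakdown, `misclassified` and
#'   `undetermined` sample indices.
#' @examples
#' # the definitional worked example on printed confusion counts:
#' calls <- c(rep("A", 133), rep("B", 4), rep("undetermined", 60))
#' truth <- c(rep("A", 137), rep("A", 60))
#' r <- sensitivity_specificity(calls, truth)
#' c(r$sensitivity_2dp, r$specificity_2dp)  # 0.68, 0.97
#' @export
sensitivity_specificity <- function(predictions, truth) {
  call <- .calls_of(predictions)
  truth <- as.character(truth)
  if (length(call) != length(truth))
    stop("predictions and truth differ in length")
  assigned <- call != "undetermined"
  correct <- assigned & call == truth
  n_total <- length(call)
  n_assigned <- sum(assigned)
  n_correct <- sum(correct)
  sens <- n_correct / n_total
  spec <- if (n_assigned > 0) n_correct / n_assigned else NA_real_

  per_entity <- lapply(split(seq_along(truth), truth), function(idx) {
    a <- assigned[idx]; c_ <- correct[idx]
    list(n = length(idx), n_assigned = sum(a), n_correct = sum(c_),
         sensitivity = sum(c_) / length(idx),
         specificity = if (sum(a)) sum(c_) / sum(a) else NA_real_)
  })
  structure(list(n_total = n_total, n_assigned = n_assigned,
                 n_correct = n_correct,
                 sensitivity = sens, specificity = spec,
                 sensitivity_2dp = round(sens, 2),
                 specificity_2dp = if (is.na(spec)) NA_real_
                                   else round(spec, 2),
                 per_entity = per_entity,
                 misclassified = which(assigned & !correct),
                 undetermined = which(!assigned)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.2f (%d/%d), specificity %s (%d/%d); %d undetermined\n",
    x$sensitivity, x$n_correct, x$n_total,
    if (is.na(x$specificity)) "undefined" else sprintf("%.2f", x$specificity),
    x$n_correct, x$n_assigned, length(x$undetermined)))
  invisible(x)
}

#' Minimal tumor-content cutoff per entity
#'
#' For one entity, given each sample's tumor cell content and its cascade
#' probability of belonging to that entity, finds the smallest observed
#' content value c such that strictly more than `target_fraction` of the
#' samples with content >= c have probability strictly above
#' `prob_threshold`. If no observed value qualifies, the maximum content
#' is returned flagged as not attainable.
#'
#' @param probabilities probability of the true entity, per sample.
#' @param tumor_contents tumor cell content in [0,1], per sample.
#' @param target_fraction default 0.9 (the ">90%" rule; strict).
#' @param prob_threshold default 0.5 (strict).
#' @param grid optional step for a fixed grid of candidate cutoffs
#'   (e.g. 0.01) instead of the observed content values.
#' @return the cutoff, with attributes `attainable` (logical) and
#'   `fraction` (the fraction achieved at the cutoff).
#' @export
purity_cutoff <- function(probabilities, tumor_contents,
                          target_fraction = 0.9, prob_threshold = 0.5,
                          grid = NULL) {
  if (!length(probabilities)) stop("no samples for this entity")
  if (length(probabilities) != length(tumor_contents))
    stop("probabilities and tumor_contents differ in length")
  cand <- if (is.null(grid)) sort(unique(tumor_contents))
          else seq(0, 1, by = grid)
  for (c_ in cand) {
    idx <- tumor_contents >= c_
    if (!any(idx)) next
    frac <- mean(probabilities[idx] > prob_threshold)
    if (frac > target_fraction) {
      out <- c_
      attr(out, "attainable") <- TRUE
      attr(out, "fraction") <- frac
      return(out)
    }
  }
  out <- max(tumor_contents)
  idx <- tumor_contents >= out
  attr(out, "attainable") <- FALSE
  attr(out, "fraction") <- mean(probabilities[idx] > prob_threshold)
  out
}

#' Cumulative sensitivity/specificity over tumor-content thresholds
#'
#' Recomputes the operational sensitivity and specificity on the subset of
#' samples with tumor cell content at or above each observed content
#' value, yielding the cumulative performance curve.
#'
#' @param predictions,truth as in [sensitivity_specificity()].
#' @param tumor_contents per-sample tumor cell content.
#' @return data.frame with columns `threshold`, `n`, `sensitivity`,
#'   `specificity` (NA where nothing assigned).
#' @export
cumulative_metrics <- function(predictions, truth, tumor_contents) {
  call <- .calls_of(predictions)
  truth <- as.character(truth)
  if (anyNA(tumor_contents))
    stop("tumor_contents required for every sample")
  th <- sort(unique(tumor_contents))
  rows <- lapply(th, function(t_) {
    idx <- tumor_contents >= t_
    r <- sensitivity_specificity(call[idx], truth[idx])
    data.frame(threshold = t_, n = sum(idx),
               sensitivity = r$sensitivity, specificity = r$specificity)
  })
  do.call(rbind, rows)
}

#' Fisher exact comparison of accuracy between two groups
#'
#' Builds the 2x2 table (correct / incorrect) x group and runs the
#' two-sided Fisher exact test, e.g. FFPE vs fresh-frozen predictive
#' accuracy. Degenerate tables (an empty margin) return p = 1 with a
#' note rather than an error.
#'
#' @param predictions,truth as in [sensitivity_specificity()].
#' @param group_labels two-level factor/character per sample.
#' @return list: `table` (2x2), `odds_ratio`, `p_value`, `degenerate`.
#' @export
group_accuracy_test <- function(predictions, truth, group_labels) {
  call <- .calls_of(predictions)
  truth <- as.character(truth)
  grp <- as.character(group_labels)
  if (length(unique(grp)) != 2L) stop("exactly two groups required")
  correct <- factor(call == truth, levels = c(TRUE, FALSE),
                    labels = c("correct", "incorrect"))
  tab <- table(correct, grp)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1,
                degenerate = TRUE,
                note = "degenerate table (empty margin); p set to 1"))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value, degenerate = FALSE)
}
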