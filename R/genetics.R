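#' Default genetic-marker integration rules
#'
#' Maps each supplemental genetic marker to its diagnostic entity and a
#' precedence: by default IGH-BCL2, MYD88 L265P and EZH2 Y646 only rescue
#' samples the expression model left `"undetermined"`, while BRAF V600E
#' always overrides, because hairy cell leukemia lies outside the
#' expression model entirely and can only be diagnosed via the mutation.
#'
#' @param precedence named character vector overriding the per-marker
#'   precedence, values in `c("override_undetermined_only",
#'   "override_all")`.
#' @return data.frame with columns `marker`, `entity`, `precedence`,
#'   ordered by conflict priority (BRAF > MYD88 > IGH-BCL2 > EZH2).
#' @export
integration_rules <- function(precedence = NULL) {
  rules <- data.frame(
    marker = c("BRAF_V600E", "MYD88_L265P", "IGH_BCL2", "EZH2_Y646"),
    entity = c("HCL", "LPL/WM", "FL", "FL"),
    precedence = c("override_all", "override_undetermined_only",
                   "override_undetermined_only",
                   "override_undetermined_only"),
    stringsAsFactors = FALSE)
  if (!is.null(precedence)) {
    ok <- c("override_undetermined_only", "override_all")
    if (!all(precedence %in% ok))
      stop("precedence values must be one of: ", paste(ok, collapse = ", "))
    i <- match(names(precedence), rules$marker)
    if (anyNA(i)) stop("unknown marker in precedence override")
    rules$precedence[i] <- unname(precedence)
  }
  rules
}

#' Read an annotated variant table
#'
#' TSV with columns `gene`, `effect`, `reads`, `popfreq`,
#' `lymphoma_relevant` (annotation and database flags are inputs; no
#' external lookup is performed).
#'
#' @param path path to the TSV.
#' @return data.frame of variant records.
#' @export
read_variant_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Filter annotated variants by the diagnostic NGS rules
#'
#' Retains a variant iff it is exonic nonsynonymous or a splice
#' donor/acceptor-site variant, has at least 20 supporting reads, and has
#' a population frequency at most 1e-4 — unless it is flagged as
#' lymphoma-relevant, in which case the frequency filter is waived.
#' The filter is idempotent.
#'
#' @param records data.frame with columns `gene`, `effect` (values
#'   `"exonic_nonsynonymous"`, `"splice_site"`, or anything else, which is
#'   dropped), `reads`, `popfreq`, `lymphoma_relevant` (logical).
#' @param min_reads default 20 (inclusive).
#' @param max_popfreq default 1e-4 (inclusive; the published rule excludes
#'   frequency strictly above this).
#' @return the retained rows of `records`.
#' @export
filter_variants <- function(records, min_reads = 20, max_popfreq = 1e-4) {
  need <- c("gene", "effect", "reads", "popfreq", "lymphoma_relevant")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("variant records lack fields: ", paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(records[need])
  if (any(bad))
    stop("missing values in variant record(s): ",
         paste(which(bad), collapse = ", "))
  keep <- records$effect %in% c("exonic_nonsynonymous", "splice_site") &
    records$reads >= min_reads &
    (records$popfreq <= max_popfreq | records$lymphoma_relevant)
  records[keep, , drop = FALSE]
}

# marker status matrix (samples x markers) from an annotation data.frame
.marker_status <- function(annotations, markers) {
  out <- sapply(markers, function(m) {
    if (m %in% names(annotations)) as.character(annotations[[m]])
    else rep("unknown", nrow(annotations))
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, markers))
  out
}

#' Integrate genetic markers into cascade calls
#'
#' Revises expression-model calls with the supplemental genetic markers.
#' Under the default rules, a positive IGH-BCL2 / MYD88 L265P / EZH2 Y646
#' only converts an `"undetermined"` call (to FL, LPL/WM, FL), while a
#' positive BRAF V600E always calls HCL. When several markers are
#' positive in one sample, only the highest-priority one fires
#' (BRAF > MYD88 > IGH-BCL2 > EZH2) and a warning reports the conflict.
#' Samples with all markers negative or unknown are untouched.
#'
#' @param predictions a `cascade_prediction` or character vector of calls.
#' @param annotations `sample_annotation` data.frame whose marker columns
#'   (see [SBCLN_MARKERS]) hold positive / negative / unknown, in the same
#'   sample order.
#' @param rules an [integration_rules()] table.
#' @return the predictions with `final_call` revised and a logical column
#'   `genetics_revised`; for a character input, a character vector with
#'   attribute `revised`.
#' @export
integrate_markers <- function(predictions, annotations,
                              rules = integration_rules()) {
  known <- c(SBCLN_ENTITIES, "HCL", "other_SBCLN", "control",
             "unknown", "undetermined")
  if (!all(rules$entity %in% known))
    stop("unknown entity in rules: ",
         paste(setdiff(rules$entity, known), collapse = ", "))
  call <- .calls_of(predictions)
  if (nrow(annotations) != length(call))
    stop("annotations and predictions differ in length")
  status <- .marker_status(annotations, rules$marker)

  revised <- logical(length(call))
  new_call <- call
  for (s in seq_along(call)) {
    pos <- rules$marker[status[s, rules$marker] == "positive"]
    if (!length(pos)) next
    if (length(pos) > 1L)
      warning("sample ", s, ": multiple positive markers (",
              paste(pos, collapse = ", "), "); applying ", pos[1])
    r <- rules[rules$marker == pos[1], ]
    fire <- r$precedence == "override_all" || call[s] == "undetermined"
    if (fire && new_call[s] != r$entity) {
      new_call[s] <- r$entity
      revised[s] <- TRUE
    }
  }
  if (is.data.frame(predictions)) {
    predictions$final_call <- new_call
    predictions$genetics_revised <- revised
    predictions
  } else {
    structure(new_call, revised = revised)
  }
}

#' Admit genetic markers by the reclassification rule
#'
#' A candidate rule is admitted as a combined marker of the model only if,
#' applied alone to the expression-model calls, it correctly reclassifies
#' at least `min_rescued` samples (default 2). Admitted rules are then
#' meant to be applied jointly via [integrate_markers()].
#'
#' @param candidate_rules an [integration_rules()]-shaped table.
#' @param predictions expression-model calls (before integration).
#' @param truth true entity labels.
#' @param annotations `sample_annotation` with marker status columns.
#' @param min_rescued admission threshold, default 2.
#' @return the admitted subset of `candidate_rules`, with a column
#'   `n_rescued`.
#' @export
select_combined_markers <- function(candidate_rules, predictions, truth,
                                    annotations, min_rescued = 2) {
  call <- .calls_of(predictions)
  truth <- as.character(truth)
  n_rescued <- vapply(seq_len(nrow(candidate_rules)), function(i) {
    one <- candidate_rules[i, , drop = FALSE]
    after <- .calls_of(integrate_markers(call, annotations, one))
    sum(after == truth & call != truth)
  }, 0L)
  out <- candidate_rules[n_rescued >= min_rescued, , drop = FALSE]
  out$n_rescued <- n_rescued[n_rescued >= min_rescued]
  out
}
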