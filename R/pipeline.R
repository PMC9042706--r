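#' Run the full classification pipeline
#'
#' Wires the stages end to end: housekeeping selection on the training
#' cohort, per-cohort normalization, cascade fitting on the training
#' cohort, prediction for all samples, and evaluation against the truth
#' labels where available. Artifacts are written under `out_dir`:
#' `norm.tsv` (normalized matrix), `hk.txt` (housekeeping set),
#' `model.rds` (cascade bundle), `calls.tsv` (per-sample probabilities
#' and final calls), `report.json` (metrics plus provenance: package
#' version and seed). Deterministic given the seed.
#'
#' @param counts a [count_matrix()] or path to a count table.
#' @param annotations a `sample_annotation` data.frame or path to an
#'   annotation TSV; needs `sample_id`, `label`, and optionally `cohort`.
#' @param out_dir output directory, created if absent.
#' @param panel optional [gene_panel()] or path; its housekeeping
#'   candidates override the count matrix roles.
#' @param seed integer seed driving every stochastic stage.
#' @param hk_k,min_expression,max_cv housekeeping selection parameters.
#' @param integrate apply [integrate_markers()] to the calls when the
#'   annotation carries marker status columns.
#' @param ... passed to [fit_cascade()].
#' @return list with `model`, `predictions`, `report` (invisible).
#' @export
run_pipeline <- function(counts, annotations, out_dir,
                         panel = NULL, seed = 1L,
                         hk_k = 4, min_expression = 64, max_cv = 0.5,
                         integrate = FALSE, ...) {
  if (is.character(counts)) counts <- read_count_table(
    counts, panel = if (is.character(panel)) read_gene_panel(panel)
                    else panel)
  if (is.character(panel)) panel <- read_gene_panel(panel)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  annotations <- as_sample_annotation(annotations)
  ord <- match(counts$sample_ids, annotations$sample_id)
  if (anyNA(ord))
    stop("samples without annotation: ",
         paste(counts$sample_ids[is.na(ord)], collapse = ", "))
  annotations <- annotations[ord, ]
  if (!"label" %in% names(annotations))
    stop("annotation lacks truth labels (column 'label')")
  cohort <- if ("cohort" %in% names(annotations)) annotations$cohort
            else rep("training", nrow(annotations))

  hk_cand <- if (!is.null(panel)) panel$housekeeping_candidates
             else names(counts$gene_role)[
               counts$gene_role == "housekeeping_candidate"]
  if (!length(hk_cand)) stop("no housekeeping candidates available")
  train_idx <- cohort == "training"
  if (!any(train_idx)) stop("no training-cohort samples")
  hk <- select_housekeeping(counts$counts[, train_idx, drop = FALSE],
                            hk_cand, min_expression = min_expression,
                            max_cv = max_cv, k = hk_k)
  nm <- normalize_counts(counts, hk, cohort = cohort)

  labels <- as.character(annotations$label)
  model <- fit_cascade(nm$values[, train_idx, drop = FALSE],
                       labels[train_idx], seed = seed, ...)
  pred <- predict(model, nm)
  if (integrate) pred <- integrate_markers(pred, annotations)

  known <- labels %in% c(model$entity_order, "HCL")
  report <- list(package_version = as.character(
                   utils::packageVersion("lymphcascade")),
                 seed = seed,
                 housekeeping = as.character(hk),
                 entity_order = model$entity_order,
                 n_samples = ncol(nm$values))
  if (any(known)) {
    ev <- sensitivity_specificity(pred$final_call[known], labels[known])
    report$sensitivity <- ev$sensitivity
    report$specificity <- ev$specificity
    report$n_undetermined <- length(ev$undetermined)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(gene = rownames(nm$values), nm$values, check.names = FALSE),
    file.path(out_dir, "norm.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(hk, file.path(out_dir, "hk.txt"))
  save_cascade(model, file.path(out_dir, "model.rds"))
  utils::write.table(pred, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, predictions = pred, report = report))
}
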