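# entity sample selector: cascade entities exclude controls and unknowns
.entity_labels <- function(labels) {
  setdiff(unique(as.character(labels)), c("control", "unknown"))
}

#' Davies-Bouldin ordering of entities
#'
#' Measures how distinguishable each entity is in expression space.
#' Per entity e, the within-cluster scatter S_e is the mean Euclidean
#' distance of its samples to the entity centroid; for every other entity
#' f, M_ef is the distance between the centroids; the entity's
#' Davies-Bouldin index is D_e = max over f of (S_e + S_f) / M_ef.
#' Entities with lower D are more separable and are discriminated first
#' in the cascade. Control samples are excluded.
#'
#' @param norm a `normalized_matrix` or log2 matrix (genes x samples).
#' @param labels per-sample labels; `"control"`/`"unknown"` ignored.
#' @return data.frame with columns `entity`, `dbi`, sorted ascending by
#'   `dbi` with alphabetical tie-break.
#' @export
entity_dbi_order <- function(norm, labels) {
  v <- .values_of(norm)
  labels <- as.character(labels)
  ents <- sort(.entity_labels(labels))
  if (length(ents) < 2L) stop("need at least 2 entities for DBI ordering")
  cent <- sapply(ents, function(e)
    rowMeans(v[, labels == e, drop = FALSE]))
  S <- vapply(ents, function(e) {
    x <- v[, labels == e, drop = FALSE]
    mean(sqrt(colSums((x - cent[, e])^2)))
  }, 0)
  D <- vapply(ents, function(e) {
    others <- setdiff(ents, e)
    r <- vapply(others, function(f) {
      m <- sqrt(sum((cent[, e] - cent[, f])^2))
      if (m == 0)
        stop("entities ", e, " and ", f, " have coincident centroids; ",
             "Davies-Bouldin index undefined")
      (S[e] + S[f]) / m
    }, 0)
    max(r)
  }, 0)
  out <- data.frame(entity = ents, dbi = D, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$dbi, out$entity), ]
  rownames(out) <- NULL
  out
}

# fit one binary forest: target entity vs everything else (incl. controls)
.fit_forest <- function(v, labels, target, genes, ntree, mtry, seed) {
  y <- factor(ifelse(labels == target, "target", "rest"),
              levels = c("rest", "target"))
  if (length(unique(y)) < 2L)
    stop("single-class input for target ", target)
  x <- t(v[genes, , drop = FALSE])
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(genes))))
  set.seed(seed)
  randomForest::randomForest(x, y, ntree = ntree, mtry = mtry,
                             importance = FALSE)
}

#' Train one cascade step (pre-refinement)
#'
#' Fits a binary random forest for one entity against the rest — all other
#' entity samples plus all control samples — on the full candidate gene
#' set, and records the normalized Gini importances used for marker
#' refinement. The probability of the target is the fraction of trees
#' voting for it.
#'
#' @param norm a `normalized_matrix` or log2 matrix.
#' @param labels per-sample labels (entities and `"control"`).
#' @param target_entity the entity this step discriminates.
#' @param candidate_genes genes offered to the forest.
#' @param seed integer seed; fits are bit-reproducible given the seed.
#' @param ntree number of trees (default 500).
#' @param mtry variables tried per split (default floor(sqrt(p))).
#' @return An object of class `cascade_step`: list with `entity`,
#'   `marker_genes` (= candidates before refinement), `forest`,
#'   `gini_importances` (normalized to sum 1), `seed`.
#' @export
train_step <- function(norm, labels, target_entity, candidate_genes,
                       seed = 1L, ntree = 500, mtry = NULL) {
  v <- .values_of(norm)
  labels <- as.character(labels)
  missing <- setdiff(candidate_genes, rownames(v))
  if (length(missing))
    stop("candidate genes absent from matrix: ",
         paste(missing, collapse = ", "))
  if (!target_entity %in% labels)
    stop("target entity ", target_entity, " absent from labels")
  rf <- .fit_forest(v, labels, target_entity, candidate_genes,
                    ntree, mtry, seed)
  gi <- rf$importance[, "MeanDecreaseGini"]
  gi <- if (sum(gi) > 0) gi / sum(gi) else gi
  structure(list(entity = target_entity,
                 marker_genes = candidate_genes,
                 forest = rf,
                 gini_importances = gi,
                 ntree = ntree, mtry = mtry, seed = seed),
            class = "cascade_step")
}

#' Refine a step's marker set by Gini importance
#'
#' Ranks the step's candidate genes by Gini importance (descending), keeps
#' only genes upregulated in the target entity (mean normalized expression
#' in target strictly above the mean in the rest), truncates to the top
#' `k`, and refits the forest on the refined set.
#'
#' @param step a fitted [train_step()] result.
#' @param norm,labels the training data the step was fitted on.
#' @param k number of markers to keep; if more than the available
#'   upregulated genes, all of them are kept.
#' @return A refined `cascade_step` whose `marker_genes` is the ordered
#'   refined list.
#' @export
refine_markers <- function(step, norm, labels, k) {
  v <- .values_of(norm)
  labels <- as.character(labels)
  target <- step$entity
  in_t <- labels == target
  up <- vapply(step$marker_genes, function(g)
    mean(v[g, in_t]) > mean(v[g, !in_t]), TRUE)
  cand <- step$marker_genes[up]
  if (!length(cand))
    stop("no upregulated gene among candidates for entity ", target)
  ord <- order(step$gini_importances[cand], decreasing = TRUE)
  refined <- utils::head(cand[ord], k)
  rf <- .fit_forest(v, labels, target, refined,
                    step$ntree, step$mtry, step$seed)
  out <- step
  out$marker_genes <- refined
  out$forest <- rf
  out
}

# OOB Youden scan for the refined marker count of one step
.youden_k <- function(step, v, labels, k_grid = 3:10) {
  y_true <- labels == step$entity
  best_k <- k_grid[1]; best_j <- -Inf
  for (k in k_grid) {
    st <- tryCatch(refine_markers(step, v, labels, k),
                   error = function(e) NULL)
    if (is.null(st)) next
    p <- st$forest$votes[, "target"]   # OOB vote fractions
    call <- p >= 0.5
    sens <- mean(call[y_true]); spec <- mean(!call[!y_true])
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_k <- k }
  }
  best_k
}

# published per-entity refined set sizes; 8 for unlisted entities
.default_k <- function(entity) {
  pub <- c("CLL/SLL" = 5, "cMCL" = 6, "FL" = 8, "nnMCL" = 4,
           "MZL" = 6, "LPL/WM" = 7)
  if (entity %in% names(pub)) unname(pub[entity]) else 8L
}

#' Fit the cascade classifier
#'
#' Builds the full multi-step SBCLN classifier: entities are ordered by
#' ascending Davies-Bouldin index (or a user-forced order), and for each
#' entity a one-vs-rest binary random forest is trained on the candidate
#' genes and refined to its top upregulated Gini-ranked markers. At
#' prediction time the steps are evaluated in order and the first step
#' whose target probability reaches the threshold wins; a sample passing
#' every step unclaimed is called `"undetermined"`.
#'
#' @param norm a `normalized_matrix` or log2 matrix (genes x samples) of
#'   the training cohort.
#' @param labels per-sample labels: entity names plus `"control"` for
#'   nonmalignant samples (controls join the rest class of every step).
#' @param candidate_genes genes offered to the forests; default all rows
#'   of `norm` minus the housekeeping set when `norm` carries one.
#' @param entity_order `"dbi"` (default) or a character vector forcing the
#'   step order.
#' @param k per-entity refined marker count: a single number, a named
#'   vector/list by entity, `NULL` for the published per-entity sizes
#'   (5, 6, 8, 4, 6, 7 for CLL/SLL, cMCL, FL, nnMCL, MZL, LPL/WM; 8
#'   otherwise), or `"youden"` to pick k in 3..10 maximizing the
#'   out-of-bag Youden index of the step.
#' @param threshold cascade probability threshold, default 0.5; the
#'   boundary is inclusive (p equal to the threshold claims the sample).
#' @param ntree,mtry forest hyperparameters (500 trees,
#'   floor(sqrt(p)) variables per split).
#' @param seed integer seed; each step uses a seed derived from it, so the
#'   whole fit is bit-reproducible.
#' @return An object of class `sbcln_cascade`: list with `steps` (ordered
#'   `cascade_step`s), `entity_order`, `dbi` (NULL under a forced order),
#'   `threshold`, `refined_markers` (named list), `housekeeping`,
#'   `candidate_genes`, `seed`, `version`.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(synthetic_config(samples_per_entity = 10,
#'                                         n_controls = 20, seed = 7))
#' nm <- normalize_counts(sim$counts,
#'                        grep("^HK", sim$counts$gene_ids, value = TRUE))
#' fit <- fit_cascade(nm, sim$annotation$label, seed = 7)
#' predict(fit, nm)
#' }
#' @export
fit_cascade <- function(norm, labels, candidate_genes = NULL,
                        entity_order = "dbi", k = NULL, threshold = 0.5,
                        ntree = 500, mtry = NULL, seed = 1L) {
  v <- .values_of(norm)
  labels <- as.character(labels)
  if (length(labels) != ncol(v))
    stop("labels must have one entry per sample")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  hk <- if (inherits(norm, "normalized_matrix")) norm$housekeeping_used
        else character()
  if (is.null(candidate_genes))
    candidate_genes <- setdiff(rownames(v), hk)

  dbi <- NULL
  if (identical(entity_order, "dbi")) {
    ents <- .entity_labels(labels)
    if (length(ents) > 1L) {
      dbi <- entity_dbi_order(v[candidate_genes, , drop = FALSE], labels)
      order_vec <- dbi$entity
    } else order_vec <- ents
  } else {
    order_vec <- as.character(entity_order)
    missing <- setdiff(order_vec, labels)
    if (length(missing))
      stop("entities in forced order absent from labels: ",
           paste(missing, collapse = ", "))
  }

  k_of <- function(entity) {
    if (is.null(k)) return(.default_k(entity))
    if (identical(k, "youden")) return("youden")
    if (!is.null(names(k))) {
      if (!entity %in% names(k))
        stop("no k given for entity ", entity)
      return(as.integer(k[[entity]]))
    }
    as.integer(k[[1]])
  }

  steps <- vector("list", length(order_vec))
  for (i in seq_along(order_vec)) {
    ent <- order_vec[i]
    st <- train_step(v, labels, ent, candidate_genes,
                     seed = seed + i, ntree = ntree, mtry = mtry)
    ki <- k_of(ent)
    if (identical(ki, "youden")) ki <- .youden_k(st, v, labels)
    steps[[i]] <- refine_markers(st, v, labels, ki)
  }
  names(steps) <- order_vec
  structure(list(steps = steps,
                 entity_order = order_vec,
                 dbi = dbi,
                 threshold = threshold,
                 refined_markers = lapply(steps, `[[`, "marker_genes"),
                 housekeeping = hk,
                 candidate_genes = candidate_genes,
                 ntree = ntree, seed = seed,
                 version = "1"),
            class = "sbcln_cascade")
}

#' Predict entity calls with a fitted cascade
#'
#' Evaluates the cascade steps in order on new samples. Each step reports
#' the fraction of its trees voting for the target entity; the sample is
#' called as the first entity whose probability reaches the model
#' threshold (boundary inclusive), and `"undetermined"` when no step
#' fires. Probabilities of all steps are reported for diagnostics.
#'
#' @param object a fitted [fit_cascade()] model.
#' @param newdata a `normalized_matrix` or log2 matrix containing every
#'   marker gene of the model.
#' @param ... unused.
#' @return data.frame of class `cascade_prediction`: `sample_id`, one
#'   `p_<entity>` column per step, `final_call`, `stopped_at` (step index,
#'   NA for undetermined).
#' @export
predict.sbcln_cascade <- function(object, newdata, ...) {
  v <- .values_of(newdata)
  need <- unique(unlist(object$refined_markers))
  missing <- setdiff(need, rownames(v))
  if (length(missing))
    stop("marker gene(s) missing from new data: ",
         paste(missing, collapse = ", "))
  probs <- sapply(object$steps, function(st) {
    x <- t(v[st$marker_genes, , drop = FALSE])
    stats::predict(st$forest, x, type = "prob")[, "target"]
  })
  if (is.null(dim(probs)))
    probs <- matrix(probs, nrow = 1,
                    dimnames = list(NULL, names(object$steps)))
  n <- nrow(probs)
  call <- rep("undetermined", n)
  stopped <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- which(probs[i, ] >= object$threshold)
    if (length(hit)) {
      stopped[i] <- hit[1]
      call[i] <- object$entity_order[hit[1]]
    }
  }
  out <- data.frame(sample_id = colnames(v), probs,
                    final_call = call, stopped_at = stopped,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_along(object$entity_order)] <-
    paste0("p_", object$entity_order)
  class(out) <- c("cascade_prediction", class(out))
  out
}

#' @export
print.sbcln_cascade <- function(x, ...) {
  cat("SBCLN cascade classifier (", length(x$steps), " steps, threshold ",
      x$threshold, ")\n", sep = "")
  for (i in seq_along(x$steps)) {
    st <- x$steps[[i]]
    d <- if (!is.null(x$dbi)) {
      sprintf(" [DBI %.3f]", x$dbi$dbi[x$dbi$entity == st$entity])
    } else ""
    cat(sprintf("  %d. %s%s: %s\n", i, st$entity, d,
                paste(st$marker_genes, collapse = ", ")))
  }
  cat("marker union:", length(unique(unlist(x$refined_markers))),
      "genes\n")
  invisible(x)
}

#' @export
summary.sbcln_cascade <- function(object, ...) {
  tab <- data.frame(
    step = seq_along(object$steps),
    entity = object$entity_order,
    n_markers = vapply(object$refined_markers, length, 0L),
    dbi = if (!is.null(object$dbi)) {
      object$dbi$dbi[match(object$entity_order, object$dbi$entity)]
    } else NA_real_,
    row.names = NULL)
  structure(list(steps = tab,
                 marker_union = unique(unlist(object$refined_markers)),
                 threshold = object$threshold,
                 housekeeping = object$housekeeping),
            class = "summary.sbcln_cascade")
}

#' @export
print.summary.sbcln_cascade <- function(x, ...) {
  print(x$steps)
  cat("marker union:", length(x$marker_union), "genes\n")
  if (length(x$housekeeping))
    cat("housekeeping:", paste(x$housekeeping, collapse = ", "), "\n")
  invisible(x)
}

#' Per-step Gini importances of a fitted cascade
#'
#' @param object a fitted [fit_cascade()] model.
#' @param ... unused.
#' @return named list (by entity) of normalized Gini importance vectors
#'   over the step's pre-refinement candidates.
#' @export
coef.sbcln_cascade <- function(object, ...) {
  lapply(object$steps, `[[`, "gini_importances")
}

#' Plot the refined markers of a cascade
#'
#' Barplot of Gini importances of the refined markers, one panel per step.
#'
#' @param x a fitted [fit_cascade()] model.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sbcln_cascade <- function(x, ...) {
  ns <- length(x$steps)
  op <- graphics::par(mfrow = c(ceiling(ns / 2), min(ns, 2)),
                      mar = c(6, 4, 2, 1))
  on.exit(graphics::par(op))
  for (st in x$steps) {
    gi <- st$gini_importances[st$marker_genes]
    graphics::barplot(gi, las = 2, main = st$entity,
                      ylab = "Gini importance", ...)
  }
  invisible(x)
}

#' Leave-one-out evaluation of the cascade
#'
#' For every sample, refits each cascade step without that sample and
#' predicts it, then summarizes accuracy over the SBCLN (non-control)
#' samples. By default the refined marker sets are frozen from the full
#' fit and only the forests are refit per fold; `refit_markers = TRUE`
#' redoes Gini refinement inside each fold.
#'
#' @param norm,labels training data as in [fit_cascade()].
#' @param model optional pre-fitted [fit_cascade()] model supplying the
#'   step order and marker sets; fitted from the data when `NULL`.
#' @param refit_markers redo marker refinement per fold (slower).
#' @param ... passed to [fit_cascade()] when `model` is `NULL`.
#' @return list with `predictions` (a `cascade_prediction` for all
#'   samples), `accuracy` (correct / SBCLN samples), `n_undetermined`,
#'   `n_misclassified`.
#' @export
loo_evaluate <- function(norm, labels, model = NULL,
                         refit_markers = FALSE, ...) {
  v <- .values_of(norm)
  labels <- as.character(labels)
  if (is.null(model)) model <- fit_cascade(v, labels, ...)
  tab <- table(labels[labels %in% model$entity_order])
  if (any(tab < 2L))
    stop("leave-one-out needs >=2 samples per entity")

  n <- ncol(v)
  probs <- matrix(NA_real_, n, length(model$steps),
                  dimnames = list(colnames(v), model$entity_order))
  for (s in seq_len(n)) {
    vtr <- v[, -s, drop = FALSE]
    ltr <- labels[-s]
    for (i in seq_along(model$steps)) {
      st <- model$steps[[i]]
      genes <- if (refit_markers) model$candidate_genes else st$marker_genes
      fold <- train_step(vtr, ltr, st$entity, genes,
                         seed = st$seed, ntree = st$ntree, mtry = st$mtry)
      if (refit_markers)
        fold <- refine_markers(fold, vtr, ltr, length(st$marker_genes))
      x <- t(v[fold$marker_genes, s, drop = FALSE])
      probs[s, i] <- stats::predict(fold$forest, x, type = "prob")[, "target"]
    }
  }
  call <- rep("undetermined", n)
  stopped <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    hit <- which(probs[s, ] >= model$threshold)
    if (length(hit)) {
      stopped[s] <- hit[1]
      call[s] <- model$entity_order[hit[1]]
    }
  }
  pred <- data.frame(sample_id = colnames(v), probs, final_call = call,
                     stopped_at = stopped, row.names = NULL,
                     check.names = FALSE, stringsAsFactors = FALSE)
  names(pred)[1 + seq_along(model$entity_order)] <-
    paste0("p_", model$entity_order)
  class(pred) <- c("cascade_prediction", class(pred))

  is_sbcln <- labels %in% model$entity_order
  correct <- is_sbcln & call == labels
  miscls <- is_sbcln & call != labels & call != "undetermined"
  undet <- is_sbcln & call == "undetermined"
  list(predictions = pred,
       accuracy = sum(correct) / sum(is_sbcln),
       n_undetermined = sum(undet),
       n_misclassified = sum(miscls))
}

#' Save / load a fitted cascade model
#'
#' The bundle is an RDS file carrying a format version; loading checks
#' both the class and the version so that stale bundles fail loudly.
#'
#' @param model a fitted [fit_cascade()] model.
#' @param path file path for the bundle.
#' @return `load_cascade` returns the model; `save_cascade` the path,
#'   invisibly.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "sbcln_cascade"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model bundle ", path, ": ", conditionMessage(e)))
  if (!inherits(model, "sbcln_cascade"))
    stop("file is not a cascade model bundle")
  if (!identical(model$version, "1"))
    stop("model bundle version mismatch: got ", model$version)
  model
}
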