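# Welch t-test p-value robust to zero within-group variance: when both
# groups are (near-)constant the test degenerates to exact mean comparison.
.welch_p <- function(x, y) {
  if (stats::sd(x) < .Machine$double.eps^0.5 &&
      stats::sd(y) < .Machine$double.eps^0.5) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
}

.anova_p <- function(v, grp) {
  if (stats::sd(v) < .Machine$double.eps^0.5) return(1)
  stats::anova(stats::lm(v ~ grp))[["Pr(>F)"]][1]
}

#' Differential-expression screening between entities
#'
#' For each gene and contrast, computes the log2 fold change (difference of
#' group means on the log2 normalized scale), a per-contrast Welch t-test
#' p-value, the global one-way ANOVA p across all groups, and the
#' Benjamini-Hochberg FDR within each contrast. A gene is flagged
#' `selected` iff |log2FC| > `lfc` and fdr < `fdr` — both inequalities
#' strict, so a gene at exactly the fold-change threshold is not selected.
#'
#' @param norm a `normalized_matrix` or log2-scale matrix.
#' @param labels per-sample group labels (entities; any non-entity groups
#'   such as controls should be excluded by the caller or form a group).
#' @param strategy `"one_vs_rest"` (each group vs the pooled others) or
#'   `"one_vs_one"` (every group pair).
#' @param lfc log2 fold-change threshold (strict; default 1).
#' @param fdr FDR threshold (strict; default 0.05).
#' @return data.frame with columns `gene`, `contrast`, `log2FC`, `p_value`,
#'   `anova_p`, `fdr`, `selected`.
#' @export
differential_expression <- function(norm, labels,
                                    strategy = c("one_vs_rest", "one_vs_one"),
                                    lfc = 1, fdr = 0.05) {
  strategy <- match.arg(strategy)
  v <- .values_of(norm)
  labels <- as.character(labels)
  if (length(labels) != ncol(v))
    stop("labels must have one entry per sample")
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("groups with <2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  grp <- factor(labels)
  anova_p <- apply(v, 1, .anova_p, grp = grp)

  contrasts <- if (strategy == "one_vs_rest") {
    lapply(names(tab), function(g) list(name = paste0(g, "_vs_rest"),
                                        a = labels == g, b = labels != g))
  } else {
    prs <- utils::combn(names(tab), 2, simplify = FALSE)
    lapply(prs, function(p) list(name = paste0(p[1], "_vs_", p[2]),
                                 a = labels == p[1], b = labels == p[2]))
  }

  res <- lapply(contrasts, function(ct) {
    l2 <- rowMeans(v[, ct$a, drop = FALSE]) -
      rowMeans(v[, ct$b, drop = FALSE])
    p <- apply(v, 1, function(r) .welch_p(r[ct$a], r[ct$b]))
    q <- stats::p.adjust(p, method = "BH")
    data.frame(gene = rownames(v), contrast = ct$name, log2FC = l2,
               p_value = p, anova_p = anova_p, fdr = q,
               selected = abs(l2) > lfc & q < fdr,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Assemble the candidate screening panel
#'
#' Union of the DE-selected genes (ordered by best FDR across contrasts)
#' and a literature-supplement list; duplicates are counted once.
#'
#' @param de_results output of [differential_expression()].
#' @param supplements character vector of additional genes from the
#'   literature.
#' @return character vector of candidate panel genes.
#' @export
assemble_candidate_panel <- function(de_results, supplements = character()) {
  sel <- de_results[de_results$selected, , drop = FALSE]
  if (nrow(sel)) {
    best <- tapply(sel$fdr, sel$gene, min)
    de_genes <- names(sort(best))
  } else de_genes <- character()
  unique(c(de_genes, as.character(supplements)))
}

#' Fraction of samples appropriately clustered
#'
#' Unsupervised hierarchical clustering check of panel feasibility:
#' agglomerative clustering (Ward linkage on Euclidean distances of the
#' log2 profiles), tree cut into `n_branches`; a sample is "appropriately
#' clustered" when its own label is a modal (majority) label of its
#' branch.
#'
#' @param norm a `normalized_matrix` or log2 matrix (genes x samples).
#' @param labels per-sample entity labels.
#' @param n_branches number of branches to cut the tree into; must be at
#'   least the number of entities and at most the number of samples.
#' @param method linkage method for [stats::hclust()] (default `"ward.D2"`).
#' @return fraction in [0,1]; attributes `correct` and `total`.
#' @export
cluster_feasibility <- function(norm, labels, n_branches = NULL,
                                method = "ward.D2") {
  v <- .values_of(norm)
  labels <- as.character(labels)
  n <- ncol(v)
  if (is.null(n_branches)) n_branches <- length(unique(labels))
  if (n_branches < length(unique(labels)))
    stop("n_branches must be at least the number of entities")
  if (n_branches > n) stop("n_branches exceeds the number of samples")
  hc <- stats::hclust(stats::dist(t(v)), method = method)
  br <- stats::cutree(hc, k = n_branches)
  ok <- vapply(seq_len(n), function(i) {
    tab <- table(labels[br == br[i]])
    labels[i] %in% names(tab)[tab == max(tab)]
  }, TRUE)
  out <- sum(ok) / n
  attr(out, "correct") <- sum(ok)
  attr(out, "total") <- n
  out
}
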