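# extract the raw count matrix whichever container is passed
.counts_of <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

.geomean <- function(x) exp(mean(log(x)))

#' geNorm expression-stability ranking of housekeeping candidates
#'
#' Computes, per candidate gene g, the geNorm stability statistic
#' M_g: the mean, over all other candidates k, of the standard deviation
#' across samples of log2(c_g / c_k). A constant ratio to every partner
#' gives M = 0; unstable genes get large M. Lower M = more stable.
#'
#' Also reports each candidate's coefficient of variation (sd/mean of raw
#' counts) and geometric-mean expression, the quantities used by
#' [select_housekeeping()].
#'
#' @param counts a [count_matrix()] or genes x samples matrix.
#' @param candidates character vector of candidate genes (>= 2).
#' @param pseudocount added to counts before ratios; 0 requires strictly
#'   positive counts.
#' @param iterative if `TRUE`, additionally performs the stepwise geNorm
#'   exclusion: repeatedly drops the least-stable candidate and records the
#'   exclusion order.
#' @return A data.frame of class `stability_report` with columns `gene`,
#'   `M`, `cv`, `geomean`, sorted ascending by `M`. With
#'   `iterative = TRUE`, an attribute `exclusion_order` lists genes from
#'   least to most stable.
#' @export
genorm_rank <- function(counts, candidates, pseudocount = 0,
                        iterative = FALSE) {
  m <- .counts_of(counts)
  if (length(candidates) < 2L)
    stop("geNorm needs at least 2 candidate genes")
  missing <- setdiff(candidates, rownames(m))
  if (length(missing))
    stop("candidates absent from matrix: ", paste(missing, collapse = ", "))
  x <- m[candidates, , drop = FALSE] + pseudocount
  if (any(x <= 0))
    stop("zero counts among candidates; supply a pseudocount")
  lx <- log2(x)

  M_of <- function(set) {
    vapply(set, function(g) {
      others <- setdiff(set, g)
      mean(vapply(others, function(k) stats::sd(lx[g, ] - lx[k, ]), 0))
    }, 0)
  }
  M <- M_of(candidates)
  cv <- apply(x, 1, function(r) stats::sd(r) / mean(r))
  gm <- apply(x, 1, .geomean)
  out <- data.frame(gene = candidates, M = M, cv = cv, geomean = gm,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$M, match(out$gene, candidates)), ]
  rownames(out) <- NULL
  class(out) <- c("stability_report", class(out))
  if (iterative) {
    rem <- candidates
    dropped <- character()
    while (length(rem) > 2L) {
      worst <- rem[which.max(M_of(rem))]
      dropped <- c(dropped, worst)
      rem <- setdiff(rem, worst)
    }
    attr(out, "exclusion_order") <- c(dropped, rem)
  }
  out
}

#' Select the final housekeeping set
#'
#' From the housekeeping candidates, drops genes with a low expression
#' level (geometric-mean raw count below `min_expression`) or a high
#' coefficient of variation (above `max_cv`), then keeps the `k` survivors
#' with the lowest CV (all survivors if fewer than `k`). CV ties are broken
#' by input order.
#'
#' @param counts a [count_matrix()] or matrix (typically the training
#'   cohort only).
#' @param candidates candidate housekeeping genes.
#' @param min_expression minimal geometric-mean raw count (default 64).
#' @param max_cv maximal coefficient of variation (default 0.5).
#' @param k number of genes to keep (default 4).
#' @param pseudocount passed to the CV/geomean computation.
#' @return Character vector: the selected housekeeping genes, lowest CV
#'   first. Attribute `report` holds the per-candidate table.
#' @export
select_housekeeping <- function(counts, candidates, min_expression = 64,
                                max_cv = 0.5, k = 4, pseudocount = 0) {
  rep_ <- genorm_rank(counts, candidates, pseudocount = pseudocount)
  rep_ <- rep_[match(candidates, rep_$gene), ]   # input order for ties
  keep <- rep_$geomean >= min_expression & rep_$cv <= max_cv
  surv <- rep_[keep, ]
  if (nrow(surv) == 0L)
    stop("no housekeeping candidate passed the filters; ",
         "relax min_expression/max_cv")
  surv <- surv[order(surv$cv), ]   # stable sort keeps input order on ties
  sel <- utils::head(surv$gene, k)
  attr(sel, "report") <- rep_
  sel
}

#' Normalize counts by housekeeping geometric means, per cohort
#'
#' Within each cohort, every sample s gets a scaling factor
#' f_s = (mean over cohort samples of the per-sample housekeeping geometric
#' mean) / (housekeeping geometric mean of sample s); normalized expression
#' is log2(count * f_s + 1). After scaling, the housekeeping geometric
#' means are identical across all samples of a cohort. Cohorts are
#' normalized independently — the training and validation references never
#' mix.
#'
#' @param counts a [count_matrix()] or genes x samples matrix.
#' @param housekeeping character vector of housekeeping genes.
#' @param cohort optional per-sample cohort labels (recycled name-matched to
#'   columns); default treats all samples as one cohort.
#' @param pseudocount_hk pseudocount applied to housekeeping counts before
#'   geometric means (default 0: zero housekeeping counts are an error).
#' @param reference the target housekeeping geometric mean: `"cohort_mean"`
#'   (default; the arithmetic mean of the per-sample housekeeping
#'   geometric means within each cohort) or a fixed positive number.
#'   Any choice equalizes the housekeeping geomeans within a cohort and
#'   only rescales samples uniformly; a fixed reference additionally
#'   makes each sample's values exactly invariant to rescaling its own
#'   library.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (log2-scale matrix), `housekeeping_used`, `factors` (per-sample f_s),
#'   `cohort`.
#' @examples
#' m <- matrix(c(16L, 64L, 100L, 4L, 16L, 100L), nrow = 3,
#'             dimnames = list(c("hk1", "hk2", "g1"), c("A", "B")))
#' nm <- normalize_counts(m, c("hk1", "hk2"))
#' nm$factors           # A: 0.625, B: 2.5
#' nm$values["g1", "B"] # log2(100 * 2.5 + 1)
#' @export
normalize_counts <- function(counts, housekeeping, cohort = NULL,
                             pseudocount_hk = 0,
                             reference = "cohort_mean") {
  m <- .counts_of(counts)
  if (length(housekeeping) < 1L) stop("housekeeping set is empty")
  missing <- setdiff(housekeeping, rownames(m))
  if (length(missing))
    stop("housekeeping genes absent: ", paste(missing, collapse = ", "))
  ns <- ncol(m)
  if (is.null(cohort)) cohort <- rep("all", ns)
  if (length(cohort) != ns)
    stop("cohort must have one entry per sample")

  hk <- m[housekeeping, , drop = FALSE] + pseudocount_hk
  gm_s <- apply(hk, 2, function(x) {
    if (any(x <= 0)) return(0)
    .geomean(x)
  })
  if (any(gm_s == 0))
    stop("housekeeping geometric mean is zero for sample(s): ",
         paste(colnames(m)[gm_s == 0], collapse = ", "),
         " — QC failure")
  if (is.numeric(reference) && reference <= 0)
    stop("a fixed reference must be positive")
  f <- numeric(ns)
  for (co in unique(cohort)) {
    idx <- which(cohort == co)
    ref <- if (identical(reference, "cohort_mean")) mean(gm_s[idx])
           else as.numeric(reference)
    f[idx] <- ref / gm_s[idx]
  }
  names(f) <- colnames(m)
  vals <- log2(sweep(m, 2, f, `*`) + 1)
  structure(list(values = vals,
                 gene_ids = rownames(m),
                 sample_ids = colnames(m),
                 housekeeping_used = housekeeping,
                 factors = f,
                 cohort = cohort),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples; housekeeping:", paste(x$housekeeping_used, collapse = ", "),
      "\n")
  invisible(x)
}

# values matrix whichever container is passed
.values_of <- function(x) {
  if (inherits(x, "normalized_matrix")) x$values else as.matrix(x)
}
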