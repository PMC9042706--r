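#' Published refined marker sets of the SBCLN classifier
#'
#' The per-entity refined gene signatures of the six-step cascade, as used
#' in the published diagnostic model. CCND1 appears in both the cMCL and
#' nnMCL steps, so the union over all six steps contains 35 distinct genes.
#' Note the LPL/WM list carries 7 genes; together with the shared CCND1
#' this is what makes the 35-gene total add up (5+6+8+4+6+7 - 1 = 35).
#'
#' Supplied as the default `refined_markers` slot for panels targeting the
#' published assay, and used by [marker_union()] bookkeeping.
#'
#' @format Named list of character vectors, one per entity in cascade order.
#' @export
sbcln_published_markers <- list(
  "CLL/SLL" = c("BTLA", "ARHGAP44", "ZBTB24", "CLNK", "CD200"),
  "cMCL"    = c("SOX11", "PLEKHG4B", "ZNF711", "CCND1", "FAM129C", "ABCA6"),
  "FL"      = c("BCL2", "EML6", "ELL3", "CTLA4", "FCER2", "IGF2BP3",
                "RGS13", "EBF1"),
  "nnMCL"   = c("CCND1", "ZNF331", "PAX5", "CNR1"),
  "MZL"     = c("FCRLA", "HDAC9", "MS4A1", "SIGLEC6", "ZBTB32", "BHLHE41"),
  "LPL/WM"  = c("CCR2", "HOPX", "FKBP11", "ANK3", "ZNF226", "MFAP5", "MEF2A")
)

#' Union of refined markers across cascade steps
#'
#' Deduplicated union of the per-step marker lists, preserving first
#' appearance order along the cascade.
#'
#' @param markers named list of per-entity marker vectors, e.g.
#'   [sbcln_published_markers] or the `refined_markers` of a fitted cascade.
#' @return Character vector of distinct marker genes.
#' @export
marker_union <- function(markers) {
  unique(unlist(markers, use.names = FALSE))
}
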