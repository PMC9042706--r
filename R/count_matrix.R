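#' Construct a digital gene expression count matrix
#'
#' Container for raw NanoString-style counts: a nonnegative integer matrix
#' (genes x samples) with a per-gene role tag distinguishing endogenous
#' genes, housekeeping candidates, and the platform's positive/negative
#' spike-in controls.
#'
#' @param counts numeric matrix of nonnegative integers, genes in rows
#'   (rownames = gene symbols), samples in columns (colnames = sample ids).
#' @param gene_role character vector, one of `"endogenous"`,
#'   `"housekeeping_candidate"`, `"positive_control"`, `"negative_control"`,
#'   recycled gene-wise. Defaults to all endogenous.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `gene_ids`, `sample_ids`, `gene_role`.
#' @examples
#' m <- matrix(c(10L, 20L, 5L, 8L), 2, 2,
#'             dimnames = list(c("BTLA", "ACTB"), c("s1", "s2")))
#' cm <- count_matrix(m, gene_role = c("endogenous", "housekeeping_candidate"))
#' cm
#' @export
count_matrix <- function(counts, gene_role = "endogenous") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  gene_role <- rep_len(as.character(gene_role), nrow(counts))
  ok <- c("endogenous", "housekeeping_candidate", "positive_control",
          "negative_control")
  if (!all(gene_role %in% ok))
    stop("gene_role must be one of: ", paste(ok, collapse = ", "))
  names(gene_role) <- rownames(counts)
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 gene_role = gene_role),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  cat("gene roles:",
      paste(names(table(x$gene_role)), table(x$gene_role),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Column-bind count matrices sharing a gene set
#'
#' Binds samples from several `count_matrix` objects (e.g. one per RCC
#' file) into one matrix. Gene sets and roles must agree; the gene order
#' of the first object is kept.
#'
#' @param ... `count_matrix` objects.
#' @return A combined `count_matrix`.
#' @export
cbind_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "count_matrix"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "count_matrix")))
  ref <- xs[[1]]
  mats <- lapply(xs, function(x) {
    if (!setequal(x$gene_ids, ref$gene_ids))
      stop("gene sets differ between count matrices")
    x$counts[ref$gene_ids, , drop = FALSE]
  })
  count_matrix(do.call(cbind, mats), gene_role = ref$gene_role[ref$gene_ids])
}

# map an RCC CodeClass string to a gene role tag
.role_from_codeclass <- function(cc) {
  cc <- tolower(cc)
  out <- rep("endogenous", length(cc))
  out[startsWith(cc, "housekeeping")] <- "housekeeping_candidate"
  out[startsWith(cc, "positive")] <- "positive_control"
  out[startsWith(cc, "negative")] <- "negative_control"
  out
}

#' Read a NanoString RCC raw count file
#'
#' Parses the bracketed-section RCC layout (`<Header>`, `<Sample_Attributes>`,
#' `<Lane_Attributes>`, `<Code_Summary>`). Both comma- and tab-delimited
#' `Code_Summary` tables are accepted. Positive/negative control probes are
#' retained in the object (tagged by role) but are ignored by all downstream
#' normalization and classification steps.
#'
#' @param path path to an RCC file.
#' @return A list with `counts` (a single-sample [count_matrix()]) and
#'   `metadata` (named list of Sample_Attributes / Lane_Attributes fields).
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  sec_start <- grep("^<[^/].*>$", lines)
  sec_names <- gsub("^<|>$", "", lines[sec_start])
  sections <- list()
  for (i in seq_along(sec_start)) {
    end_tag <- paste0("</", sec_names[i], ">")
    end <- which(lines == end_tag)
    end <- end[end > sec_start[i]][1]
    if (is.na(end)) end <- length(lines) + 1L
    body <- lines[seq(sec_start[i] + 1L, end - 1L)]
    sections[[sec_names[i]]] <- body[nzchar(body)]
  }
  if (is.null(sections$Code_Summary))
    stop("RCC parse error: missing Code_Summary section in ", path)

  split_row <- function(x) {
    sep <- if (grepl("\t", x[1])) "\t" else ","
    do.call(rbind, strsplit(x, sep, fixed = TRUE))
  }
  tab <- split_row(sections$Code_Summary)
  header <- tolower(tab[1, ])
  tab <- tab[-1, , drop = FALSE]
  need <- c("codeclass", "name", "count")
  idx <- match(need, header)
  if (anyNA(idx))
    stop("RCC parse error: Code_Summary lacks columns ",
         paste(need[is.na(idx)], collapse = ", "))
  cnt_chr <- tab[, idx[3]]
  cnt <- suppressWarnings(as.numeric(cnt_chr))
  if (any(is.na(cnt)) || any(cnt != round(cnt)))
    stop("RCC value error: non-integer Count value in ", path)

  meta <- list()
  for (s in c("Sample_Attributes", "Lane_Attributes", "Header")) {
    if (!is.null(sections[[s]])) {
      kv <- split_row(sections[[s]])
      keys <- as.character(kv[, 1])
      if (s == "Lane_Attributes") keys <- paste0("Lane_", keys)
      meta[make.unique(keys)] <- kv[, 2]
    }
  }
  sample_id <- if (!is.null(meta$ID)) meta$ID else basename(path)

  m <- matrix(as.integer(cnt), ncol = 1,
              dimnames = list(tab[, idx[2]], sample_id))
  list(counts = count_matrix(m, gene_role = .role_from_codeclass(tab[, idx[1]])),
       metadata = meta)
}

#' Read a gene-by-sample count table
#'
#' Reads a TSV/CSV table (first column gene symbols, remaining columns one
#' sample each) into a [count_matrix()]. Gene roles are assigned from a
#' [gene_panel()] when given: panel housekeeping candidates are tagged
#' `housekeeping_candidate`, everything else `endogenous`. Matching is
#' exact and case-sensitive.
#'
#' @param path path to the table; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @param panel optional [gene_panel()].
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, panel = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  if (any(m < 0)) stop("negative counts in ", path)
  role <- rep("endogenous", nrow(m))
  if (!is.null(panel))
    role[genes %in% panel$housekeeping_candidates] <- "housekeeping_candidate"
  count_matrix(m, gene_role = role)
}

#' Write a count matrix to a TSV table
#'
#' @param x a [count_matrix()] or plain matrix.
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define a gene panel
#'
#' A closed codeset panel: the screening candidates (endogenous targets),
#' the housekeeping candidates, and optionally the per-entity refined
#' marker lists. The two gene sets must be disjoint and refined markers
#' must be drawn from the candidates.
#'
#' @param candidate_genes character vector of screening-panel genes.
#' @param housekeeping_candidates character vector of normalization
#'   candidates.
#' @param refined_markers optional named list (entity -> ordered gene list).
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(candidate_genes, housekeeping_candidates = character(),
                       refined_markers = NULL) {
  candidate_genes <- as.character(candidate_genes)
  housekeeping_candidates <- as.character(housekeeping_candidates)
  if (length(intersect(candidate_genes, housekeeping_candidates)))
    stop("candidate and housekeeping gene sets must be disjoint")
  if (anyDuplicated(candidate_genes)) stop("duplicate candidate genes")
  if (!is.null(refined_markers)) {
    extra <- setdiff(unlist(refined_markers), candidate_genes)
    if (length(extra))
      stop("refined markers not in candidate panel: ",
           paste(extra, collapse = ", "))
  }
  structure(list(candidate_genes = candidate_genes,
                 housekeeping_candidates = housekeeping_candidates,
                 refined_markers = refined_markers),
            class = "gene_panel")
}

#' Read a gene panel from YAML or JSON
#'
#' Expects top-level keys `candidate_genes`, `housekeeping_candidates`,
#' and optionally `refined_markers`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` panel file.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  rm_list <- x$refined_markers
  if (!is.null(rm_list)) rm_list <- lapply(rm_list, as.character)
  gene_panel(x$candidate_genes, x$housekeeping_candidates %||% character(),
             rm_list)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sample annotation table
#'
#' Reads a TSV with one row per sample. Recognized columns: `sample_id`
#' (required), `cohort` (training/validation/other), `label` (entity name,
#' `control`, or `unknown`), `tumor_cell_content` (fraction in [0,1], may be
#' missing), `sample_type` (FFPE / fresh_frozen), and one column per genetic
#' marker (`IGH_BCL2`, `MYD88_L265P`, `BRAF_V600E`, `EZH2_Y646`) with values
#' positive / negative / unknown.
#'
#' @param path path to the annotation TSV.
#' @return A data.frame of class `sample_annotation`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_sample_annotation(df)
}

#' Validate a sample annotation data.frame
#'
#' @param df data.frame with at least a `sample_id` column; see
#'   [read_annotations()] for recognized columns.
#' @return The validated data.frame with class `sample_annotation` prepended.
#' @export
as_sample_annotation <- function(df) {
  if (!"sample_id" %in% names(df)) stop("annotation needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in annotation")
  if ("tumor_cell_content" %in% names(df)) {
    tc <- df$tumor_cell_content
    bad <- !is.na(tc) & (tc < 0 | tc > 1)
    if (any(bad))
      stop("tumor_cell_content outside [0,1] for: ",
           paste(df$sample_id[bad], collapse = ", "))
  }
  if (!inherits(df, "sample_annotation"))
    class(df) <- c("sample_annotation", class(df))
  df
}

#' Genetic markers recognized by the integration layer
#' @export
SBCLN_MARKERS <- c("IGH_BCL2", "MYD88_L265P", "BRAF_V600E", "EZH2_Y646")

#' The six expression-model entities, in the published cascade order
#' @export
SBCLN_ENTITIES <- c("CLL/SLL", "cMCL", "FL", "nnMCL", "MZL", "LPL/WM")
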