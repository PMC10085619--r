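#' Construct a labeled case/control expression matrix
#'
#' A light container for gene-by-sample expression values (counts or
#' normalized units) with a case/control label per sample.  Values must be
#' finite and non-negative; both groups need at least one sample.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param groups Character vector of `"case"`/`"control"` labels, one per
#'   column (may be named by sample id).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rv_validation_error("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rv_validation_error("'values' needs gene rownames and sample colnames")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    rv_validation_error("expression values must be finite and >= 0")
  }
  groups <- as.character(groups)
  if (!is.null(names(groups))) groups <- groups[colnames(values)]
  if (length(groups) != ncol(values) || anyNA(groups)) {
    rv_validation_error("'groups' must supply one label per sample column")
  }
  if (!all(groups %in% c("case", "control"))) {
    rv_validation_error("group labels must be 'case' or 'control'")
  }
  if (!all(c("case", "control") %in% groups)) {
    rv_validation_error("need at least one 'case' and one 'control' sample")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    rv_validation_error("duplicate gene symbols in expression matrix")
  }
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Read an expression matrix and its design from TSV
#'
#' The matrix file has a first column `gene` followed by one column per
#' sample; the design file has columns `sample` and `group` with values
#' `case`/`control`.
#'
#' @param matrix_path,design_path File paths.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_path, design_path) {
  tab <- read_tsv(matrix_path)
  if (names(tab)[1] != "gene") {
    rv_format_error("expression matrix TSV must start with a 'gene' column")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  design <- read_tsv(design_path)
  if (!all(c("sample", "group") %in% names(design))) {
    rv_format_error("design TSV must have columns 'sample' and 'group'")
  }
  groups <- design$group
  names(groups) <- design$sample
  missing <- setdiff(colnames(m), design$sample)
  if (length(missing)) {
    rv_validation_error(sprintf("design is missing sample(s): %s",
                                paste(missing, collapse = ", ")))
  }
  expression_matrix(m, groups)
}

#' Pseudocount fold change from a case/control matrix
#'
#' A deliberately simple fold-change estimator feeding the signature
#' thresholds: per gene, `FC = (mean_case + pseudocount) /
#' (mean_control + pseudocount)`.  No dispersion modeling and no p-values —
#' the downstream signature definition is fold-change-only.  The
#' pseudocount stabilizes ratios for low-expression genes and very small
#' control groups.
#'
#' @param matrix An [expression_matrix()].
#' @param pseudocount Added to both group means before the ratio; must be
#'   > 0 (default 1, in expression units).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` group mean.
#'   The geometric mean of a group containing a zero is zero.
#' @param library_size_normalize If `TRUE`, sample columns are first scaled
#'   to the mean library size (column total), making the result invariant
#'   to a global per-sample scale factor.
#' @param contrast_id Label for the resulting profile.
#' @return An [fc_profile()] with one entry per gene.
#' @examples
#' m <- matrix(c(10, 10, 5, 5), 1, 4,
#'             dimnames = list("G1", paste0("s", 1:4)))
#' em <- expression_matrix(m, c("case", "case", "control", "control"))
#' compute_fc(em)$fc  # (10+1)/(5+1)
#' @export
compute_fc <- function(matrix, pseudocount = 1,
                       mean_type = c("arithmetic", "geometric"),
                       library_size_normalize = FALSE,
                       contrast_id = "case_vs_control") {
  mean_type <- match.arg(mean_type)
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!is_scalar_number(pseudocount) || pseudocount <= 0) {
    rv_validation_error("'pseudocount' must be a single number > 0")
  }
  vals <- matrix$values
  if (library_size_normalize) {
    libsize <- colSums(vals)
    if (any(libsize == 0)) {
      rv_validation_error("cannot library-size normalize a sample with zero total")
    }
    vals <- sweep(vals, 2, mean(libsize) / libsize, `*`)
  }
  group_mean <- function(block) {
    if (mean_type == "arithmetic") {
      rowMeans(block)
    } else {
      # geometric; rows containing a zero give 0
      exp(rowMeans(log(block)))
    }
  }
  mc <- group_mean(vals[, matrix$groups == "case", drop = FALSE])
  m0 <- group_mean(vals[, matrix$groups == "control", drop = FALSE])
  fc <- (mc + pseudocount) / (m0 + pseudocount)
  names(fc) <- rownames(vals)
  fc_profile(fc, contrast_id = contrast_id)
}

#' Import an externally computed differential-expression table
#'
#' Reads a table produced by an external DE tool and converts it to a
#' linear-scale fold-change profile.  The table must contain a `gene`
#' column plus either `log2FoldChange` (the conventional DE-output column
#' name) or a linear `fc` column; all other columns are ignored.
#'
#' @param path TSV (or CSV with `sep=","`) file path.
#' @param contrast_id Label; defaults to the file name.
#' @param sep Field separator (default tab).
#' @return An [fc_profile()].
#' @export
import_external_de <- function(path, contrast_id = NULL, sep = "\t") {
  if (!file.exists(path)) {
    rv_validation_error(sprintf("file not found: %s", path))
  }
  tab <- tryCatch(
    utils::read.delim(path, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) rv_format_error(sprintf(
      "cannot parse '%s': %s", path, conditionMessage(e))))
  if (!"gene" %in% names(tab)) {
    rv_format_error(sprintf("'%s' is missing required column 'gene'", path))
  }
  if ("log2FoldChange" %in% names(tab)) {
    fc <- 2^as.numeric(tab$log2FoldChange)
  } else if ("fc" %in% names(tab)) {
    fc <- as.numeric(tab$fc)
  } else {
    rv_format_error(sprintf(
      "'%s' must contain a 'log2FoldChange' or 'fc' column", path))
  }
  keep <- is.finite(fc) & fc > 0
  if (!all(keep)) {
    rv_validation_error(sprintf(
      "non-finite or non-positive fold change for gene(s): %s",
      paste(utils::head(tab$gene[!keep], 5L), collapse = ", ")))
  }
  names(fc) <- tab$gene
  fc_profile(fc, contrast_id = contrast_id %||% basename(path))
}
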