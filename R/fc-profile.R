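#' Construct a fold-change profile
#'
#' A fold-change profile maps gene symbols to linear-scale fold changes for
#' one contrast (disease vs normal, treated vs untreated, or an agent
#' perturbation).  Values are stored on the linear scale internally; log2
#' inputs are accepted only at the I/O boundary ([load_fc_profile()],
#' [import_external_de()]).  Gene symbols are upper-cased on construction
#' because mixed-case duplicates of the same human symbol are a common
#' artifact of public expression tables.
#'
#' @param fc Named numeric vector of linear fold changes; every value must
#'   be finite and strictly positive, and names must be unique after
#'   case-normalization.
#' @param contrast_id Text label for the contrast.
#' @return An object of class `fc_profile`: a list with elements
#'   `contrast_id` and `fc` (named numeric, linear scale).
#' @examples
#' p <- fc_profile(c(KRAS = 2.0, TP53 = 0.5), contrast_id = "tumor_vs_normal")
#' p$fc[["KRAS"]]
#' @export
fc_profile <- function(fc, contrast_id = "contrast") {
  if (!is.numeric(fc) || length(fc) == 0L) {
    rv_validation_error("'fc' must be a non-empty named numeric vector")
  }
  if (is.null(names(fc)) || any(!nzchar(names(fc)))) {
    rv_validation_error("every fold change must be named by a gene symbol")
  }
  genes <- toupper(names(fc))
  bad <- !is.finite(fc) | fc <= 0
  if (any(bad)) {
    rv_validation_error(sprintf(
      "non-finite or non-positive fold change for gene(s): %s",
      paste(utils::head(genes[bad], 5L), collapse = ", ")))
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    rv_validation_error(sprintf(
      "duplicate gene symbol(s) after case-normalization: %s",
      paste(utils::head(dup, 5L), collapse = ", ")))
  }
  fc <- as.numeric(fc)
  names(fc) <- genes
  structure(list(contrast_id = as.character(contrast_id)[1L], fc = fc),
            class = "fc_profile")
}

#' @export
print.fc_profile <- function(x, ...) {
  cat(sprintf("Fold-change profile '%s': %d genes\n", x$contrast_id,
              length(x$fc)))
  cat(sprintf("  FC range [%.3g, %.3g], median %.3g\n",
              min(x$fc), max(x$fc), stats::median(x$fc)))
  invisible(x)
}

#' @export
length.fc_profile <- function(x) length(x$fc)

#' @export
as.data.frame.fc_profile <- function(x, ...) {
  data.frame(gene = names(x$fc), fc = unname(x$fc),
             stringsAsFactors = FALSE)
}

#' Genes of a profile, signature, or collection
#'
#' @param x An `fc_profile` object.
#' @return Character vector of gene symbols.
#' @export
profile_genes <- function(x) {
  stopifnot(inherits(x, "fc_profile"))
  names(x$fc)
}

#' Read a fold-change profile from a TSV file
#'
#' Expects a header line with a `gene` column and a value column named `fc`
#' (linear scale) or `log2fc`.  Lines starting with `#` are comments.  log2
#' values are exponentiated so that the profile is linear-scale internally.
#'
#' @param path Path to the TSV file.
#' @param scale `"linear"` or `"log2"`.  Defaults to `"linear"` when an `fc`
#'   column is present and `"log2"` when only a `log2fc` column is.
#' @param duplicates Policy for genes appearing more than once after
#'   case-normalization: `"error"` (default) or `"keep-max"`, which keeps
#'   the row with the largest absolute log2 fold change.
#' @param contrast_id Label for the contrast; defaults to the file name.
#' @return An [fc_profile()].
#' @export
load_fc_profile <- function(path, scale = NULL,
                            duplicates = c("error", "keep-max"),
                            contrast_id = NULL) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) {
    rv_validation_error(sprintf("file not found: %s", path))
  }
  tab <- tryCatch(read_tsv(path),
                  error = function(e) rv_format_error(sprintf(
                    "cannot parse '%s' as TSV: %s", path, conditionMessage(e))))
  if (!"gene" %in% names(tab)) {
    rv_format_error(sprintf("'%s' is missing required column 'gene'", path))
  }
  value_col <- intersect(c("fc", "log2fc"), names(tab))[1]
  if (is.na(value_col)) {
    rv_format_error(sprintf(
      "'%s' must have a value column named 'fc' or 'log2fc'", path))
  }
  if (is.null(scale)) scale <- if (value_col == "fc") "linear" else "log2"
  scale <- match.arg(scale, c("linear", "log2"))
  if (nrow(tab) == 0L) {
    rv_validation_error(sprintf("'%s' contains no data rows", path))
  }
  val <- suppressWarnings(as.numeric(tab[[value_col]]))
  if (anyNA(val)) {
    rv_validation_error(sprintf(
      "non-numeric fold change for gene(s): %s",
      paste(utils::head(tab$gene[is.na(val)], 5L), collapse = ", ")))
  }
  if (scale == "log2") val <- 2^val
  bad <- !is.finite(val) | val <= 0
  if (any(bad)) {
    rv_validation_error(sprintf(
      "non-positive or non-finite linear fold change for gene(s): %s",
      paste(utils::head(tab$gene[bad], 5L), collapse = ", ")))
  }
  gene <- toupper(trimws(as.character(tab$gene)))
  if (anyDuplicated(gene)) {
    if (duplicates == "error") {
      rv_format_error(sprintf(
        "duplicate gene symbol(s) in '%s': %s (use duplicates = \"keep-max\" to resolve)",
        path, paste(unique(gene[duplicated(gene)]), collapse = ", ")))
    }
    # keep the row with the largest |log2 FC| per gene
    keep <- order(abs(log2(val)), decreasing = TRUE)
    keep <- keep[!duplicated(gene[keep])]
    keep <- sort(keep)
    gene <- gene[keep]
    val <- val[keep]
  }
  names(val) <- gene
  fc_profile(val, contrast_id = contrast_id %||% basename(path))
}

#' Write a fold-change profile to TSV
#'
#' Writes columns `gene` and `fc` (linear scale, 6 significant digits),
#' readable back with [load_fc_profile()].
#'
#' @param profile An `fc_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fc_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fc_profile"))
  write_tsv(signif_cols(as.data.frame(profile)), path)
}
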