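#' Signature thresholds
#'
#' A pair of inclusive linear fold-change cutoffs defining a gene signature:
#' genes at or above `up_threshold` are up-regulated, genes at or below
#' `down_threshold` are down-regulated.  The defaults (1.50 / 0.67) are the
#' screening-signature cutoffs; the differentially-expressed-gene variant
#' uses 2.0 / 0.5 (see [deg_config()]).
#'
#' @param up_threshold Linear FC, must be > 1.
#' @param down_threshold Linear FC, must lie in (0, 1).
#' @return An object of class `signature_config`.
#' @export
signature_config <- function(up_threshold = 1.50, down_threshold = 0.67) {
  if (!is_scalar_number(up_threshold) || up_threshold <= 1) {
    rv_validation_error("'up_threshold' must be a single finite number > 1")
  }
  if (!is_scalar_number(down_threshold) ||
      down_threshold <= 0 || down_threshold >= 1) {
    rv_validation_error("'down_threshold' must lie strictly between 0 and 1")
  }
  structure(list(up_threshold = up_threshold,
                 down_threshold = down_threshold),
            class = "signature_config")
}

#' DEG thresholds (2.0 / 0.5)
#'
#' Convenience constructor for the stricter cutoffs used to call
#' differentially expressed genes.
#'
#' @return A [signature_config()] with `up_threshold = 2`,
#'   `down_threshold = 0.5`.
#' @export
deg_config <- function() signature_config(2.0, 0.5)

#' @export
print.signature_config <- function(x, ...) {
  cat(sprintf("Signature thresholds: FC >= %.4g (up) or FC <= %.4g (down)\n",
              x$up_threshold, x$down_threshold))
  invisible(x)
}

#' Extract an up/down gene signature from a fold-change profile
#'
#' Thresholding is inclusive on both sides: `up = {g : FC(g) >= up}` and
#' `down = {g : FC(g) <= down}`.  Genes strictly between the cutoffs belong
#' to neither set; in particular FC = 1 is never in the signature.
#'
#' @param profile An [fc_profile()].
#' @param config A [signature_config()]; default 1.50 / 0.67.
#' @return An object of class `gene_signature`: list with `source_contrast`,
#'   `up`, `down` (character vectors, disjoint) and `config`.  Warns if the
#'   signature is empty.
#' @examples
#' p <- fc_profile(c(A = 2, B = 1.5, C = 1, D = 0.67, E = 0.4))
#' s <- extract_signature(p)
#' s$up    # A, B
#' s$down  # D, E
#' @export
extract_signature <- function(profile, config = signature_config()) {
  stopifnot(inherits(profile, "fc_profile"))
  if (!inherits(config, "signature_config")) {
    rv_validation_error("'config' must be a signature_config")
  }
  if (length(profile$fc) == 0L) {
    rv_validation_error("profile is empty")
  }
  up <- names(profile$fc)[profile$fc >= config$up_threshold]
  down <- names(profile$fc)[profile$fc <= config$down_threshold]
  if (length(up) == 0L && length(down) == 0L) {
    warning(sprintf(
      "empty signature for '%s' at thresholds (%.4g, %.4g)",
      profile$contrast_id, config$up_threshold, config$down_threshold),
      call. = FALSE)
  }
  new_gene_signature(profile$contrast_id, up, down, config)
}

new_gene_signature <- function(source_contrast, up, down, config,
                               inverted = FALSE) {
  structure(list(source_contrast = source_contrast,
                 up = sort(unique(up)), down = sort(unique(down)),
                 config = config, inverted = inverted),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature of '%s'%s: %d up, %d down (FC >= %.4g / <= %.4g)\n",
              x$source_contrast, if (isTRUE(x$inverted)) " [inverted]" else "",
              length(x$up), length(x$down),
              x$config$up_threshold, x$config$down_threshold))
  invisible(x)
}

#' Swap the up and down sets of a signature
#'
#' Inversion is an involution: `invert_signature(invert_signature(s))`
#' equals `s`.  The configuration is carried over with an `inverted` flag.
#'
#' @param sig A `gene_signature`.
#' @return The inverted `gene_signature`.
#' @export
invert_signature <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  new_gene_signature(sig$source_contrast, up = sig$down, down = sig$up,
                     config = sig$config, inverted = !isTRUE(sig$inverted))
}

#' All member genes of a signature
#'
#' @param sig A `gene_signature`.
#' @return Character vector, the union of the up and down sets.
#' @export
signature_genes <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  union(sig$up, sig$down)
}

#' Extract differentially expressed genes
#'
#' Applies the DEG cutoffs (inclusive FC >= 2.0 or <= 0.5 by default) to a
#' treated-vs-untreated fold-change profile.
#'
#' @param profile An [fc_profile()].
#' @param config Thresholds; defaults to [deg_config()].
#' @return A `gene_signature` whose union ([signature_genes()]) is the DEG
#'   list.
#' @export
extract_degs <- function(profile, config = deg_config()) {
  extract_signature(profile, config)
}

#' Write / read a gene signature as JSON
#'
#' JSON schema: `{"contrast": str, "up": [...], "down": [...],
#' "up_threshold": num, "down_threshold": num}`.
#'
#' @param sig A `gene_signature`.
#' @param path File path.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   returns a `gene_signature`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  jsonlite::write_json(
    list(contrast = sig$source_contrast,
         up = as.list(sig$up), down = as.list(sig$down),
         up_threshold = sig$config$up_threshold,
         down_threshold = sig$config$down_threshold),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("contrast", "up", "down", "up_threshold", "down_threshold")
  if (!all(need %in% names(x))) {
    rv_format_error(sprintf("signature JSON missing field(s): %s",
                            paste(setdiff(need, names(x)), collapse = ", ")))
  }
  new_gene_signature(x$contrast, as.character(x$up), as.character(x$down),
                     signature_config(x$up_threshold, x$down_threshold))
}
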