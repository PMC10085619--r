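# Internal helpers: classed conditions and small utilities.

rv_stop <- function(message, class) {
  stop(errorCondition(message, class = c(class, "revscreen_error")))
}

rv_format_error <- function(message) rv_stop(message, "revscreen_format_error")
rv_validation_error <- function(message) rv_stop(message, "revscreen_validation_error")
rv_overlap_error <- function(message) rv_stop(message, "revscreen_overlap_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar checks
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_count_scalar <- function(x) {
  is_scalar_number(x) && x >= 0 && abs(x - round(x)) < .Machine$double.eps^0.5
}

# 6 significant digits for all floating-point columns of a data.frame,
# leaving integer-valued columns intact
signif_cols <- function(df, digits = 6L) {
  num <- vapply(df, function(col) is.double(col), logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
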