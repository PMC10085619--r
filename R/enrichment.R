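#' Construct a gene-set collection
#'
#' Named gene sets over a defined gene universe, for over-representation
#' analysis.  Members outside the universe are dropped with a warning (the
#' number dropped is kept in the `n_dropped` attribute); sets left empty
#' after filtering are removed.
#'
#' @param sets Named list of character vectors (gene symbols).
#' @param universe Character vector of gene symbols; defaults to the union
#'   of all sets.  Supplying the measured-gene universe of the experiment
#'   is recommended — the union default understates the background.
#' @param name Collection label.
#' @return An object of class `gene_set_collection` with elements `name`,
#'   `sets`, `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL, name = "collection") {
  if (!is.list(sets) || length(sets) == 0L) {
    rv_validation_error("'sets' must be a non-empty named list")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    rv_validation_error("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) {
    rv_format_error(sprintf(
      "duplicate set name(s): %s",
      paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")))
  }
  sets <- lapply(sets, function(s) unique(toupper(as.character(s))))
  if (any(lengths(sets) == 0L)) {
    rv_validation_error("empty gene set(s) in collection")
  }
  universe <- unique(toupper(universe %||% unlist(sets, use.names = FALSE)))
  filtered <- lapply(sets, intersect, y = universe)
  n_dropped <- sum(lengths(sets)) - sum(lengths(filtered))
  if (n_dropped > 0L) {
    warning(sprintf("%d gene-set member(s) outside the universe were dropped",
                    n_dropped), call. = FALSE)
  }
  keep <- lengths(filtered) > 0L
  if (!any(keep)) {
    rv_validation_error("no gene set overlaps the supplied universe")
  }
  structure(list(name = name, sets = filtered[keep], universe = universe),
            class = "gene_set_collection", n_dropped = n_dropped)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets over %d universe genes\n",
              x$name, length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @param universe Optional gene universe; defaults to the union of sets.
#' @param name Collection label; defaults to the file name.
#' @return A [gene_set_collection()].
#' @export
load_gmt <- function(path, universe = NULL, name = NULL) {
  if (!file.exists(path)) {
    rv_validation_error(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) rv_validation_error(sprintf("'%s' is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    rv_format_error(sprintf(
      "GMT line %d has fewer than 3 tab-separated fields", short[1]))
  }
  set_names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(set_names)) {
    rv_format_error(sprintf(
      "duplicate set name(s) in '%s': %s", path,
      paste(unique(set_names[duplicated(set_names)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- set_names
  gene_set_collection(sets, universe = universe,
                      name = name %||% basename(path))
}

#' Write a collection to GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' For each set, tests whether the DEG list overlaps it more than expected
#' under random sampling from the universe, with the upper-tail
#' hypergeometric probability `P(X >= overlap)` (population = universe,
#' successes = set members, draws = DEGs restricted to the universe).
#' Unweighted, over-representation only; depletion is not reported.
#' p-values are Benjamini-Hochberg adjusted across sets and results are
#' sorted by ascending p, ties broken by set name.
#'
#' @param degs Character vector of gene symbols (case-insensitive), or a
#'   `gene_signature` whose member genes are used.
#' @param collection A [gene_set_collection()].
#' @return data.frame with columns `set_name`, `overlap_count`, `set_size`,
#'   `degs_in_universe`, `universe_size`, `p`, `q`, `overlap_genes`
#'   (comma-separated).  The `method` attribute records that the test is
#'   unweighted hypergeometric ORA.
#' @examples
#' coll <- gene_set_collection(list(s1 = c("A", "B", "C")),
#'                             universe = LETTERS[1:10])
#' ora(c("A", "B", "D"), coll)
#' @export
ora <- function(degs, collection) {
  if (inherits(degs, "gene_signature")) degs <- signature_genes(degs)
  if (!inherits(collection, "gene_set_collection")) {
    rv_validation_error("'collection' must be a gene_set_collection")
  }
  if (length(collection$sets) == 0L) {
    rv_validation_error("collection contains no sets")
  }
  degs <- unique(toupper(as.character(degs)))
  dd <- intersect(degs, collection$universe)
  if (length(dd) == 0L) {
    rv_validation_error("no DEG lies in the collection's universe")
  }
  N <- length(collection$universe)
  n_draw <- length(dd)
  res <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    hit <- intersect(dd, members)
    k <- length(hit)
    K <- length(members)
    data.frame(set_name = nm, overlap_count = k, set_size = K,
               degs_in_universe = n_draw, universe_size = N,
               p = stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE),
               overlap_genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set_name), , drop = FALSE]
  res <- res[, c("set_name", "overlap_count", "set_size", "degs_in_universe",
                 "universe_size", "p", "q", "overlap_genes")]
  rownames(res) <- NULL
  attr(res, "method") <- "unweighted hypergeometric over-representation"
  res
}
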