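#' Construct an agent library
#'
#' An agent library is a named, ordered collection of fold-change profiles
#' to be screened against a disease signature — each agent is any
#' perturbation with an expression contrast: a small molecule, a biologic,
#' or another disease's case/control contrast.
#'
#' @param profiles A named list of [fc_profile()] objects, or an unnamed
#'   list (agent ids are then taken from each profile's `contrast_id`).
#' @return An object of class `agent_library`.
#' @export
agent_library <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0L) {
    rv_validation_error("'profiles' must be a non-empty list of fc_profile objects")
  }
  ok <- vapply(profiles, inherits, logical(1), what = "fc_profile")
  if (!all(ok)) {
    rv_validation_error("every library element must be an fc_profile")
  }
  ids <- names(profiles) %||%
    vapply(profiles, function(p) p$contrast_id, character(1))
  if (is.null(names(profiles)) || any(!nzchar(ids))) {
    ids <- vapply(profiles, function(p) p$contrast_id, character(1))
  }
  if (anyDuplicated(ids)) {
    rv_validation_error(sprintf(
      "duplicate agent id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(profiles) <- ids
  structure(list(agents = profiles), class = "agent_library")
}

#' @export
print.agent_library <- function(x, ...) {
  cat(sprintf("Agent library: %d agents\n", length(x$agents)))
  invisible(x)
}

#' @export
length.agent_library <- function(x) length(x$agents)

#' Agent identifiers of a library
#' @param library An `agent_library`.
#' @return Character vector of agent ids, in library order.
#' @export
agent_ids <- function(library) {
  stopifnot(inherits(library, "agent_library"))
  names(library$agents)
}

#' Read an agent library from disk
#'
#' Two on-disk layouts are supported: a directory of per-agent fold-change
#' TSVs (each readable by [load_fc_profile()]; the file name minus extension
#' is the agent id), or a single long-format TSV with columns
#' `agent_id`, `gene`, `fc`.
#'
#' @param path Directory or long-format TSV file.
#' @param ... Passed on to [load_fc_profile()] for the directory layout.
#' @return An [agent_library()].
#' @export
load_agent_library <- function(path, ...) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (length(files) == 0L) {
      rv_validation_error(sprintf("no .tsv files found in directory '%s'", path))
    }
    profiles <- lapply(files, function(f) {
      load_fc_profile(f, contrast_id = sub("\\.tsv$", "", basename(f)), ...)
    })
    names(profiles) <- vapply(profiles, function(p) p$contrast_id, character(1))
    return(agent_library(profiles))
  }
  if (!file.exists(path)) {
    rv_validation_error(sprintf("file or directory not found: %s", path))
  }
  tab <- read_tsv(path)
  need <- c("agent_id", "gene", "fc")
  if (!all(need %in% names(tab))) {
    rv_format_error(sprintf(
      "long-format agent library must have columns %s",
      paste(need, collapse = ", ")))
  }
  split_rows <- split(tab, tab$agent_id)
  profiles <- lapply(names(split_rows), function(id) {
    rows <- split_rows[[id]]
    fc <- as.numeric(rows$fc)
    names(fc) <- rows$gene
    fc_profile(fc, contrast_id = id)
  })
  names(profiles) <- names(split_rows)
  agent_library(profiles)
}

#' Write an agent library as one long-format TSV
#'
#' @param library An `agent_library`.
#' @param path Output path; columns `agent_id`, `gene`, `fc`.
#' @return `path`, invisibly.
#' @export
write_agent_library <- function(library, path) {
  stopifnot(inherits(library, "agent_library"))
  rows <- do.call(rbind, lapply(names(library$agents), function(id) {
    p <- library$agents[[id]]
    data.frame(agent_id = id, gene = names(p$fc), fc = unname(p$fc),
               stringsAsFactors = FALSE)
  }))
  write_tsv(signif_cols(rows), path)
}
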