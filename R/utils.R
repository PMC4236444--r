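## Internal helpers shared across modules.

#' @importFrom tools md5sum
NULL

## Error constructors: every user-facing failure carries a subclass so callers
## (and the CLI) can branch on the condition class rather than match messages.
eqStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "eqmatrix_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

eqWarn <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(class, "eqmatrix_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state (the generator contract: outputs are pure functions of the seed).
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## MD5 of a raw vector, via a scratch file (tools::md5sum is file-based).
md5Bytes <- function(bytes) {
  stopifnot(is.raw(bytes))
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(bytes, tmp)
  unname(md5sum(tmp))
}

## Atomic file write: write to a sibling temp file, then rename. A folder-sync
## service watching the directory never observes a half-written document.
atomicWriteBytes <- function(bytes, path) {
  dir <- dirname(path)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  ok <- tryCatch({
    writeBin(bytes, tmp)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    eqStop("eq_io_error", "cannot write file '%s'", path)
  }
  invisible(path)
}

#' Expand a term identifier to a full URI
#'
#' Term references are held internally as OBO-style CURIEs (e.g.
#' \code{"UBERON:0000001"}) or full URIs; on serialization CURIEs are expanded.
#' A prefix found in \code{prefixMap} is expanded with its mapped base URI;
#' any other \code{PREFIX:LOCAL} CURIE uses the OBO Library PURL pattern
#' \code{http://purl.obolibrary.org/obo/PREFIX_LOCAL}.
#'
#' @param id character CURIE or URI.
#' @param prefixMap named character vector mapping prefixes to base URIs.
#' @return character URI.
#' @export
#' @examples
#' expandTermId("UBERON:0000001")
#' expandTermId("http://example.org/provisional/x")
expandTermId <- function(id, prefixMap = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", id)) {
    return(id)
  }
  if (grepl(":", id, fixed = TRUE)) {
    parts <- regmatches(id, regexpr(":", id, fixed = TRUE), invert = TRUE)[[1L]]
    prefix <- parts[1L]
    local <- parts[2L]
    if (!is.null(prefixMap) && prefix %in% names(prefixMap)) {
      return(paste0(prefixMap[[prefix]], local))
    }
    return(sprintf("http://purl.obolibrary.org/obo/%s_%s", prefix, local))
  }
  id
}

#' Contract a term URI back to a CURIE
#'
#' Inverse of \code{\link{expandTermId}}: URIs matching an entry of
#' \code{prefixMap} or the OBO Library PURL pattern are contracted to a
#' CURIE; anything else is returned unchanged (provisional-term URIs stay
#' full URIs).
#'
#' @inheritParams expandTermId
#' @param uri character URI.
#' @return character CURIE or URI.
#' @export
contractTermId <- function(uri, prefixMap = NULL) {
  stopifnot(is.character(uri), length(uri) == 1L)
  if (!is.null(prefixMap)) {
    for (prefix in names(prefixMap)) {
      base <- prefixMap[[prefix]]
      if (startsWith(uri, base)) {
        return(paste0(prefix, ":", substring(uri, nchar(base) + 1L)))
      }
    }
  }
  m <- regmatches(
    uri,
    regexec("^http://purl\\.obolibrary\\.org/obo/([A-Za-z][A-Za-z0-9]*)_([A-Za-z0-9_.-]+)$", uri)
  )[[1L]]
  if (length(m) == 3L) {
    return(paste0(m[2L], ":", m[3L]))
  }
  uri
}

## ISO-8601 UTC timestamp with millisecond precision.
isoNow <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

## Random UUID-v4-shaped string from the session RNG.
randomUUID <- function() {
  hex <- c(0:9, letters[1:6])
  pick <- function(n) paste(sample(hex, n, replace = TRUE), collapse = "")
  sprintf("%s-%s-4%s-%s%s-%s",
          pick(8L), pick(4L), pick(3L),
          sample(c("8", "9", "a", "b"), 1L), pick(3L), pick(12L))
}
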