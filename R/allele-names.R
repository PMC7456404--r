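#' Parse WHO colon-delimited HLA allele names
#'
#' Splits names such as \code{"B*15:27:02"} into locus, numeric fields and
#' the optional expression suffix. Parsing is strict: the asterisk between
#' locus and first field is required, every field must be a non-empty digit
#' string, and only the WHO suffix letters N, Q, L, S, C, A are accepted.
#' Formatting a parsed name (\code{as.character}) reproduces the input
#' exactly.
#'
#' @param name character vector of allele names.
#' @return An \code{\linkS4class{HLAAlleleName}} of the same length.
#' @examples
#' an <- parseAlleleName(c("B*15:27:02", "B*15:11N"))
#' as.character(an)
#' isExpressed(an)
#' @export
parseAlleleName <- function(name) {
  if (length(name) == 0L || any(is.na(name)) || any(!nzchar(name)))
    stop("allele name must be a non-empty string")
  locus <- character(length(name))
  suffix <- rep(NA_character_, length(name))
  fieldList <- vector("list", length(name))
  for (i in seq_along(name)) {
    x <- name[i]
    if (!grepl("*", x, fixed = TRUE))
      stop(sprintf("malformed allele name '%s': missing '*' separator", x))
    parts <- strsplit(x, "*", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]) || !nzchar(parts[2L]))
      stop(sprintf("malformed allele name '%s'", x))
    locus[i] <- parts[1L]
    body <- parts[2L]
    last <- substr(body, nchar(body), nchar(body))
    if (grepl("[A-Z]", last)) {
      if (!last %in% .SUFFIXES)
        stop(sprintf("malformed allele name '%s': unknown expression suffix '%s'",
                     x, last))
      suffix[i] <- last
      body <- substr(body, 1L, nchar(body) - 1L)
    }
    fields <- strsplit(body, ":", fixed = TRUE)[[1L]]
    if (length(fields) < 1L || length(fields) > 4L)
      stop(sprintf("malformed allele name '%s': expected 1-4 fields", x))
    bad <- which(!nzchar(fields) | grepl("[^0-9]", fields))
    if (length(bad))
      stop(sprintf("malformed allele name '%s': non-numeric field '%s'",
                   x, fields[bad[1L]]))
    fieldList[[i]] <- fields
  }
  new("HLAAlleleName", locus = locus, fieldList = fieldList,
      suffix = suffix, raw = name)
}

#' @describeIn HLAAlleleName-class number of names.
#' @param x an \code{HLAAlleleName}
#' @export
setMethod("length", "HLAAlleleName", function(x) length(x@raw))

#' @describeIn HLAAlleleName-class format back to WHO nomenclature strings.
#' @param ... ignored
#' @export
setMethod("as.character", "HLAAlleleName", function(x, ...) {
  vapply(seq_along(x@raw), function(i)
    paste0(x@locus[i], "*", paste(x@fieldList[[i]], collapse = ":"),
           ifelse(is.na(x@suffix[i]), "", x@suffix[i])),
    character(1L))
})

#' @describeIn HLAAlleleName-class subset names.
#' @param i index
#' @param j,drop ignored
#' @export
setMethod("[", "HLAAlleleName", function(x, i, j, ..., drop = TRUE) {
  new("HLAAlleleName", locus = x@locus[i], fieldList = x@fieldList[i],
      suffix = x@suffix[i], raw = x@raw[i])
})

setMethod("show", "HLAAlleleName", function(object) {
  cat(sprintf("HLAAlleleName of length %d\n", length(object)))
  cat(paste(utils::head(as.character(object), 10L), collapse = " "), "\n")
  if (length(object) > 10L) cat("...\n")
})

#' Two-field antigen designation of an allele
#'
#' Reduces an allele name to its first two fields (e.g.
#' \code{"B*15:03:01:03"} to \code{"B*15:03"}), the resolution at which
#' alleles encode distinct proteins and are counted as distinct antigens.
#' Idempotent on two-field names.
#'
#' @param name an \code{\linkS4class{HLAAlleleName}} or character vector of
#'   parseable names.
#' @return character vector of two-field antigen names.
#' @examples
#' twoFieldAntigen("B*15:03:01:03")
#' @export
twoFieldAntigen <- function(name) {
  if (is.character(name)) name <- parseAlleleName(name)
  stopifnot(is(name, "HLAAlleleName"))
  short <- lengths(name@fieldList) < 2L
  if (any(short))
    stop(sprintf("allele name '%s' has fewer than two fields",
                 name@raw[which(short)[1L]]))
  vapply(seq_along(name@raw), function(i)
    paste0(name@locus[i], "*", name@fieldList[[i]][1L], ":",
           name@fieldList[[i]][2L]), character(1L))
}

#' Is an allele expressed?
#'
#' \code{FALSE} for null (suffix N) and questionable (suffix Q) alleles,
#' which are excluded from antigen counting; \code{TRUE} otherwise. The
#' remaining WHO suffixes (L, S, C, A) denote altered but present expression
#' and count as expressed.
#'
#' @param name an \code{\linkS4class{HLAAlleleName}} or character vector.
#' @return logical vector.
#' @examples
#' isExpressed(c("B*15:01", "B*15:11N", "B*15:01Q"))
#' @export
isExpressed <- function(name) {
  if (is.character(name)) name <- parseAlleleName(name)
  stopifnot(is(name, "HLAAlleleName"))
  !(name@suffix %in% c("N", "Q"))
}
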