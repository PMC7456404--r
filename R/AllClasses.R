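#' @import methods
NULL

#' Parsed WHO HLA allele names
#'
#' Vector-like S4 container for HLA allele names in WHO colon-delimited
#' nomenclature (e.g. \code{"B*15:03:01:03"}): a locus, one to four numeric
#' fields, and an optional single-letter expression suffix (N, Q, L, S, C
#' or A). Construct with \code{\link{parseAlleleName}}; \code{as.character}
#' reproduces the input strings exactly.
#'
#' @slot locus character, locus symbol per name (e.g. \code{"B"}).
#' @slot fieldList list of character vectors, the numeric fields per name.
#' @slot suffix character, expression suffix per name (\code{NA} if none).
#' @slot raw character, the original input strings.
#'
#' @seealso \code{\link{parseAlleleName}}, \code{\link{twoFieldAntigen}},
#'   \code{\link{isExpressed}}
#' @export
setClass("HLAAlleleName",
  representation(locus = "character", fieldList = "list",
                 suffix = "character", raw = "character"))

setValidity("HLAAlleleName", function(object) {
  n <- length(object@raw)
  if (length(object@locus) != n || length(object@fieldList) != n ||
      length(object@suffix) != n)
    return("slots must have equal length")
  for (i in seq_len(n)) {
    f <- object@fieldList[[i]]
    if (length(f) < 1L || any(!nzchar(f)) || any(grepl("[^0-9]", f)))
      return(sprintf("fields of '%s' must be non-empty digit strings",
                     object@raw[i]))
    if (!is.na(object@suffix[i]) && !object@suffix[i] %in% .SUFFIXES)
      return(sprintf("unknown expression suffix '%s'", object@suffix[i]))
    rebuilt <- paste0(object@locus[i], "*", paste(f, collapse = ":"),
                      ifelse(is.na(object@suffix[i]), "", object@suffix[i]))
    if (rebuilt != object@raw[i])
      return(sprintf("name '%s' does not round-trip ('%s')",
                     object@raw[i], rebuilt))
  }
  TRUE
})

#' Motif profiles at the fifteen diagnostic positions
#'
#' S4 container holding, for one or more sequences, the residues at the
#' fifteen diagnostic mature-protein positions (see
#' \code{\link{diagnosticPositions}}). Residues are single uppercase letters
#' from the 20-letter amino acid alphabet; \code{"X"} marks a gap or unknown
#' residue and always classifies as UNASSIGNED downstream.
#'
#' @slot ids character, one identifier per profile (allele name or FASTA id).
#' @slot profile character matrix, one row per profile, columns
#'   \code{aa24 ... aa167} in position order.
#'
#' @seealso \code{\link{extractProfile}}, \code{\link{classifyProfile}},
#'   \code{\link{makeScaffold}}
#' @export
setClass("MotifProfile",
  representation(ids = "character", profile = "matrix"))

setValidity("MotifProfile", function(object) {
  m <- object@profile
  if (!is.character(m)) return("profile matrix must be character")
  if (ncol(m) != 15L || !identical(colnames(m), .profileCols()))
    return("profile matrix must have columns aa24 ... aa167")
  if (nrow(m) != length(object@ids))
    return("ids must match profile rows")
  bad <- !(m %in% c(.AA20, "X"))
  if (any(bad))
    return(sprintf("invalid residue symbol '%s'", m[which(bad)[1L]]))
  TRUE
})

#' Serological assignments
#'
#' Vectorised S4 result of \code{\link{classifyProfile}}: for each profile a
#' serotype label (one of \code{\link{seroLabels}} or \code{"UNASSIGNED"}),
#' the Bw4/Bw6 epitope call, a rationale code from a fixed vocabulary, and
#' the diagnostic positions responsible for a failed assignment.
#'
#' Rationale codes: \code{assigned} (clean match),
#' \code{b63-atypical-context} (B63 called on the RNM motif alone although
#' epitope or position 70 is atypical), \code{incomplete-profile},
#' \code{epitope-indeterminate}, \code{group-key-mismatch},
#' \code{pocket-motif-mismatch}, \code{no-rule}, \code{truncated}.
#'
#' @slot label character, serotype label or \code{"UNASSIGNED"}.
#' @slot epitope character, \code{"Bw4"}, \code{"Bw6"} or
#'   \code{"indeterminate"}.
#' @slot rationale character, reason code per assignment.
#' @slot offending list of integer vectors, positions blocking assignment
#'   (empty for assigned records).
#'
#' @seealso \code{\link{classifyProfile}}, \code{\link{seroLabel}},
#'   \code{\link{summarizeAssignments}}
#' @export
setClass("SeroAssignment",
  representation(label = "character", epitope = "character",
                 rationale = "character", offending = "list"))

setValidity("SeroAssignment", function(object) {
  n <- length(object@label)
  if (length(object@epitope) != n || length(object@rationale) != n ||
      length(object@offending) != n)
    return("slots must have equal length")
  if (any(!object@label %in% c(seroLabels(), .UNASSIGNED)))
    return("unknown serotype label")
  if (any(!object@epitope %in% c("Bw4", "Bw6", "indeterminate")))
    return("unknown epitope value")
  if (any(!object@rationale %in% .RATIONALES))
    return("unknown rationale code")
  assigned <- object@label != .UNASSIGNED
  if (any(assigned & lengths(object@offending) > 0L))
    return("assigned records must have no offending positions")
  clean <- object@rationale == "assigned"
  if (any(clean & object@label %in% .BW4_LABELS & object@epitope != "Bw4") ||
      any(clean & object@label %in% .BW6_LABELS & object@epitope != "Bw6"))
    return("label/epitope inconsistency in a cleanly assigned record")
  TRUE
})

#' Batch classification reports
#'
#' S4 container pairing per-record results (id, the fifteen profile residues,
#' epitope, serotype, rationale) with a per-label tally. Produced by
#' \code{\link{buildReport}} / \code{\link{classifyFasta}} and serialised by
#' \code{\link{writeReport}}.
#'
#' @slot records data.frame with columns \code{id}, \code{aa24 ... aa167},
#'   \code{epitope}, \code{serotype}, \code{rationale}.
#' @slot summary named integer, record count per observed serotype label.
#'
#' @export
setClass("ClassificationReport",
  representation(records = "data.frame", summary = "integer"))

setValidity("ClassificationReport", function(object) {
  need <- c("id", .profileCols(), "epitope", "serotype", "rationale")
  if (!identical(colnames(object@records), need))
    return("records must have columns id, aa24..aa167, epitope, serotype, rationale")
  if (sum(object@summary) != nrow(object@records))
    return("summary counts must sum to the number of records")
  tab <- table(object@records$serotype)
  if (!identical(sort(as.character(names(object@summary))),
                 sort(as.character(names(tab)))) ||
      any(object@summary[names(tab)] != as.integer(tab)))
    return("summary does not tally the record labels")
  TRUE
})

#' Position patterns from motif discovery
#'
#' S4 record produced by \code{\link{enumerateVariablePatterns}}: a set of
#' (possibly grouped) mature-protein positions at which the labelled input
#' alleles vary, the residue combination observed at those positions for
#' every input allele, and — when one exists — the single label for which
#' some combination is private (occurs in no other label's alleles).
#'
#' @slot positions integer, the mature-protein positions of the pattern.
#' @slot values character, residue combination per input allele.
#' @slot labels character, serological label per input allele.
#' @slot uniqueFor character of length 0 or 1; the label this pattern is
#'   unique for, if any.
#'
#' @seealso \code{\link{filterUniquePatterns}}, \code{\link{conjoinPatterns}}
#' @export
setClass("PositionPattern",
  representation(positions = "integer", values = "character",
                 labels = "character", uniqueFor = "character"))

setValidity("PositionPattern", function(object) {
  if (length(object@values) != length(object@labels))
    return("values and labels must be parallel")
  if (length(object@positions) < 1L) return("positions must be non-empty")
  if (length(object@uniqueFor) > 1L)
    return("uniqueFor must have length 0 or 1")
  if (length(object@uniqueFor) == 1L) {
    priv <- .privateLabels(object@values, object@labels)
    if (!object@uniqueFor %in% priv)
      return("uniqueFor label has no private residue combination")
  }
  TRUE
})
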