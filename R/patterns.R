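## Motif discovery: find positions at which labelled alleles vary, group
## contiguous ones, and keep the patterns whose residue combination is
## private to a single serotype.

## labels that own at least one residue combination seen in no other label
.privateLabels <- function(values, labels) {
  labs <- unique(labels)
  priv <- vapply(labs, function(L) {
    inL <- unique(values[labels == L])
    length(setdiff(inL, values[labels != L])) > 0L
  }, logical(1L))
  sort(labs[priv])
}

.newPattern <- function(positions, values, labels) {
  priv <- .privateLabels(values, labels)
  new("PositionPattern", positions = as.integer(positions),
      values = values, labels = labels,
      uniqueFor = if (length(priv)) priv[1L] else character(0L))
}

#' @describeIn PositionPattern-class the pattern's positions.
#' @export
setMethod("patternPositions", "PositionPattern",
          function(object) object@positions)

#' @describeIn PositionPattern-class label the pattern is unique for
#'   (length 0 when none).
#' @export
setMethod("uniqueFor", "PositionPattern", function(object) object@uniqueFor)

#' @describeIn PositionPattern-class residue combinations observed per
#'   label (named list of character vectors).
#' @export
setMethod("residuesByLabel", "PositionPattern", function(object) {
  lapply(split(object@values, object@labels), function(v) sort(unique(v)))
})

setMethod("show", "PositionPattern", function(object) {
  cat(sprintf("PositionPattern at position(s) %s%s\n",
              paste(object@positions, collapse = "-"),
              if (length(object@uniqueFor))
                paste0(" [unique for ", object@uniqueFor, "]") else ""))
  by <- residuesByLabel(object)
  for (L in names(by))
    cat(sprintf("  %-8s %s\n", L, paste(by[[L]], collapse = ", ")))
})

#' Enumerate variable position patterns in a labelled allele set
#'
#' Scans a labelled set of colinear sequences (or motif profiles) for the
#' positions at which at least two alleles carry different residues —
#' monomorphic positions carry no discriminating information and are
#' skipped. Contiguous variable positions are merged into one pattern
#' (the natural groupings 45-46, 65-67, 80-83, 166-167 arise this way);
#' set \code{groupContiguous = FALSE} to keep single-position patterns.
#'
#' @param labels character vector of serological labels, one per sequence.
#' @param sequences character vector of equal-length protein sequences in
#'   mature coordinates (position 1 = first character), or a
#'   \code{\linkS4class{MotifProfile}} (positions are then the fifteen
#'   diagnostic ones).
#' @param groupContiguous merge adjacent variable positions (default
#'   \code{TRUE}).
#' @return list of \code{\linkS4class{PositionPattern}} objects, ordered by
#'   first position.
#' @examples
#' set <- generateLabeledSet(1, 0, seed = 1)
#' pats <- enumerateVariablePatterns(set$label, set$sequence)
#' sapply(pats, function(p) paste(patternPositions(p), collapse = "-"))
#' @export
enumerateVariablePatterns <- function(labels, sequences,
                                      groupContiguous = TRUE) {
  stopifnot(length(labels) >= 2L)
  if (is(sequences, "MotifProfile")) {
    m <- sequences@profile
    positions <- diagnosticPositions()
  } else {
    stopifnot(is.character(sequences), length(sequences) == length(labels))
    if (length(unique(nchar(sequences))) != 1L)
      stop("sequences must all have the same length")
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
    positions <- seq_len(ncol(m))
  }
  if (length(unique(labels)) < 1L) stop("labels required")
  variable <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  if (length(variable) == 0L) return(list())
  varPos <- positions[variable]
  groups <- if (groupContiguous) {
    split(seq_along(varPos), cumsum(c(1L, diff(varPos) != 1L)))
  } else as.list(seq_along(varPos))
  lapply(groups, function(g) {
    cols <- variable[g]
    vals <- if (length(cols) > 1L)
      do.call(paste0, as.data.frame(m[, cols, drop = FALSE]))
    else m[, cols]
    .newPattern(varPos[g], vals, labels)
  })
}

#' Partition patterns into subtype-unique and excluded
#'
#' A pattern is kept when some residue combination at its positions is
#' private to a single label — it then suffices to recognise that subtype.
#' Patterns whose every combination is shared between two or more labels
#' carry no subtype-specific signal on their own and are excluded. With
#' \code{pairwise = TRUE} an otherwise excluded pattern is also kept when
#' its conjunction with another input pattern (see
#' \code{\link{conjoinPatterns}}) is unique for some label; the partner and
#' label are reported in the \code{combinations} element.
#'
#' @param patterns list of \code{\linkS4class{PositionPattern}} objects
#'   over the same allele set.
#' @param pairwise also test two-pattern conjunctions (default
#'   \code{FALSE}).
#' @return list with elements \code{kept}, \code{excluded} (disjoint, and
#'   together the input) and, when \code{pairwise}, a data.frame
#'   \code{combinations} of pattern/partner/label triples.
#' @examples
#' set <- generateLabeledSet(1, 0, seed = 1)
#' pats <- enumerateVariablePatterns(set$label, set$sequence)
#' res <- filterUniquePatterns(pats)
#' sapply(res$kept, uniqueFor)
#' @export
filterUniquePatterns <- function(patterns, pairwise = FALSE) {
  stopifnot(is.list(patterns))
  aloneKept <- vapply(patterns, function(p) length(p@uniqueFor) == 1L,
                      logical(1L))
  keptIdx <- which(aloneKept)
  combos <- data.frame(pattern = integer(0L), partner = integer(0L),
                       unique_for = character(0L),
                       stringsAsFactors = FALSE)
  if (pairwise && length(patterns) > 1L) {
    for (i in which(!aloneKept)) {
      for (j in setdiff(seq_along(patterns), i)) {
        conj <- conjoinPatterns(patterns[[i]], patterns[[j]])
        if (length(conj@uniqueFor) == 1L) {
          combos <- rbind(combos, data.frame(
            pattern = i, partner = j, unique_for = conj@uniqueFor,
            stringsAsFactors = FALSE))
        }
      }
    }
    keptIdx <- sort(union(keptIdx, unique(combos$pattern)))
  }
  out <- list(kept = patterns[keptIdx],
              excluded = patterns[setdiff(seq_along(patterns), keptIdx)])
  if (pairwise) out$combinations <- combos
  out
}

#' Conjoin two position patterns
#'
#' Builds the conjunction pattern over the union of positions of two
#' patterns observed on the same allele set: its value for an allele is the
#' concatenation of the two member values, and uniqueness is re-evaluated
#' on the combined combination.
#'
#' @param p1,p2 \code{\linkS4class{PositionPattern}} objects with identical
#'   label vectors.
#' @return a \code{PositionPattern}.
#' @export
conjoinPatterns <- function(p1, p2) {
  stopifnot(is(p1, "PositionPattern"), is(p2, "PositionPattern"),
            identical(p1@labels, p2@labels))
  .newPattern(c(p1@positions, p2@positions),
              paste0(p1@values, p2@values), p1@labels)
}

#' Rebuild a decision table from kept patterns
#'
#' Concatenates, per allele, the values of the given patterns into a key
#' and maps each key to its label. An error is raised when a key maps to
#' two labels (the patterns do not separate the set). Apply the table with
#' \code{\link{applyPatternTable}}.
#'
#' @param patterns list of \code{\linkS4class{PositionPattern}} objects
#'   over the same allele set.
#' @return named character vector, key to label.
#' @export
buildPatternTable <- function(patterns) {
  stopifnot(length(patterns) >= 1L)
  keys <- do.call(paste, c(lapply(patterns, function(p) p@values),
                           sep = "|"))
  labels <- patterns[[1L]]@labels
  tab <- tapply(labels, keys, function(x) unique(x), simplify = FALSE)
  ambiguous <- names(tab)[lengths(tab) > 1L]
  if (length(ambiguous))
    stop("patterns do not separate the labels; ambiguous key(s): ",
         paste(utils::head(ambiguous, 3L), collapse = ", "))
  stats::setNames(vapply(tab, `[`, character(1L), 1L), names(tab))
}

#' Apply a rebuilt decision table
#'
#' @param table named character vector from
#'   \code{\link{buildPatternTable}}.
#' @param patterns the same patterns (or patterns over new alleles with
#'   identical positions) to classify with the table.
#' @return character vector of labels, \code{NA} for unseen keys.
#' @export
applyPatternTable <- function(table, patterns) {
  keys <- do.call(paste, c(lapply(patterns, function(p) p@values),
                           sep = "|"))
  unname(table[keys])
}

#' Write a pattern table to TSV
#'
#' One row per pattern: positions, status (kept/excluded), the label the
#' pattern is unique for (if any) and the residue combinations per label.
#'
#' @param result the list returned by \code{\link{filterUniquePatterns}}.
#' @param file optional output path.
#' @return the TSV text, invisibly when \code{file} is given.
#' @export
writePatternTable <- function(result, file = NULL) {
  fmt <- function(p, status) {
    by <- residuesByLabel(p)
    paste(paste(p@positions, collapse = "-"), status,
          if (length(p@uniqueFor)) p@uniqueFor else "-",
          paste(vapply(names(by), function(L)
            paste0(L, ":", paste(by[[L]], collapse = ",")),
            character(1L)), collapse = ";"),
          sep = "\t")
  }
  lines <- c("positions\tstatus\tunique_for\tresidues_by_label",
             vapply(result$kept, fmt, character(1L), status = "kept"),
             vapply(result$excluded, fmt, character(1L),
                    status = "excluded"))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeChar(text, con, eos = NULL)
    return(invisible(text))
  }
  text
}
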