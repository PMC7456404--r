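#' Construct a MotifProfile
#'
#' Builds a \code{\linkS4class{MotifProfile}} from a character matrix or
#' data.frame whose columns \code{aa24 ... aa167} hold single residues, or
#' from a single named character vector of the fifteen residues. Residues
#' are uppercased; gap characters (\code{-}, \code{.}, \code{*}) and any
#' symbol outside the 20-letter alphabet become \code{"X"}.
#'
#' @param residues matrix, data.frame or named character vector with entries
#'   for all columns in \code{paste0("aa", diagnosticPositions())}.
#' @param ids optional character identifiers (default: rownames or blank).
#' @return a \code{MotifProfile}.
#' @examples
#' p <- MotifProfile(c(aa24 = "A", aa45 = "M", aa46 = "A", aa63 = "E",
#'                     aa65 = "Q", aa66 = "I", aa67 = "S", aa70 = "N",
#'                     aa77 = "S", aa80 = "N", aa81 = "L", aa82 = "R",
#'                     aa83 = "G", aa166 = "E", aa167 = "W"), ids = "toy")
#' profileMatrix(p)
#' @export
MotifProfile <- function(residues, ids = NULL) {
  cols <- .profileCols()
  if (is.character(residues) && is.null(dim(residues)))
    residues <- matrix(residues, nrow = 1L,
                       dimnames = list(NULL, names(residues)))
  if (is.data.frame(residues))
    residues <- as.matrix(residues[, intersect(cols, colnames(residues)),
                                   drop = FALSE])
  if (is.null(colnames(residues)) || !all(cols %in% colnames(residues)))
    stop("residues must provide columns ", paste(cols, collapse = ", "))
  m <- residues[, cols, drop = FALSE]
  mode(m) <- "character"
  m[] <- toupper(m)
  m[!(m %in% .AA20)] <- "X"
  if (is.null(ids)) ids <- rownames(residues)
  if (is.null(ids)) ids <- rep("", nrow(m))
  rownames(m) <- NULL
  new("MotifProfile", ids = as.character(ids), profile = m)
}

#' @describeIn MotifProfile-class residue matrix (rows = profiles, columns
#'   \code{aa24 ... aa167}), with ids as rownames.
#' @export
setMethod("profileMatrix", "MotifProfile", function(object) {
  m <- object@profile
  rownames(m) <- object@ids
  m
})

#' @describeIn MotifProfile-class number of profiles.
#' @param x a \code{MotifProfile}
#' @export
setMethod("length", "MotifProfile", function(x) nrow(x@profile))

#' @describeIn MotifProfile-class subset profiles.
#' @param i index
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "MotifProfile", function(x, i, j, ..., drop = TRUE) {
  new("MotifProfile", ids = x@ids[i], profile = x@profile[i, , drop = FALSE])
})

setMethod("show", "MotifProfile", function(object) {
  cat(sprintf("MotifProfile with %d profile(s) at %d diagnostic positions\n",
              length(object), ncol(object@profile)))
  print(utils::head(profileMatrix(object), 5L), quote = FALSE)
  if (length(object) > 5L) cat("...\n")
})

#' Locate mature-protein position 1 in a protein sequence
#'
#' Mature class I heavy chains start with the tetrapeptide \code{GSHS};
#' precursor records carry the 24-residue signal peptide before it. The
#' offset returned is the 0-based index of mature position 1: 0 when the
#' sequence itself starts \code{GSHS}, otherwise the position of the first
#' \code{GSHS} found within the leading 30 residues. An explicit
#' \code{offset} bypasses detection (for unusual leaders or fragments).
#'
#' @param sequence single protein sequence (character scalar).
#' @param offset optional explicit 0-based offset; returned unchanged.
#' @return integer offset.
#' @examples
#' detectMatureOffset("GSHSMRYF")
#' detectMatureOffset(paste0(strrep("A", 24), "GSHSMRYF"))
#' @export
detectMatureOffset <- function(sequence, offset = NULL) {
  if (!is.null(offset)) return(as.integer(offset))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (startsWith(sequence, .MATURE_ANCHOR)) return(0L)
  hit <- regexpr(.MATURE_ANCHOR, substr(sequence, 1L, 30L + 3L),
                 fixed = TRUE)
  if (hit > 0L && hit <= 31L) return(as.integer(hit) - 1L)
  stop(structure(class = c("undeterminableOffset", "error", "condition"),
                 list(message = paste0("cannot determine mature-protein ",
                                       "offset: '", .MATURE_ANCHOR,
                                       "' anchor not found in the first 30 ",
                                       "residues and no explicit offset given"),
                      call = sys.call(-1L))))
}

#' Extract the diagnostic motif profile from protein sequences
#'
#' Reads the residues at the fifteen diagnostic mature-protein positions.
#' The residue at mature position p of a sequence with 0-based offset k is
#' character k + p of the string (1-based mature numbering). Offsets are
#' detected per sequence via \code{\link{detectMatureOffset}} unless given.
#' Gap characters and non-standard symbols at diagnostic positions map to
#' \code{"X"}.
#'
#' @param sequences an \code{AAStringSet} or (named) character vector of
#'   protein sequences, assumed colinear with the HLA-B protein.
#' @param offset optional integer offset(s), recycled across sequences;
#'   \code{NULL} to auto-detect.
#' @return a \code{\linkS4class{MotifProfile}} with one row per sequence.
#' @examples
#' prof <- extractProfile(makeScaffold(expandTable1()[1, ]))
#' profileMatrix(prof)
#' @export
extractProfile <- function(sequences, offset = NULL) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  ids <- names(sequences)
  if (is.null(ids)) ids <- rep("", length(sequences))
  sequences <- toupper(sequences)
  offs <- if (is.null(offset)) {
    vapply(sequences, detectMatureOffset, integer(1L), USE.NAMES = FALSE)
  } else rep_len(as.integer(offset), length(sequences))
  pos <- diagnosticPositions()
  m <- matrix("X", nrow = length(sequences), ncol = length(pos),
              dimnames = list(NULL, .profileCols()))
  for (i in seq_along(sequences)) {
    len <- nchar(sequences[i])
    missing <- pos[offs[i] + pos > len]
    if (length(missing))
      stop(structure(class = c("truncatedSequence", "error", "condition"),
                     list(message = sprintf(
                       "sequence %s too short (%d residues after offset %d): first missing diagnostic position is %d",
                       if (nzchar(ids[i])) sQuote(ids[i]) else i,
                       len - offs[i], offs[i], min(missing)),
                       call = sys.call(-1L))))
    m[i, ] <- substring(sequences[i], offs[i] + pos, offs[i] + pos)
  }
  MotifProfile(m, ids = ids)
}
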