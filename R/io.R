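#' Read a protein FASTA file
#'
#' Thin wrapper around \code{Biostrings::readAAStringSet} that uppercases
#' sequences (gap characters \code{-} and \code{.} are preserved for the
#' caller), takes the first whitespace-delimited header token as the record
#' id, and optionally parses IPD-IMGT/HLA-style headers
#' (\code{"HLA:HLA00162 B*15:01:01:01 362 bp"}) so the allele name becomes
#' the id.
#'
#' @param path path to a FASTA file.
#' @param parseHeaders logical; parse IPD-IMGT/HLA headers when they match
#'   the \code{HLA:HLAxxxxx <allele> ...} dialect (default \code{FALSE}).
#' @return a named \code{AAStringSet} in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "gshsmryf", ">b", "GSHSMRYT"), fa)
#' readProteinFasta(fa)
#' @export
readProteinFasta <- function(path, parseHeaders = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, character(1L), 1L)
  if (parseHeaders) {
    toks <- strsplit(names(seqs), "[[:space:]]+")
    imgt <- grepl("^HLA:HLA[0-9]+$", ids) & lengths(toks) >= 2L
    ids[imgt] <- vapply(toks[imgt], `[`, character(1L), 2L)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  out <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(out) <- ids
  out
}

#' Read a motif-profile table
#'
#' Loads a TSV with an id column (\code{id} or \code{allele}) and the
#' fifteen residue columns \code{aa24 ... aa167}; extra columns are
#' ignored. This is the \code{profile-tsv} input format of the command-line
#' front-end, and the format the packaged fixture tables use.
#'
#' @param path path to a tab-separated file.
#' @return list with elements \code{profile}
#'   (\code{\linkS4class{MotifProfile}}) and \code{table} (the raw
#'   data.frame).
#' @export
readProfileTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  idcol <- intersect(c("id", "allele"), colnames(df))
  if (length(idcol) == 0L)
    stop("profile table needs an 'id' or 'allele' column")
  missing <- setdiff(.profileCols(), colnames(df))
  if (length(missing))
    stop("profile table lacks column(s): ", paste(missing, collapse = ", "))
  list(profile = MotifProfile(df, ids = df[[idcol[1L]]]), table = df)
}

#' Build a classification report
#'
#' Pairs profiles with their assignments into a
#' \code{\linkS4class{ClassificationReport}} whose summary tallies records
#' per label.
#'
#' @param profile a \code{\linkS4class{MotifProfile}}.
#' @param assignment the matching \code{\linkS4class{SeroAssignment}}.
#' @param ids optional ids overriding the profile ids.
#' @return a \code{ClassificationReport}.
#' @examples
#' fx <- loadFixture("T2")
#' p <- MotifProfile(fx, ids = fx$allele)
#' buildReport(p, classifyProfile(p))
#' @export
buildReport <- function(profile, assignment, ids = NULL) {
  stopifnot(is(profile, "MotifProfile"), is(assignment, "SeroAssignment"),
            length(profile) == length(assignment))
  if (is.null(ids)) ids <- profile@ids
  records <- data.frame(id = ids, profile@profile,
                        epitope = epitopeCall(assignment),
                        serotype = seroLabel(assignment),
                        rationale = rationale(assignment),
                        stringsAsFactors = FALSE)
  new("ClassificationReport", records = records,
      summary = summarizeAssignments(assignment))
}

#' @describeIn ClassificationReport-class per-record data.frame.
#' @export
setMethod("reportRecords", "ClassificationReport",
          function(object) object@records)

#' @describeIn ClassificationReport-class named integer tally per label.
#' @export
setMethod("reportSummary", "ClassificationReport",
          function(object) object@summary)

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport with %d record(s)\n",
              nrow(object@records)))
  if (length(object@summary)) {
    cat("summary:\n")
    print(object@summary)
  }
})

#' Serialise a classification report
#'
#' TSV output has the columns id, the fifteen residues, epitope, serotype
#' and rationale; JSON mirrors the same fields as a \code{records} array
#' plus a \code{summary} object. Output is deterministic given record
#' order: the same report always serialises to identical bytes.
#'
#' @param report a \code{\linkS4class{ClassificationReport}}.
#' @param file optional path; when given the text is also written there.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return the serialised text, invisibly when \code{file} is given.
#' @export
writeReport <- function(report, file = NULL, format = c("tsv", "json")) {
  stopifnot(is(report, "ClassificationReport"))
  format <- match.arg(format)
  rec <- report@records
  if (format == "tsv") {
    header <- paste(colnames(rec), collapse = "\t")
    body <- if (nrow(rec)) do.call(paste, c(unname(as.list(rec)), sep = "\t"))
            else character(0L)
    text <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  } else {
    payload <- list(records = rec,
                    summary = as.list(report@summary))
    text <- paste0(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                    dataframe = "rows", pretty = TRUE,
                                    na = "null"), "\n")
  }
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeChar(text, con, eos = NULL)
    return(invisible(text))
  }
  text
}

#' Classify every sequence in a protein FASTA file
#'
#' Convenience pipeline: \code{\link{readProteinFasta}},
#' \code{\link{classifySequence}}, \code{\link{buildReport}}. Optionally
#' drops null/questionable alleles (ids must then parse as allele names)
#' and collapses records to distinct two-field antigens, keeping the first
#' record of each.
#'
#' @param path FASTA path.
#' @param offset optional explicit mature offset.
#' @param parseHeaders see \code{\link{readProteinFasta}}.
#' @param excludeNonExpressed drop ids with expression suffix N or Q.
#' @param twoField collapse ids to two-field antigen names.
#' @return a \code{\linkS4class{ClassificationReport}}.
#' @export
classifyFasta <- function(path, offset = NULL, parseHeaders = FALSE,
                          excludeNonExpressed = FALSE, twoField = FALSE) {
  seqs <- readProteinFasta(path, parseHeaders = parseHeaders)
  ids <- names(seqs)
  if (excludeNonExpressed) {
    keep <- isExpressed(parseAlleleName(ids))
    seqs <- seqs[keep]
    ids <- ids[keep]
    if (length(seqs) == 0L) stop("no expressed alleles left after filtering")
  }
  if (twoField) {
    anti <- twoFieldAntigen(parseAlleleName(ids))
    keep <- !duplicated(anti)
    seqs <- seqs[keep]
    ids <- anti[keep]
  }
  res <- classifySequence(stats::setNames(as.character(seqs), ids))
  buildReport(res$profile, res$assignment)
}
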