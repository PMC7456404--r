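## The serotype decision procedure. Rules are evaluated in a fixed order:
## incomplete profile, epitope, group key (24/45-46), then the family
## branches. Everything that matches no rule is UNASSIGNED with a reason
## code and the positions responsible.

.bwEpitopeCore <- function(aa77, motif8083) {
  out <- rep("indeterminate", length(aa77))
  out[aa77 == .BW6_77 & motif8083 == .BW6_8083] <- "Bw6"
  out[aa77 %in% .BW4_77 & motif8083 %in% .BW4_8083] <- "Bw4"
  out
}

#' Call the Bw4/Bw6 public epitope from a motif profile
#'
#' Bw4 requires N, D or S at residue 77 together with the IALR, TLLR or
#' TALR motif at residues 80-83; Bw6 requires S at 77 with NLRG at 80-83.
#' The two rules are disjoint (NLRG is not a Bw4 motif); any other
#' combination — e.g. the KLRG motif — is \code{"indeterminate"} and blocks
#' serotype assignment.
#'
#' @param profile a \code{\linkS4class{MotifProfile}}.
#' @return character vector of \code{"Bw4"}, \code{"Bw6"} or
#'   \code{"indeterminate"}, one per profile.
#' @examples
#' callBwEpitope(extractProfile(makeScaffold(expandTable1()[1, ])))
#' @export
callBwEpitope <- function(profile) {
  stopifnot(is(profile, "MotifProfile"))
  m <- profile@profile
  .bwEpitopeCore(m[, "aa77"],
                 paste0(m[, "aa80"], m[, "aa81"], m[, "aa82"], m[, "aa83"]))
}

## vectorised decision tree over a profile matrix; returns parallel vectors
.classifyCore <- function(m) {
  n <- nrow(m)
  label <- rep(.UNASSIGNED, n)
  rationale <- rep("no-rule", n)
  offending <- rep(list(integer(0L)), n)
  epi <- .bwEpitopeCore(m[, "aa77"],
                        paste0(m[, "aa80"], m[, "aa81"], m[, "aa82"],
                               m[, "aa83"]))
  pocket <- paste0(m[, "aa65"], m[, "aa66"], m[, "aa67"])
  tail167 <- paste0(m[, "aa166"], m[, "aa167"])
  pos <- diagnosticPositions()

  mark <- function(idx, reason, offpos) {
    rationale[idx] <<- reason
    offending[idx] <<- rep(list(as.integer(offpos)), length(idx))
  }

  ## (1) unknown residue anywhere in the profile
  hasX <- rowSums(m == "X") > 0L
  for (i in which(hasX)) {
    rationale[i] <- "incomplete-profile"
    offending[[i]] <- pos[m[i, ] == "X"]
  }
  done <- hasX

  ## (2) epitope must be resolvable before any serotype rule applies
  ind <- !done & epi == "indeterminate"
  mark(which(ind), "epitope-indeterminate", c(77L, 80L, 81L, 82L, 83L))
  done <- done | ind

  ## (3) group key at 24/45-46: A-MA = B62 family, S-EE = B70 family
  fam62 <- !done & m[, "aa24"] == "A" & m[, "aa45"] == "M" & m[, "aa46"] == "A"
  fam70 <- !done & m[, "aa24"] == "S" & m[, "aa45"] == "E" & m[, "aa46"] == "E"
  gkm <- !done & !fam62 & !fam70
  mark(which(gkm), "group-key-mismatch", c(24L, 45L, 46L))

  bw4 <- epi == "Bw4"

  ## (4) B62 family: B63 on the RNM pocket alone; otherwise the pocket must
  ## be QIC/QIF/QIS/QIY with N at 70, then position 63 and the 166-167 tail
  ## split B62 / B62-Bw4 / B75 / B77 / B76
  b63 <- fam62 & pocket == "RNM"
  label[b63] <- "B63"
  typical <- b63 & bw4 & m[, "aa70"] == "S"
  rationale[which(typical)] <- "assigned"
  rationale[which(b63 & !typical)] <- "b63-atypical-context"

  rest <- fam62 & !b63
  pocketOK <- pocket %in% c("QIC", "QIF", "QIS", "QIY")
  ok70 <- m[, "aa70"] == "N"
  pmm <- rest & !(pocketOK & ok70)
  for (i in which(pmm)) {
    rationale[i] <- "pocket-motif-mismatch"
    offending[[i]] <- c(if (!pocketOK[i]) c(65L, 66L, 67L),
                        if (!ok70[i]) 70L)
  }
  ok62 <- rest & pocketOK & ok70
  ew <- tail167 == "EW"
  n63 <- ok62 & m[, "aa63"] == "N"
  label[n63 & ew & !bw4] <- "B75"
  label[n63 & ew & bw4] <- "B77"
  rationale[which(n63 & ew)] <- "assigned"
  ## N at 63 without the EW tail matches no serotype definition
  mark(which(n63 & !ew), "no-rule", c(166L, 167L))
  e63 <- ok62 & m[, "aa63"] == "E"
  label[e63 & ew & !bw4] <- "B62"
  label[e63 & ew & bw4] <- "B62-Bw4"
  rationale[which(e63 & ew)] <- "assigned"
  ## B76 is defined by the missing EW motif, under Bw6 only
  label[e63 & !ew & !bw4] <- "B76"
  rationale[which(e63 & !ew & !bw4)] <- "assigned"
  mark(which(e63 & !ew & bw4), "no-rule", c(166L, 167L))
  bad63 <- ok62 & !(m[, "aa63"] %in% c("E", "N"))
  mark(which(bad63), "no-rule", 63L)

  ## (5) B70 family: pocket QIC/QIF/QIS, N at 70 and the EW tail are all
  ## required; position 63 then splits B71 / B71-Bw4 / B72
  pocketOK70 <- pocket %in% c("QIC", "QIF", "QIS")
  pmm70 <- fam70 & !(pocketOK70 & ok70)
  for (i in which(pmm70)) {
    rationale[i] <- "pocket-motif-mismatch"
    offending[[i]] <- c(if (!pocketOK70[i]) c(65L, 66L, 67L),
                        if (!ok70[i]) 70L)
  }
  tailBad <- fam70 & pocketOK70 & ok70 & !ew
  mark(which(tailBad), "no-rule", c(166L, 167L))
  ok71 <- fam70 & pocketOK70 & ok70 & ew
  n63b <- ok71 & m[, "aa63"] == "N"
  label[n63b & !bw4] <- "B71"
  label[n63b & bw4] <- "B71-Bw4"
  rationale[which(n63b)] <- "assigned"
  e63b <- ok71 & m[, "aa63"] == "E"
  label[e63b & !bw4] <- "B72"
  rationale[which(e63b & !bw4)] <- "assigned"
  ## no B72-Bw4 serotype is defined
  mark(which(e63b & bw4), "no-rule", c(77L, 80L, 81L, 82L, 83L))
  bad63b <- ok71 & !(m[, "aa63"] %in% c("E", "N"))
  mark(which(bad63b), "no-rule", 63L)

  list(label = label, epitope = epi, rationale = rationale,
       offending = offending)
}

#' Assign serological splits to motif profiles
#'
#' Applies the B15 decision rules to each profile: unknown residues and
#' indeterminate epitopes are rejected first, the group key at positions
#' 24/45-46 selects the B62 (A-MA) or B70 (S-EE) family, and the pocket
#' motif at 65-67 with positions 63, 70 and 166-167 then resolves the split.
#' Every profile receives exactly one label — one of
#' \code{\link{seroLabels}} or \code{"UNASSIGNED"} with a rationale code and
#' the offending positions.
#'
#' @param profile a \code{\linkS4class{MotifProfile}} (or matrix/data.frame
#'   coercible to one).
#' @return a \code{\linkS4class{SeroAssignment}} parallel to the profiles.
#' @examples
#' t1 <- expandTable1()
#' a <- classifyProfile(MotifProfile(t1, ids = t1$label))
#' table(seroLabel(a))
#' @export
classifyProfile <- function(profile) {
  if (!is(profile, "MotifProfile")) profile <- MotifProfile(profile)
  res <- .classifyCore(profile@profile)
  new("SeroAssignment", label = res$label, epitope = res$epitope,
      rationale = res$rationale, offending = res$offending)
}

#' @describeIn SeroAssignment-class serotype labels.
#' @export
setMethod("seroLabel", "SeroAssignment", function(object) object@label)

#' @describeIn SeroAssignment-class Bw4/Bw6/indeterminate epitope calls.
#' @export
setMethod("epitopeCall", "SeroAssignment", function(object) object@epitope)

#' @describeIn SeroAssignment-class rationale codes.
#' @export
setMethod("rationale", "SeroAssignment", function(object) object@rationale)

#' @describeIn SeroAssignment-class list of offending position vectors.
#' @export
setMethod("offendingPositions", "SeroAssignment",
          function(object) object@offending)

#' @describeIn SeroAssignment-class number of assignments.
#' @param x a \code{SeroAssignment}
#' @export
setMethod("length", "SeroAssignment", function(x) length(x@label))

#' @describeIn SeroAssignment-class subset assignments.
#' @param i index
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "SeroAssignment", function(x, i, j, ..., drop = TRUE) {
  new("SeroAssignment", label = x@label[i], epitope = x@epitope[i],
      rationale = x@rationale[i], offending = x@offending[i])
})

setMethod("show", "SeroAssignment", function(object) {
  cat(sprintf("SeroAssignment of length %d\n", length(object)))
  print(utils::head(data.frame(label = object@label,
                               epitope = object@epitope,
                               rationale = object@rationale), 8L))
  if (length(object) > 8L) cat("...\n")
})

#' Classify protein sequences end to end
#'
#' Composes \code{\link{extractProfile}} and \code{\link{classifyProfile}}.
#' Sequences that end before diagnostic position 167 are not dropped: they
#' yield an all-\code{X} profile and an UNASSIGNED record with rationale
#' \code{truncated}, so batch runs complete. A sequence whose mature offset
#' cannot be determined (no \code{GSHS} anchor, no explicit offset) raises
#' the \code{undeterminableOffset} error from the numbering layer.
#'
#' @param sequences an \code{AAStringSet} or (named) character vector.
#' @param offset optional explicit 0-based offset(s); \code{NULL} to detect.
#' @return list with elements \code{profile}
#'   (\code{\linkS4class{MotifProfile}}) and \code{assignment}
#'   (\code{\linkS4class{SeroAssignment}}).
#' @examples
#' seqs <- generateLabeledSet(1, 0, seed = 7)
#' res <- classifySequence(setNames(seqs$sequence, seqs$id))
#' seroLabel(res$assignment)
#' @export
classifySequence <- function(sequences, offset = NULL) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  stopifnot(is.character(sequences))
  ids <- if (is.null(names(sequences))) rep("", length(sequences))
         else names(sequences)
  cols <- .profileCols()
  m <- matrix("X", nrow = length(sequences), ncol = length(cols),
              dimnames = list(NULL, cols))
  failReason <- rep(NA_character_, length(sequences))
  for (i in seq_along(sequences)) {
    off_i <- if (is.null(offset)) NULL
             else offset[((i - 1L) %% length(offset)) + 1L]
    prof_i <- tryCatch(
      extractProfile(sequences[i], offset = off_i),
      truncatedSequence = function(e) { failReason[i] <<- "truncated"; NULL })
    if (!is.null(prof_i)) m[i, ] <- prof_i@profile[1L, ]
  }
  profile <- MotifProfile(m, ids = ids)
  assignment <- classifyProfile(profile)
  fails <- which(!is.na(failReason))
  if (length(fails)) {
    assignment@rationale[fails] <- failReason[fails]
    assignment@offending[fails] <- rep(list(diagnosticPositions()),
                                       length(fails))
  }
  validObject(assignment)
  list(profile = profile, assignment = assignment)
}

#' Tally assignments per serotype label
#'
#' Permutation-invariant count of records per label (observed labels only,
#' in canonical order with UNASSIGNED last).
#'
#' @param assignments a \code{\linkS4class{SeroAssignment}} or character
#'   vector of labels.
#' @return named integer vector; empty input gives an empty vector.
#' @examples
#' fx <- loadFixture("T2")
#' summarizeAssignments(classifyProfile(MotifProfile(fx, ids = fx$allele)))
#' @export
summarizeAssignments <- function(assignments) {
  labels <- if (is(assignments, "SeroAssignment")) seroLabel(assignments)
            else as.character(assignments)
  if (length(labels) == 0L)
    return(stats::setNames(integer(0L), character(0L)))
  counts <- table(labels)
  order <- intersect(c(seroLabels(), .UNASSIGNED), names(counts))
  out <- as.integer(counts[order])
  names(out) <- order
  out
}
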