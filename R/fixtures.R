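## Packaged motif tables. T1 holds the canonical motif definition per
## serotype (alternatives slash-separated, Bw4 rows with the printed
## representative N/IALR epitope); T2-T4 hold the fully resolved profiles
## of the discrepant (6), expert-undefined (11) and unassignable (22)
## alleles, with the expected classifier outcome per row.

.fixtureFile <- function(table) {
  fn <- c(T1 = "b15_table1_motifs.tsv", T2 = "b15_table2_profiles.tsv",
          T3 = "b15_table3_profiles.tsv", T4 = "b15_table4_profiles.tsv")
  if (!table %in% names(fn)) stop("unknown fixture table: ", table)
  system.file("extdata", fn[[table]], package = "SeroB15", mustWork = TRUE)
}

#' Load a packaged motif-table fixture
#'
#' \code{"T1"} returns the 9-row canonical motif table (one row per
#' serotype; residue alternatives slash-separated — expand with
#' \code{\link{expandTable1}}). \code{"T2"} (6 rows), \code{"T3"} (11 rows)
#' and \code{"T4"} (22 rows) return per-allele profile tables with columns
#' \code{allele}, \code{aa24 ... aa167}, \code{expected_label} (a serotype
#' or \code{UNASSIGNED}) and \code{source_table}.
#'
#' @param table one of \code{"T1"}, \code{"T2"}, \code{"T3"}, \code{"T4"}.
#' @return a data.frame.
#' @examples
#' nrow(loadFixture("T4"))
#' loadFixture("T2")$expected_label
#' @export
loadFixture <- function(table = c("T1", "T2", "T3", "T4")) {
  table <- match.arg(table)
  utils::read.delim(.fixtureFile(table), stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Expand the canonical motif table into concrete profiles
#'
#' Expands each serotype's motif row into every concrete residue profile it
#' covers: slash-separated alternatives at the 65-67 pocket and the 166-167
#' tail are enumerated, and for Bw4-bearing serotypes the epitope slot is
#' expanded either to the printed representative (N at 77 with IALR) or to
#' the full Bw4 set — N, D or S at 77 crossed with IALR, TLLR, TALR at
#' 80-83.
#'
#' @param bw4 \code{"full"} (default, 48 profiles) or \code{"printed"}
#'   (16 profiles).
#' @return data.frame with columns \code{label} and \code{aa24 ... aa167},
#'   one row per concrete profile.
#' @examples
#' table(expandTable1()$label)
#' @export
expandTable1 <- function(bw4 = c("full", "printed")) {
  bw4 <- match.arg(bw4)
  t1 <- loadFixture("T1")
  rows <- lapply(seq_len(nrow(t1)), function(i) {
    r <- t1[i, ]
    pockets <- strsplit(r$aa65_67, "/", fixed = TRUE)[[1L]]
    tails <- strsplit(r$aa166_167, "/", fixed = TRUE)[[1L]]
    epi <- if (r$epitope == "Bw4" && bw4 == "full") {
      expand.grid(aa77 = .BW4_77, m = .BW4_8083, stringsAsFactors = FALSE)
    } else data.frame(aa77 = r$aa77, m = r$aa80_83, stringsAsFactors = FALSE)
    grid <- expand.grid(pocket = pockets, tail = tails,
                        e = seq_len(nrow(epi)), stringsAsFactors = FALSE)
    data.frame(label = r$label,
               aa24 = r$aa24,
               aa45 = substr(r$aa45_46, 1L, 1L),
               aa46 = substr(r$aa45_46, 2L, 2L),
               aa63 = r$aa63,
               aa65 = substr(grid$pocket, 1L, 1L),
               aa66 = substr(grid$pocket, 2L, 2L),
               aa67 = substr(grid$pocket, 3L, 3L),
               aa70 = r$aa70,
               aa77 = epi$aa77[grid$e],
               aa80 = substr(epi$m[grid$e], 1L, 1L),
               aa81 = substr(epi$m[grid$e], 2L, 2L),
               aa82 = substr(epi$m[grid$e], 3L, 3L),
               aa83 = substr(epi$m[grid$e], 4L, 4L),
               aa166 = substr(grid$tail, 1L, 1L),
               aa167 = substr(grid$tail, 2L, 2L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## residues never observed at a diagnostic position in any motif table;
## V is the scaffold background so accidental motif creation is impossible
.SCAFFOLD_BG <- "V"
.SCAFFOLD_LEN <- 338L

#' Build a synthetic protein scaffold carrying a motif profile
#'
#' Deterministically constructs a 338-residue mature-length sequence that
#' begins with the \code{GSHS} anchor, carries the given residues at the
#' fifteen diagnostic positions, and an inert background residue
#' (valine — never part of any diagnostic motif) everywhere else. With
#' \code{withLeader} a fixed 24-residue synthetic leader is prepended, so
#' precursor-style numbering can be exercised. The same profile always
#' yields the identical string.
#'
#' @param profile a single-row \code{\linkS4class{MotifProfile}}, a named
#'   character vector of the fifteen residues, or a one-row data.frame with
#'   \code{aa24 ... aa167} columns.
#' @param withLeader prepend the synthetic 24-residue leader.
#' @return a protein sequence string.
#' @examples
#' s <- makeScaffold(expandTable1()[1, ])
#' substr(s, 1, 4)
#' @export
makeScaffold <- function(profile, withLeader = FALSE) {
  if (!is(profile, "MotifProfile")) profile <- MotifProfile(profile)
  stopifnot(length(profile) == 1L)
  chars <- rep(.SCAFFOLD_BG, .SCAFFOLD_LEN)
  chars[1:4] <- strsplit(.MATURE_ANCHOR, "")[[1L]]
  chars[diagnosticPositions()] <- profile@profile[1L, ]
  seq <- paste(chars, collapse = "")
  if (withLeader)
    seq <- paste0("M", strrep(.SCAFFOLD_BG, .SIGNAL_LENGTH - 1L), seq)
  seq
}

#' Generate a labelled synthetic allele set
#'
#' Emits, for each of the nine serotypes, \code{nPerLabel} scaffold
#' sequences built from that serotype's canonical motif row (choosing
#' uniformly among its expanded alternatives) with \code{noisePositions}
#' random substitutions at non-diagnostic, non-anchor positions. Noise
#' never touches a diagnostic position, so every sequence still classifies
#' to its generating label. Reproducible for a given seed.
#'
#' @param nPerLabel sequences per serotype (>= 1).
#' @param noisePositions number of random background substitutions per
#'   sequence.
#' @param seed integer seed.
#' @return data.frame with columns \code{label}, \code{id},
#'   \code{sequence}.
#' @examples
#' set <- generateLabeledSet(2, 3, seed = 42)
#' table(set$label)
#' @export
generateLabeledSet <- function(nPerLabel = 1L, noisePositions = 0L,
                               seed = 1L) {
  stopifnot(nPerLabel >= 1L, noisePositions >= 0L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expanded <- expandTable1("full")
  cols <- .profileCols()
  freePos <- setdiff(5:.SCAFFOLD_LEN, diagnosticPositions())
  out <- list()
  for (lab in seroLabels()) {
    variants <- expanded[expanded$label == lab, , drop = FALSE]
    for (k in seq_len(nPerLabel)) {
      row <- variants[sample.int(nrow(variants), 1L), cols, drop = FALSE]
      seq <- makeScaffold(row)
      if (noisePositions > 0L) {
        at <- sample(freePos, min(noisePositions, length(freePos)))
        chars <- strsplit(seq, "")[[1L]]
        chars[at] <- sample(.AA20, length(at), replace = TRUE)
        seq <- paste(chars, collapse = "")
      }
      out[[length(out) + 1L]] <- data.frame(
        label = lab, id = sprintf("%s_%02d", lab, k), sequence = seq,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
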