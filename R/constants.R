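## Diagnostic coordinate set and residue vocabularies shared across modules.
## All positions are mature-protein, 1-based (numbering restarts after the
## 24-residue signal peptide of the class I heavy chain).

#' Diagnostic amino acid positions of the B15 motif profile
#'
#' The fifteen mature-protein positions whose residues determine the
#' serological split of an HLA-B*15 molecule: the subtype motifs at 24,
#' 45-46, 63, 65-67, 70 and 166-167, plus the Bw4/Bw6 epitope positions
#' 77 and 80-83. Positions 24-83 lie in the exon-2-encoded alpha-1 domain,
#' 166-167 in the exon-3-encoded alpha-2 domain.
#'
#' @return Integer vector of length 15, increasing.
#' @examples
#' diagnosticPositions()
#' @export
diagnosticPositions <- function() {
  c(24L, 45L, 46L, 63L, 65L, 66L, 67L, 70L, 77L, 80L, 81L, 82L, 83L,
    166L, 167L)
}

#' Assignable serological labels
#'
#' The nine serological equivalents the classifier can assign: the classical
#' B15 splits B62, B63, B75, B76 and B77, the B70-associated splits B71 and
#' B72, and the two epitope-composite types B62-Bw4 and B71-Bw4. Profiles
#' matching no rule receive \code{"UNASSIGNED"}, which is not a member of
#' this set.
#'
#' @return Character vector of length 9.
#' @examples
#' seroLabels()
#' @export
seroLabels <- function() {
  c("B62", "B62-Bw4", "B63", "B71", "B71-Bw4", "B72", "B75", "B76", "B77")
}

.UNASSIGNED <- "UNASSIGNED"

## profile matrix column names, in position order
.profileCols <- function() paste0("aa", diagnosticPositions())

## the 20 proteinogenic residues; "X" marks gap/unknown at a diagnostic slot
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Bw4: N/D/S at 77 together with IALR, TLLR or TALR at 80-83.
## Bw6: S at 77 together with NLRG at 80-83. Anything else is indeterminate.
.BW4_77 <- c("N", "D", "S")
.BW4_8083 <- c("IALR", "TLLR", "TALR")
.BW6_77 <- "S"
.BW6_8083 <- "NLRG"

## rationale vocabulary (fixed so reports are machine-checkable)
.RATIONALES <- c("assigned", "b63-atypical-context", "incomplete-profile",
                 "epitope-indeterminate", "group-key-mismatch",
                 "pocket-motif-mismatch", "no-rule", "truncated")

## labels whose definition carries the Bw4 epitope / the Bw6 epitope
.BW4_LABELS <- c("B62-Bw4", "B63", "B71-Bw4", "B77")
.BW6_LABELS <- c("B62", "B71", "B72", "B75", "B76")

## mature HLA-B proteins start G-S-H-S; used to anchor precursor input
.MATURE_ANCHOR <- "GSHS"
.SIGNAL_LENGTH <- 24L

## expression suffixes of the WHO nomenclature; N (null) and Q (questionable)
## mark alleles excluded from antigen counting
.SUFFIXES <- c("N", "Q", "L", "S", "C", "A")
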