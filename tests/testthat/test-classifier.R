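# helper: build a one-row MotifProfile from the compact slot notation
profileFrom <- function(aa24, aa4546, aa63, pocket, aa70, aa77, m8083,
                        tail) {
  MotifProfile(setNames(c(aa24, substring(aa4546, 1:2, 1:2), aa63,
                          substring(pocket, 1:3, 1:3), aa70, aa77,
                          substring(m8083, 1:4, 1:4),
                          substring(tail, 1:2, 1:2)),
                        paste0("aa", diagnosticPositions())))
}

test_that("Bw4/Bw6 epitope calling follows the 77 + 80-83 rules", {
  expect_identical(
    callBwEpitope(profileFrom("A", "MA", "E", "QIS", "N", "D", "TLLR", "EW")),
    "Bw4")
  expect_identical(
    callBwEpitope(profileFrom("A", "MA", "E", "QIS", "N", "S", "NLRG", "EW")),
    "Bw6")
  # the KLRG motif matches neither epitope
  expect_identical(
    callBwEpitope(profileFrom("A", "MA", "E", "QIS", "N", "S", "KLRG", "EW")),
    "indeterminate")
  # N at 77 with the Bw6 motif is likewise unresolvable
  expect_identical(
    callBwEpitope(profileFrom("A", "MA", "E", "QIS", "N", "N", "NLRG", "EW")),
    "indeterminate")
})

test_that("classifyProfile reproduces the documented single-profile calls", {
  cases <- list(
    list(c("A", "MA", "N", "QIF", "N", "S", "NLRG", "EW"), "B75"),
    list(c("S", "EE", "N", "QIC", "N", "S", "TALR", "EW"), "B71-Bw4"),
    list(c("A", "MA", "E", "QIS", "N", "N", "TALR", "EW"), "B62-Bw4"),
    list(c("S", "EE", "E", "QIS", "N", "S", "NLRG", "ES"), "UNASSIGNED"),
    list(c("A", "MA", "N", "QIY", "Q", "S", "NLRG", "EW"), "UNASSIGNED"),
    list(c("T", "MA", "E", "QIS", "N", "S", "NLRG", "EW"), "UNASSIGNED"),
    list(c("A", "MA", "E", "QIS", "N", "S", "NLRG", "DG"), "B76"))
  for (cs in cases) {
    a <- classifyProfile(do.call(profileFrom, as.list(cs[[1L]])))
    expect_identical(seroLabel(a), cs[[2L]])
  }
  # reason codes for the three UNASSIGNED cases above
  expect_identical(
    rationale(classifyProfile(
      do.call(profileFrom, list("S", "EE", "E", "QIS", "N", "S", "NLRG",
                                "ES")))), "no-rule")
  expect_identical(
    rationale(classifyProfile(
      do.call(profileFrom, list("A", "MA", "N", "QIY", "Q", "S", "NLRG",
                                "EW")))), "pocket-motif-mismatch")
  expect_identical(
    offendingPositions(classifyProfile(
      do.call(profileFrom, list("T", "MA", "E", "QIS", "N", "S", "NLRG",
                                "EW"))))[[1L]], c(24L, 45L, 46L))
})

test_that("unknown residues and indeterminate epitopes block assignment first", {
  p <- profileFrom("A", "MA", "X", "QIS", "N", "S", "NLRG", "EW")
  a <- classifyProfile(p)
  expect_identical(seroLabel(a), "UNASSIGNED")
  expect_identical(rationale(a), "incomplete-profile")
  expect_identical(offendingPositions(a)[[1L]], 63L)

  a2 <- classifyProfile(profileFrom("A", "MA", "E", "QIS", "N", "S",
                                    "KLRG", "EW"))
  expect_identical(rationale(a2), "epitope-indeterminate")
  expect_identical(offendingPositions(a2)[[1L]], c(77L, 80L, 81L, 82L, 83L))
})

test_that("B63 is assigned on the RNM pocket alone, flagged when atypical", {
  clean <- classifyProfile(profileFrom("A", "MA", "E", "RNM", "S", "N",
                                       "IALR", "EW"))
  expect_identical(seroLabel(clean), "B63")
  expect_identical(rationale(clean), "assigned")
  # Bw6 epitope or N at 70: label stands, rationale flags the context
  odd <- classifyProfile(profileFrom("A", "MA", "E", "RNM", "N", "S",
                                     "NLRG", "EW"))
  expect_identical(seroLabel(odd), "B63")
  expect_identical(rationale(odd), "b63-atypical-context")
})

test_that("no Bw4 counterpart exists for B72 or B76", {
  b72bw4 <- classifyProfile(profileFrom("S", "EE", "E", "QIS", "N", "N",
                                        "IALR", "EW"))
  expect_identical(seroLabel(b72bw4), "UNASSIGNED")
  b76bw4 <- classifyProfile(profileFrom("A", "MA", "E", "QIS", "N", "N",
                                        "IALR", "ES"))
  expect_identical(seroLabel(b76bw4), "UNASSIGNED")
  # QIY is not accepted in the B70 family
  expect_identical(seroLabel(classifyProfile(
    profileFrom("S", "EE", "N", "QIY", "N", "S", "NLRG", "EW"))),
    "UNASSIGNED")
})

test_that("every expansion of every canonical motif row self-classifies", {
  t1 <- expandTable1("full")
  a <- classifyProfile(MotifProfile(t1, ids = t1$label))
  expect_identical(seroLabel(a), t1$label)
  expect_true(all(rationale(a) == "assigned"))
  # and the epitope matches the label family
  expect_identical(epitopeCall(a) == "Bw4",
                   t1$label %in% c("B62-Bw4", "B63", "B71-Bw4", "B77"))
})

test_that("single foreign substitutions never preserve the label, except the
           documented B63/B76 relaxations", {
  t1 <- expandTable1("full")
  cols <- paste0("aa", diagnosticPositions())
  relaxed <- function(label, pos) {
    (label == "B76" && pos %in% c(166L, 167L)) ||
      (label == "B63" && pos %in% c(63L, 70L, 166L, 167L))
  }
  for (i in seq_len(nrow(t1))) {
    for (j in seq_along(cols)) {
      pos <- diagnosticPositions()[j]
      if (relaxed(t1$label[i], pos)) next
      mut <- t1[i, ]
      mut[[cols[j]]] <- "P"  # P occurs at no diagnostic position
      got <- seroLabel(classifyProfile(MotifProfile(mut)))
      expect_false(identical(got, t1$label[i]),
                   info = sprintf("%s position %d", t1$label[i], pos))
    }
  }
})

test_that("assignments always satisfy the label/epitope contract", {
  set.seed(7)
  m <- randomProfileRows(500L)
  a <- classifyProfile(MotifProfile(m))
  expect_true(validObject(a))
  clean <- rationale(a) == "assigned"
  bw4labels <- c("B62-Bw4", "B63", "B71-Bw4", "B77")
  expect_true(all(epitopeCall(a)[clean & seroLabel(a) %in% bw4labels] ==
                    "Bw4"))
  expect_true(all(epitopeCall(a)[clean &
                                   seroLabel(a) %in%
                                   c("B62", "B71", "B72", "B75", "B76")] ==
                    "Bw6"))
  expect_true(all(lengths(offendingPositions(a)[seroLabel(a) !=
                                                  "UNASSIGNED"]) == 0L))
})

test_that("sequence classification composes extraction and rules", {
  t1 <- expandTable1("printed")
  b63 <- t1[t1$label == "B63", ]
  res <- classifySequence(c(b63ish = makeScaffold(b63)))
  expect_identical(seroLabel(res$assignment), "B63")

  # a mutation away from the diagnostic positions changes nothing
  s <- makeScaffold(t1[t1$label == "B62" & t1$aa67 == "S", ])
  substr(s, 100, 100) <- "W"
  expect_identical(seroLabel(classifySequence(s)$assignment), "B62")

  # a gap at position 63 makes the profile incomplete
  g <- makeScaffold(t1[t1$label == "B72", ])
  substr(g, 63, 63) <- "-"
  a <- classifySequence(g)$assignment
  expect_identical(seroLabel(a), "UNASSIGNED")
  expect_identical(rationale(a), "incomplete-profile")

  # truncated records survive as UNASSIGNED/truncated in batch mode
  short <- substr(makeScaffold(t1[1L, ]), 1L, 150L)
  batch <- classifySequence(c(ok = makeScaffold(t1[1L, ]), bad = short))
  expect_identical(rationale(batch$assignment), c("assigned", "truncated"))
  expect_identical(seroLabel(batch$assignment)[2L], "UNASSIGNED")
})

test_that("summaries tally labels and ignore record order", {
  fx4 <- loadFixture("T4")
  a4 <- classifyProfile(MotifProfile(fx4, ids = fx4$allele))
  expect_identical(summarizeAssignments(a4),
                   c(UNASSIGNED = 22L))
  fx2 <- loadFixture("T2")
  a2 <- classifyProfile(MotifProfile(fx2, ids = fx2$allele))
  expect_identical(summarizeAssignments(a2),
                   c("B62-Bw4" = 2L, "B71-Bw4" = 2L, "B75" = 2L))
  expect_length(summarizeAssignments(character(0L)), 0L)
})
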