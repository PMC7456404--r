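test_that("identical sequences yield no variable patterns", {
  pats <- enumerateVariablePatterns(c("B62", "B75"),
                                    rep(strrep("A", 20L), 2L))
  expect_length(pats, 0L)
})

test_that("a single variable position yields a single-position pattern", {
  base <- strrep("A", 100L)
  varied <- paste0(substr(base, 1, 62), "N", substr(base, 64, 100))
  pats <- enumerateVariablePatterns(c("B62", "B75"), c(base, varied))
  expect_length(pats, 1L)
  expect_identical(patternPositions(pats[[1L]]), 63L)
  expect_identical(residuesByLabel(pats[[1L]]),
                   list(B62 = "A", B75 = "N"))
})

test_that("sequences of unequal length are rejected", {
  expect_error(enumerateVariablePatterns(c("a", "b"),
                                         c(strrep("A", 10L),
                                           strrep("A", 11L))),
               "same length")
})

test_that("canonical scaffolds vary at exactly the diagnostic positions,
           grouped contiguously", {
  set <- generateLabeledSet(1L, 0L, seed = 5)
  pats <- enumerateVariablePatterns(set$label, set$sequence)
  got <- lapply(pats, patternPositions)
  expect_true(all(sort(unlist(got)) %in% diagnosticPositions()))
  keys <- vapply(got, paste, character(1L), collapse = "-")
  expect_true(all(c("45-46", "65-66-67", "166-167") %in% keys))
  expect_true("24" %in% keys)
  # ungrouped mode returns one pattern per position
  single <- enumerateVariablePatterns(set$label, set$sequence,
                                      groupContiguous = FALSE)
  expect_true(all(lengths(lapply(single, patternPositions)) == 1L))
})

test_that("filtering keeps subtype-unique patterns and partitions the input", {
  set <- generateLabeledSet(2L, 0L, seed = 5)
  pats <- enumerateVariablePatterns(set$label, set$sequence)
  res <- filterUniquePatterns(pats)
  expect_identical(length(res$kept) + length(res$excluded), length(pats))
  # disjoint cover: every input pattern lands in exactly one part
  allPos <- lapply(c(res$kept, res$excluded), patternPositions)
  expect_identical(sort(unlist(allPos)),
                   sort(unlist(lapply(pats, patternPositions))))

  # the RNM pocket (65-67) and S at 70 are private to B63
  keptKeys <- vapply(res$kept, function(p)
    paste(patternPositions(p), collapse = "-"), character(1L))
  expect_true("65-66-67" %in% keptKeys)
  expect_identical(uniqueFor(res$kept[[match("65-66-67", keptKeys)]]),
                   "B63")
  expect_true("70" %in% keptKeys)
  # the 166-167 tail is private to B76
  expect_identical(uniqueFor(res$kept[[match("166-167", keptKeys)]]),
                   "B76")
  # the group key positions alone separate no single subtype
  exclKeys <- vapply(res$excluded, function(p)
    paste(patternPositions(p), collapse = "-"), character(1L))
  expect_true(all(c("24", "45-46") %in% exclKeys))
})

test_that("kept patterns are sound under an independent uniqueness scan", {
  set <- generateLabeledSet(2L, 0L, seed = 17)
  pats <- enumerateVariablePatterns(set$label, set$sequence)
  res <- filterUniquePatterns(pats)
  for (p in res$kept) {
    lab <- uniqueFor(p)
    # brute force: collect the combination of residues at the pattern's
    # positions directly from the sequences
    combos <- vapply(set$sequence, function(s)
      paste(substring(s, patternPositions(p), patternPositions(p)),
            collapse = ""), character(1L), USE.NAMES = FALSE)
    inLab <- unique(combos[set$label == lab])
    expect_true(length(setdiff(inLab, combos[set$label != lab])) > 0L)
  }
})

test_that("single-label input keeps every pattern vacuously", {
  seqs <- c(strrep("A", 30L),
            paste0(strrep("A", 15L), "S", strrep("A", 14L)))
  pats <- enumerateVariablePatterns(c("B62", "B62"), seqs)
  res <- filterUniquePatterns(pats)
  expect_length(res$excluded, 0L)
  expect_identical(uniqueFor(res$kept[[1L]]), "B62")
})

test_that("pairwise conjunctions recover context-dependent motifs", {
  set <- generateLabeledSet(2L, 0L, seed = 5)
  pats <- enumerateVariablePatterns(set$label, set$sequence)
  res <- filterUniquePatterns(pats, pairwise = TRUE)
  expect_identical(length(res$kept) + length(res$excluded), length(pats))
  # position 63 alone separates nothing, but with the 45-46 group key the
  # EE+E combination is private to B72
  keys <- vapply(pats, function(p) paste(patternPositions(p),
                                         collapse = "-"), character(1L))
  i63 <- match("63", keys)
  expect_length(uniqueFor(pats[[i63]]), 0L)
  hits <- res$combinations[res$combinations$pattern == i63, ]
  expect_true("B72" %in% hits$unique_for)
  i4546 <- match("45-46", keys)
  conj <- conjoinPatterns(pats[[i4546]], pats[[i63]])
  expect_identical(uniqueFor(conj), "B72")
})

test_that("kept patterns rebuild a decision table that reclassifies the
           generating set perfectly", {
  set <- generateLabeledSet(3L, 0L, seed = 23)
  pats <- enumerateVariablePatterns(set$label, set$sequence)
  res <- filterUniquePatterns(pats, pairwise = TRUE)
  tab <- buildPatternTable(res$kept)
  expect_identical(applyPatternTable(tab, res$kept), set$label)
})

test_that("pattern tables refuse non-separating pattern sets", {
  set <- generateLabeledSet(1L, 0L, seed = 2)
  pats <- enumerateVariablePatterns(set$label, set$sequence)
  keys <- vapply(pats, function(p) paste(patternPositions(p),
                                         collapse = "-"), character(1L))
  # the group key alone cannot separate nine subtypes
  expect_error(buildPatternTable(pats[match("24", keys)]), "ambiguous")
})

test_that("pattern tables serialise deterministically", {
  set <- generateLabeledSet(1L, 0L, seed = 9)
  pats <- enumerateVariablePatterns(set$label, set$sequence)
  res <- filterUniquePatterns(pats)
  txt <- writePatternTable(res)
  expect_identical(writePatternTable(res), txt)
  lines <- strsplit(txt, "\n")[[1L]]
  expect_identical(lines[1L], "positions\tstatus\tunique_for\tresidues_by_label")
  expect_length(lines, length(pats) + 1L)
})
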