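# Independent brute-force oracle for the serotype rules: expands the
# canonical motif definitions (with the stated generalisations — full Bw4
# residue set, B63 on the RNM pocket alone, B76 as the missing EW tail)
# into an explicit profile->label lookup table and classifies by set
# membership. Deliberately shares no code with the package's decision tree.

# per-slot residue alphabets observed across the printed motif tables
oracleAlphabets <- function() {
  list(aa24 = c("A", "S", "T"),
       aa45_46 = c("MA", "KE", "EE", "TA", "TE", "GE"),
       aa63 = c("E", "N", "G"),
       pocket = c("QIS", "QIF", "QIC", "QIY", "RNM"),
       aa70 = c("N", "S", "Q"),
       aa77 = c("S", "N", "D"),
       m8083 = c("NLRG", "IALR", "TLLR", "TALR", "KLRG"),
       tail = c("EW", "DG", "ES"))
}

# every profile in the enumerated space, as a character matrix with the
# package's aa24..aa167 columns
oracleEnumerate <- function() {
  al <- oracleAlphabets()
  g <- expand.grid(aa24 = al$aa24, aa45_46 = al$aa45_46, aa63 = al$aa63,
                   pocket = al$pocket, aa70 = al$aa70, aa77 = al$aa77,
                   m8083 = al$m8083, tail = al$tail,
                   stringsAsFactors = FALSE)
  cbind(aa24 = g$aa24,
        aa45 = substr(g$aa45_46, 1, 1), aa46 = substr(g$aa45_46, 2, 2),
        aa63 = g$aa63,
        aa65 = substr(g$pocket, 1, 1), aa66 = substr(g$pocket, 2, 2),
        aa67 = substr(g$pocket, 3, 3),
        aa70 = g$aa70, aa77 = g$aa77,
        aa80 = substr(g$m8083, 1, 1), aa81 = substr(g$m8083, 2, 2),
        aa82 = substr(g$m8083, 3, 3), aa83 = substr(g$m8083, 4, 4),
        aa166 = substr(g$tail, 1, 1), aa167 = substr(g$tail, 2, 2))
}

.oracleKey <- function(m) {
  apply(m, 1L, paste, collapse = "")
}

# named character vector: profile key -> serotype label
buildOracleTable <- function() {
  bw6 <- data.frame(aa77 = "S", m = "NLRG", stringsAsFactors = FALSE)
  bw4 <- expand.grid(aa77 = c("N", "D", "S"),
                     m = c("IALR", "TLLR", "TALR"),
                     stringsAsFactors = FALSE)
  pockets62 <- c("QIS", "QIF", "QIC", "QIY")
  pockets70 <- c("QIS", "QIF", "QIC")
  rows <- list()
  add <- function(aa24, aa45_46, aa63s, pockets, aa70s, epis, tails, label) {
    g <- expand.grid(aa63 = aa63s, pocket = pockets, aa70 = aa70s,
                     e = seq_len(nrow(epis)), tail = tails,
                     stringsAsFactors = FALSE)
    key <- paste0(aa24, aa45_46, g$aa63, g$pocket, g$aa70,
                  epis$aa77[g$e], epis$m[g$e], g$tail)
    rows[[length(rows) + 1L]] <<- stats::setNames(rep(label, length(key)),
                                                  key)
  }
  add("A", "MA", "E", pockets62, "N", bw6, "EW", "B62")
  add("A", "MA", "E", pockets62, "N", bw4, "EW", "B62-Bw4")
  # B63: the RNM pocket alone suffices; 63, 70 and the tail are free as
  # long as the epitope itself is resolvable
  add("A", "MA", c("E", "N", "G"), "RNM", c("N", "S", "Q"),
      rbind(bw6, bw4), c("EW", "DG", "ES"), "B63")
  add("A", "MA", "N", pockets62, "N", bw6, "EW", "B75")
  add("A", "MA", "N", pockets62, "N", bw4, "EW", "B77")
  # B76: B62 pattern missing the EW tail, Bw6 only
  add("A", "MA", "E", pockets62, "N", bw6, c("DG", "ES"), "B76")
  add("S", "EE", "N", pockets70, "N", bw6, "EW", "B71")
  add("S", "EE", "N", pockets70, "N", bw4, "EW", "B71-Bw4")
  add("S", "EE", "E", pockets70, "N", bw6, "EW", "B72")
  tab <- unlist(rows)
  stopifnot(anyDuplicated(names(tab)) == 0L)
  tab
}

oracleClassify <- function(m, table = buildOracleTable()) {
  out <- unname(table[.oracleKey(m)])
  out[is.na(out)] <- "UNASSIGNED"
  out
}

# random concrete profile rows drawn from the enumeration alphabets
randomProfileRows <- function(n) {
  al <- oracleAlphabets()
  pick <- function(v) sample(v, n, replace = TRUE)
  p4546 <- pick(al$aa45_46); pocket <- pick(al$pocket)
  m8083 <- pick(al$m8083); tail <- pick(al$tail)
  cbind(aa24 = pick(al$aa24),
        aa45 = substr(p4546, 1, 1), aa46 = substr(p4546, 2, 2),
        aa63 = pick(al$aa63),
        aa65 = substr(pocket, 1, 1), aa66 = substr(pocket, 2, 2),
        aa67 = substr(pocket, 3, 3),
        aa70 = pick(al$aa70), aa77 = pick(al$aa77),
        aa80 = substr(m8083, 1, 1), aa81 = substr(m8083, 2, 2),
        aa82 = substr(m8083, 3, 3), aa83 = substr(m8083, 4, 4),
        aa166 = substr(tail, 1, 1), aa167 = substr(tail, 2, 2))
}
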