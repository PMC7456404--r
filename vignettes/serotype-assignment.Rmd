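---
title: "Assigning serological splits to HLA-B*15 alleles from amino acid motifs"
author: "SeroB15 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning serological splits to HLA-B*15 alleles from amino acid motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeroB15)
```

## Why serotype conversion

Antibody screening of transplant candidates reports anti-HLA specificities
at the serological split level (B62, B63, B71, ...), while donor and patient
HLA typing is DNA-based and allele-level (B\*15:03:01:03). For a patient with
an anti-B15-split antibody, every B\*15-positive donor is uninterpretable —
and in practice contraindicated — until the donor allele is translated into
its split. Expert dictionary assignments exist for only a minority of the
hundreds of known B\*15 alleles, and classical serological typing requires
viable cells and split-specific antisera that are frequently unavailable.
The motif model implemented here predicts the split deterministically from
the protein sequence.

## The classification model

The molecule's serological reactivity is carried by fifteen surface residues
of the mature heavy chain. All coordinates in this package are
**mature-protein, 1-based**: numbering starts after cleavage of the
24-residue signal peptide, which is how the Bw4/Bw6 literature and all motif
positions are conventionally quoted. Positions 24–83 lie in the
exon-2-encoded α1 domain, 166–167 in the exon-3-encoded α2 domain.

`classifyProfile()` applies the rules in a fixed order; every profile
receives exactly one outcome, and failures are labels too (`UNASSIGNED`
plus a reason code and offending positions), never errors:

1. **Completeness.** Any `X` (gap/unknown) among the fifteen residues →
   `UNASSIGNED` / `incomplete-profile`.
2. **Epitope.** Bw4 requires N, D or S at 77 together with IALR, TLLR or
   TALR at 80–83; Bw6 requires S at 77 with NLRG. The two rules are
   disjoint. Anything else (e.g. the KLRG motif seen in one unassignable
   allele) → `UNASSIGNED` / `epitope-indeterminate`. The epitope is checked
   *before* the subtype motifs so that epitope-broken profiles fail here
   regardless of an otherwise perfect group key.
3. **Group key.** (24, 45–46) = (A, MA) selects the B62 family,
   (S, EE) the B70 family; anything else → `group-key-mismatch`. Most
   unassignable alleles fail exactly here, with novel combinations such as
   KE, TE or GE at 45–46.
4. **B62 family.** RNM at 65–67 defines B63 outright (see below). Otherwise
   the pocket must be QIC/QIF/QIS/QIY with N at 70
   (`pocket-motif-mismatch` otherwise). Then position 63 and the 166–167
   tail resolve the split: N at 63 with the EW tail gives B75 (Bw6) or B77
   (Bw4); E at 63 with EW gives B62 (Bw6) or B62-Bw4 (Bw4); E at 63
   without EW gives B76 under Bw6 — B76 is *defined* by the missing EW
   motif, so any non-EW pair qualifies, not only the observed DG and ES.
5. **B70 family.** Pocket QIC/QIF/QIS, N at 70 and the EW tail are all
   required; position 63 then gives B71/B71-Bw4 (N) or B72 (E, Bw6 only).

Points that were genuinely open and how we resolved them:

* **B63 on RNM alone.** The RNM pocket is fully conserved in the B63 group
  and no counterexample exists in any published table, so the label is
  assigned on the pocket alone. When the usual B63 context is absent
  (epitope not Bw4, or 70 ≠ S) the label stands but the rationale code is
  `b63-atypical-context` rather than `assigned`, so downstream consumers
  can treat it as a flagged call. A consequence is that for B63 the
  positions 63, 70 and 166–167 are deliberately not load-bearing.
* **The EW tail in the N-branch.** Every canonical serotype definition
  except B76 carries EW at 166–167. We therefore require EW for B75 and
  B77 as well: N at 63 with a non-EW tail is a novel combination and is
  reported `UNASSIGNED` rather than forced into B75. (One published
  undefined allele with exactly this shape, ES at 166–167 on a B70-family
  background, is likewise unassigned.)
* **QIY in the B70 family.** QIY at 65–67 is observed only on the B62-family
  background (and there only with Q at 70, which already fails). The B70
  pocket whitelist is QIC/QIF/QIS; a hypothetical S-EE allele with QIY is
  `UNASSIGNED`.
* **No invented composite types.** A B72-pattern or B76-pattern profile with
  a Bw4 epitope matches no defined serotype and stays `UNASSIGNED`; we do
  not mint B72-Bw4 or B76-Bw4 labels.
* **Non-N/Q expression suffixes.** The nomenclature parser accepts L, S, C
  and A suffixes and treats them as expressed; only null (N) and
  questionable (Q) alleles are excluded from antigen counting.

## Coordinate handling and degenerate inputs

Input sequences may be mature or precursor. `detectMatureOffset()` anchors
on the canonical mature N-terminus `GSHS`: offset 0 when the sequence
starts with it, otherwise the first occurrence within the leading 30
residues (the HLA-B signal peptide is 24 residues; the margin absorbs
annotation slack). An explicit offset overrides detection — the escape
hatch for fragments or unusual leaders. A sequence with no anchor and no
offset raises `undeterminableOffset`; we refuse to guess.

Sequences that end before position 167 raise `truncatedSequence` from
`extractProfile()` (naming the first missing position); the batch entry
point `classifySequence()` converts that into an `UNASSIGNED` record with
rationale `truncated` so a database-scale run completes while the summary
still accounts for every input. Gap characters and non-standard symbols at
diagnostic positions become `X` and classify as `incomplete-profile` for
the same reason. Such records are visible in reports, not silently dropped.

## The synthetic generator

`makeScaffold()` builds a deterministic 338-residue mature-length sequence:
`GSHS` at 1–4, the requested residues at the fifteen diagnostic positions,
and valine — a residue that occurs at no diagnostic position in any motif
table — everywhere else, so noise or background can never create a spurious
motif. `generateLabeledSet()` emits per-serotype scaffolds drawn from the
expanded canonical motif rows, with optional random substitutions restricted
to non-diagnostic, non-anchor positions.

What this emulates is the *combinatorics* of the motif space: which residue
combinations co-occur with which labels. What it does not emulate is real
HLA-B sequence context — linkage between diagnostic and non-diagnostic
polymorphism, alignment artefacts, or the allele-frequency structure of a
real database. Tests passing on scaffolds therefore validate the rule logic
and the coordinate arithmetic, not robustness to misaligned or non-colinear
input (inputs are assumed colinear with the HLA-B protein, which holds for
IPD-IMGT/HLA protein records; no alignment is computed).

## Motif discovery

`enumerateVariablePatterns()` scans a labelled, colinear set for positions
where at least two alleles differ (monomorphic columns carry no signal) and
merges contiguous variable positions into one pattern — the groupings
45–46, 65–67, 80–83 and 166–167 arise naturally this way. A pattern is
**unique for** a label when some residue combination at its positions occurs
in that label's alleles and in no other label's; `filterUniquePatterns()`
keeps exactly those patterns and excludes the rest, a partition of the
input. This is the formalisation we chose for "unique for a certain
subtype"; the criterion is deliberately existential (one private
combination suffices) rather than requiring within-subtype conservation,
which matches how the B76 tail behaves (two different private motifs, DG
and ES, within one subtype).

Many real motifs are only discriminative *in context* — E at 63 means B72
on the S-EE background but B62 on A-MA. With `pairwise = TRUE` the filter
also keeps patterns whose conjunction with one other pattern is unique
(pairwise only: no published motif needs more than two cooperating
position groups besides the epitope). On canonical data the alone-unique
patterns are just 65–67 and 70 (both private to B63) and 166–167 (private
to B76); the pairwise mode recovers the rest, and `buildPatternTable()`
then rebuilds a decision table that reclassifies the generating set
exactly. The Bw4/Bw6 epitope is treated as a built-in feature of the
classifier, not a discovered pattern, so the epitope positions may appear
in either partition without affecting the serotype rules.

On noisy sets, note that a private substitution in a single allele makes
its position vacuously "unique" for that allele's label — with few alleles
per subtype the procedure overfits exactly the way any discriminative
motif search does. The published motif table was derived from over a
hundred expert-labelled alleles; rediscovery experiments here use the
clean generator where the intended structure is known.

## Problem sizes and numerical choices

Everything the package computes is exact, discrete string logic — there
are no tolerances, optimisations or tie-breaks. The test suite checks the
classifier against an independently written brute-force rule-table oracle
over the full cross-product of residue values observed in the published
tables (36,450 profiles, a few seconds), property-style round-trips over
randomly generated profiles and names (a few hundred cases each under
fixed seeds), and synthetic panels of up to a few hundred sequences; the
whole suite runs in well under a minute on one CPU. Determinism is part of
the contract: identical inputs produce byte-identical TSV/JSON reports,
and the generator is reproducible per seed.

## Limitations

* The rules are B15/B70-specific. Nothing restricts the *input* to B\*15
  alleles, but profiles from other allele groups will simply be
  `UNASSIGNED` (or, worse, coincidentally match — the classifier does not
  verify the allele group from the sequence).
* Serological reactivity of genuinely novel motif combinations is unknown;
  the classifier reports them `UNASSIGNED` by design rather than
  extrapolating.
* Nucleotide input, intron analysis and alignment are out of scope; inputs
  must be protein sequences colinear with HLA-B or pre-extracted motif
  profiles.
* Database-scale validation against a full IPD-IMGT/HLA release requires
  that external dataset; the package ships only the published desk-scale
  tables and the synthetic generator.
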