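# SeroB15

Rule-based conversion of DNA-defined **HLA-B\*15** typing results into their
**serological split equivalents**.

HLA-B15 is the largest broad antigen group of the HLA-B locus, subdivided by
antibody reactivity into the splits B62, B63, B75, B76 and B77 and associated
with B70 (splits B71, B72). Clinical laboratories type HLA at high resolution
by sequencing, but antibody screening of transplant candidates reports
specificities at the serological split level: to decide whether an anti-B15
antibody is donor-specific, the donor's B\*15 allele must be translated into
its split. Serological typing by complement-dependent cytotoxicity is often
impossible (no viable cells, no split-specific sera), and expert dictionary
assignments cover only a fraction of known alleles. SeroB15 performs that
translation directly from the protein sequence.

## The model

The serological split of a B15 molecule is determined by the residues at
fifteen diagnostic positions of the mature heavy chain (mature 1-based
numbering, i.e. after cleavage of the 24-residue signal peptide):

* subtype motifs at **24**, **45–46**, **63**, **65–67**, **70**, **166–167**
  (α1 and α2 domains), and
* the **Bw4/Bw6** public-epitope positions **77** and **80–83**
  (Bw4 = N/D/S at 77 with IALR, TLLR or TALR at 80–83;
  Bw6 = S at 77 with NLRG).

The decision rules, with B62 as the reference pattern:

| serotype | 24 | 45–46 | 63 | 65–67 | 70 | 77, 80–83 | 166–167 |
|----------|----|-------|----|-------|----|-----------|---------|
| B62      | A  | MA    | E  | QIS/QIF/QIC | N | Bw6 | EW |
| B62-Bw4  | A  | MA    | E  | QIS   | N  | Bw4 | EW |
| B63      | A  | MA    | —  | **RNM** | (S) | Bw4 | — |
| B71      | S  | EE    | N  | QIC/QIF/QIS | N | Bw6 | EW |
| B71-Bw4  | S  | EE    | N  | QIC   | N  | Bw4 | EW |
| B72      | S  | EE    | E  | QIS   | N  | Bw6 | EW |
| B75      | A  | MA    | N  | QIS/QIY/QIC | N | Bw6 | EW |
| B76      | A  | MA    | E  | QIS   | N  | Bw6 | **not EW** |
| B77      | A  | MA    | N  | QIS   | N  | Bw4 | EW |

The A-MA vs S-EE key at 24/45–46 separates the B62 and B70 families, N vs E
at 63 separates B75/B77 from B62 and B71 from B72, the RNM pocket at 65–67
alone defines B63, and a missing EW tail at 166–167 defines B76. Profiles
carrying any other residue combination — and there are many among recently
sequenced alleles — are reported as `UNASSIGNED` with a machine-readable
reason code and the offending positions, never silently forced into a split.

The package also implements the discovery procedure behind that table:
given serologically labelled sequences, it enumerates the variable position
patterns, keeps those whose residue combination is private to a single
subtype (optionally in pairwise combination), and can rebuild a decision
table from the kept patterns.

## Worked example

Classify a FASTA of B\*15 protein sequences (here a generated panel, one
allele per subtype), collapsing to two-field antigens:

```r
library(SeroB15)
set <- generateLabeledSet(1, 3, seed = 42)
fa <- tempfile(fileext = ".fasta")
writeLines(as.vector(rbind(paste0(">B*15:", 900 + seq_len(nrow(set)), ":01"),
                           set$sequence)), fa)
report <- classifyFasta(fa, twoField = TRUE)
report
#> ClassificationReport with 9 record(s)
#> summary:
#>     B62 B62-Bw4     B63     B71 B71-Bw4     B72     B75     B76     B77
#>       1       1       1       1       1       1       1       1       1
cat(writeReport(report))
#> id  aa24  aa45  aa46  aa63  aa65  aa66  aa67  aa70  aa77  aa80  aa81  aa82  aa83  aa166  aa167  epitope  serotype  rationale
#> B*15:901  A  M  A  E  Q  I  S  N  S  N  L  R  G  E  W  Bw6  B62      assigned
#> B*15:902  A  M  A  E  Q  I  S  N  D  T  A  L  R  E  W  Bw4  B62-Bw4  assigned
#> B*15:903  A  M  A  E  R  N  M  S  S  I  A  L  R  E  W  Bw4  B63      assigned
#> ...
```

Each row shows the fifteen diagnostic residues the call was made from, the
epitope, the split, and why (`assigned`, or a reason such as
`group-key-mismatch` when the 24/45–46 key matches neither family). The
packaged fixture tables (`loadFixture("T1")` … `"T4"`) hold the canonical
motif rows and the published discrepant / undefined / unassignable allele
profiles.

A command-line front-end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","b15sero.R",package="SeroB15"))') \
  classify --input alleles.fasta --out report.tsv
```

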