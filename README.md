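# chardiag — character-based molecular diagnoses for DNA taxonomy

Formally describing a cryptic species requires a diagnosis: a testable
statement of characters that separate it from its congeners. When
morphology fails — as it does for many meiofaunal invertebrates — the
diagnosis can be built from DNA sequence data itself. `chardiag` is for
taxonomists and molecular systematists who have per-marker multiple
sequence alignments and a specimen-to-species partition and want, for
every species, the **single pure character attributes** that support a
formal molecular diagnosis.

A state *s* at alignment column *c* is a single pure character of species
*X* when it occurs in **all** scored specimens of *X* and in **none** of
the specimens of any other ingroup species. With one focal state the
character is *homogeneous pure* (admissible in a diagnosis); with two or
three focal states, all absent elsewhere, it is *heterogeneous pure*
(reported as supplementary information with carrier specimens); states
absent elsewhere in only part of the focal sample are *private*
(computed, never emitted). Internal gaps are first-class DELETION
states; terminal gap runs, IUPAC ambiguity codes, `N` and absent markers
are MISSING and contribute nothing. Each species is compared against all
congeners pooled — no guide tree, no polarity assignment — and characters
are reported in dual coordinates, `alignment (reference-sequence)`, so
they stay traceable when alignments change.

Around that core the package provides:

* **Coordinates** — gapped-to-ungapped mapping onto per-species reference
  (holotype) sequences, offset inference against deposited sequences,
  and the `145 (146), C` / `235, deletion` table notation.
* **Translation diagnostics** — reading-frame inference, codon-wise
  translation under the invertebrate mitochondrial code with explicit
  DELETION/MISSING codons, and the same classification on amino acids.
* **Masking** — a Gblocks-style conserved-block selector with an index
  map back to unmasked columns.
* **Robustness** — reference-keyed comparison of diagnoses across
  alternative alignments/maskings, with a strict-intersection consensus.
* **Simulation** — multi-marker alignments with planted species-fixed
  differences and a ground-truth ledger, so the whole pipeline is
  validated by exact recovery.

## Worked example

Simulate a noiseless 12-species, 4-marker dataset, diagnose the 16S
marker and render one species' diagnosis:

```r
library(chardiag)

sim <- simulate_dataset(noiseless_config(sim_config(seed = 7)))
aln <- sim$alignments$`16S`
pm  <- partition_for_marker(sim$partition, aln)
d   <- add_ref_positions(diagnose_all(aln, pm), reference_frames(aln, pm))
head(d[, c("marker", "taxon", "column", "category", "states",
           "ref_position")], 8)
#>   marker taxon column         category states ref_position
#> 1    16S  sp01    100 HOMOGENEOUS_PURE      C           91
#> 2    16S  sp01    108 HOMOGENEOUS_PURE      -           NA
#> 3    16S  sp01    109 HOMOGENEOUS_PURE      -           NA
#> 4    16S  sp01    110 HOMOGENEOUS_PURE      -           NA
#> 5    16S  sp01    144 HOMOGENEOUS_PURE      C          129
#> 6    16S  sp01    166 HOMOGENEOUS_PURE      C          151
#> 7    16S  sp01    309 HOMOGENEOUS_PURE      C          285
#> 8    16S  sp01    425 HOMOGENEOUS_PURE      G          389
```

Row 1 says: at alignment column 100 every sp01 specimen carries `C` and
no other species does; in sp01's reference sequence that base is
position 91 (the reference row is gapped upstream). Columns 108–110 are
a species-fixed deletion — the reference has no base there, so no
parenthetical position exists. `render_diagnosis(d)` formats this as a
publication-style table row:

```
| 16S | 100 (91), C; 108, deletion; 109, deletion; 110, deletion;
        144 (129), C; 166 (151), C; 309 (285), C; 425 (389), G; ... | - |
```

Because the dataset is simulated, recovery can be scored against the
planted truth:

```r
ev <- evaluate_recovery(d, sim$truth[sim$truth$marker == "16S", ],
                        sim$alignments["16S"], sim$partition)
ev$overall
#> $precision  1      $recall  1
```

Precision and recall of 1 mean the classifier found exactly the planted
species-fixed differences — nothing more, nothing less.

The numbered scripts under `analysis/` run the full study-scale workflow
(simulation with noise, diagnosis of all markers, amino-acid level COI
diagnostics, masking sensitivity, alignment robustness) and write their
tables under `results/`.

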