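---
title: "Extracting diagnostic characters for molecular taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting diagnostic characters for molecular taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cryptic species — lineages that molecular data delimit cleanly but
morphology cannot — still need formal, testable diagnoses. For such taxa
the diagnosis can be built from the DNA itself: fixed nucleotide (or amino
acid) differences that separate each species from all of its congeners.
`chardiag` implements this procedure end to end for multi-marker datasets
of aligned sequences, in the style used for character-based DNA taxonomy
of meiofaunal invertebrates: per-marker multiple sequence alignments, a
specimen-to-species partition, exhaustive per-species comparison, and
diagnosis tables that report every character in dual coordinates
(alignment column and position in a deposited reference sequence).

## The classification model

All inference is column-wise. For a focal species, at one alignment
column, each specimen contributes a **character state**: one of
`A/C/G/T` (or an amino-acid letter after translation), or **DELETION**
(`-`) for an internal gap. Three kinds of observation are **MISSING** and
contribute nothing:

* maximal gap runs touching either end of a row (incomplete reads, or a
  specimen that simply lacks flanking sequence — treating these as
  deletions would fabricate diagnostic indels);
* IUPAC ambiguity codes and `N` (an ambiguous base can neither confirm a
  state in the focal species nor its absence elsewhere);
* absence of the whole marker for a specimen.

Given the per-species state multisets at a column, the focal species
receives:

* **homogeneous pure** — exactly one distinct focal state, carried by
  every scored focal specimen and by no specimen of any other ingroup
  species. These are the characters admissible in a diagnosis.
* **heterogeneous pure** — two or three distinct focal states, all absent
  from every other ingroup species. Reported as additional information
  only (the multiple states may be convergent), with the carrier
  specimens annotated.
* **private** — some but not all focal states absent elsewhere. Computed
  for information, never emitted into a diagnosis.

Compound characters (combinations of columns) are not searched at all:
as a conjunction of possibly independent mutations they have no claim to
homology and are avoided in DNA taxonomy.

Two guard rules prevent vacuous purity: a column where the focal species
has no scored state is "no data", and a column where *every* other
ingroup species is entirely MISSING is "uncontrasted"; neither can yield
a character. A stricter policy (`strict_ambiguity = TRUE`) additionally
disqualifies any column where a contrast specimen carries an ambiguity
code, for users who prefer to lose a column rather than trust the
remaining reads.

Each species is compared against **all congeners pooled**, not against
its sister group on some tree: `diagnose_all()` iterates the focal
species directly, which is exactly equivalent to re-rooting a guide tree
so that each species in turn is sister to all remaining ones, and makes
the result independent of any topology. States occurring in outgroups
beyond the genus are deliberately left unconsidered at species level
(their homoplasy risk is high); they matter only for the genus-level
diagnosis (`diagnose_group()`), where the whole ingroup is the focal
unit and the outgroup specimens are the contrast.

Species sampled by a single specimen are allowed — five of the twelve
species in the motivating dataset are singletons — and the output records
`n_specimens` so a reader can weigh homogeneity claims accordingly.

## Coordinates

Diagnosis tables print positions as `alignment (reference)`, e.g.
`145 (146), C`, so a character remains traceable when the alignment
changes. `reference_frame()` maps a column to the count of non-gap
characters of the species' reference row up to that column, plus a
**leading offset** for bases present in the deposited sequence but
trimmed from the alignment (e.g. primer-proximal bases). The offset can
be inferred with `infer_offset()`, which requires the degapped reference
row to occur exactly once in the deposited sequence and refuses to guess
otherwise. Deletion characters have no reference base; they are keyed by
the last reference position before the gap run plus the run length,
which is the only description stable across alignments. All coordinates
are 1-based and closed; no 0-based interop is exposed. When a species'
designated reference specimen lacks a marker, a per-marker fallback must
be named in the configuration — except when only one specimen of the
species carries the marker, where the choice is forced and made
automatically.

## Translation

For the protein-coding marker the same classification runs on amino-acid
columns. The genetic code defaults to the invertebrate mitochondrial
table (NCBI table 5), appropriate for gastropod COI and overridable.
The reading frame is chosen to minimize *internal* stop codons — a stop
in a row's final complete codon is what a complete coding sequence looks
like and does not penalize a frame; ties prefer the frame with terminal
stops in the most rows, then frame 0 with a warning. (Minimizing *total*
stops would perversely reject a frame ending in a genuine terminal
stop.) If every frame leaves internal stops in more than half the rows
the marker is rejected as "not protein-coding?".

Codon handling is explicit about data quality: three bases translate;
`---` is an in-frame codon DELETION (a first-class diagnostic state);
a codon containing any MISSING base is MISSING; and a codon mixing gap
and base characters signals a frame-disrupting indel and is scored
MISSING with a summary warning. Amino-acid positions are codon indices
from the first complete codon of the frame, which is stated so table
comparisons are reproducible.

## Masking

Ambiguously aligned regions inflate diagnostic counts with artifacts, so
alignments are masked to conserved blocks before character extraction.
`mask_alignment()` is an independent reimplementation of the classic
conserved-block rules, with five parameters mirroring the familiar ones:
a column is *conserved* when its most frequent non-gap state exceeds
`min_conserved_fraction` (default 0.5) of the sequences, *flank-grade*
at `min_flank_fraction` (default equal — the relaxed preset);
gap-violating columns (policy `NONE`/`HALF`/`ALL`, default `HALF`:
at least half the rows gapped) count as nonconserved and never as
flanks. Maximal nonconserved runs longer than
`max_contiguous_nonconserved` (default 10) are removed, blocks are
trimmed to flank-grade boundaries, and blocks shorter than
`min_block_length` (default 5) are dropped. The defaults are the relaxed
("less stringent") preset. Bit-exact parity with any particular masking
binary version is not claimed; for reproducing published tables the
deposited pre-masked alignments are the inputs, and the internal masker
serves the sensitivity analysis. `MaskingResult` keeps the surviving
column indices so `remap_diagnostics()` can report everything in the
unmasked coordinates. Masking is idempotent, and — because it only
removes candidate columns — it can only shrink the reference-keyed
diagnostic set, never enlarge it. (One caveat: if masking removed all of
a specimen's flanking bases, an internal gap could be reclassified as
terminal and alter states; the block rules keep conserved flanks, which
makes this a non-issue in practice, and the invariant is asserted on
every simulated run.)

## Robustness across alignments

Different aligners, or different maskings, number columns differently
and can genuinely disagree about homology. `to_ref_keys()` re-keys every
character by (reference specimen, reference position, state, category) —
alignment-independent coordinates — and `compare_runs()` reports per-run
counts, the union, the Jaccard index and the **consensus**, defined as
the strict intersection: the conservative choice of fewer but more
reliable characters. Run-specific extras are flagged as
alignment-sensitive; a local misalignment shows up as an inflated extras
list for that run while leaving the consensus intact.

## The simulator and what passing tests mean

`simulate_dataset()` generates the statistical structure the analysis
assumes, not evolutionary realism: a uniform-random root sequence per
marker; per-species clusters of near-identical sequences; per species
and marker a configurable number of planted fixed substitutions (states
verified unique across species at generation time), one species-fixed
deletion run and one species-specific insertion block; then
specimen-level noise — intraspecific polymorphism (uniform over the
three alternative bases; deliberately not a biological substitution
model), internal deletion runs, wholesale missing markers and IUPAC
ambiguity codes. Coding markers are generated codon-wise without stop
codons, and all planted and noise indels on them are codon-aligned, so a
clean reading frame exists by construction. Every planted difference is
written to a truth ledger; `audit_truth()` re-checks each entry after
noise and marks entries broken by collisions or missing species
inactive, so that the active ledger equals the exact expected set of
homogeneous pure characters. `gap_shift_variant()` produces a second
alignment of identical sequences with shifted column numbering (all-gap
blocks inserted between gap-free columns, codon-aligned), the regime in
which reference-keyed diagnoses are provably invariant.

Default conditions mirror the motivating study's structure: 12 species
with uneven sampling `(5, 10, 7, 1, 3, 1, 2, 4, 4, 1, 1, 1)` — five
singletons — and four markers, 18S (1800 columns), 28S (900), 16S (410)
and coding COI (657), with four planted substitutions plus one deletion
and one insertion run per species and marker, polymorphism 0.002/site,
specimen indel rate 5e-4 (mean length 3), missing-marker rate 0.15 and
ambiguity rate 0.001 — values chosen once as realistic for a
multi-specimen barcoding study of this size. These sizes keep the whole
validation suite (hundreds of property checks, a 200-toy brute-force
oracle comparison and several full 12-species pipelines) around a
quarter of a minute.

What passing does and does not show: exact recovery in the noiseless
regime and oracle equivalence validate the *classification logic*; they
do not show that real markers contain enough fixed differences, that
real alignments are correct, or that intraspecific sampling suffices —
those are properties of data, not of the algorithm. Under noise,
precision against the planted ledger drops below 1 not because the
classifier errs but because noise creates *incidental* fixed differences
(most visibly: any private mutation in a singleton species is, by
definition, a perfectly valid diagnostic character that was never
planted). That is a faithful reflection of the method's behavior on
singletons, and the reason the output flags `n=1` species.

## Numerical choices and degenerate inputs

* Ingroups of fewer than two species are refused (every variable column
  would be trivially "pure").
* State sets are reported in plain sorted order; deletion sorts first.
* Empty masking results warn and return zero columns rather than error.
* The simulator restores the caller's RNG state; all randomness is
  governed by the `seed` field, and reruns are byte-identical.
* Heterogeneous pure characters are capped at three focal states,
  following the field's definition; four or more distinct focal states
  (even if all absent elsewhere) are treated as private-grade
  information.
* Reading-frame ties and frame-disrupting codons warn rather than fail.

## Limitations

* No apomorphy polarization against a phylogeny, and no 80%-frequency
  private-character rule: unique-within-the-genus is the criterion.
* The masker reproduces the published block rules, not any specific
  binary's quirks.
* Reproducing the published diagnosis tables requires the deposited
  supplementary alignments (and, for parenthetical coordinates, the
  deposited reference sequences); the package ships the specimen/
  accession table and reference configuration to run that comparison
  when the files are placed under `inst/extdata/deposited/`.
* The simulator's noise model is intentionally minimal; rate
  heterogeneity, transition/transversion bias and coalescent structure
  are out of scope.
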