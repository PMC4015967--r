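#!/usr/bin/env Rscript
# Alignment-robustness of the diagnoses: re-key every diagnostic by its
# reference-sequence position, compare the sets obtained from (i) the
# original alignment, (ii) a gap-shifted re-alignment of the same
# sequences and (iii) a deliberately corrupted alignment with a local
# misalignment in one species, and report the conservative consensus
# (strict intersection).

library(chardiag)
dir.create("results", showWarnings = FALSE)

sim <- simulate_dataset(sim_config(seed = 20260930))
aln <- sim$alignments$`16S`
pm <- partition_for_marker(sim$partition, aln)

run_keys <- function(a) to_ref_keys(diagnose_all(a, pm),
                                    reference_frames(a, pm))

set.seed(20260931)
shifted <- gap_shift_variant(aln)

corrupt <- aln
victims <- species_members(pm, pm$ingroup[1])
for (v in victims) {
  win <- 150:170
  corrupt$mat[v, win] <- c(corrupt$mat[v, win[-1]], corrupt$mat[v, win[1]])
}

cmp <- compare_runs(list(original = run_keys(aln),
                         gap_shifted = run_keys(shifted),
                         misaligned = run_keys(corrupt)))
write.table(cmp$summary, "results/05_robustness_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cmp$extras, "results/05_alignment_sensitive_entries.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

print(cmp)
cat("\nGap shifting alone leaves every reference-keyed entry in place;",
    "the injected misalignment produces run-specific extras that the",
    "strict-intersection consensus discards.\n")
cat("Extras by run:\n")
print(table(cmp$extras$run))
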