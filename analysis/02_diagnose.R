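#!/usr/bin/env Rscript
# Extract single pure character attributes for every species against all
# congeners, on every marker of the simulated dataset; render the
# per-species diagnosis tables in dual alignment/reference coordinates and
# score recovery of the planted differences.

library(chardiag)
dir.create("results", showWarnings = FALSE)

sim <- simulate_dataset(sim_config(seed = 20260930))

diags <- list()
for (m in names(sim$alignments)) {
  aln <- sim$alignments[[m]]
  pm <- partition_for_marker(sim$partition, aln)
  d <- diagnose_all(aln, pm)
  diags[[m]] <- add_ref_positions(d, reference_frames(aln, pm))
}
all_d <- do.call(rbind, diags)
write_classifications(all_d, "results/02_classifications.tsv")
writeLines(paste(render_diagnosis(all_d), collapse = "\n\n"),
           "results/02_diagnosis_tables.md")

ev <- evaluate_recovery(all_d, sim$truth, sim$alignments, sim$partition)
write.table(ev$per_species, "results/02_recovery_per_species.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Diagnostics found:", nrow(all_d), "entries;",
    sum(all_d$category == "HOMOGENEOUS_PURE"), "homogeneous pure,",
    sum(all_d$category == "HETEROGENEOUS_PURE"), "heterogeneous pure\n")
cat(sprintf("Recovery of planted differences: precision %.3f, recall %.3f\n",
            ev$overall$precision, ev$overall$recall))
cat("Per-species table, classifications TSV and markdown diagnoses",
    "written under results/\n")
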