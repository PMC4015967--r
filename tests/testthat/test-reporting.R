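test_that("diagnosis entries render in the dual-coordinate notation,
           including deletions and carrier notes", {
  aln <- make_aln(c(a1 = "T-CGT", a2 = "T-CGT",
                    b1 = "CACGA", b2 = "CACGA"), marker = "16S")
  pm <- make_partition(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  d <- add_ref_positions(diagnose_all(aln, pm), reference_frames(aln, pm))
  tab <- render_diagnosis(d)
  expect_named(tab, c("A", "B"))
  # A's column 2 is a deletion; its column 5 maps to reference position 4
  expect_match(tab[["A"]], "2, deletion", fixed = TRUE)
  expect_match(tab[["A"]], "5 (4), T", fixed = TRUE)
  expect_match(tab[["B"]], "5, A", fixed = TRUE)

  # heterogeneous entries carry the minority specimen annotation
  aln2 <- make_aln(c(a1 = "TA", a2 = "TA", a3 = "GA",
                     b1 = "CA", b2 = "CA"), marker = "16S")
  pm2 <- make_partition(c(a1 = "A", a2 = "A", a3 = "A",
                          b1 = "B", b2 = "B"))
  d2 <- add_ref_positions(diagnose_all(aln2, pm2),
                          reference_frames(aln2, pm2))
  tab2 <- render_diagnosis(d2)
  expect_match(tab2[["A"]], "1, T (G in a3, position 1)", fixed = TRUE)

  # a marker with no diagnostics renders as "-"
  tab3 <- render_diagnosis(d, markers = c("16S", "18S"))
  expect_match(tab3[["A"]], "\\| 18S \\| - \\| - \\|")
})

test_that("classification TSV round-trips the diagnosis table", {
  sim <- simulate_dataset(sim_config(seed = 71))
  d <- diagnose_all(sim$alignments$`16S`, sim$partition)
  d <- add_ref_positions(
    d, reference_frames(sim$alignments$`16S`,
                        partition_for_marker(sim$partition,
                                             sim$alignments$`16S`)))
  path <- tempfile(fileext = ".tsv")
  write_classifications(d, path)
  back <- read_classifications(path)
  rownames(d) <- NULL
  expect_equal(back, d)
})

test_that("the pipeline produces a deterministic bundle from a config", {
  sim <- simulate_dataset(noiseless_config(sim_config(
    n_species = 4, specimens_per_species = c(2, 1, 3, 2),
    markers = list(list(name = "16S", length = 240, coding = FALSE),
                   list(name = "COI", length = 300, coding = TRUE)),
    seed = 73)))
  dir <- tempfile()
  dir.create(dir)
  fastas <- list()
  for (m in names(sim$alignments)) {
    f <- file.path(dir, paste0(m, ".fasta"))
    write_alignment(sim$alignments[[m]], f)
    fastas[[m]] <- f
  }
  part_cfg <- list(species = lapply(sim$partition$ingroup, function(tx) {
    list(name = tx, specimens = as.list(species_members(sim$partition, tx)),
         reference = unname(sim$partition$reference_specimen[tx]))
  }))
  part_file <- file.path(dir, "partition.yaml")
  yaml::write_yaml(part_cfg, part_file)
  cfg <- list(markers = list(
    list(id = "16S", fasta = fastas$`16S`),
    list(id = "COI", fasta = fastas$COI, coding = TRUE)),
    partition = part_file)
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  res1 <- run_pipeline(cfg, outdir = out1)
  res2 <- run_pipeline(cfg, outdir = out2)
  expect_true(file.exists(res1$paths["classifications"]))
  expect_identical(readLines(res1$paths["classifications"]),
                   readLines(res2$paths["classifications"]))
  expect_identical(readLines(res1$paths["tables"]),
                   readLines(res2$paths["tables"]))
  # nucleotide and amino-acid levels both present
  expect_setequal(unique(res1$diagnoses$marker),
                  c("16S", "COI", "COI_AA"))
  # the rendered tables are backed by the classification rows
  back <- read_classifications(res1$paths["classifications"])
  expect_setequal(diag_sig(back), diag_sig(res1$diagnoses))
})

test_that("pipeline output is independent of FASTA record order", {
  sim <- simulate_dataset(noiseless_config(sim_config(
    n_species = 3, specimens_per_species = c(2, 2, 2),
    markers = list(list(name = "16S", length = 240, coding = FALSE)),
    seed = 79)))
  aln <- sim$alignments$`16S`
  dir <- tempfile(); dir.create(dir)
  f1 <- file.path(dir, "a.fasta"); f2 <- file.path(dir, "b.fasta")
  write_alignment(aln, f1)
  set.seed(1)
  write_alignment(subset_alignment(aln,
                                   sample(specimen_ids(aln))), f2)
  part_cfg <- list(species = lapply(sim$partition$ingroup, function(tx)
    list(name = tx, specimens = as.list(species_members(sim$partition, tx)),
         reference = unname(sim$partition$reference_specimen[tx]))))
  pf <- file.path(dir, "p.yaml")
  yaml::write_yaml(part_cfg, pf)
  r1 <- run_pipeline(list(markers = list(list(id = "16S", fasta = f1)),
                          partition = pf),
                     outdir = file.path(dir, "o1"))
  r2 <- run_pipeline(list(markers = list(list(id = "16S", fasta = f2)),
                          partition = pf),
                     outdir = file.path(dir, "o2"))
  expect_identical(diag_sig(r1$diagnoses), diag_sig(r2$diagnoses))
})

test_that("masking inside the pipeline is recorded and applied", {
  sim <- simulate_dataset(noiseless_config(sim_config(
    n_species = 3, specimens_per_species = c(2, 2, 2),
    markers = list(list(name = "16S", length = 240, coding = FALSE)),
    seed = 83)))
  dir <- tempfile(); dir.create(dir)
  f <- file.path(dir, "m.fasta")
  write_alignment(sim$alignments$`16S`, f)
  part_cfg <- list(species = lapply(sim$partition$ingroup, function(tx)
    list(name = tx, specimens = as.list(species_members(sim$partition, tx)),
         reference = unname(sim$partition$reference_specimen[tx]))))
  pf <- file.path(dir, "p.yaml")
  yaml::write_yaml(part_cfg, pf)
  r <- run_pipeline(list(markers = list(list(id = "16S", fasta = f)),
                         partition = pf,
                         masking = list(max_contiguous_nonconserved = 1)),
                    outdir = file.path(dir, "o"))
  log <- readLines(r$paths["log"])
  expect_true(any(grepl("masking kept", log)))
})
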