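test_that("config validation rejects impossible plans", {
  expect_error(sim_config(markers = list(
    list(name = "x", length = 100, coding = FALSE))), "too short")
  expect_error(sim_config(markers = list(
    list(name = "c", length = 301, coding = TRUE))), "divisible by 3")
})

test_that("noiseless recovery is exact for every species including
           singletons", {
  sim <- simulate_dataset(noiseless_config(sim_config(seed = 41)))
  found <- do.call(rbind, lapply(sim$alignments, function(a)
    diagnose_all(a, sim$partition)))
  expect_true(all(sim$truth$active))
  ev <- evaluate_recovery(found, sim$truth, sim$alignments, sim$partition)
  expect_equal(ev$overall$precision, 1)
  expect_equal(ev$overall$recall, 1)
  expect_true(all(ev$per_species$precision == 1))
  expect_true(all(ev$per_species$recall == 1))
  # singleton species are present in the scoring
  singles <- names(which(table(sim$partition$species_of) == 1))
  expect_true(all(singles %in% ev$per_species$species))
})

test_that("a forced collision is logged and the classifier reports
           neither species", {
  cfg <- noiseless_config(sim_config(
    n_species = 3, specimens_per_species = c(2, 2, 2),
    markers = list(list(name = "16S", length = 200, coding = FALSE)),
    planted_deletion_length = 0, planted_insertion_length = 0,
    seed = 43))
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  # plant sp02 with sp01's state at sp01's first diagnostic column
  e <- tr[tr$species == "sp01", ][1, ]
  aln <- sim$alignments$`16S`
  for (v in species_members(sim$partition, "sp02"))
    aln$mat[v, e$column] <- e$state
  sim$alignments$`16S` <- aln
  audited <- audit_truth(tr, sim$alignments, sim$partition)
  bad <- audited[audited$column == e$column, ]
  expect_true(all(!bad$active))
  expect_true(all(bad$reason == "collision"))
  d <- diagnose_all(aln, sim$partition)
  expect_false(e$column %in% d$column[d$category == "HOMOGENEOUS_PURE" &
                                        d$taxon %in% c("sp01", "sp02")])
})

test_that("the same seed reproduces the bundle byte for byte", {
  s1 <- simulate_dataset(sim_config(seed = 47))
  s2 <- simulate_dataset(sim_config(seed = 47))
  expect_identical(lapply(s1$alignments, alignment_seqs),
                   lapply(s2$alignments, alignment_seqs))
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_alignment(s1$alignments$COI, f1)
  write_alignment(s2$alignments$COI, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_dataset(sim_config(seed = 48))
  expect_false(identical(lapply(s1$alignments, alignment_seqs),
                         lapply(s3$alignments, alignment_seqs)))
})

test_that("recovery of planted entries degrades as intraspecific
           polymorphism rises", {
  planted_recovery <- function(rho) {
    cfg <- noiseless_config(sim_config(seed = 53))
    cfg$intraspecific_polymorphism_rate <- rho
    s <- simulate_dataset(cfg)
    f <- do.call(rbind, lapply(s$alignments, function(a)
      diagnose_all(a, s$partition)))
    e <- evaluate_recovery(f, s$truth, s$alignments, s$partition)
    sum(e$detail$recovered) / nrow(e$detail)
  }
  r <- vapply(c(0, 0.02, 0.08), planted_recovery, 0)
  expect_equal(r[1], 1)
  expect_true(r[1] >= r[2] && r[2] >= r[3])
  expect_lt(r[3], 1)
})

test_that("a planted difference masked out is flagged with the masked
           cause and lowers recall", {
  sim <- simulate_dataset(noiseless_config(sim_config(seed = 59)))
  found <- list()
  kept <- list()
  for (mname in names(sim$alignments)) {
    aln <- sim$alignments[[mname]]
    # aggressive masking: tiny tolerated variable runs
    res <- mask_alignment(aln, masking_params(
      max_contiguous_nonconserved = 1, min_block_length = 5))
    kept[[mname]] <- res$kept_columns
    if (length(res$kept_columns) == 0) next
    pm <- partition_for_marker(sim$partition, res$masked_alignment)
    found[[mname]] <- remap_diagnostics(diagnose_all(res$masked_alignment,
                                                     pm), res)
  }
  ev <- evaluate_recovery(do.call(rbind, found), sim$truth,
                          sim$alignments, sim$partition,
                          kept_columns = kept)
  expect_lt(ev$overall$recall, 1)
  masked_entries <- ev$detail[ev$detail$cause == "masked", ]
  expect_gt(nrow(masked_entries), 0)
  # every "masked" cause points at a column the masking really removed
  expect_true(all(vapply(seq_len(nrow(masked_entries)), function(i)
    !masked_entries$column[i] %in% kept[[masked_entries$marker[i]]],
    TRUE)))
})

test_that("missing-marker noise never leaves a marker with fewer than two
           species", {
  cfg <- sim_config(seed = 61)
  cfg$missing_marker_rate <- 0.9
  sim <- simulate_dataset(cfg)
  for (aln in sim$alignments) {
    pm <- partition_for_marker(sim$partition, aln)
    expect_gte(length(pm$ingroup), 2)
  }
})
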