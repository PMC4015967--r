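# Fixture geometry used in several blocks:
#   species A: a1..a3/a4, species B: b1..b2, species C: c1
toy_partition <- function(ids, species) make_partition(setNames(species, ids))

test_that("column profile separates DELETION from terminal MISSING", {
  aln <- make_aln(c(a1 = "AC-GTACG",   # internal gap at col 3
                    a2 = "ACTGTACG",
                    b1 = "--TGTACG",   # leading terminal gaps cols 1-2
                    b2 = "ACTGTAC-"))  # trailing terminal gap col 8
  pm <- toy_partition(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  p3 <- column_profile(aln, pm, 3)
  expect_setequal(unname(p3$states_by_taxon$A), c("-", "T"))
  p1 <- column_profile(aln, pm, 1)
  expect_equal(unname(p1$states_by_taxon$B), "A")      # b1 missing, b2 A
  expect_equal(unname(p1$n_missing_by_taxon["B"]), 1L)
  p8 <- column_profile(aln, pm, 8)
  expect_equal(unname(p8$n_missing_by_taxon["B"]), 1L) # trailing gap
})

test_that("ambiguity codes and N are missing for the carrier only", {
  aln <- make_aln(c(a1 = "AR", a2 = "AC", b1 = "GN", b2 = "GC"))
  pm <- toy_partition(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  p2 <- column_profile(aln, pm, 2)
  expect_equal(unname(p2$states_by_taxon$A), "C")
  expect_equal(unname(p2$states_by_taxon$B), "C")
  expect_equal(sum(p2$n_missing_by_taxon), 2L)
})

test_that("classify_column implements the pure/private taxonomy", {
  # homogeneous pure: focal T fixed, absent from others
  aln <- make_aln(c(a1 = "TA", a2 = "TA", a3 = "TA",
                    b1 = "CA", b2 = "GA", c1 = "CA"))
  pm <- toy_partition(c("a1", "a2", "a3", "b1", "b2", "c1"),
                      c("A", "A", "A", "B", "B", "C"))
  r <- classify_column(column_profile(aln, pm, 1), "A")
  expect_equal(r$category, "HOMOGENEOUS_PURE")
  expect_equal(r$states, "T")
  # invariant column: nothing
  expect_null(classify_column(column_profile(aln, pm, 2), "A"))

  # heterogeneous pure: focal {T,G}, both absent elsewhere
  aln2 <- make_aln(c(a1 = "TT", a2 = "TT", a3 = "GT",
                     b1 = "CT", b2 = "AT", c1 = "CT"))
  r2 <- classify_column(column_profile(aln2, pm, 1), "A")
  expect_equal(r2$category, "HETEROGENEOUS_PURE")
  expect_equal(r2$states, "G,T")
  expect_match(r2$carriers, "a3=G")

  # private: one of the focal states is shared with another species
  aln3 <- make_aln(c(a1 = "AT", a2 = "CT", a3 = "CT",
                     b1 = "CT", b2 = "GT", c1 = "GT"))
  r3 <- classify_column(column_profile(aln3, pm, 1), "A")
  expect_equal(r3$category, "PRIVATE")
  expect_equal(r3$states, "A")
})

test_that("a column with no focal data or no contrast data is not
           classified", {
  aln <- make_aln(c(a1 = "N-A", a2 = "N-A", b1 = "C-A", b2 = "C-A"))
  pm <- toy_partition(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  expect_null(classify_column(column_profile(aln, pm, 1), "A")) # focal N
  # contrast entirely missing (uncontrasted)
  aln2 <- make_aln(c(a1 = "TGA", a2 = "TGA", b1 = "--A", b2 = "N-A"))
  expect_null(classify_column(column_profile(aln2, pm, 1), "A"))
})

test_that("diagnose_taxon refuses a single-species ingroup and sorts by
           column", {
  aln <- make_aln(c(a1 = "ACGT", a2 = "ACGT"))
  pm <- toy_partition(c("a1", "a2"), c("A", "A"))
  expect_error(diagnose_taxon(aln, pm, "A"), ">= 2 ingroup")

  toy <- random_toy(77)
  d <- diagnose_taxon(toy$aln, toy$partition, toy$partition$ingroup[1])
  expect_true(!is.unsorted(d$column))
})

test_that("two-species case: both species share the diagnostic column set
           with complementary states", {
  for (seed in c(11, 12, 13, 14)) {
    set.seed(seed)
    nc <- 30
    root <- sample(c("A", "C", "G", "T"), nc, replace = TRUE)
    alt <- root
    k <- sample(3:6, 1)
    flip <- sample(nc, k)
    for (h in flip)
      alt[h] <- sample(setdiff(c("A", "C", "G", "T"), root[h]), 1)
    aln <- make_aln(c(a1 = paste(root, collapse = ""),
                      a2 = paste(root, collapse = ""),
                      b1 = paste(alt, collapse = ""),
                      b2 = paste(alt, collapse = "")))
    pm <- toy_partition(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
    d <- diagnose_all(aln, pm)
    da <- d[d$taxon == "A", ]
    db <- d[d$taxon == "B", ]
    expect_setequal(da$column, sort(flip))
    expect_identical(da$column, db$column)
    expect_true(all(da$states != db$states))
  }
})

test_that("classifier equals the brute-force oracle on random toys", {
  for (seed in 101:140) {
    toy <- random_toy(seed)
    if (length(toy$partition$ingroup) < 2) next
    got <- diagnose_all(toy$aln, toy$partition, include_private = TRUE)
    want <- oracle_diagnose(alignment_seqs(toy$aln), toy$species_of)
    expect_identical(
      diag_sig(got[, c("taxon", "column", "category", "states")]),
      diag_sig(want),
      info = paste("seed", seed))
  }
})

test_that("output is independent of specimen and species order", {
  toy <- random_toy(57)
  d1 <- diagnose_all(toy$aln, toy$partition)
  set.seed(1)
  perm <- sample(specimen_ids(toy$aln))
  aln2 <- subset_alignment(toy$aln, specimens = perm)
  pm2 <- make_partition(toy$species_of[perm])
  d2 <- diagnose_all(aln2, pm2)
  expect_identical(diag_sig(d1), diag_sig(d2))
})

test_that("exclusivity: a homogeneous pure state never occurs in another
           ingroup specimen at that column (re-scan)", {
  for (seed in c(201, 202, 203)) {
    toy <- random_toy(seed)
    if (length(toy$partition$ingroup) < 2) next
    d <- diagnose_all(toy$aln, toy$partition)
    S <- state_matrix(toy$aln)
    hom <- d[d$category == "HOMOGENEOUS_PURE", ]
    for (i in seq_len(nrow(hom))) {
      others <- names(toy$species_of)[toy$species_of != hom$taxon[i]]
      vals <- S[others, hom$column[i]]
      expect_false(hom$states[i] %in% vals[!is.na(vals)])
    }
  }
})

test_that("monotonicity: removing a specimen never removes a diagnostic
           column from a comparison that retains its data", {
  for (seed in c(301, 302, 303, 304)) {
    toy <- random_toy(seed)
    pm <- toy$partition
    if (length(pm$ingroup) < 2) next
    before <- diagnose_all(toy$aln, pm)
    ids <- names(toy$species_of)
    victim <- ids[1]
    vsp <- toy$species_of[[victim]]
    keep <- setdiff(ids, victim)
    if (length(unique(toy$species_of[keep])) < 2) next
    aln2 <- subset_alignment(toy$aln, specimens = keep)
    after <- diagnose_all(aln2, make_partition(toy$species_of[keep]))
    S <- state_matrix(aln2)
    for (tx in setdiff(unique(toy$species_of[keep]), vsp)) {
      b <- before[before$taxon == tx, ]
      a <- after[after$taxon == tx, ]
      contrast <- keep[toy$species_of[keep] != tx]
      contrasted <- colSums(!is.na(S[contrast, , drop = FALSE])) > 0
      expect_true(all(b$column %in% a$column | !contrasted[b$column]),
                  info = paste("seed", seed))
    }
  }
})

test_that("singleton species are diagnosable and flagged n=1", {
  aln <- make_aln(c(a1 = "ACGT", b1 = "AGGT", b2 = "AGGT"))
  pm <- toy_partition(c("a1", "b1", "b2"), c("A", "B", "B"))
  d <- diagnose_all(aln, pm)
  expect_equal(d$n_specimens[d$taxon == "A"], 1L)
  expect_equal(d$column[d$taxon == "A"], 2L)
})

test_that("strict ambiguity mode disqualifies columns with ambiguous
           contrast specimens", {
  aln <- make_aln(c(a1 = "TA", a2 = "TA", b1 = "RA", b2 = "CA"))
  pm <- toy_partition(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  lax <- diagnose_all(aln, pm)
  expect_equal(lax$column[lax$taxon == "A"], 1L)
  strict <- diagnose_all(aln, pm, strict_ambiguity = TRUE)
  # A's column is disqualified (ambiguous contrast specimen b1); B's
  # contrast (a1, a2) is unambiguous, so B keeps its diagnostic
  expect_equal(nrow(strict[strict$taxon == "A", ]), 0L)
  expect_equal(strict$column[strict$taxon == "B"], 1L)
})

test_that("group diagnosis contrasts the pooled ingroup against outgroup
           specimens", {
  aln <- make_aln(c(a1 = "TCGT", a2 = "TCGT", b1 = "TAGT", b2 = "TAGT",
                    o1 = "CCGA", o2 = "CCGA"))
  pm <- make_partition(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
                       outgroup = c("o1", "o2"))
  g <- diagnose_group(aln, pm)
  expect_setequal(g$column, c(1L, 4L))
  expect_true(all(g$category == "HOMOGENEOUS_PURE"))
  # matches the oracle with the ingroup merged into one taxon
  merged <- c(a1 = "G", a2 = "G", b1 = "G", b2 = "G", o1 = "O", o2 = "O")
  want <- oracle_diagnose(alignment_seqs(aln), merged)
  want <- want[want$taxon == "G" & want$category != "PRIVATE", ]
  expect_setequal(g$column, want$column)

  expect_error(
    diagnose_group(subset_alignment(aln, c("a1", "a2", "b1", "b2")),
                   make_partition(c(a1 = "A", a2 = "A",
                                    b1 = "B", b2 = "B"))),
    "outgroup")
})

test_that("an outgroup copy identical to an ingroup specimen kills all
           group diagnostics", {
  aln <- make_aln(c(a1 = "TCGT", a2 = "TCGA", o1 = "TCGT"))
  pm <- make_partition(c(a1 = "A", a2 = "A"), outgroup = "o1")
  expect_equal(nrow(diagnose_group(aln, pm)), 0L)
})

test_that("species-level scans leave outgroup states unconsidered", {
  # A's T also occurs in the outgroup; still diagnostic within the genus
  aln <- make_aln(c(a1 = "TA", a2 = "TA", b1 = "CA", b2 = "CA",
                    o1 = "TA"))
  pm <- make_partition(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
                       outgroup = "o1")
  d <- diagnose_all(aln, pm)
  expect_equal(d$column[d$taxon == "A"], 1L)
})
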