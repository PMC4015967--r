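# Small fixtures built in code.

make_aln <- function(seqs, marker = "toy", ...) {
  marker_alignment(seqs, marker_id = marker, ...)
}

make_partition <- function(species_of, refs = NULL, outgroup = character()) {
  if (is.null(refs)) {
    taxa <- unique(unname(species_of))
    refs <- vapply(taxa, function(tx)
      names(species_of)[species_of == tx][1], "")
  }
  partition_map(species_of, refs, outgroup)
}

# random toy alignment with gaps (terminal and internal) and ambiguity
# noise: <= 12 specimens over 2-4 species, <= 50 columns
random_toy <- function(seed) {
  set.seed(seed)
  n_sp <- sample(2:4, 1)
  sizes <- sample(1:3, n_sp, replace = TRUE)
  nc <- sample(20:50, 1)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, nc, replace = TRUE)
  seqs <- character()
  species_of <- character()
  for (s in seq_len(n_sp)) {
    cons <- root
    hit <- sample(nc, sample(0:4, 1))
    for (h in hit) cons[h] <- sample(bases, 1)
    for (v in seq_len(sizes[s])) {
      row <- cons
      hit2 <- sample(nc, sample(0:2, 1))
      for (h in hit2) row[h] <- sample(c(bases, "N", "R", "Y"), 1)
      if (runif(1) < 0.4) {            # internal deletion run
        st <- sample(5:(nc - 6), 1)
        row[st:(st + sample(1:3, 1))] <- "-"
      }
      if (runif(1) < 0.3)              # ragged 5' end (terminal gap)
        row[1:sample(1:4, 1)] <- "-"
      if (runif(1) < 0.3)
        row[(nc - sample(0:3, 1)):nc] <- "-"
      id <- sprintf("sp%d_v%d", s, v)
      seqs[id] <- paste(row, collapse = "")
      species_of[id] <- sprintf("sp%d", s)
    }
  }
  list(aln = make_aln(seqs), species_of = species_of,
       partition = make_partition(species_of))
}

# canonical comparable form of a diagnosis table
diag_sig <- function(d) {
  d <- d[order(d$taxon, d$column, d$category), ]
  paste(d$taxon, d$column, d$category, d$states, sep = ":", collapse = "|")
}
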