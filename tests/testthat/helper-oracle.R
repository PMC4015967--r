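# Independent brute-force classifier used as the oracle for the
# column-classification engine. Deliberately written against the raw
# sequence strings with set operations, not against the package's state
# matrix machinery.

ORACLE_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

# per-row state vector: NA = missing, "-" = internal deletion, else base
oracle_row_states <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  lead <- attr(regexpr("^-*", seq), "match.length")
  trail <- attr(regexpr("-*$", seq), "match.length")
  out <- chars
  out[chars %in% ORACLE_AMBIG] <- NA
  if (lead > 0) out[1:lead] <- NA
  if (trail > 0) out[(length(chars) - trail + 1):length(chars)] <- NA
  out
}

# enumerate pure columns for every species by literal application of the
# definitions; returns data.frame(taxon, column, category, states)
oracle_diagnose <- function(seqs, species_of) {
  states <- lapply(seqs, oracle_row_states)
  nc <- nchar(seqs[[1]])
  taxa <- sort(unique(unname(species_of)))
  res <- list()
  for (focal in taxa) {
    f_ids <- names(species_of)[species_of == focal]
    o_ids <- names(species_of)[species_of != focal]
    for (col in seq_len(nc)) {
      fv <- unlist(lapply(f_ids, function(id) states[[id]][col]))
      ov <- unlist(lapply(o_ids, function(id) states[[id]][col]))
      fv <- fv[!is.na(fv)]
      ov <- ov[!is.na(ov)]
      if (length(fv) == 0 || length(ov) == 0) next
      fset <- sort(unique(fv))
      if (all(!fset %in% ov)) {
        cat_ <- if (length(fset) == 1) "HOMOGENEOUS_PURE"
                else if (length(fset) <= 3) "HETEROGENEOUS_PURE"
                else "PRIVATE"
        res[[length(res) + 1]] <- data.frame(
          taxon = focal, column = col, category = cat_,
          states = paste(fset, collapse = ","), stringsAsFactors = FALSE)
      } else if (any(!fset %in% ov)) {
        res[[length(res) + 1]] <- data.frame(
          taxon = focal, column = col, category = "PRIVATE",
          states = paste(fset[!fset %in% ov], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(taxon = character(), column = integer(),
                      category = character(), states = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$taxon, out$column), , drop = FALSE]
}
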