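# Alignment-independent comparison of diagnostic sets. Different alignment
# programs (or maskings) of the same sequences number columns differently;
# keying each diagnostic by its position in the species' deposited
# reference sequence makes the sets comparable, and the strict
# intersection across runs is the conservative consensus (fewer but more
# reliable diagnostic characters).

#' Re-key diagnostics by reference coordinates
#'
#' Substitution diagnostics are keyed by (reference specimen, reference
#' position, state, category). Deletion diagnostics (and entries where the
#' reference row is gapped) are keyed by the last reference base preceding
#' the gap run plus the run length, which is independent of where an
#' aligner placed the gap columns.
#'
#' @param diags Diagnosis data frame (one marker).
#' @param frames Named list of \code{reference_frame} objects per taxon,
#'   built from the same alignment as \code{diags}.
#' @return An object of class \code{ref_keyed_diagnosis}: a data frame with
#'   \code{taxon}, \code{marker}, \code{reference_specimen}, \code{key}
#'   (character), \code{category}.
#' @export
to_ref_keys <- function(diags, frames) {
  n <- nrow(diags)
  out <- data.frame(taxon = character(n), marker = character(n),
                    reference_specimen = character(n), key = character(n),
                    category = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    taxon <- diags$taxon[i]
    fr <- frames[[taxon]]
    if (is.null(fr))
      stop("no reference frame for taxon '", taxon, "'", call. = FALSE)
    col <- diags$column[i]
    if (fr$gap[col]) {
      fl <- flanking_ref_position(fr, col)
      key <- paste0("after", fl$prev_ref, "+", fl$run_length, ":",
                    diags$states[i])
    } else {
      key <- paste0("ref", align_to_ref(fr, col), ":", diags$states[i])
    }
    out$taxon[i] <- taxon
    out$marker[i] <- diags$marker[i]
    out$reference_specimen[i] <- fr$specimen_id
    out$key[i] <- key
    out$category[i] <- diags$category[i]
  }
  class(out) <- c("ref_keyed_diagnosis", "data.frame")
  out
}

#' Compare diagnostic sets across runs
#'
#' Takes reference-keyed diagnoses from >= 2 runs over the same species
#' (alternative alignments and/or maskings of the same sequences) and
#' reports, per species: per-run counts, the consensus (strict
#' intersection), the union and the Jaccard index. Run-specific extras are
#' the alignment-sensitive entries.
#'
#' @param runs Named list of \code{ref_keyed_diagnosis} objects.
#' @return An object of class \code{run_comparison}: list with
#'   \code{summary} (data frame per taxon), \code{consensus} (data frame
#'   taxon/key) and \code{extras} (entries absent from the consensus, with
#'   the runs carrying them).
#' @export
compare_runs <- function(runs) {
  stopifnot(length(runs) >= 2L)
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("run", seq_along(runs))
  taxa_per_run <- lapply(runs, function(r) unique(r$taxon))
  taxa <- Reduce(intersect, taxa_per_run)
  if (length(taxa) == 0L)
    stop("runs share no species: nothing to compare", call. = FALSE)
  key_of <- function(r, tx) unique(r$key[r$taxon == tx])
  summary <- do.call(rbind, lapply(taxa, function(tx) {
    keys <- lapply(runs, key_of, tx)
    inter <- Reduce(intersect, keys)
    union <- Reduce(base::union, keys)
    cnt <- vapply(keys, length, 0L)
    df <- data.frame(taxon = tx, n_consensus = length(inter),
                     n_union = length(union),
                     jaccard = if (length(union) == 0L) 1
                               else length(inter) / length(union),
                     stringsAsFactors = FALSE)
    for (nm in names(runs)) df[[paste0("n_", nm)]] <- cnt[[nm]]
    df
  }))
  consensus <- do.call(rbind, lapply(taxa, function(tx) {
    inter <- Reduce(intersect, lapply(runs, key_of, tx))
    if (length(inter) == 0L) return(NULL)
    data.frame(taxon = tx, key = sort(inter), stringsAsFactors = FALSE)
  }))
  if (is.null(consensus))
    consensus <- data.frame(taxon = character(), key = character(),
                            stringsAsFactors = FALSE)
  extras <- do.call(rbind, lapply(taxa, function(tx) {
    keys <- lapply(runs, key_of, tx)
    inter <- Reduce(intersect, keys)
    ex <- lapply(names(runs), function(nm) {
      e <- setdiff(keys[[nm]], inter)
      if (length(e) == 0L) return(NULL)
      data.frame(taxon = tx, run = nm, key = sort(e),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, ex)
  }))
  if (is.null(extras))
    extras <- data.frame(taxon = character(), run = character(),
                         key = character(), stringsAsFactors = FALSE)
  structure(list(summary = summary, consensus = consensus, extras = extras),
            class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat("<run_comparison> over", nrow(x$summary), "species\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
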