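# Translation of protein-coding markers (COI) and amino-acid level
# diagnosis. The genetic code defaults to the invertebrate mitochondrial
# table (NCBI table 5), as appropriate for gastropod COI. Codon handling
# is deliberate about data quality:
#   codon of three bases        -> amino acid
#   codon that is exactly "---" -> DELETION (an in-frame codon deletion)
#   codon containing MISSING    -> MISSING
#   codon mixing gap and base   -> MISSING (frame-disrupting indel; warned)

#' Infer the reading frame of a coding alignment
#'
#' Picks the frame minimizing the summed count of internal stop codons
#' (stops before a row's last complete codon); a terminal stop is expected
#' in a complete coding sequence and does not penalize a frame. Ties break
#' toward the frame whose last complete codon is a stop in the most rows,
#' then toward the smallest frame with a warning. Amino-acid position 1 is
#' the first complete codon of the chosen frame.
#'
#' @param alignment A DNA \code{marker_alignment} with >= 3 columns.
#' @param genetic_code_id NCBI translation-table identifier (default
#'   \code{"5"}, invertebrate mitochondrial).
#' @return An object of class \code{codon_frame}: \code{frame_shift}
#'   (0, 1 or 2), \code{genetic_code_id}, \code{stop_count_by_frame}
#'   (internal stops) and \code{terminal_stop_rows_by_frame}.
#' @export
infer_reading_frame <- function(alignment, genetic_code_id = "5") {
  stopifnot(n_columns(alignment) >= 3L)
  code <- Biostrings::getGeneticCode(genetic_code_id)
  S <- state_matrix(alignment)
  n <- nrow(S)
  internal <- integer(3)
  terminal <- integer(3)
  rows_with_stop <- integer(3)
  for (shift in 0:2) {
    per_row <- vapply(seq_len(n), function(i)
      count_stops(S[i, ], shift, code), c(internal = 0L, terminal = 0L))
    internal[shift + 1L] <- sum(per_row["internal", ])
    terminal[shift + 1L] <- sum(per_row["terminal", ])
    rows_with_stop[shift + 1L] <- sum(per_row["internal", ] > 0L)
  }
  if (all(rows_with_stop > n / 2))
    stop("every reading frame yields internal stop codons in more than ",
         "half the rows: not protein-coding?", call. = FALSE)
  cand <- which(internal == min(internal))
  if (length(cand) > 1L) {
    cand2 <- cand[terminal[cand] == max(terminal[cand])]
    if (length(cand2) > 1L)
      warning("reading-frame tie (frames ",
              paste(cand2 - 1L, collapse = ", "), "); choosing frame ",
              cand2[1L] - 1L)
    cand <- cand2
  }
  structure(list(frame_shift = cand[1L] - 1L,
                 genetic_code_id = genetic_code_id,
                 stop_count_by_frame = stats::setNames(internal,
                                                       paste0("frame", 0:2)),
                 terminal_stop_rows_by_frame =
                   stats::setNames(terminal, paste0("frame", 0:2))),
            class = "codon_frame")
}

count_stops <- function(states, shift, code) {
  nc <- length(states)
  if (shift + 3L > nc) return(c(internal = 0L, terminal = 0L))
  starts <- seq(shift + 1L, nc - 2L, by = 3L)
  is_stop <- vapply(starts, function(s) {
    codon <- states[s:(s + 2L)]
    if (anyNA(codon) || any(codon == "-")) return(NA)
    identical(code[[paste(codon, collapse = "")]], "*")
  }, NA)
  complete <- which(!is.na(is_stop))
  if (length(complete) == 0L) return(c(internal = 0L, terminal = 0L))
  last <- complete[length(complete)]
  c(internal = sum(is_stop[setdiff(complete, last)]),
    terminal = as.integer(isTRUE(is_stop[last])))
}

#' Translate a coding alignment codon-wise
#'
#' One amino-acid column per complete codon of the chosen frame. Trailing
#' columns that do not fill a codon are dropped. Codons mixing gap and base
#' characters indicate a frame-disrupting indel and are scored MISSING with
#' a single summary warning.
#'
#' @param alignment A DNA \code{marker_alignment}.
#' @param frame A \code{codon_frame} (from \code{\link{infer_reading_frame}})
#'   or an integer shift 0/1/2.
#' @param genetic_code_id Used when \code{frame} is given as an integer.
#' @return An amino-acid \code{marker_alignment} (marker id suffixed
#'   \code{"_AA"}; \code{"?"} encodes MISSING).
#' @export
translate_rows <- function(alignment, frame, genetic_code_id = "5") {
  if (is.numeric(frame))
    frame <- structure(list(frame_shift = as.integer(frame),
                            genetic_code_id = genetic_code_id),
                       class = "codon_frame")
  code <- Biostrings::getGeneticCode(frame$genetic_code_id)
  S <- state_matrix(alignment)
  nc <- ncol(S)
  starts <- seq(frame$frame_shift + 1L, nc - 2L, by = 3L)
  n_mixed <- 0L
  aa <- vapply(seq_len(nrow(S)), function(i) {
    row <- S[i, ]
    chars <- vapply(starts, function(s) {
      codon <- row[s:(s + 2L)]
      if (anyNA(codon)) return("?")
      gaps <- sum(codon == "-")
      if (gaps == 3L) return("-")
      if (gaps > 0L) { n_mixed <<- n_mixed + 1L; return("?") }
      code[[paste(codon, collapse = "")]]
    }, "")
    paste(chars, collapse = "")
  }, "")
  if (n_mixed > 0L)
    warning(n_mixed, " codon(s) mixing gap and base characters scored as ",
            "MISSING (frame-disrupting indel)")
  seqs <- stats::setNames(aa, rownames(S))
  # rows with no translatable codon (all MISSING/DELETION) cannot carry
  # amino-acid states; drop them rather than invalidate the alignment
  keep <- vapply(seqs, function(s)
    any(!strsplit(s, "")[[1]] %in% c("?", "-")), TRUE)
  if (!all(keep))
    warning("rows with no translatable codon dropped: ",
            paste(names(seqs)[!keep], collapse = ", "))
  marker_alignment(seqs[keep], marker_id = paste0(alignment$marker_id, "_AA"),
                   alphabet = "AA",
                   position_origin = alignment$position_origin)
}

#' Amino-acid level diagnosis of a coding marker
#'
#' Translates the alignment and runs the standard character-attribute
#' classification on the amino-acid columns. Amino-acid positions are codon
#' indices counted from the first complete codon of the frame.
#'
#' @param alignment A DNA \code{marker_alignment} of the coding marker.
#' @param partition A \code{partition_map}.
#' @param frame A \code{codon_frame}; inferred when \code{NULL}.
#' @param ... Passed to \code{\link{diagnose_all}}.
#' @return Diagnosis data frame on amino-acid columns.
#' @export
diagnose_protein <- function(alignment, partition, frame = NULL, ...) {
  if (is.null(frame)) frame <- infer_reading_frame(alignment)
  aa <- translate_rows(alignment, frame)
  diagnose_all(aa, partition, ...)
}
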