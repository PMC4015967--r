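# Mapping 1-based alignment columns to ungapped positions in a per-taxon
# reference sequence, and rendering the dual "alignment (reference)"
# position notation. Coordinates are 1-based and closed throughout.

#' Build a reference frame from an alignment row
#'
#' @param alignment A \code{marker_alignment}.
#' @param specimen_id Reference specimen (a row of the alignment), ideally
#'   derived from type material.
#' @param taxon Species label the frame belongs to (metadata).
#' @param leading_offset Number of bases present in the deposited reference
#'   sequence before alignment column 1 (e.g. primer-proximal bases trimmed
#'   from the alignment). See \code{\link{infer_offset}}.
#' @return An object of class \code{reference_frame}.
#' @export
reference_frame <- function(alignment, specimen_id, taxon = NA_character_,
                            leading_offset = 0L) {
  if (!specimen_id %in% specimen_ids(alignment))
    stop("reference specimen '", specimen_id, "' not in alignment '",
         alignment$marker_id, "'", call. = FALSE)
  row <- alignment$mat[specimen_id, ]
  gap <- row == "-"
  structure(list(marker_id = alignment$marker_id, taxon = taxon,
                 specimen_id = specimen_id,
                 leading_offset = as.integer(leading_offset),
                 gap = gap, cum = cumsum(!gap)),
            class = "reference_frame")
}

#' Map an alignment column to a reference position
#'
#' Counts the non-gap characters of the reference row up to and including
#' the column and adds the leading offset. Returns \code{NA} where the
#' reference row is gapped (the reference sequence has no base there).
#'
#' @param frame A \code{reference_frame}.
#' @param column 1-based alignment column(s); vectorized.
#' @return Integer vector of reference positions (\code{NA} at reference
#'   gaps).
#' @export
align_to_ref <- function(frame, column) {
  stopifnot(all(column >= 1L & column <= length(frame$gap)))
  ifelse(frame$gap[column], NA_integer_,
         frame$leading_offset + frame$cum[column])
}

#' Map a reference position back to its alignment column
#'
#' Inverse of \code{\link{align_to_ref}} on non-gap columns.
#'
#' @param frame A \code{reference_frame}.
#' @param ref_position Reference position(s); vectorized.
#' @return Integer alignment column(s); \code{NA} when the position falls
#'   outside the aligned part of the reference sequence.
#' @export
ref_to_align <- function(frame, ref_position) {
  target <- ref_position - frame$leading_offset
  nongap <- which(!frame$gap)
  idx <- match(target, frame$cum[nongap])
  nongap[idx]
}

#' Infer the leading offset against a deposited sequence
#'
#' Deposited reference sequences may include bases trimmed from the
#' alignment (e.g. primer regions). The degapped reference row must occur
#' exactly once as a substring of the deposited sequence; the offset is the
#' number of deposited bases preceding that occurrence.
#'
#' @param frame A \code{reference_frame}.
#' @param alignment The alignment the frame was built from.
#' @param deposited_sequence Ungapped deposited sequence (character scalar).
#' @return Integer offset (>= 0).
#' @export
infer_offset <- function(frame, alignment, deposited_sequence) {
  row <- alignment$mat[frame$specimen_id, ]
  degapped <- paste(row[row != "-"], collapse = "")
  deposited <- toupper(gsub("[^A-Za-z]", "", deposited_sequence))
  hits <- gregexpr(degapped, deposited, fixed = TRUE)[[1L]]
  hits <- hits[hits > 0L]
  if (length(hits) != 1L)
    stop("degapped reference row occurs ", length(hits),
         " times in the deposited sequence (need exactly 1); ",
         "supply the offset explicitly", call. = FALSE)
  as.integer(hits - 1L)
}

#' Last reference position before an alignment column
#'
#' For deletion diagnostics (the reference row is gapped at the column):
#' the position of the last reference base preceding the gap run, plus the
#' run length, keys the deletion independently of the alignment.
#'
#' @param frame A \code{reference_frame}.
#' @param column 1-based alignment column (scalar).
#' @return List with \code{prev_ref} (0 when the gap run starts the
#'   alignment) and \code{run_length} of the reference-row gap run
#'   containing \code{column} (1 when the reference row has a base there).
#' @export
flanking_ref_position <- function(frame, column) {
  if (!frame$gap[column])
    return(list(prev_ref = frame$leading_offset + frame$cum[column] - 1L,
                run_length = 1L))
  lo <- column
  while (lo > 1L && frame$gap[lo - 1L]) lo <- lo - 1L
  hi <- column
  while (hi < length(frame$gap) && frame$gap[hi + 1L]) hi <- hi + 1L
  prev <- if (lo == 1L) 0L else frame$leading_offset + frame$cum[lo - 1L]
  list(prev_ref = as.integer(prev), run_length = hi - lo + 1L)
}

#' Format a dual-coordinate position
#'
#' Renders the "alignment (reference)" notation of diagnosis tables:
#' \code{"8"} when both coordinates agree, \code{"145 (146)"} when they
#' differ, and the bare alignment position when the reference has no base
#' at the column (deletion entries).
#'
#' @param column Alignment position(s).
#' @param ref_position Reference position(s) or \code{NA}; vectorized.
#' @return Character vector.
#' @export
format_position <- function(column, ref_position) {
  ifelse(is.na(ref_position) | ref_position == column,
         as.character(column),
         paste0(column, " (", ref_position, ")"))
}

#' Build reference frames for every species of a partition
#'
#' @param alignment A \code{marker_alignment}.
#' @param partition A \code{partition_map} (restricted to the marker).
#' @param offsets Optional named integer vector of leading offsets per
#'   species (default 0).
#' @return Named list of \code{reference_frame} objects (species lacking a
#'   resolvable reference specimen are omitted).
#' @export
reference_frames <- function(alignment, partition, offsets = NULL) {
  partition <- partition_for_marker(partition, alignment)
  refs <- partition$reference_specimen
  frames <- list()
  for (taxon in names(refs)) {
    off <- 0L
    if (!is.null(offsets) && taxon %in% names(offsets))
      off <- as.integer(offsets[[taxon]])
    frames[[taxon]] <- reference_frame(alignment, refs[[taxon]],
                                       taxon = taxon, leading_offset = off)
  }
  frames
}

#' Fill reference positions into a diagnosis table
#'
#' @param diags Diagnosis data frame from \code{\link{diagnose_taxon}} or
#'   \code{\link{diagnose_all}}.
#' @param frames Named list of \code{reference_frame} objects by taxon (see
#'   \code{\link{reference_frames}}).
#' @return \code{diags} with \code{ref_position} filled (\code{NA} where the
#'   reference row is gapped or no frame exists for the taxon).
#' @export
add_ref_positions <- function(diags, frames) {
  if (nrow(diags) == 0L) return(diags)
  for (i in seq_len(nrow(diags))) {
    fr <- frames[[diags$taxon[i]]]
    if (is.null(fr)) next
    diags$ref_position[i] <- align_to_ref(fr, diags$column[i])
  }
  diags
}
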