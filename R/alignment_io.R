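# Alignment containers and FASTA I/O.
#
# A marker alignment is a character matrix (specimens x columns) of
# single-character states over {A,C,G,T,-} plus IUPAC ambiguity letters and
# N for DNA, or the amino-acid alphabet (incl. "-" and "?" for missing) for
# translated markers. All positions are 1-based alignment columns.

DNA_BASES    <- c("A", "C", "G", "T")
IUPAC_AMBIG  <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
AA_LETTERS   <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a marker alignment
#'
#' @param seqs Named character vector of aligned sequences (equal length).
#'   Names are specimen identifiers and must be unique.
#' @param marker_id Text label for the marker (e.g. \code{"16S"}).
#' @param alphabet \code{"DNA"} or \code{"AA"}.
#' @param position_origin Integer documenting what alignment column 1 means
#'   in the lab protocol (e.g. first base after the primer region). Internal
#'   indices are always the alignment's own 1-based columns; this field is
#'   provenance only.
#' @param normalize Apply symbol normalization (uppercase, U->T, .->-)?
#'   Only meaningful for DNA.
#' @return An object of class \code{marker_alignment}: a list with elements
#'   \code{marker_id}, \code{mat} (character matrix, rownames = specimen
#'   ids), \code{alphabet} and \code{position_origin}.
#' @export
marker_alignment <- function(seqs, marker_id, alphabet = c("DNA", "AA"),
                             position_origin = 1L, normalize = TRUE) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) < 1L)
    stop("alignment '", marker_id, "' is empty", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named with specimen ids", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (alphabet == "DNA" && normalize) {
    seqs <- toupper(seqs)
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment '", marker_id, "': rows of differing length: ",
         paste(ids[lens != stats::median(lens)], collapse = ", "),
         call. = FALSE)
  if (lens[1] < 1L)
    stop("alignment '", marker_id, "' has zero columns", call. = FALSE)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- ids
  ok <- if (alphabet == "DNA") c(DNA_BASES, "-", IUPAC_AMBIG)
        else c(AA_LETTERS, "-", "?", "X", "*")
  bad <- setdiff(unique(as.vector(mat)), ok)
  if (length(bad) > 0L)
    stop("alignment '", marker_id, "' contains invalid symbols: ",
         paste(bad, collapse = " "), call. = FALSE)
  all_gap <- rowSums(mat != "-") == 0L
  if (any(all_gap))
    stop("rows with no non-gap characters: ",
         paste(ids[all_gap], collapse = ", "), call. = FALSE)
  structure(list(marker_id = marker_id, mat = mat, alphabet = alphabet,
                 position_origin = as.integer(position_origin)),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("<marker_alignment> ", x$marker_id, " (", x$alphabet, "): ",
      nrow(x$mat), " specimens x ", ncol(x$mat), " columns\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param alignment A \code{marker_alignment}.
#' @export
n_columns <- function(alignment) ncol(alignment$mat)

#' Specimen identifiers of an alignment
#' @param alignment A \code{marker_alignment}.
#' @export
specimen_ids <- function(alignment) rownames(alignment$mat)

#' Aligned sequences as a named character vector
#' @param alignment A \code{marker_alignment}.
#' @export
alignment_seqs <- function(alignment) {
  stats::setNames(apply(alignment$mat, 1, paste, collapse = ""),
                  rownames(alignment$mat))
}

#' Read an aligned FASTA file
#'
#' Parses an aligned FASTA file into a \code{\link{marker_alignment}}.
#' Symbols are normalized: lowercase folded to uppercase, \code{U} mapped to
#' \code{T}, \code{.} mapped to \code{-}. The specimen id is the first
#' whitespace-delimited token of each header; \code{aliases} can remap
#' accession-style labels to voucher ids.
#'
#' @param path Path to a FASTA file with >= 2 aligned records.
#' @param marker_id Marker label attached to the alignment.
#' @param aliases Optional named character vector mapping FASTA labels to
#'   specimen ids.
#' @param position_origin See \code{\link{marker_alignment}}.
#' @return A \code{marker_alignment}.
#' @export
read_alignment <- function(path, marker_id, aliases = NULL,
                           position_origin = 1L) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("cannot parse FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) < 2L)
    stop("FASTA '", path, "' has fewer than 2 records", call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  if (!is.null(aliases)) {
    hit <- ids %in% names(aliases)
    ids[hit] <- unname(aliases[ids[hit]])
  }
  seqs <- stats::setNames(as.character(set), ids)
  marker_alignment(seqs, marker_id = marker_id,
                   position_origin = position_origin)
}

#' Write an alignment to FASTA
#'
#' @param alignment A \code{marker_alignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  set <- Biostrings::BStringSet(alignment_seqs(alignment))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Subset an alignment
#'
#' @param alignment A \code{marker_alignment}.
#' @param specimens Specimen ids to keep (default: all).
#' @param columns 1-based column indices to keep (default: all).
#' @return A \code{marker_alignment}.
#' @export
subset_alignment <- function(alignment, specimens = NULL, columns = NULL) {
  mat <- alignment$mat
  if (!is.null(specimens)) {
    missing <- setdiff(specimens, rownames(mat))
    if (length(missing) > 0L)
      stop("specimens not in alignment: ",
           paste(missing, collapse = ", "), call. = FALSE)
    mat <- mat[specimens, , drop = FALSE]
  }
  if (!is.null(columns)) {
    if (any(columns < 1L | columns > ncol(mat)))
      stop("column indices out of range", call. = FALSE)
    mat <- mat[, columns, drop = FALSE]
  }
  out <- alignment
  out$mat <- mat
  out
}
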