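# Conserved-block masking of alignments, in the style of the classic
# block-selection heuristics used to strip ambiguously aligned regions
# before character extraction, with an index map back to the unmasked
# columns. This is an independent reimplementation of the published block
# rules, not a wrapper; bit-exact parity with any particular masking binary
# is not claimed.

#' Masking parameters
#'
#' @param min_conserved_fraction A column is conserved when its most
#'   frequent non-gap state is carried by strictly more than this fraction
#'   of the sequences (default 0.5, i.e. more than half).
#' @param min_flank_fraction Threshold (>= \code{min_conserved_fraction})
#'   for a column to qualify as a block flank. The relaxed preset sets it
#'   equal to \code{min_conserved_fraction}.
#' @param max_contiguous_nonconserved Maximal run of contiguous
#'   nonconserved columns tolerated inside a block (default 10, the relaxed
#'   setting).
#' @param min_block_length Blocks shorter than this are dropped (default 5,
#'   the relaxed setting).
#' @param gap_policy \code{"NONE"} (any gap disqualifies a column),
#'   \code{"HALF"} (columns with >= 50\% gaps are disqualified; default) or
#'   \code{"ALL"} (gaps never disqualify).
#' @return An object of class \code{masking_params}.
#' @export
masking_params <- function(min_conserved_fraction = 0.5,
                           min_flank_fraction = min_conserved_fraction,
                           max_contiguous_nonconserved = 10L,
                           min_block_length = 5L,
                           gap_policy = c("HALF", "NONE", "ALL")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(min_conserved_fraction > 0, min_conserved_fraction <= 1,
            min_flank_fraction >= min_conserved_fraction,
            min_flank_fraction <= 1,
            max_contiguous_nonconserved >= 1, min_block_length >= 1)
  structure(list(min_conserved_fraction = min_conserved_fraction,
                 min_flank_fraction = min_flank_fraction,
                 max_contiguous_nonconserved =
                   as.integer(max_contiguous_nonconserved),
                 min_block_length = as.integer(min_block_length),
                 gap_policy = gap_policy),
            class = "masking_params")
}

# run-length groups of TRUE stretches: list of index vectors
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(seq, starts[r$values], ends[r$values])
}

#' Mask an alignment to its conserved blocks
#'
#' Columns are classified conserved / nonconserved / gap-violating;
#' maximal runs of nonconserved columns longer than
#' \code{max_contiguous_nonconserved} are removed; the remaining blocks are
#' trimmed so that they start and end on flank-grade columns; blocks
#' shorter than \code{min_block_length} are dropped. Gap-violating columns
#' count as nonconserved and never as flanks.
#'
#' @param alignment A \code{marker_alignment}.
#' @param params A \code{masking_params} object.
#' @return An object of class \code{masking_result}: \code{kept_columns}
#'   (strictly increasing original 1-based columns), \code{masked_alignment}
#'   and \code{params}. Parameters that leave zero columns produce an
#'   empty-result warning, not an error.
#' @export
mask_alignment <- function(alignment, params = masking_params()) {
  mat <- alignment$mat
  n <- nrow(mat)
  nc <- ncol(mat)
  gap_frac <- colSums(mat == "-") / n
  gap_violating <- switch(params$gap_policy,
                          NONE = gap_frac > 0,
                          HALF = gap_frac >= 0.5,
                          ALL  = rep(FALSE, nc))
  alpha <- state_alphabet(alignment)
  residues <- setdiff(alpha, "-")
  cnt <- vapply(residues, function(a) colSums(mat == a), numeric(nc))
  if (nc == 1L) cnt <- matrix(cnt, nrow = 1L)
  top <- apply(cnt, 1L, max)
  conserved <- !gap_violating & top > params$min_conserved_fraction * n
  flank <- conserved & top >= params$min_flank_fraction * n
  keep <- rep(TRUE, nc)
  for (run in true_runs(!conserved))
    if (length(run) > params$max_contiguous_nonconserved) keep[run] <- FALSE
  for (block in true_runs(keep)) {
    fl <- block[flank[block]]
    if (length(fl) == 0L) { keep[block] <- FALSE; next }
    keep[block[block < fl[1L] | block > fl[length(fl)]]] <- FALSE
  }
  for (block in true_runs(keep))
    if (length(block) < params$min_block_length) keep[block] <- FALSE
  kept <- which(keep)
  if (length(kept) == 0L) {
    warning("masking removed every column of '", alignment$marker_id, "'")
    return(structure(list(kept_columns = integer(),
                          masked_alignment = NULL, params = params),
                     class = "masking_result"))
  }
  structure(list(kept_columns = kept,
                 masked_alignment = subset_alignment(alignment,
                                                     columns = kept),
                 params = params),
            class = "masking_result")
}

#' @export
print.masking_result <- function(x, ...) {
  cat("<masking_result> kept ", length(x$kept_columns), " columns\n",
      sep = "")
  invisible(x)
}

#' Remap diagnostics from masked to original coordinates
#'
#' @param diags Diagnosis data frame computed on the masked alignment.
#' @param result The \code{masking_result} that produced that alignment.
#' @return \code{diags} with \code{column} rewritten to the unmasked
#'   alignment's 1-based columns.
#' @export
remap_diagnostics <- function(diags, result) {
  if (nrow(diags) == 0L) return(diags)
  if (any(diags$column < 1L | diags$column > length(result$kept_columns)))
    stop("diagnostic column outside the masked alignment: internal ",
         "inconsistency between diagnosis and masking result",
         call. = FALSE)
  diags$column <- result$kept_columns[diags$column]
  diags
}
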