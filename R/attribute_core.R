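# Column-wise character-attribute classification.
#
# A column state is one of the four bases (or amino-acid letters) or
# DELETION ("-") for an internal gap. Terminal gap runs, Ns and IUPAC
# ambiguity codes are MISSING (NA): an ambiguous base can neither confirm
# presence of a state in the focal taxon nor absence in the others. A
# column is diagnostic for a focal taxon when the focal state(s) occur in
# all its scored specimens and in none of the congeners:
#   HOMOGENEOUS_PURE  - one shared focal state, absent elsewhere
#   HETEROGENEOUS_PURE - 2-3 focal states, all absent elsewhere
#   PRIVATE           - some (not all) focal states absent elsewhere;
#                       computed for information, never emitted in diagnoses.

MISSING_AA <- c("?", "X")

#' State matrix of an alignment
#'
#' Converts the raw symbol matrix into a matrix of character states:
#' bases/residues as themselves, internal gaps as \code{"-"} (DELETION),
#' and MISSING as \code{NA}. Maximal gap runs touching either end of a row
#' are terminal (incomplete reads), hence MISSING, not DELETION. IUPAC
#' ambiguity letters and \code{N} are MISSING for the carrying specimen.
#'
#' @param alignment A \code{marker_alignment}.
#' @return Character matrix of the same shape, with \code{NA} for MISSING.
#' @export
state_matrix <- function(alignment) {
  mat <- alignment$mat
  nc <- ncol(mat)
  amb <- if (alignment$alphabet == "DNA") IUPAC_AMBIG else MISSING_AA
  out <- mat
  out[mat %in% amb] <- NA
  for (i in seq_len(nrow(mat))) {
    nongap <- which(mat[i, ] != "-")
    lo <- nongap[1L]
    hi <- nongap[length(nongap)]
    if (lo > 1L) out[i, seq_len(lo - 1L)] <- NA
    if (hi < nc) out[i, seq(hi + 1L, nc)] <- NA
  }
  out
}

ambiguity_matrix <- function(alignment) {
  amb <- if (alignment$alphabet == "DNA") IUPAC_AMBIG else MISSING_AA
  matrix(alignment$mat %in% amb, nrow = nrow(alignment$mat),
         dimnames = dimnames(alignment$mat))
}

state_alphabet <- function(alignment) {
  if (alignment$alphabet == "DNA") c(DNA_BASES, "-")
  else c(AA_LETTERS, "*", "-")
}

#' Per-taxon state profile of one column
#'
#' @param alignment A \code{marker_alignment}.
#' @param partition A \code{partition_map} covering the alignment.
#' @param column 1-based alignment column.
#' @return An object of class \code{column_profile}: per-taxon multisets of
#'   observed states (MISSING excluded) and per-taxon missing counts.
#'   Outgroup specimens, if any, are pooled under \code{".outgroup"}.
#' @export
column_profile <- function(alignment, partition, column) {
  stopifnot(column >= 1L, column <= n_columns(alignment))
  S <- state_matrix(alignment)[, column]
  taxa <- partition$ingroup
  states <- lapply(taxa, function(tx) {
    v <- S[species_members(partition, tx)]
    v[!is.na(v)]
  })
  names(states) <- taxa
  miss <- vapply(taxa, function(tx)
    sum(is.na(S[species_members(partition, tx)])), 0L)
  if (length(partition$outgroup_specimens) > 0L) {
    v <- S[partition$outgroup_specimens]
    states[[".outgroup"]] <- v[!is.na(v)]
    miss[".outgroup"] <- sum(is.na(v))
  }
  structure(list(column = as.integer(column), states_by_taxon = states,
                 n_missing_by_taxon = miss),
            class = "column_profile")
}

#' Classify one column for a focal taxon
#'
#' @param profile A \code{column_profile}.
#' @param focal Focal taxon label (must be profiled).
#' @param include_outgroup Contrast against the pooled outgroup states as
#'   well (used for genus-level diagnoses).
#' @return A one-row data frame (see \code{\link{diagnose_taxon}}) or
#'   \code{NULL} when the column is not pure for the focal taxon. A column
#'   where the focal taxon has no scored state, or where every contrast
#'   taxon is entirely MISSING ("uncontrasted"), returns \code{NULL}.
#' @export
classify_column <- function(profile, focal, include_outgroup = FALSE) {
  st <- profile$states_by_taxon
  if (!focal %in% names(st)) stop("unknown focal taxon: ", focal,
                                  call. = FALSE)
  others <- setdiff(names(st), c(focal, if (!include_outgroup) ".outgroup"))
  focal_states <- st[[focal]]
  if (length(focal_states) == 0L) return(NULL)          # no data
  other_pool <- unlist(st[others], use.names = FALSE)
  if (length(other_pool) == 0L) return(NULL)            # uncontrasted
  fu <- sort(unique(focal_states))
  absent <- !fu %in% other_pool
  category <- NULL
  if (length(fu) == 1L && absent[1L]) {
    category <- "HOMOGENEOUS_PURE"
  } else if (length(fu) >= 2L && length(fu) <= 3L && all(absent)) {
    category <- "HETEROGENEOUS_PURE"
  } else if (any(absent)) {
    category <- "PRIVATE"
  }
  if (is.null(category)) return(NULL)
  carriers <- ""
  if (category != "HOMOGENEOUS_PURE") {
    nm <- names(focal_states)
    carriers <- paste(nm, focal_states, sep = "=", collapse = ";")
  }
  data.frame(column = profile$column, category = category,
             states = paste(if (category == "PRIVATE") fu[absent] else fu,
                            collapse = ","),
             n_states = if (category == "PRIVATE") sum(absent) else length(fu),
             carriers = carriers, stringsAsFactors = FALSE)
}

# Per-taxon state-count cube: one count matrix (states x columns) per taxon,
# plus non-missing totals. Shared by all focal scans of one alignment.
taxon_state_counts <- function(alignment, partition) {
  S <- state_matrix(alignment)
  alpha <- state_alphabet(alignment)
  taxa <- partition$ingroup
  groups <- lapply(taxa, function(tx) species_members(partition, tx))
  names(groups) <- taxa
  if (length(partition$outgroup_specimens) > 0L)
    groups[[".outgroup"]] <- partition$outgroup_specimens
  counts <- lapply(groups, function(rows) {
    sub <- S[rows, , drop = FALSE]
    cnt <- vapply(alpha, function(a) colSums(sub == a, na.rm = TRUE),
                  numeric(ncol(S)))
    if (ncol(S) == 1L) cnt <- matrix(cnt, nrow = 1L,
                                     dimnames = list(NULL, alpha))
    t(cnt)   # states x columns
  })
  nonmiss <- vapply(groups, function(rows)
    colSums(!is.na(S[rows, , drop = FALSE])), numeric(ncol(S)))
  if (ncol(S) == 1L)
    nonmiss <- matrix(nonmiss, nrow = 1L, dimnames = list(NULL, names(groups)))
  list(S = S, counts = counts, nonmissing = nonmiss, alphabet = alpha,
       groups = groups)
}

empty_diagnosis <- function() {
  data.frame(marker = character(), taxon = character(), column = integer(),
             category = character(), states = character(),
             n_states = integer(), carriers = character(),
             n_specimens = integer(), ref_position = integer(),
             stringsAsFactors = FALSE)
}

diagnose_focal <- function(alignment, partition, focal, cube,
                           contrast_groups, include_private = FALSE,
                           strict_ambiguity = FALSE) {
  alpha <- cube$alphabet
  fc <- cube$counts[[focal]]                      # states x columns
  oc <- Reduce(`+`, cube$counts[contrast_groups]) # pooled contrast counts
  f_nm <- cube$nonmissing[, focal]
  o_nm <- rowSums(cube$nonmissing[, contrast_groups, drop = FALSE])
  n_distinct <- colSums(fc > 0L)
  absent <- (fc > 0L) & (oc == 0L)
  n_absent <- colSums(absent)
  evaluable <- f_nm > 0L & o_nm > 0L
  if (strict_ambiguity) {
    amb <- ambiguity_matrix(alignment)
    contrast_rows <- unlist(cube$groups[contrast_groups], use.names = FALSE)
    evaluable <- evaluable &
      colSums(amb[contrast_rows, , drop = FALSE]) == 0L
  }
  hom <- evaluable & n_distinct == 1L & n_absent == 1L
  het <- evaluable & n_distinct >= 2L & n_distinct <= 3L &
    n_absent == n_distinct
  prv <- evaluable & !hom & !het & n_absent > 0L
  pick <- which(hom | het | if (include_private) prv else FALSE)
  if (length(pick) == 0L) return(empty_diagnosis())
  rows <- lapply(pick, function(j) {
    category <- if (hom[j]) "HOMOGENEOUS_PURE"
                else if (het[j]) "HETEROGENEOUS_PURE" else "PRIVATE"
    sts <- sort(alpha[if (category == "PRIVATE") absent[, j]
                      else fc[, j] > 0L])
    carriers <- ""
    if (category != "HOMOGENEOUS_PURE") {
      members <- cube$groups[[focal]]
      v <- cube$S[members, j]
      keep <- !is.na(v) & if (category == "PRIVATE") v %in% sts else TRUE
      carriers <- paste(members[keep], v[keep], sep = "=", collapse = ";")
    }
    data.frame(marker = alignment$marker_id, taxon = focal,
               column = j, category = category,
               states = paste(sts, collapse = ","),
               n_states = length(sts), carriers = carriers,
               n_specimens = length(cube$groups[[focal]]),
               ref_position = NA_integer_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diagnose one species against all its congeners
#'
#' Scans every alignment column and reports the pure character attributes of
#' the focal species relative to all other ingroup species pooled together
#' (exhaustive comparison; outgroup specimens are left unconsidered).
#' Species represented by a single specimen are allowed; homogeneity is then
#' trivially satisfied and \code{n_specimens} records the sample size.
#'
#' @param alignment A \code{marker_alignment}.
#' @param partition A \code{partition_map}; restricted to the marker first.
#' @param focal Focal species label.
#' @param include_private Also return PRIVATE columns (informational; never
#'   part of a diagnosis).
#' @param strict_ambiguity Disqualify a column when any contrast specimen
#'   carries an ambiguity code there (stricter than the default policy of
#'   scoring ambiguous bases as MISSING).
#' @return Data frame with columns \code{marker}, \code{taxon},
#'   \code{column}, \code{category}, \code{states} (comma-separated;
#'   \code{"-"} is a deletion), \code{n_states}, \code{carriers}
#'   (specimen=state pairs for heterogeneous/private columns),
#'   \code{n_specimens}, \code{ref_position} (NA until filled by
#'   \code{\link{add_ref_positions}}), sorted by column.
#' @export
diagnose_taxon <- function(alignment, partition, focal,
                           include_private = FALSE,
                           strict_ambiguity = FALSE) {
  partition <- partition_for_marker(partition, alignment)
  if (!focal %in% partition$ingroup) {
    warning("species '", focal, "' absent from marker '",
            alignment$marker_id, "'")
    return(empty_diagnosis())
  }
  if (length(partition$ingroup) < 2L)
    stop("need >= 2 ingroup species to diagnose (every variable column ",
         "would be trivially pure)", call. = FALSE)
  cube <- taxon_state_counts(alignment, partition)
  out <- diagnose_focal(alignment, partition, focal, cube,
                        contrast_groups = setdiff(partition$ingroup, focal),
                        include_private = include_private,
                        strict_ambiguity = strict_ambiguity)
  out[order(out$column), , drop = FALSE]
}

#' Diagnose every species of the ingroup
#'
#' Applies \code{\link{diagnose_taxon}} to each ingroup species in turn:
#' the per-node comparisons of a tree-based scan are replaced by direct
#' exhaustive comparison of each species against all congeners, which is
#' the intended semantics.
#'
#' @inheritParams diagnose_taxon
#' @return One data frame (rbind of the per-species results), sorted by
#'   taxon then column.
#' @export
diagnose_all <- function(alignment, partition, include_private = FALSE,
                         strict_ambiguity = FALSE) {
  partition <- partition_for_marker(partition, alignment)
  if (length(partition$ingroup) < 2L)
    stop("need >= 2 ingroup species to diagnose", call. = FALSE)
  cube <- taxon_state_counts(alignment, partition)
  res <- lapply(sort(partition$ingroup), function(tx)
    diagnose_focal(alignment, partition, tx, cube,
                   contrast_groups = setdiff(partition$ingroup, tx),
                   include_private = include_private,
                   strict_ambiguity = strict_ambiguity))
  out <- do.call(rbind, res)
  out <- out[order(out$taxon, out$column), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diagnose the whole ingroup against outgroup specimens
#'
#' Treats all ingroup specimens as a single focal group and the outgroup
#' specimens as its "congeners" (a genus-level diagnosis). Classification
#' rules are identical to the species-level scan.
#'
#' @inheritParams diagnose_taxon
#' @return Data frame as in \code{\link{diagnose_taxon}} with
#'   \code{taxon = ".group"}.
#' @export
diagnose_group <- function(alignment, partition, include_private = FALSE,
                           strict_ambiguity = FALSE) {
  partition <- partition_for_marker(partition, alignment)
  if (length(partition$outgroup_specimens) == 0L)
    stop("group diagnosis requires a nonempty outgroup", call. = FALSE)
  merged <- partition_map(
    stats::setNames(rep(".group", length(partition$species_of)),
                    names(partition$species_of)),
    outgroup_specimens = partition$outgroup_specimens)
  cube <- taxon_state_counts(alignment, merged)
  out <- diagnose_focal(alignment, merged, ".group", cube,
                        contrast_groups = ".outgroup",
                        include_private = include_private,
                        strict_ambiguity = strict_ambiguity)
  out[order(out$column), , drop = FALSE]
}
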