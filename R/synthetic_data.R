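# Simulated multi-marker alignments with planted species-fixed differences
# and a ground-truth ledger, so every pipeline stage can be validated
# without external data. The generator emulates the statistical structure
# the analysis assumes: per-species clusters of near-identical sequences
# separated by fixed substitutions, species-fixed indels, intraspecific
# polymorphism, per-specimen missing markers and IUPAC ambiguity noise.
# The background substitution model is uniform over the three alternative
# bases -- sufficient for correctness testing, not a biological model.

#' Simulation configuration
#'
#' Defaults mirror the structure of a small cryptic-species radiation
#' sampled for four standard markers: 12 species with uneven sample sizes
#' (five singletons), two nuclear rRNA markers, one mitochondrial rRNA
#' marker and one protein-coding mitochondrial marker.
#'
#' @param n_species Number of ingroup species.
#' @param specimens_per_species Integer vector (recycled) of specimens per
#'   species; singletons allowed.
#' @param markers List of \code{list(name, length, coding)} marker
#'   descriptors. Coding markers must have length divisible by 3.
#' @param planted_diffs_per_species_per_marker Species-fixed substitutions
#'   planted per species per marker.
#' @param planted_deletion_length Length of the one species-fixed deletion
#'   run planted per species per marker (0 = none; forced to a multiple of
#'   3 on coding markers).
#' @param planted_insertion_length Length of the one species-specific
#'   insertion block planted per species per marker (0 = none; multiple of
#'   3 on coding markers).
#' @param intraspecific_polymorphism_rate Per-site per-specimen probability
#'   of a substitution away from the species consensus.
#' @param indel_rate Expected per-site rate of specimen-level deletion
#'   runs.
#' @param mean_indel_length Mean specimen-level deletion run length.
#' @param missing_marker_rate Probability that a specimen lacks a marker
#'   entirely.
#' @param ambiguity_rate Per-site probability of replacing a base by an
#'   IUPAC ambiguity code compatible with it.
#' @param seed Integer RNG seed; the whole bundle is reproducible
#'   byte-for-byte under it.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_species = 12L,
                       specimens_per_species = c(5L, 10L, 7L, 1L, 3L, 1L,
                                                 2L, 4L, 4L, 1L, 1L, 1L),
                       markers = list(
                         list(name = "18S", length = 1800L, coding = FALSE),
                         list(name = "28S", length = 900L,  coding = FALSE),
                         list(name = "16S", length = 410L,  coding = FALSE),
                         list(name = "COI", length = 657L,  coding = TRUE)),
                       planted_diffs_per_species_per_marker = 4L,
                       planted_deletion_length = 3L,
                       planted_insertion_length = 3L,
                       intraspecific_polymorphism_rate = 0.002,
                       indel_rate = 5e-4,
                       mean_indel_length = 3,
                       missing_marker_rate = 0.15,
                       ambiguity_rate = 0.001,
                       seed = 1L) {
  stopifnot(n_species >= 2L,
            planted_diffs_per_species_per_marker >= 0L,
            intraspecific_polymorphism_rate >= 0,
            intraspecific_polymorphism_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            missing_marker_rate >= 0, missing_marker_rate <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1)
  spp <- rep_len(as.integer(specimens_per_species), n_species)
  for (mk in markers) {
    stopifnot(mk$length >= 30L)
    if (isTRUE(mk$coding) && mk$length %% 3L != 0L)
      stop("coding marker '", mk$name, "' length not divisible by 3",
           call. = FALSE)
    need <- n_species * (planted_diffs_per_species_per_marker +
                           planted_deletion_length + 4L)
    if (need > mk$length - 30L)
      stop("marker '", mk$name, "' too short for the requested planted ",
           "differences", call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species),
                 specimens_per_species = spp,
                 markers = markers,
                 planted_diffs_per_species_per_marker =
                   as.integer(planted_diffs_per_species_per_marker),
                 planted_deletion_length =
                   as.integer(planted_deletion_length),
                 planted_insertion_length =
                   as.integer(planted_insertion_length),
                 intraspecific_polymorphism_rate =
                   intraspecific_polymorphism_rate,
                 indel_rate = indel_rate,
                 mean_indel_length = mean_indel_length,
                 missing_marker_rate = missing_marker_rate,
                 ambiguity_rate = ambiguity_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' A noiseless variant of a simulation configuration
#'
#' Sets polymorphism, specimen indels, missing markers and ambiguity noise
#' to zero (the regime in which recovery must be exact).
#'
#' @param config A \code{sim_config}.
#' @return A \code{sim_config}.
#' @export
noiseless_config <- function(config = sim_config()) {
  config$intraspecific_polymorphism_rate <- 0
  config$indel_rate <- 0
  config$missing_marker_rate <- 0
  config$ambiguity_rate <- 0
  config
}

other_bases <- function(b) DNA_BASES[DNA_BASES != b]

# stop codons across the mitochondrial and standard tables; avoided when
# generating coding sequence so a clean reading frame exists
STOP_CODONS <- c("TAA", "TAG", "TGA")

# coding-frame sequence: codons drawn uniformly from the non-stop codons
sample_coding_bases <- function(len) {
  stopifnot(len %% 3L == 0L)
  out <- character(len)
  for (i in seq(1L, len, by = 3L)) {
    repeat {
      codon <- sample(DNA_BASES, 3L, replace = TRUE)
      if (!paste(codon, collapse = "") %in% STOP_CODONS) break
    }
    out[i:(i + 2L)] <- codon
  }
  out
}

# base substitution at root position cc that does not create a stop codon
# in the (frame-0) codon containing it
nonstop_substitution <- function(root, cc) {
  cand <- sample(other_bases(root[cc]))
  start <- cc - (cc - 1L) %% 3L
  for (st in cand) {
    codon <- root[start:(start + 2L)]
    codon[cc - start + 1L] <- st
    if (!paste(codon, collapse = "") %in% STOP_CODONS) return(st)
  }
  cand[1L]   # unreachable: every position has a non-stop alternative
}

AMBIG_FOR <- list(A = c("R", "W", "M", "N"), C = c("Y", "S", "M", "N"),
                  G = c("R", "S", "K", "N"), T = c("Y", "W", "K", "N"))

# sample that never treats a scalar x as 1:x
sample_from <- function(x, size) x[sample.int(length(x), size)]

#' Simulate a multi-marker dataset with planted diagnostics
#'
#' Draws a uniform root sequence per marker, plants per-species fixed
#' substitutions (states verified unique across species at generation
#' time), one species-fixed deletion run and one species-specific insertion
#' block per species per marker, then applies specimen-level noise. The
#' returned truth ledger records every planted column/state; entries broken
#' by later noise (collisions, missing species) are flagged inactive so
#' that active truth equals the exact expected set of homogeneous pure
#' characters.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{alignments} (named list of
#'   \code{marker_alignment}), \code{partition} (a \code{partition_map}
#'   with per-marker reference fallbacks), \code{truth} (data frame:
#'   species, marker, column, state, origin, active, reason) and
#'   \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  species <- sprintf("sp%02d", seq_len(config$n_species))
  spec_ids <- unlist(lapply(seq_along(species), function(i)
    sprintf("%s_v%02d", species[i],
            seq_len(config$specimens_per_species[i]))))
  species_of <- stats::setNames(
    rep(species, config$specimens_per_species), spec_ids)

  alignments <- list()
  truth <- list()
  by_marker_refs <- stats::setNames(
    replicate(length(species), list(), simplify = FALSE), species)

  for (mk in config$markers) {
    gen <- simulate_marker(mk, species, species_of, config)
    alignments[[mk$name]] <- gen$alignment
    truth[[mk$name]] <- gen$truth
    for (tx in species)
      by_marker_refs[[tx]][[mk$name]] <- gen$marker_ref[[tx]]
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  refs <- stats::setNames(
    vapply(species, function(tx)
      names(species_of)[species_of == tx][1L], ""), species)
  partition <- partition_map(species_of, refs)
  attr(partition$reference_specimen, "by_marker") <- by_marker_refs

  truth <- audit_truth(truth, alignments, partition)
  list(alignments = alignments, partition = partition, truth = truth,
       config = config)
}

simulate_marker <- function(mk, species, species_of, config) {
  L <- mk$length
  coding <- isTRUE(mk$coding)
  nsub <- config$planted_diffs_per_species_per_marker
  dlen <- config$planted_deletion_length
  if (coding && dlen > 0L) dlen <- max(3L, 3L * (dlen %/% 3L))
  ilen <- config$planted_insertion_length
  if (coding && ilen > 0L) ilen <- max(3L, 3L * (ilen %/% 3L))
  margin <- 15L
  root <- if (coding) sample_coding_bases(L) else
    sample(DNA_BASES, L, replace = TRUE)

  occupied <- logical(L)
  occupied[c(seq_len(margin), seq(L - margin + 1L, L))] <- TRUE
  pick_run <- function(len, codon_start = FALSE) {
    for (try in 1:2000) {
      s <- sample.int(L - len, 1L)
      if (codon_start) s <- s - (s - 1L) %% 3L
      run <- s:(s + len - 1L)
      if (!any(occupied[run])) { occupied[run] <<- TRUE; return(run) }
    }
    stop("cannot place planted differences: marker too crowded",
         call. = FALSE)
  }

  sub_cols <- lapply(species, function(tx)
    vapply(seq_len(nsub), function(i) pick_run(1L)[1L], 0L))
  del_runs <- if (dlen > 0L)
    lapply(species, function(tx) pick_run(dlen, codon_start = coding))
  else lapply(species, function(tx) integer())
  pick_anchor <- function() {
    for (try in 1:2000) {
      a <- sample.int(L - 2L * margin, 1L) + margin
      if (coding) a <- a - a %% 3L    # insert after a codon boundary
      if (a > margin && a < L - margin && !occupied[a] &&
          !occupied[a + 1L]) {
        occupied[a:(a + 1L)] <<- TRUE
        return(a)
      }
    }
    stop("cannot place insertion anchors: marker too crowded",
         call. = FALSE)
  }
  ins_anchors <- if (ilen > 0L) lapply(species, function(tx) pick_anchor())
  else lapply(species, function(tx) integer())
  names(sub_cols) <- names(del_runs) <- names(ins_anchors) <- species

  # final layout: root columns plus insertion blocks after their anchors
  anchors <- sort(unlist(ins_anchors))
  final_of_root <- seq_len(L)
  for (a in anchors) final_of_root[(a + 1L):L] <-
    final_of_root[(a + 1L):L] + ilen
  nF <- L + length(anchors) * ilen
  ins_cols <- stats::setNames(lapply(species, function(tx) {
    if (length(ins_anchors[[tx]]) == 0L) return(integer())
    a <- ins_anchors[[tx]]
    (final_of_root[a] + 1L):(final_of_root[a] + ilen)
  }), species)

  # species consensus rows in final coordinates
  base_row <- rep("-", nF)
  base_row[final_of_root] <- root
  consensus <- list()
  truth <- list()
  for (tx in species) {
    row <- base_row
    for (cc in sub_cols[[tx]]) {
      st <- if (coding) nonstop_substitution(root, cc)
            else sample_from(other_bases(root[cc]), 1L)
      row[final_of_root[cc]] <- st
      truth[[length(truth) + 1L]] <- data.frame(
        species = tx, marker = mk$name, column = final_of_root[cc],
        state = st, origin = "substitution", stringsAsFactors = FALSE)
    }
    if (length(del_runs[[tx]]) > 0L) {
      fcols <- final_of_root[del_runs[[tx]]]
      row[fcols] <- "-"
      for (fc in fcols)
        truth[[length(truth) + 1L]] <- data.frame(
          species = tx, marker = mk$name, column = fc, state = "-",
          origin = "deletion", stringsAsFactors = FALSE)
    }
    if (length(ins_cols[[tx]]) > 0L) {
      ins_states <- if (coding) sample_coding_bases(length(ins_cols[[tx]]))
                    else sample(DNA_BASES, length(ins_cols[[tx]]),
                                replace = TRUE)
      row[ins_cols[[tx]]] <- ins_states
      for (k in seq_along(ins_cols[[tx]]))
        truth[[length(truth) + 1L]] <- data.frame(
          species = tx, marker = mk$name, column = ins_cols[[tx]][k],
          state = ins_states[k], origin = "insertion",
          stringsAsFactors = FALSE)
    }
    consensus[[tx]] <- row
  }
  # insertion columns of other species stay "-" (internal deletions there)

  # specimen rows with noise
  ids <- names(species_of)
  keep <- stats::setNames(rep(TRUE, length(ids)), ids)
  if (config$missing_marker_rate > 0) {
    drop <- stats::runif(length(ids)) < config$missing_marker_rate
    # never drop below 2 represented species
    for (i in which(drop)) {
      left <- unique(species_of[keep & !(ids == ids[i])])
      if (length(left) >= 2L) keep[i] <- FALSE
    }
  }
  rows <- list()
  for (id in ids[keep]) {
    row <- consensus[[species_of[[id]]]]
    bases <- which(row %in% DNA_BASES)
    if (config$intraspecific_polymorphism_rate > 0) {
      hit <- bases[stats::runif(length(bases)) <
                     config$intraspecific_polymorphism_rate]
      for (h in hit) row[h] <- sample_from(other_bases(row[h]), 1L)
    }
    if (config$indel_rate > 0) {
      n_ind <- stats::rpois(1L, config$indel_rate * length(bases))
      for (k in seq_len(n_ind)) {
        len <- 1L + stats::rpois(1L, max(config$mean_indel_length - 1, 0))
        if (coding) len <- 3L * max(1L, round(len / 3))
        s <- sample.int(nF - len - 2L * 15L, 1L) + 15L
        if (coding) s <- s - (s - 1L) %% 3L
        row[s:(s + len - 1L)] <- "-"
      }
    }
    if (config$ambiguity_rate > 0) {
      bases <- which(row %in% DNA_BASES)
      hit <- bases[stats::runif(length(bases)) < config$ambiguity_rate]
      for (h in hit) row[h] <- sample_from(AMBIG_FOR[[row[h]]], 1L)
    }
    rows[[id]] <- paste(row, collapse = "")
  }
  aln <- marker_alignment(unlist(rows), marker_id = mk$name)
  marker_ref <- stats::setNames(lapply(species, function(tx) {
    present <- intersect(ids[keep], names(species_of)[species_of == tx])
    if (length(present) == 0L) NULL else present[1L]
  }), species)
  list(alignment = aln, truth = do.call(rbind, truth),
       marker_ref = marker_ref)
}

#' Re-audit a truth ledger against (possibly edited) alignments
#'
#' Recomputes, for every planted entry, whether it still defines a
#' homogeneous pure character: the species must be present in the marker,
#' every scored focal specimen must carry the planted state at the column,
#' no non-focal ingroup specimen may carry it, and at least one non-focal
#' specimen must be scored there. Entries failing these checks are flagged
#' inactive with a reason (\code{"absent"}, \code{"collision"}).
#'
#' @param truth Truth data frame (see \code{\link{simulate_dataset}}).
#' @param alignments Named list of \code{marker_alignment}.
#' @param partition A \code{partition_map}.
#' @return \code{truth} with \code{active} and \code{reason} columns.
#' @export
audit_truth <- function(truth, alignments, partition) {
  truth$active <- TRUE
  truth$reason <- ""
  for (mname in unique(truth$marker)) {
    aln <- alignments[[mname]]
    S <- state_matrix(aln)
    pm <- partition_for_marker(partition, aln)
    idx <- which(truth$marker == mname)
    for (i in idx) {
      tx <- truth$species[i]
      cc <- truth$column[i]
      st <- truth$state[i]
      if (!tx %in% pm$ingroup) {
        truth$active[i] <- FALSE; truth$reason[i] <- "absent"; next
      }
      members <- species_members(pm, tx)
      others <- setdiff(rownames(S), members)
      fv <- S[members, cc]
      fv <- fv[!is.na(fv)]
      ov <- S[others, cc]
      ov <- ov[!is.na(ov)]
      ok <- length(fv) > 0L && all(fv == st) && length(ov) > 0L &&
        !st %in% ov
      if (!ok) {
        truth$active[i] <- FALSE
        truth$reason[i] <- if (length(fv) == 0L || length(ov) == 0L)
          "absent" else "collision"
      }
    }
  }
  truth
}

#' Gap-shift variant of an alignment
#'
#' Produces an alternative alignment of the same sequences by inserting
#' blocks of all-gap columns between gap-free column pairs (as an aligner
#' confronted with extra sequences would). No base changes: every row's
#' degapped sequence is unchanged, column numbering shifts downstream of
#' each block, and reference-keyed diagnostic sets are provably identical.
#'
#' @param alignment A \code{marker_alignment}.
#' @param n_blocks Number of all-gap blocks to insert.
#' @param block_length Columns per block (use a multiple of 3 on coding
#'   markers to preserve the reading frame).
#' @return A \code{marker_alignment} with shifted coordinates.
#' @export
gap_shift_variant <- function(alignment, n_blocks = 3L, block_length = 3L) {
  mat <- alignment$mat
  nc <- ncol(mat)
  gapfree <- colSums(mat == "-") == 0L
  # boundaries between two adjacent gap-free columns, at codon boundaries
  cand <- which(gapfree[-nc] & gapfree[-1L])
  cand <- cand[cand %% 3L == 0L & cand > 15L & cand < nc - 15L]
  if (length(cand) < n_blocks)
    stop("not enough gap-free column pairs to shift", call. = FALSE)
  at <- sort(sample_from(cand, n_blocks))
  out <- matrix("-", nrow = nrow(mat), ncol = nc + n_blocks * block_length,
                dimnames = list(rownames(mat), NULL))
  src <- seq_len(nc)
  dest <- src
  for (a in at) dest[src > a] <- dest[src > a] + block_length
  out[, dest] <- mat
  res <- alignment
  res$mat <- out
  res
}

#' Recovery of planted diagnostics
#'
#' Matches found homogeneous pure characters against the active truth
#' ledger on (species, marker, reference position, state): both sides are
#' re-keyed through the reference frames of their own alignments, so the
#' metrics are invariant to re-alignment. Inactive truth entries are
#' excluded from the recall denominator, and found entries matching them
#' are excluded from the precision denominator.
#'
#' @param found Diagnosis data frame (any markers; only HOMOGENEOUS_PURE
#'   rows are scored).
#' @param truth Truth ledger with \code{active} flags (see
#'   \code{\link{audit_truth}}).
#' @param alignments Named list of alignments the diagnoses were computed
#'   on (for reference frames).
#' @param partition A \code{partition_map}.
#' @param truth_alignments Alignments the truth columns refer to (default:
#'   \code{alignments}).
#' @param kept_columns Optional named list (per marker) of surviving
#'   columns of a masking step, used to label missed entries whose column
#'   was masked out.
#' @return List with \code{per_species} (species x marker precision and
#'   recall), \code{overall} (pooled precision and recall) and
#'   \code{detail} (per truth entry: recovered flag and cause).
#' @export
evaluate_recovery <- function(found, truth, alignments, partition,
                              truth_alignments = alignments,
                              kept_columns = NULL) {
  found <- found[found$category == "HOMOGENEOUS_PURE", , drop = FALSE]
  key_one <- function(df, alns) {
    keys <- rep(NA_character_, nrow(df))
    for (mname in unique(df$marker)) {
      aln <- alns[[mname]]
      pm <- partition_for_marker(partition, aln)
      frames <- reference_frames(aln, pm)
      idx <- which(df$marker == mname & df$taxon %in% names(frames))
      if (length(idx) == 0L) next
      rk <- to_ref_keys(df[idx, , drop = FALSE], frames)
      keys[idx] <- paste(rk$taxon, rk$marker, rk$key, sep = "|")
    }
    keys
  }
  found_keys <- if (nrow(found) > 0L) key_one(found, alignments)
                else character()
  found_keys <- found_keys[!is.na(found_keys)]
  tr <- truth
  pseudo <- data.frame(marker = tr$marker, taxon = tr$species,
                       column = tr$column, states = tr$state,
                       category = "TRUTH", stringsAsFactors = FALSE)
  truth_keys <- key_one(pseudo, truth_alignments)
  tr$key <- truth_keys
  tr$recovered <- tr$active & truth_keys %in% found_keys
  tr$cause <- ""
  miss <- which(tr$active & !tr$recovered)
  if (length(miss) > 0L) {
    tr$cause[miss] <- "missed"
    if (!is.null(kept_columns))
      for (i in miss)
        if (!tr$column[i] %in% kept_columns[[tr$marker[i]]])
          tr$cause[i] <- "masked"
  }
  inactive_keys <- tr$key[!tr$active]
  scored_found <- setdiff(found_keys, inactive_keys)
  tp_keys <- intersect(scored_found, tr$key[tr$active])
  cells <- unique(tr[tr$active, c("species", "marker")])
  per <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    sel <- tr$active & tr$species == cells$species[r] &
      tr$marker == cells$marker[r]
    fkeys <- scored_found[startsWith(
      scored_found, paste0(cells$species[r], "|", cells$marker[r], "|"))]
    tkeys <- unique(tr$key[sel])    # deletion-run columns share one key
    n_tp <- sum(fkeys %in% tkeys)
    data.frame(species = cells$species[r], marker = cells$marker[r],
               n_truth = length(tkeys), n_found = length(fkeys),
               tp = n_tp,
               precision = if (length(fkeys) == 0L) NA_real_
                           else n_tp / length(fkeys),
               recall = n_tp / length(tkeys), stringsAsFactors = FALSE)
  }))
  overall <- list(
    precision = if (length(scored_found) == 0L) NA_real_
                else length(tp_keys) / length(scored_found),
    recall = if (sum(tr$active) == 0L) NA_real_
             else sum(tr$recovered) / sum(tr$active))
  list(per_species = per, overall = overall, detail = tr)
}
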