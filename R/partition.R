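# Specimen -> species partition, with per-species reference specimens and
# an optional outgroup specimen set.

#' Construct a partition map
#'
#' Assigns every specimen either to exactly one ingroup species or to the
#' outgroup set, and names a reference specimen per species (used for
#' reference-sequence coordinates).
#'
#' @param species_of Named character vector: specimen id -> species label.
#' @param reference_specimen Named character vector: species label ->
#'   specimen id. May omit species (then no reference coordinates are
#'   available for them); per-marker fallbacks are resolved in
#'   \code{\link{partition_for_marker}}.
#' @param outgroup_specimens Character vector of specimen ids outside the
#'   focal group (may be empty).
#' @return An object of class \code{partition_map}.
#' @export
partition_map <- function(species_of, reference_specimen = character(),
                          outgroup_specimens = character()) {
  if (length(species_of) > 0 &&
      (is.null(names(species_of)) || any(names(species_of) == "")))
    stop("species_of must be a named vector (specimen -> species)",
         call. = FALSE)
  dup <- intersect(names(species_of), outgroup_specimens)
  if (length(dup) > 0L)
    stop("specimens assigned both to a species and to the outgroup: ",
         paste(dup, collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(species_of)))
    stop("specimens assigned to more than one species: ",
         paste(unique(names(species_of)[duplicated(names(species_of))]),
               collapse = ", "), call. = FALSE)
  bad_ref <- reference_specimen[!reference_specimen %in% names(species_of)]
  if (length(bad_ref) > 0L)
    stop("reference specimens not assigned to their species: ",
         paste(bad_ref, collapse = ", "), call. = FALSE)
  structure(list(species_of = species_of,
                 reference_specimen = reference_specimen,
                 ingroup = sort(unique(unname(species_of))),
                 outgroup_specimens = outgroup_specimens),
            class = "partition_map")
}

#' @export
print.partition_map <- function(x, ...) {
  cat("<partition_map> ", length(x$ingroup), " species, ",
      length(x$species_of), " ingroup specimens, ",
      length(x$outgroup_specimens), " outgroup specimens\n", sep = "")
  invisible(x)
}

#' Load a partition configuration
#'
#' Reads a YAML partition file and validates it against an alignment. The
#' file lists species blocks (name, specimens, reference), an optional
#' \code{outgroup} specimen list and an optional \code{aliases} map.
#' Specimens listed in the config but absent from the alignment are silently
#' dropped for this marker (a specimen need not have every marker); aligned
#' specimens missing from the config are an error.
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @param alignment Optional \code{marker_alignment} to validate coverage
#'   against and to restrict the map to.
#' @return A \code{partition_map}.
#' @export
load_partition <- function(config, alignment = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$species) || length(cfg$species) == 0L)
    stop("partition config has no species blocks", call. = FALSE)
  species_of <- character()
  refs <- character()
  for (blk in cfg$species) {
    if (is.null(blk$name) || is.null(blk$specimens))
      stop("each species block needs 'name' and 'specimens'", call. = FALSE)
    sp <- as.character(blk$specimens)
    # append (not names<-assign) so duplicate assignments are detectable
    species_of <- c(species_of, stats::setNames(rep(blk$name, length(sp)),
                                                sp))
    if (!is.null(blk$reference)) refs[blk$name] <- blk$reference
    if (!is.null(blk$reference_by_marker))
      attr(refs, "by_marker") <- c(attr(refs, "by_marker"),
                                   stats::setNames(list(blk$reference_by_marker),
                                                   blk$name))
  }
  out <- as.character(cfg$outgroup %||% character())
  pm <- partition_map(species_of, refs, out)
  attr(pm$reference_specimen, "by_marker") <- attr(refs, "by_marker")
  if (!is.null(alignment)) pm <- partition_for_marker(pm, alignment)
  pm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict a partition map to the specimens of one marker
#'
#' Drops specimens absent from the marker's alignment, re-resolves reference
#' specimens (using per-marker fallbacks where the designated reference
#' lacks this marker) and errors on aligned specimens the partition does not
#' cover.
#'
#' @param partition A \code{partition_map}.
#' @param alignment A \code{marker_alignment}.
#' @return A \code{partition_map} covering exactly the aligned specimens.
#' @export
partition_for_marker <- function(partition, alignment) {
  ids <- specimen_ids(alignment)
  known <- c(names(partition$species_of), partition$outgroup_specimens)
  unassigned <- setdiff(ids, known)
  if (length(unassigned) > 0L)
    stop("aligned specimens not covered by the partition: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  sp <- partition$species_of[names(partition$species_of) %in% ids]
  out <- intersect(partition$outgroup_specimens, ids)
  by_marker <- attr(partition$reference_specimen, "by_marker")
  refs <- character()
  for (taxon in unique(unname(sp))) {
    members <- names(sp)[sp == taxon]
    ref <- unname(partition$reference_specimen[taxon])
    if (!is.na(ref) && !is.null(ref) && ref %in% members) {
      refs[taxon] <- ref
      next
    }
    fb <- by_marker[[taxon]][[alignment$marker_id]]
    if (is.null(fb))   # translated markers inherit the DNA marker's fallback
      fb <- by_marker[[taxon]][[sub("_AA$", "", alignment$marker_id)]]
    if (!is.null(fb) && fb %in% members) {
      refs[taxon] <- fb
    } else if (length(members) == 1L) {
      refs[taxon] <- members   # singleton: the only specimen is the reference
    } else if (!is.null(ref) && !is.na(ref)) {
      stop("species '", taxon, "': designated reference specimen '", ref,
           "' lacks marker '", alignment$marker_id,
           "' and no per-marker fallback is configured", call. = FALSE)
    }
  }
  partition_map(sp, refs, out)
}

#' Specimens belonging to one species
#' @param partition A \code{partition_map}.
#' @param taxon Species label.
#' @export
species_members <- function(partition, taxon) {
  names(partition$species_of)[partition$species_of == taxon]
}
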