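# Rendering species diagnoses in the dual-coordinate table format, TSV
# export of raw classifications, and the end-to-end pipeline driver.

state_label <- function(state) ifelse(state == "-", "deletion", state)

# "145 (146), C" / "235, deletion" for a homogeneous row;
# heterogeneous rows annotate minority carriers:
# "351 (381), T (G in ZSM Mol 20080953, position 381)"
format_entry <- function(row, frame = NULL) {
  pos <- format_position(row$column, row$ref_position)
  if (row$category == "HOMOGENEOUS_PURE")
    return(paste0(pos, ", ", state_label(row$states)))
  pairs <- strsplit(strsplit(row$carriers, ";")[[1]], "=")
  ids <- vapply(pairs, `[`, "", 1L)
  sts <- vapply(pairs, `[`, "", 2L)
  tab <- sort(table(sts), decreasing = TRUE)
  major <- names(tab)[1L]
  notes <- vapply(setdiff(names(tab), major), function(s) {
    who <- ids[sts == s]
    refpos <- if (!is.na(row$ref_position)) row$ref_position
              else row$column
    paste0(state_label(s), " in ", paste(who, collapse = ", "),
           ", position ", refpos)
  }, "")
  paste0(pos, ", ", state_label(major),
         if (length(notes) > 0L) paste0(" (", paste(notes, collapse = "; "),
                                        ")"))
}

#' Render species diagnoses as markdown tables
#'
#' One table per species; one row per marker with the homogeneous pure
#' entries in dual "alignment (reference)" notation, plus a separate column
#' for heterogeneous single pure positions with carrier annotations.
#' Markers without diagnostic characters are shown as \code{"-"}.
#'
#' @param diags Diagnosis data frame (ref positions filled where
#'   available), covering one or more markers; amino-acid level rows use
#'   the translated marker id (e.g. \code{"COI_AA"}).
#' @param markers Marker display order (default: order of appearance).
#' @return Named character vector of markdown table strings per taxon.
#' @export
render_diagnosis <- function(diags, markers = unique(diags$marker)) {
  taxa <- sort(unique(diags$taxon))
  out <- character()
  for (tx in taxa) {
    lines <- c(paste0("### Molecular diagnosis of ", tx), "",
               paste("| Marker | Diagnostic characters with position in",
                     "alignment (in reference sequence) |",
                     "Heterogeneous single pure positions |"),
               "| --- | --- | --- |")
    for (mk in markers) {
      sub <- diags[diags$taxon == tx & diags$marker == mk, , drop = FALSE]
      hom <- sub[sub$category == "HOMOGENEOUS_PURE", , drop = FALSE]
      het <- sub[sub$category == "HETEROGENEOUS_PURE", , drop = FALSE]
      cell <- function(d) {
        if (nrow(d) == 0L) return("-")
        paste(vapply(seq_len(nrow(d)),
                     function(i) format_entry(d[i, ]), ""),
              collapse = "; ")
      }
      lines <- c(lines, paste0("| ", mk, " | ", cell(hom), " | ",
                               cell(het), " |"))
    }
    out[tx] <- paste(lines, collapse = "\n")
  }
  out
}

#' Write raw classifications to TSV
#'
#' @param diags Diagnosis data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_classifications <- function(diags, path) {
  utils::write.table(diags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a classifications TSV
#'
#' Inverse of \code{\link{write_classifications}} (round-trips the
#' diagnosis data frame).
#'
#' @param path TSV path.
#' @return Diagnosis data frame.
#' @export
read_classifications <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(marker = "character",
                                         taxon = "character",
                                         column = "integer",
                                         category = "character",
                                         states = "character",
                                         n_states = "integer",
                                         carriers = "character",
                                         n_specimens = "integer",
                                         ref_position = "integer"),
                          na.strings = "", stringsAsFactors = FALSE)
  df$carriers[is.na(df$carriers)] <- ""
  df
}

#' Run the whole diagnosis pipeline from a configuration
#'
#' Reads per-marker alignments and the partition, optionally masks each
#' alignment, diagnoses every species (nucleotide level, plus amino-acid
#' level for coding markers), fills reference coordinates, and writes an
#' artifact bundle: classifications TSV, per-species markdown tables and a
#' provenance log (input checksums, parameters). Deterministic: rerunning
#' the same configuration reproduces the bundle byte for byte.
#'
#' @param config Path to a YAML file or an equivalent list with elements
#'   \code{markers} (list of \code{id}, \code{fasta}, optional
#'   \code{coding}), \code{partition} (path or list), optional
#'   \code{offsets} (taxon -> leading offset, per marker), optional
#'   \code{masking} (masking_params arguments or \code{NULL}) and
#'   \code{outdir}.
#' @param outdir Overrides \code{config$outdir}.
#' @return Invisible list with \code{diagnoses}, \code{tables},
#'   \code{alignments} and the output paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  outdir <- outdir %||% cfg$outdir
  if (is.null(outdir)) stop("no output directory configured", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  partition <- load_partition(cfg$partition)
  mask_par <- if (!is.null(cfg$masking))
    do.call(masking_params, cfg$masking)
  log <- c(paste0("chardiag ", as.character(utils::packageVersion("chardiag"))),
           paste0("R ", R.version.string))
  all_diags <- list()
  alignments <- list()
  for (mk in cfg$markers) {
    aln <- read_alignment(mk$fasta, mk$id)
    log <- c(log, paste0("marker ", mk$id, ": ", mk$fasta, " md5=",
                         unname(tools::md5sum(mk$fasta)), " (",
                         nrow(aln$mat), " x ", ncol(aln$mat), ")"))
    mask_res <- NULL
    work <- aln
    if (!is.null(mask_par)) {
      mask_res <- mask_alignment(aln, mask_par)
      if (length(mask_res$kept_columns) == 0L) next
      work <- mask_res$masked_alignment
      log <- c(log, paste0("  masking kept ",
                           length(mask_res$kept_columns), "/",
                           ncol(aln$mat), " columns"))
    }
    pm <- partition_for_marker(partition, work)
    d <- diagnose_all(work, pm)
    if (!is.null(mask_res)) d <- remap_diagnostics(d, mask_res)
    offsets <- cfg$offsets[[mk$id]]
    frames <- reference_frames(aln, partition, offsets = offsets)
    d <- add_ref_positions(d, frames)
    all_diags[[mk$id]] <- d
    alignments[[mk$id]] <- aln
    if (isTRUE(mk$coding)) {
      frame <- infer_reading_frame(aln)
      log <- c(log, paste0("  reading frame ", frame$frame_shift,
                           " (genetic code ", frame$genetic_code_id, ")"))
      aa <- translate_rows(aln, frame)
      daa <- diagnose_all(aa, partition_for_marker(partition, aa))
      aa_frames <- reference_frames(aa, partition)
      daa <- add_ref_positions(daa, aa_frames)
      all_diags[[aa$marker_id]] <- daa
      alignments[[aa$marker_id]] <- aa
    }
  }
  diags <- do.call(rbind, all_diags)
  rownames(diags) <- NULL
  tsv <- file.path(outdir, "classifications.tsv")
  write_classifications(diags, tsv)
  tables <- render_diagnosis(diags)
  md <- file.path(outdir, "diagnosis_tables.md")
  writeLines(paste(tables, collapse = "\n\n"), md)
  logfile <- file.path(outdir, "pipeline_log.txt")
  writeLines(log, logfile)
  invisible(list(diagnoses = diags, tables = tables,
                 alignments = alignments,
                 paths = c(classifications = tsv, tables = md,
                           log = logfile)))
}
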