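#' Read a FASTA file of protein sequences
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]; identifiers are the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("E_INPUT_NOT_FOUND: ", path, call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a per-residue disorder/pLDDT track TSV
#'
#' Expects a header and columns `protein_id`, `position` (1-based), `score`.
#'
#' @param path TSV file.
#' @return Named list of numeric score vectors, ordered by position.
#' @export
read_disorder_tsv <- function(path) {
  if (!file.exists(path)) stop("E_INPUT_NOT_FOUND: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(df)))
    stop("disorder TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tracks <- split(df[, c("position", "score")], df$protein_id)
  lapply(tracks, function(d) {
    d <- d[order(d$position), ]
    if (!identical(d$position, seq_len(nrow(d))))
      stop("disorder track positions must be 1..L without gaps", call. = FALSE)
    d$score
  })
}

#' Write a motif hit table as TSV
#' @param hits `motif_hits` data frame.
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read melting-curve titration CSV
#'
#' Long format with columns `temperature_C`, `signal`, `ligand_uM` (one block
#' per titration point), or wide format with `temperature_C` plus one signal
#' column per ligand concentration named like `L<conc>` or `<conc>`.
#'
#' @param path CSV file.
#' @param protein_uM Total protein concentration attached to every curve.
#' @return List of `melting_curve` objects (see [melting_curve()]).
#' @export
read_melting_csv <- function(path, protein_uM) {
  if (!file.exists(path)) stop("E_INPUT_NOT_FOUND: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (all(c("temperature_C", "signal", "ligand_uM") %in% names(df))) {
    lapply(split(df, df$ligand_uM), function(d)
      melting_curve(d$temperature_C, d$signal, ligand_uM = d$ligand_uM[1],
                    protein_uM = protein_uM))
  } else if ("temperature_C" %in% names(df)) {
    cols <- setdiff(names(df), "temperature_C")
    lt <- as.numeric(sub("^[LlX]", "", cols))
    if (anyNA(lt)) stop("cannot parse ligand concentrations from columns: ",
                        paste(cols[is.na(lt)], collapse = ", "), call. = FALSE)
    lapply(seq_along(cols), function(i)
      melting_curve(df$temperature_C, df[[cols[i]]], ligand_uM = lt[i],
                    protein_uM = protein_uM))
  } else stop("melting CSV must contain a temperature_C column", call. = FALSE)
}

#' Read a native-MS species intensity CSV
#'
#' Columns `Lt_uM`, `Pt_uM`, `n_bound`, `intensity`; one
#' [species_distribution()] per distinct `Lt_uM`.
#'
#' @param path CSV file.
#' @return List of `species_distribution` objects ordered by Lt.
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) stop("E_INPUT_NOT_FOUND: ", path, call. = FALSE)
  df <- read.csv(path)
  need <- c("Lt_uM", "Pt_uM", "n_bound", "intensity")
  if (!all(need %in% names(df)))
    stop("species CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$Lt_uM), function(d) {
    d <- d[order(d$n_bound), ]
    species_distribution(d$intensity, Lt_uM = d$Lt_uM[1], Pt_uM = d$Pt_uM[1])
  })
  out[order(vapply(out, function(x) x$Lt_uM, 0))]
}

#' Read a FRET ROI intensity CSV
#'
#' Columns `roi_id`, `group`, `donor_pre`, `donor_post`, `acceptor_pre`,
#' `acceptor_post`, optional `background` (subtracted from all four channels
#' when present).
#'
#' @param path CSV file.
#' @return Data frame of ROIs.
#' @export
read_rois_csv <- function(path) {
  if (!file.exists(path)) stop("E_INPUT_NOT_FOUND: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "group", "donor_pre", "donor_post",
            "acceptor_pre", "acceptor_post")
  if (!all(need %in% names(df)))
    stop("ROI CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("background" %in% names(df)) {
    for (cl in c("donor_pre", "donor_post", "acceptor_pre", "acceptor_post"))
      df[[cl]] <- df[[cl]] - df$background
  }
  df
}

#' Write an analysis result as JSON
#' @param x List of results (numbers, vectors, tables).
#' @param path Output file.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Fixed 6-significant-digit float formatting for diff-stable text outputs.
fmt6 <- function(x) formatC(x, digits = 6, format = "g")
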