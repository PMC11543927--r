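AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Compile a bracket-notation motif pattern
#'
#' Parses a positional character-class pattern such as
#' `"[DSNTV]L[IL]D[ILMFW]"` into a `motif_spec`: one allowed-residue set per
#' motif position. `x` or `X` is a wildcard matching all 20 amino acids.
#'
#' @param pattern Character scalar in bracket notation. Allowed tokens are
#'   single upper-case amino-acid letters, bracketed classes like `[TSNV]`,
#'   and the wildcard `x`/`X`.
#' @param name Optional motif name; defaults to the pattern itself.
#' @return A `motif_spec` object: list with `name`, `pattern`, and `classes`
#'   (a list of character vectors, one per position).
#' @examples
#' compile_motif("[DSNTV]L[IL]D[ILMFW]", name = "CBM")
#' compile_motif("WxxW", name = "W-box")
#' @export
compile_motif <- function(pattern, name = pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "")[[1]]
  classes <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      cls <- character()
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% AA20)
          stop("motif parse error: invalid residue '", chars[j],
               "' inside class at position ", j, call. = FALSE)
        cls <- c(cls, chars[j])
        j <- j + 1L
      }
      if (j > length(chars))
        stop("motif parse error: unbalanced '[' at position ", i, call. = FALSE)
      if (length(cls) == 0L)
        stop("motif parse error: empty class at position ", i, call. = FALSE)
      classes <- c(classes, list(unique(cls)))
      i <- j + 1L
    } else if (ch == "]") {
      stop("motif parse error: unmatched ']' at position ", i, call. = FALSE)
    } else if (ch %in% c("x", "X")) {
      classes <- c(classes, list(AA20))
      i <- i + 1L
    } else if (ch %in% AA20) {
      classes <- c(classes, list(ch))
      i <- i + 1L
    } else {
      stop("motif parse error: invalid token '", ch, "' at position ", i,
           call. = FALSE)
    }
  }
  if (length(classes) < 3L)
    stop("motif parse error: motif must have at least 3 positions",
         call. = FALSE)
  structure(list(name = name, pattern = pattern, classes = classes),
            class = "motif_spec")
}

#' @method print motif_spec
#' @export
print.motif_spec <- function(x, ...) {
  cat("Motif '", x$name, "': ", x$pattern, " (", length(x$classes),
      " positions, class sizes ",
      paste(vapply(x$classes, length, 1L), collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Built-in motif library
#'
#' The clathrin-binding-motif variants and the accessory NTD-box motifs used
#' throughout the package. `CBM` is the Asp-extended variant
#' `[DSNTV]L[IL]D[ILMFW]` (the default for scanning, as it also covers the
#' Asp-flanked Ent5/Apl2 instances); `CBM_core` is the narrower
#' `[TSNV]L[IL]D[ILMFW]` variant. `Arrestin` is `[LI][LI]GXL` and `Wbox` is
#' `WXXW`.
#'
#' @return Named list of `motif_spec` objects.
#' @export
cbm_motifs <- function() {
  list(
    CBM      = compile_motif("[DSNTV]L[IL]D[ILMFW]", name = "CBM"),
    CBM_core = compile_motif("[TSNV]L[IL]D[ILMFW]",  name = "CBM_core"),
    Arrestin = compile_motif("[LI][LI]GxL",          name = "Arrestin"),
    Wbox     = compile_motif("WxxW",                 name = "Wbox")
  )
}

# Logical match of every window start for one motif. Letters outside the
# 20-letter alphabet (X, B, Z, U, ...) never match a finite class but do
# match wildcards.
.match_starts <- function(seq_chars, motif) {
  L <- length(motif$classes)
  n <- length(seq_chars)
  if (n < L) return(integer())
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L)) {
    cls <- motif$classes[[k]]
    ok <- ok & seq_chars[(k):(n - L + k)] %in% cls
  }
  which(ok)
}

#' Scan one sequence for a motif
#'
#' Reports all (possibly overlapping) occurrences of a compiled motif in an
#' amino-acid sequence, in ascending 1-based start order.
#'
#' @param seq Upper-case amino-acid string (ambiguity codes allowed; they only
#'   match wildcard positions).
#' @param motif A `motif_spec` (or a pattern string, compiled on the fly).
#' @param protein_id Identifier recorded in the hits.
#' @return Data frame of class `motif_hits` with columns `protein_id`,
#'   `motif_name`, `start`, `end`, `matched`, `disorder_mean` (NA until a
#'   disorder track is applied).
#' @examples
#' scan_sequence("GVSLIDL", cbm_motifs()$CBM, protein_id = "Ent2")
#' @export
scan_sequence <- function(seq, motif, protein_id = "seq") {
  if (is.character(motif)) motif <- compile_motif(motif)
  stopifnot(inherits(motif, "motif_spec"))
  seq <- as.character(seq)
  L <- length(motif$classes)
  chars <- if (nzchar(seq)) strsplit(seq, "")[[1]] else character()
  starts <- .match_starts(chars, motif)
  hits <- data.frame(
    protein_id = rep(protein_id, length(starts)),
    motif_name = rep(motif$name, length(starts)),
    start = as.integer(starts),
    end = as.integer(starts + L - 1L),
    matched = vapply(starts, function(s)
      paste(chars[s:(s + L - 1L)], collapse = ""), ""),
    disorder_mean = rep(NA_real_, length(starts)),
    stringsAsFactors = FALSE
  )
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

#' Filter motif hits by disorder context
#'
#' Keeps a hit iff the mean disorder score over its matched span passes the
#' cutoff: for `kind = "prob"` (disorder probability in \[0,1\]) spans with
#' mean >= cutoff are kept; for `kind = "plddt"` (AlphaFold confidence in
#' \[0,100\], low = disordered) spans with mean < cutoff are kept. The
#' `disorder_mean` column is populated either way.
#'
#' @param hits A `motif_hits` data frame (single protein).
#' @param scores Numeric per-residue scores covering the full sequence.
#' @param cutoff Threshold; default 0.5 for `prob`, 50 for `plddt`.
#' @param kind `"prob"` or `"plddt"`.
#' @param seq_length Optional expected sequence length for validation.
#' @return Filtered `motif_hits` with `disorder_mean` filled in.
#' @export
filter_by_disorder <- function(hits, scores, cutoff = NULL,
                               kind = c("prob", "plddt"),
                               seq_length = NULL) {
  kind <- match.arg(kind)
  if (is.null(cutoff)) cutoff <- if (kind == "prob") 0.5 else 50
  if (!is.null(seq_length) && length(scores) != seq_length)
    stop("disorder track length (", length(scores),
         ") does not match sequence length (", seq_length, ")", call. = FALSE)
  if (nrow(hits) > 0 && max(hits$end) > length(scores))
    stop("disorder track shorter than the scanned sequence", call. = FALSE)
  if (kind == "prob" && (any(scores < 0) || any(scores > 1)))
    stop("disorder probabilities must lie in [0,1]", call. = FALSE)
  if (nrow(hits) == 0L) return(hits)
  hits$disorder_mean <- vapply(seq_len(nrow(hits)), function(i)
    mean(scores[hits$start[i]:hits$end[i]]), 0)
  keep <- if (kind == "prob") hits$disorder_mean >= cutoff
          else hits$disorder_mean < cutoff
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Scan a whole proteome for motifs
#'
#' Runs [scan_sequence()] for every sequence/motif combination and, when
#' disorder tracks are supplied, restricts hits to disordered spans via
#' [filter_by_disorder()].
#'
#' @param sequences Named character vector of sequences, or a path to a FASTA
#'   file (read with [read_fasta()]).
#' @param motifs A `motif_spec`, a list of them, or pattern strings. Default:
#'   the `CBM` (`[DSNTV]` variant) motif.
#' @param tracks Optional named list of per-residue score vectors (names =
#'   protein ids), or a path to a disorder TSV (see [read_disorder_tsv()]).
#' @param cutoff,kind Passed to [filter_by_disorder()].
#' @return A `proteome_scan` object: the concatenated `motif_hits` table with
#'   attributes `n_hits` and `n_proteins` (distinct proteins hit).
#' @export
scan_proteome <- function(sequences, motifs = cbm_motifs()$CBM,
                          tracks = NULL, cutoff = NULL,
                          kind = c("prob", "plddt")) {
  kind <- match.arg(kind)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stop("sequences must be named", call. = FALSE)
  if (anyDuplicated(names(sequences)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "), call. = FALSE)
  if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
  motifs <- lapply(motifs, function(m)
    if (is.character(m)) compile_motif(m) else m)
  if (is.character(tracks) && length(tracks) == 1L && file.exists(tracks))
    tracks <- read_disorder_tsv(tracks)

  res <- list()
  for (id in names(sequences)) {
    for (m in motifs) {
      h <- scan_sequence(sequences[[id]], m, protein_id = id)
      if (!is.null(tracks)) {
        if (is.null(tracks[[id]]))
          stop("no disorder track for protein '", id, "'", call. = FALSE)
        h <- filter_by_disorder(h, tracks[[id]], cutoff = cutoff, kind = kind,
                                seq_length = nchar(sequences[[id]]))
      }
      res[[length(res) + 1L]] <- h
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("proteome_scan", "motif_hits", "data.frame")
  attr(out, "n_hits") <- nrow(out)
  attr(out, "n_proteins") <- length(unique(out$protein_id))
  out
}

#' @method print proteome_scan
#' @export
print.proteome_scan <- function(x, ...) {
  cat("Proteome scan: ", attr(x, "n_hits"), " hits in ",
      attr(x, "n_proteins"), " proteins\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
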