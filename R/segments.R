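#' Define a four-residue anchor motif pattern
#'
#' A positional pattern of length 4 in the NxxD family: position 1 is drawn
#' from a restricted set, positions 2-3 are unconstrained (`NULL` = any
#' standard residue), and position 4 is always the conserved aspartate of the
#' charge transfer center.
#'
#' @param name Pattern name.
#' @param p1,p2,p3,p4 Allowed residue sets per position; `NULL` means any of
#'   the 20 standard residues. `p4` must contain `D`.
#' @return A `vsd_motif` object.
#' @export
#' @examples
#' motif_pattern("NxxD", "N")
motif_pattern <- function(name, p1 = NULL, p2 = NULL, p3 = NULL, p4 = "D") {
  sets <- list(p1, p2, p3, p4)
  sets <- lapply(sets, function(s) if (is.null(s)) NULL else toupper(s))
  if (!("D" %in% sets[[4]])) {
    stop("position 4 of an anchor motif must allow 'D'")
  }
  bad <- unlist(lapply(sets, function(s) setdiff(s, amino_acids())))
  if (length(bad) > 0) {
    stop("non-standard residue in motif definition: ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, sets = sets), class = "vsd_motif")
}

#' Default anchor motif patterns
#'
#' The canonical NxxD motif plus the two family variants: FxxD (found in CNG
#' channels such as TAX-4) and C/S-x-x-D (typical of the KCNQ family).
#'
#' @return Named list of `vsd_motif` patterns.
#' @export
default_motif_patterns <- function() {
  list(
    NxxD = motif_pattern("NxxD", "N"),
    FxxD = motif_pattern("FxxD", "F"),
    `CSxxD` = motif_pattern("CSxxD", c("C", "S")))
}

#' Find anchor motif matches in a sequence
#'
#' Scans every length-4 window for matches to the given positional patterns.
#' Gap and unknown symbols never match. All matches of all patterns are
#' returned in sequence order.
#'
#' @param sequence Residue sequence (string or character vector).
#' @param patterns List of `vsd_motif` patterns
#'   (default [default_motif_patterns()]).
#' @return A `data.frame` with columns `pattern` and `position` (1-based
#'   start of the 4-residue match); zero rows when nothing matches.
#' @export
#' @examples
#' find_anchor_motif("LNAADVK")
find_anchor_motif <- function(sequence, patterns = default_motif_patterns()) {
  seq <- .as_residues(sequence)
  if (length(seq) < 4L) stop("sequence must have at least 4 residues")
  if (inherits(patterns, "vsd_motif")) patterns <- list(patterns)
  aa <- amino_acids()
  hits <- list()
  for (i in seq_len(length(seq) - 3L)) {
    win <- seq[i:(i + 3L)]
    for (pat in patterns) {
      ok <- TRUE
      for (p in 1:4) {
        allowed <- pat$sets[[p]]
        if (is.null(allowed)) allowed <- aa
        if (!(win[p] %in% allowed)) { ok <- FALSE; break }
      }
      if (ok) hits[[length(hits) + 1L]] <- data.frame(
        pattern = pat$name, position = i, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(pattern = character(0), position = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$position), , drop = FALSE]
}

#' Cut the S3, S3-S4 and S1-S4 analysis windows
#'
#' Given a verified anchor-motif position and per-family transmembrane
#' boundary annotations, returns the three nested half-open windows used for
#' flexibility profiling: S3 runs from the anchor to the annotated S3 C-end,
#' S3-S4 from the anchor to the S4 C-end, and S1-S4 from the S1 N-end to the
#' S4 C-end. All coordinates are 1-based; windows are half-open
#' `[start, end)`.
#'
#' A missing boundary leaves the corresponding window absent; an anchor lying
#' outside the annotated S3 (after its C-end, or before the S1 N-start) is an
#' inconsistency error.
#'
#' @param sequence Residue sequence the windows refer to (string or vector);
#'   used for bounds checking.
#' @param anchor 1-based anchor motif start position.
#' @param boundaries List or single-row `data.frame` with (any of)
#'   `s1_start`, `s3_end`, `s4_end` (1-based inclusive residue positions).
#' @param family_id Family identifier.
#' @param boundary_source Free-text provenance of the annotation.
#' @return A `vsd_windows` object: list with `family_id`, `anchor_position`,
#'   `s3_window`, `s3s4_window`, `s1s4_window` (each `c(start, end)` half-open
#'   or `NULL` when the boundary is missing) and `boundary_source`.
#' @export
#' @examples
#' extract_windows(strrep("A", 48), anchor = 10,
#'                 boundaries = list(s1_start = 1, s3_end = 25, s4_end = 48))
extract_windows <- function(sequence, anchor, boundaries,
                            family_id = "family",
                            boundary_source = "annotation") {
  seq <- .as_residues(sequence)
  L <- length(seq)
  anchor <- as.integer(anchor)
  if (is.data.frame(boundaries)) {
    stopifnot(nrow(boundaries) == 1L)
    boundaries <- as.list(boundaries)
  }
  g <- function(k) {
    v <- boundaries[[k]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_integer_ else as.integer(v)
  }
  s1_start <- g("s1_start"); s3_end <- g("s3_end"); s4_end <- g("s4_end")
  if (anchor < 1L || anchor + 3L > L) {
    stop("anchor position ", anchor, " outside sequence of length ", L)
  }
  if (!is.na(s3_end) && anchor > s3_end) {
    stop("inconsistent annotation: anchor (", anchor,
         ") lies after the annotated S3 C-end (", s3_end, ")")
  }
  if (!is.na(s1_start) && anchor < s1_start) {
    stop("inconsistent annotation: anchor (", anchor,
         ") lies before the annotated S1 N-start (", s1_start, ")")
  }
  chk <- function(w, nm) {
    if (is.null(w)) return(NULL)
    if (w[1] < 1L || w[2] > L + 1L || w[2] <= w[1]) {
      stop("window ", nm, " [", w[1], ",", w[2],
           ") invalid for sequence of length ", L)
    }
    w
  }
  s3 <- if (!is.na(s3_end)) c(anchor, s3_end + 1L) else NULL
  s3s4 <- if (!is.na(s4_end)) c(anchor, s4_end + 1L) else NULL
  s1s4 <- if (!is.na(s4_end) && !is.na(s1_start)) c(s1_start, s4_end + 1L) else NULL
  structure(
    list(family_id = family_id, anchor_position = anchor,
         s3_window = chk(s3, "S3"), s3s4_window = chk(s3s4, "S3-S4"),
         s1s4_window = chk(s1s4, "S1-S4"),
         boundary_source = boundary_source),
    class = "vsd_windows")
}

#' @export
print.vsd_windows <- function(x, ...) {
  fmt <- function(w) if (is.null(w)) "absent" else sprintf("[%d,%d)", w[1], w[2])
  cat("<vsd_windows> family '", x$family_id, "' anchor ", x$anchor_position,
      ": S3 ", fmt(x$s3_window), ", S3-S4 ", fmt(x$s3s4_window),
      ", S1-S4 ", fmt(x$s1s4_window), "\n", sep = "")
  invisible(x)
}

#' Read a per-family boundary annotation table
#'
#' Tab-separated with columns `family_id`, `s1_start`, `s3_end`, `s4_end`
#' and optional `motif_variant` (a name from [default_motif_patterns()];
#' empty = try all patterns).
#'
#' @param path TSV file path.
#' @return A `data.frame` with one row per family.
#' @export
read_boundary_table <- function(path) {
  if (!file.exists(path)) stop("boundary table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("family_id", "s1_start", "s3_end", "s4_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("boundary table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!("motif_variant" %in% names(df))) df$motif_variant <- NA_character_
  df
}

#' BED-like window table
#'
#' @param windows A `vsd_windows` object or list of them.
#' @return `data.frame` with columns `family_id`, `segment`, `start`, `end`
#'   (half-open, 1-based) and `anchor`.
#' @export
windows_table <- function(windows) {
  if (inherits(windows, "vsd_windows")) windows <- list(windows)
  rows <- lapply(windows, function(w) {
    segs <- list(s3 = w$s3_window, s3s4 = w$s3s4_window, s1s4 = w$s1s4_window)
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (length(segs) == 0L) return(NULL)
    data.frame(family_id = w$family_id, segment = names(segs),
               start = vapply(segs, `[`, integer(1), 1L),
               end = vapply(segs, `[`, integer(1), 2L),
               anchor = w$anchor_position,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
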