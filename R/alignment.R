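#' Read a protein multiple sequence alignment
#'
#' Parses an aligned protein family from FASTA (with `-` gaps) or Clustal
#' format into a rectangular residue matrix. Ragged input (sequences of
#' unequal aligned length) is rejected. Symbols outside the 20 standard amino
#' acids are kept as `X` (unknown) or `-` (gap); lower case is folded to upper
#' case.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param family_id Family identifier; defaults to the file name without
#'   extension.
#' @return A `vsd_alignment` object: a list with `family_id`, `ids`
#'   (sequence identifiers), `seqs` (character matrix, one row per record,
#'   one column per alignment column) and `length` (number of columns).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "LNAADVKW", ">b", "LNSADVKW"), fa)
#' aln <- read_alignment(fa, "fasta")
#' aln$length
read_alignment <- function(path, format = c("fasta", "clustal"),
                           family_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (file.size(path) == 0L) stop("empty alignment file: ", path)
  sset <- tryCatch({
    if (format == "fasta") {
      Biostrings::readAAStringSet(path)
    } else {
      Biostrings::unmasked(
        Biostrings::readAAMultipleAlignment(path, format = "clustal"))
    }
  }, error = function(e) {
    stop("failed to parse '", path, "' as ", format, ": ",
         conditionMessage(e), call. = FALSE)
  })
  if (length(sset) == 0L) stop("no sequences in alignment file: ", path)
  chars <- as.character(sset)
  widths <- nchar(chars)
  if (length(unique(widths)) != 1L) {
    stop("sequences in '", path, "' have unequal aligned lengths (",
         paste(sort(unique(widths)), collapse = ", "),
         "); input must be a rectangular alignment")
  }
  m <- do.call(rbind, strsplit(toupper(chars), ""))
  rownames(m) <- names(sset)
  m[m == "."] <- "-"
  ok <- m %in% c(amino_acids(), "-", "X")
  if (!all(ok)) {
    bad <- unique(m[!ok])
    warning("non-standard residue symbol(s) ", paste(bad, collapse = ", "),
            " treated as 'X'")
    m[!ok] <- "X"
  }
  if (is.null(family_id)) {
    family_id <- sub("\\.[^.]*$", "", basename(path))
  }
  structure(
    list(family_id = family_id, ids = rownames(m), seqs = m,
         length = ncol(m)),
    class = "vsd_alignment")
}

#' Construct an alignment object from in-memory sequences
#'
#' @param seqs Character vector of equal-length aligned sequences (or a
#'   character matrix of residues).
#' @param ids Sequence identifiers.
#' @param family_id Family identifier.
#' @return A `vsd_alignment` object; see [read_alignment()].
#' @export
as_alignment <- function(seqs, ids = NULL, family_id = "family") {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    n <- nchar(seqs)
    if (length(unique(n)) != 1L) {
      stop("sequences have unequal lengths: ", paste(unique(n), collapse = ", "))
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (is.null(ids)) ids <- if (!is.null(names(seqs))) names(seqs)
                           else paste0("seq", seq_len(nrow(m)))
  rownames(m) <- ids
  structure(
    list(family_id = family_id, ids = ids, seqs = m, length = ncol(m)),
    class = "vsd_alignment")
}

#' @export
print.vsd_alignment <- function(x, ...) {
  cat("<vsd_alignment> family '", x$family_id, "': ", length(x$ids),
      " sequences x ", x$length, " columns\n", sep = "")
  invisible(x)
}

#' Per-column residue frequency profiles
#'
#' Counts residues per alignment column. Gaps (`-`) and unknowns (`X`) are
#' excluded from the residue frequencies (which are normalized over non-gap
#' residues only) and accumulated into `gap_fraction`. Profiles are invariant
#' under permutation or duplication of the input records.
#'
#' @param aln A `vsd_alignment`.
#' @return A `vsd_profiles` object: list with `counts` (20 x L integer
#'   matrix, rows named by residue), `freq` (20 x L, columns sum to 1 where
#'   any residue is present), `gap_fraction` (length-L), `n_records` and
#'   `n_columns`.
#' @export
#' @examples
#' aln <- as_alignment(c("NND-", "NND-", "NDDA"))
#' p <- column_profiles(aln)
#' p$freq[, 2]
column_profiles <- function(aln) {
  stopifnot(inherits(aln, "vsd_alignment"))
  if (length(aln$ids) == 0L || aln$length == 0L) stop("empty alignment")
  aa <- amino_acids()
  m <- aln$seqs
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = aa))
    as.integer(tab)
  }, integer(length(aa)))
  rownames(counts) <- aa
  non_gap <- colSums(counts)
  freq <- sweep(counts, 2, pmax(non_gap, 1L), "/")
  freq[, non_gap == 0L] <- 0
  gap_fraction <- 1 - non_gap / nrow(m)
  structure(
    list(counts = counts, freq = freq, gap_fraction = gap_fraction,
         n_records = nrow(m), n_columns = ncol(m),
         family_id = aln$family_id),
    class = "vsd_profiles")
}

#' @export
print.vsd_profiles <- function(x, ...) {
  cat("<vsd_profiles> ", x$n_columns, " columns from ", x$n_records,
      " records\n", sep = "")
  invisible(x)
}

#' Ranked consensus sequences
#'
#' Builds the rank-1..k consensus of a family: per column, the rank-r sequence
#' takes the r-th most frequent non-gap residue. Ties are broken
#' alphabetically by one-letter code (deterministic and record-order
#' independent). Ranks with fewer than r distinct residues are marked with the
#' `NA` sentinel and excluded from downstream averaging, as are
#' majority-gap columns (`gap_fraction >= 0.5`), which are additionally
#' flagged. An all-gap column raises a warning.
#'
#' @param profiles A `vsd_profiles` object.
#' @param k Number of consensus ranks (default 3).
#' @return A `vsd_consensus` object: list with `family_id`, `ranks`
#'   (k x L character matrix, `NA` = sentinel), `ranked_freq` (k x L),
#'   `flagged` (logical, majority-gap columns) and `k`.
#' @export
#' @examples
#' aln <- as_alignment(c("NNA", "NSA", "NDC"))
#' cs <- build_consensus_set(column_profiles(aln))
#' cs$ranks[1, ]
build_consensus_set <- function(profiles, k = 3L) {
  stopifnot(inherits(profiles, "vsd_profiles"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (profiles$n_columns == 0L) stop("no columns in profile set")
  aa <- amino_acids()
  L <- profiles$n_columns
  ranks <- matrix(NA_character_, nrow = k, ncol = L)
  ranked_freq <- matrix(NA_real_, nrow = k, ncol = L)
  flagged <- profiles$gap_fraction >= 0.5
  all_gap <- colSums(profiles$counts) == 0L
  if (any(all_gap)) {
    warning("all-gap column(s) at position(s) ",
            paste(which(all_gap), collapse = ", "),
            "; sentinel emitted")
  }
  for (j in seq_len(L)) {
    if (flagged[j] || all_gap[j]) next
    f <- profiles$freq[, j]
    present <- f > 0
    # alphabetical tie-break: aa is alphabetical, order() is stable
    ord <- order(-f[present])
    res <- aa[present][ord]
    fr <- f[present][ord]
    take <- seq_len(min(k, length(res)))
    ranks[take, j] <- res[take]
    ranked_freq[take, j] <- fr[take]
  }
  structure(
    list(family_id = profiles$family_id, ranks = ranks,
         ranked_freq = ranked_freq, flagged = flagged, k = k),
    class = "vsd_consensus")
}

#' Extract one consensus rank as a residue vector
#'
#' @param cs A `vsd_consensus`.
#' @param rank Which rank (1-based).
#' @return Character vector of residues with `NA` at sentinel positions.
#' @export
consensus_sequence <- function(cs, rank = 1L) {
  stopifnot(inherits(cs, "vsd_consensus"))
  rank <- as.integer(rank)
  if (rank < 1L || rank > cs$k) stop("rank must be in 1..", cs$k)
  cs$ranks[rank, ]
}

#' @export
print.vsd_consensus <- function(x, ...) {
  cat("<vsd_consensus> family '", x$family_id, "': ", x$k, " ranks x ",
      ncol(x$ranks), " columns (", sum(x$flagged), " majority-gap)\n",
      sep = "")
  invisible(x)
}

#' Write ranked consensus sequences as FASTA
#'
#' Three records per family with a rank tag in the header; sentinel positions
#' are written as `-`.
#'
#' @param cs A `vsd_consensus`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(cs, path) {
  stopifnot(inherits(cs, "vsd_consensus"))
  lines <- character(0)
  for (r in seq_len(cs$k)) {
    s <- cs$ranks[r, ]
    s[is.na(s)] <- "-"
    lines <- c(lines,
               sprintf(">%s|rank%d", cs$family_id, r),
               paste(s, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Sequence-logo matrix
#'
#' Shannon information content per column, in bits, with per-residue letter
#' heights. Information content is `log2(20) - H` where `H` is the Shannon
#' entropy of the non-gap residue frequencies; letter heights are
#' `frequency * information`. No small-sample correction is applied (the
#' uncorrected form keeps results independent of alignment depth). Columns
#' with no residues carry zero information.
#'
#' @param profiles A `vsd_profiles` object.
#' @return A `vsd_logo` object: list with `info_bits` (length-L vector in
#'   `[0, log2(20)]`), `heights` (20 x L matrix) and `color_class` (named
#'   classes for the 20 residues).
#' @export
#' @examples
#' aln <- as_alignment(c("ND", "ND", "NA"))
#' logo_matrix(column_profiles(aln))$info_bits
logo_matrix <- function(profiles) {
  stopifnot(inherits(profiles, "vsd_profiles"))
  if (profiles$n_columns == 0L) stop("no columns in profile set")
  f <- profiles$freq
  h <- apply(f, 2, function(p) {
    p <- p[p > 0]
    if (length(p) == 0) return(NA_real_)
    -sum(p * log2(p))
  })
  info <- log2(20) - h
  info[is.na(info)] <- 0
  info <- pmin(pmax(info, 0), log2(20))
  heights <- sweep(f, 2, info, "*")
  structure(
    list(info_bits = info, heights = heights,
         color_class = residue_color_class(amino_acids())),
    class = "vsd_logo")
}

#' Residue display classes for sequence logos
#'
#' Maps each standard residue to the side-chain class used when rendering
#' family logos: hydrophobic (red), aromatic rigid side-chains (dark red),
#' the alpha-helix stabilizing alanine (salmon), small flexible side-chains
#' (orange), polar uncharged flexible side-chains (gray), highly flexible
#' positive (dark blue) and negative (teal) charged residues, the
#' alpha-helix-breaking proline (purple), and Cys/His (black).
#'
#' @param residue Character vector of one-letter residue codes.
#' @return Named character vector of class labels.
#' @export
#' @examples
#' residue_color_class(c("P", "A", "C", "K"))
residue_color_class <- function(residue) {
  map <- c(
    I = "red (hydrophobic)", L = "red (hydrophobic)",
    M = "red (hydrophobic)", V = "red (hydrophobic)",
    F = "dark red (aromatic rigid)", W = "dark red (aromatic rigid)",
    Y = "dark red (aromatic rigid)",
    A = "salmon (alpha-helix stabilizing)",
    G = "orange (small flexible)", S = "orange (small flexible)",
    N = "gray (polar uncharged flexible)",
    Q = "gray (polar uncharged flexible)",
    T = "gray (polar uncharged flexible)",
    K = "dark blue (flexible positive)", R = "dark blue (flexible positive)",
    D = "teal (flexible negative)", E = "teal (flexible negative)",
    P = "purple (alpha-helix breaker)",
    C = "black", H = "black")
  residue <- toupper(as.character(residue))
  unknown <- setdiff(unique(residue), names(map))
  if (length(unknown) > 0) {
    stop("unknown residue symbol(s): ", paste(unknown, collapse = ", "))
  }
  out <- map[residue]
  names(out) <- residue
  out
}

#' Long-format profile/logo table
#'
#' One row per (position, residue) with counts, frequencies, column
#' information content and the residue color class; suitable for TSV export
#' and downstream plotting.
#'
#' @param profiles A `vsd_profiles` object.
#' @param logo Optional matching `vsd_logo` (computed if missing).
#' @return A `data.frame` with columns `position`, `residue`, `count`,
#'   `frequency`, `info_bits`, `color_class`.
#' @export
logo_table <- function(profiles, logo = logo_matrix(profiles)) {
  stopifnot(inherits(profiles, "vsd_profiles"))
  aa <- amino_acids()
  L <- profiles$n_columns
  data.frame(
    position = rep(seq_len(L), each = length(aa)),
    residue = rep(aa, times = L),
    count = as.integer(profiles$counts),
    frequency = as.numeric(profiles$freq),
    info_bits = rep(logo$info_bits, each = length(aa)),
    color_class = rep(unname(residue_color_class(aa)), times = L),
    stringsAsFactors = FALSE)
}
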