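#' List packaged flexibility scales
#'
#' @return Character vector of scale names usable with [load_scale()].
#' @export
list_scales <- function() {
  dir <- system.file("extdata", "scales", package = "vsdflex")
  sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$"))
}

#' Load a per-residue normalized B-value scale
#'
#' Scales ship as TSV files (columns `residue`, `value`) with provenance
#' headers, so exact published value sets can be substituted by pointing
#' `path` at a user file. The default `"rigidity"` scale is oriented so that
#' larger raw values mean more rigid side chains; the segment flexibility
#' index `1/mBf` then grows with flexibility, the orientation used in the
#' package's summary tables. `"vihinen"` and `"karplus_schulz"` are
#' flexibility-oriented normalized B-value sets.
#'
#' @param name Scale name (see [list_scales()]); ignored when `path` given.
#' @param path Optional TSV file with columns `residue`, `value`.
#' @param window_length Odd smoothing window length in residues (default 9):
#'   a residue's effective flexibility depends on its sequence neighbors.
#' @param window_weights Symmetric non-negative weights of length
#'   `window_length`; normalized to sum 1. Default: triangular weights
#'   peaking at the central residue.
#' @return A `vsd_scale` object: list with `name`, `values` (named numeric,
#'   all 20 residues, mean within \[0.9, 1.1\]), `window_length`,
#'   `window_weights`.
#' @export
#' @examples
#' sc <- load_scale("rigidity")
#' sc$values[c("K", "W")]
load_scale <- function(name = "rigidity", path = NULL,
                       window_length = 9L, window_weights = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scales", paste0(name, ".tsv"),
                        package = "vsdflex")
    if (!nzchar(path) || !file.exists(path)) {
      stop("unknown scale '", name, "'; available scales: ",
           paste(list_scales(), collapse = ", "))
    }
  } else {
    if (!file.exists(path)) stop("scale file not found: ", path)
    name <- sub("\\.tsv$", "", basename(path))
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  values <- stats::setNames(as.numeric(df$value), toupper(df$residue))
  window_length <- as.integer(window_length)
  if (window_length < 1L || window_length %% 2L == 0L) {
    stop("window_length must be a positive odd integer")
  }
  if (is.null(window_weights)) {
    h <- (window_length - 1L) / 2L
    window_weights <- (h + 1L) - abs(seq(-h, h))
  }
  window_weights <- as.numeric(window_weights)
  if (length(window_weights) != window_length) {
    stop("window_weights must have length window_length")
  }
  if (any(window_weights < 0)) stop("window_weights must be non-negative")
  if (any(abs(window_weights - rev(window_weights)) > 1e-12)) {
    stop("window_weights must be symmetric about the center")
  }
  window_weights <- window_weights / sum(window_weights)
  sc <- structure(
    list(name = name, values = values, window_length = window_length,
         window_weights = window_weights),
    class = "vsd_scale")
  validate_scale(sc)
  sc
}

#' Validate a flexibility scale's invariants
#'
#' All 20 residues present; mean of the 20 values in \[0.9, 1.1\] (the scale
#' is normalized); window weights symmetric, non-negative and summing to 1.
#'
#' @param scale A `vsd_scale`.
#' @return `scale`, invisibly; errors otherwise.
#' @export
validate_scale <- function(scale) {
  stopifnot(inherits(scale, "vsd_scale"))
  miss <- setdiff(amino_acids(), names(scale$values))
  if (length(miss) > 0) {
    stop("scale '", scale$name, "' lacks residue(s): ",
         paste(miss, collapse = ", "))
  }
  m <- mean(scale$values[amino_acids()])
  if (m < 0.9 || m > 1.1) {
    stop("scale '", scale$name, "' is not normalized: mean raw value ",
         signif(m, 4), " outside [0.9, 1.1]")
  }
  if (abs(sum(scale$window_weights) - 1) > 1e-9) {
    stop("window weights must sum to 1")
  }
  invisible(scale)
}

#' @export
print.vsd_scale <- function(x, ...) {
  cat("<vsd_scale> '", x$name, "': 20 residues, mean ",
      signif(mean(x$values[amino_acids()]), 4), ", window ",
      x$window_length, "\n", sep = "")
  invisible(x)
}

#' Neighbor-smoothed per-position flexibility profile
#'
#' Maps each residue to its raw scale value and smooths with the scale's
#' symmetric window, reflecting that the effective flexibility of a position
#' depends on its neighbors in the primary sequence. At the sequence ends the
#' window is truncated and its weights renormalized, so a homopolymer maps to
#' a constant profile equal to the raw residue value. Sentinel positions
#' (`NA`, gaps, `X`) are skipped: smoothing runs over the remaining residues
#' as a contiguous sequence, and the returned `positions` attribute maps
#' values back to input coordinates.
#'
#' @param seq Residue sequence (string or character vector; may contain `NA`
#'   or `-` sentinels).
#' @param scale A `vsd_scale` from [load_scale()].
#' @return Numeric vector of smoothed values (one per retained position),
#'   with attributes `positions` (original indices) and `residues`.
#' @export
#' @examples
#' smooth_profile("AAAAA", load_scale("vihinen"))
smooth_profile <- function(seq, scale) {
  stopifnot(inherits(scale, "vsd_scale"))
  seq <- .as_residues(seq)
  keep <- !is.na(seq) & seq %in% amino_acids()
  if (!any(keep)) stop("no standard residues to profile")
  res <- seq[keep]
  raw <- unname(scale$values[res])
  n <- length(raw)
  h <- (scale$window_length - 1L) / 2L
  w <- scale$window_weights
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    ww <- w[(lo - i + h + 1L):(hi - i + h + 1L)]
    out[i] <- sum(ww * raw[lo:hi]) / sum(ww)
  }
  attr(out, "positions") <- which(keep)
  attr(out, "residues") <- res
  out
}

#' Mean B-factor and flexibility index of a profile
#'
#' The mean B-factor `mBf` is the arithmetic mean of the per-position
#' (smoothed) normalized B-values of a segment; the flexibility index is its
#' reciprocal `1/mBf`, so `index * mBf == 1` exactly.
#'
#' @param values Non-empty numeric vector of per-position values.
#' @return List with `mBf` and `index`.
#' @export
#' @examples
#' mean_bfactor(c(0.8, 1.2))
mean_bfactor <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values: cannot compute mBf")
  mBf <- mean(values)
  if (mBf <= 0) stop("mBf must be positive; got ", mBf)
  list(mBf = mBf, index = 1 / mBf)
}

#' Flexibility index of a single segment sequence
#'
#' Convenience wrapper: smooth then average. See [smooth_profile()] and
#' [mean_bfactor()].
#'
#' @inheritParams smooth_profile
#' @return List with `mBf`, `index` and `n_positions`.
#' @export
flex_index <- function(seq, scale = load_scale()) {
  prof <- smooth_profile(seq, scale)
  mb <- mean_bfactor(prof)
  c(mb, list(n_positions = length(prof)))
}

#' Consensus-weighted flexibility profile of the anchored windows
#'
#' Computes, for each defined analysis window (S3, S3-S4, S1-S4), the
#' smoothed flexibility profile and index of every consensus rank. The
#' reported `index` comes from the rank-1 consensus; the contribution of the
#' amino acid composition enters as `dispersion`, the population standard
#' deviation of the available rank indices (ranks reduced to sentinels are
#' excluded). Smoothing is confined to the window, so the result does not
#' depend on residues outside the annotated region.
#'
#' @param cs A `vsd_consensus`.
#' @param windows A `vsd_windows` for the same family.
#' @param scale A `vsd_scale`.
#' @return A `vsd_flexprofile`: `data.frame` with one row per available
#'   segment and columns `family_id`, `segment`, `n_positions`, `mBf`,
#'   `index`, `index_rank2`, `index_rank3`, `dispersion`; the per-position
#'   rank-1 profiles are kept in attribute `profiles`.
#' @export
consensus_weighted_index <- function(cs, windows, scale = load_scale()) {
  stopifnot(inherits(cs, "vsd_consensus"), inherits(windows, "vsd_windows"))
  L <- ncol(cs$ranks)
  segs <- list(s3 = windows$s3_window, s3s4 = windows$s3s4_window,
               s1s4 = windows$s1s4_window)
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0L) stop("no windows defined")
  rows <- list()
  profs <- list()
  for (nm in names(segs)) {
    w <- segs[[nm]]
    if (w[2] - 1L > L) {
      stop("window ", nm, " [", w[1], ",", w[2],
           ") exceeds consensus length ", L)
    }
    cols <- w[1]:(w[2] - 1L)
    rank_idx <- rep(NA_real_, cs$k)
    rank_mbf <- rep(NA_real_, cs$k)
    for (r in seq_len(cs$k)) {
      s <- cs$ranks[r, cols]
      if (all(is.na(s) | !(s %in% amino_acids()))) next
      prof <- smooth_profile(s, scale)
      mb <- mean_bfactor(prof)
      rank_mbf[r] <- mb$mBf
      rank_idx[r] <- mb$index
      if (r == 1L) profs[[nm]] <- prof
    }
    if (is.na(rank_idx[1])) {
      stop("rank-1 consensus empty inside window ", nm)
    }
    avail <- rank_idx[!is.na(rank_idx)]
    disp <- sqrt(mean((avail - mean(avail))^2))
    rows[[nm]] <- data.frame(
      family_id = cs$family_id, segment = nm,
      n_positions = length(profs[[nm]] %||% cols),
      mBf = rank_mbf[1], index = rank_idx[1],
      index_rank2 = if (cs$k >= 2) rank_idx[2] else NA_real_,
      index_rank3 = if (cs$k >= 3) rank_idx[3] else NA_real_,
      dispersion = disp, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profiles") <- profs
  class(out) <- c("vsd_flexprofile", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the packaged mean relative solvent accessibility table
#'
#' @param path Optional TSV (columns `residue`, `value`) replacing the
#'   packaged table.
#' @return Named numeric vector (fractions in \[0,1\]) of class `vsd_rsa`.
#' @export
load_rsa_scale <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rsa_mean_exposure.tsv", package = "vsdflex")
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  v <- stats::setNames(as.numeric(df$value), toupper(df$residue))
  if (any(v < 0 | v > 1)) stop("RSA values must lie in [0, 1]")
  miss <- setdiff(amino_acids(), names(v))
  if (length(miss) > 0) stop("RSA table lacks: ", paste(miss, collapse = ", "))
  structure(v, class = "vsd_rsa")
}

#' Mean relative solvent accessibility of a segment
#'
#' Arithmetic mean of the per-residue mean-RSA fractions, a coarse measure of
#' how much a segment's composition contributes to folding stability.
#'
#' @param seq Residue sequence (string or vector; sentinels skipped).
#' @param rsa RSA table from [load_rsa_scale()].
#' @return Mean RSA fraction in \[0,1\].
#' @export
#' @examples
#' rsa_index("GGG") > rsa_index("WWW")
rsa_index <- function(seq, rsa = load_rsa_scale()) {
  seq <- .as_residues(seq)
  seq <- seq[!is.na(seq) & seq %in% amino_acids()]
  if (length(seq) == 0L) stop("no standard residues")
  mean(unname(rsa[seq]))
}

#' Classify families into rigid / intermediate / flexible profiles
#'
#' Families are binned on their flexibility index (1/mBf, larger = more
#' flexible) into the three profile classes. Thresholds are either an
#' explicit pair `c(rigid_max, intermediate_max)` or `"tertile"`, in which
#' case the 1/3 and 2/3 sample quantiles of the supplied indices are used.
#' An index exactly at a boundary is assigned to the lower (more rigid)
#' class. The packaged default pair `(1.53, 1.63)` reproduces the published
#' family grouping on the packaged channel table (TRPV, Hv1 and KCNQ rigid;
#' CNG flexible).
#'
#' @param indices Named numeric vector of family flexibility indices.
#' @param thresholds `"tertile"` or an increasing numeric pair.
#' @return Named ordered factor with levels `rigid < intermediate <
#'   flexible`.
#' @export
#' @examples
#' classify_flexibility(c(hHv1 = 1.40, Kv1.2 = 1.61, CNGA1 = 1.77))
classify_flexibility <- function(indices, thresholds = c(1.53, 1.63)) {
  indices <- indices[!is.na(indices)]
  if (length(indices) == 0L) stop("no indices to classify")
  if (identical(thresholds, "tertile")) {
    if (length(indices) < 3L) {
      stop("tertile mode needs at least 3 families; got ", length(indices))
    }
    thresholds <- unname(stats::quantile(indices, c(1, 2) / 3, type = 7))
  }
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 2L || thresholds[1] > thresholds[2]) {
    stop("thresholds must be an increasing pair")
  }
  cls <- ifelse(indices <= thresholds[1], "rigid",
                ifelse(indices <= thresholds[2], "intermediate", "flexible"))
  out <- factor(cls, levels = c("rigid", "intermediate", "flexible"),
                ordered = TRUE)
  names(out) <- names(indices)
  attr(out, "thresholds") <- thresholds
  out
}
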