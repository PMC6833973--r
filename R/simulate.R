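#' Specify a synthetic aligned sequence family
#'
#' Defines the ground truth for a simulated family: per-column residue
#' composition, an implanted anchor motif, known segment boundaries and a
#' substitution noise rate. Generation ([generate_family_alignment()]) is a
#' pure function of this spec and its seed.
#'
#' @param family_id Family identifier.
#' @param n_sequences Number of aligned sequences.
#' @param length Alignment length (columns).
#' @param composition Either a named probability vector over residues
#'   (recycled to every column) or a 20 x `length` matrix with rows named by
#'   residue; each column must sum to 1.
#' @param motif Name of the implanted anchor variant (`"NxxD"`, `"FxxD"` or
#'   `"CSxxD"`).
#' @param implant_at 1-based motif start column; the motif occupies 4
#'   columns, so `implant_at + 3 <= length`.
#' @param boundaries List with `s1_start`, `s3_end`, `s4_end` (1-based
#'   inclusive), the true segment annotation.
#' @param noise_rate Per-cell substitution probability toward a uniform
#'   residue background (never inside the motif columns).
#' @param seed Random seed.
#' @return A `vsd_family_spec` object.
#' @export
family_spec <- function(family_id, n_sequences, length, composition,
                        motif = "NxxD", implant_at,
                        boundaries = list(s1_start = 1L,
                                          s3_end = length,
                                          s4_end = length),
                        noise_rate = 0, seed = 1L) {
  length <- as.integer(length)
  n_sequences <- as.integer(n_sequences)
  implant_at <- as.integer(implant_at)
  if (n_sequences < 1L || length < 4L) stop("need >= 1 sequence, length >= 4")
  if (implant_at < 1L || implant_at + 3L > length) {
    stop("motif implant at ", implant_at, " does not fit in length ", length)
  }
  if (!(motif %in% names(default_motif_patterns()))) {
    stop("unknown motif variant '", motif, "'")
  }
  aa <- amino_acids()
  if (is.matrix(composition)) {
    if (ncol(composition) != length) {
      stop("composition matrix must have one column per alignment column")
    }
    comp <- matrix(0, nrow = 20, ncol = length, dimnames = list(aa, NULL))
    comp[rownames(composition), ] <- composition
  } else {
    p <- composition[names(composition) %in% aa]
    comp <- matrix(0, nrow = 20, ncol = length, dimnames = list(aa, NULL))
    comp[names(p), ] <- p
  }
  sums <- colSums(comp)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("per-column composition must sum to 1 (worst deviation ",
         signif(max(abs(sums - 1)), 3), ")")
  }
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0, 1]")
  b <- boundaries
  if (!is.null(b$s3_end) && (b$s3_end < implant_at || b$s3_end > length)) {
    stop("boundary s3_end inconsistent with implant position")
  }
  structure(
    list(family_id = family_id, n_sequences = n_sequences, length = length,
         composition = comp, motif = motif, implant_at = implant_at,
         boundaries = b, noise_rate = noise_rate, seed = as.integer(seed)),
    class = "vsd_family_spec")
}

#' Helper: column composition concentrated on chosen residues
#'
#' Uniform distribution over a residue set, e.g. rigid aromatics/branched
#' hydrophobics versus flexible charged/polar residues, for building family
#' specs with a prescribed mean raw flexibility.
#'
#' @param residues Residue one-letter codes.
#' @return Named probability vector.
#' @export
#' @examples
#' uniform_composition(c("K", "S", "N", "D"))
uniform_composition <- function(residues) {
  residues <- toupper(residues)
  bad <- setdiff(residues, amino_acids())
  if (length(bad) > 0) stop("non-standard residue(s): ",
                            paste(bad, collapse = ", "))
  stats::setNames(rep(1 / length(residues), length(residues)), residues)
}

#' Generate a synthetic aligned family with ground truth
#'
#' Draws every cell independently from the spec's per-column composition
#' (star topology: no phylogenetic correlation between records), implants
#' the anchor motif in every sequence at the spec position (motif position 1
#' and 4 fixed to the variant's defining residues; positions 2-3 drawn from
#' the composition), and applies per-cell substitution noise toward a
#' uniform background everywhere except the motif columns. Deterministic
#' given the spec seed.
#'
#' @param spec A `vsd_family_spec`.
#' @param scale Scale used to record the true mean raw flexibility of each
#'   annotated region in the ground truth (default [load_scale()]).
#' @return List with `alignment` (a `vsd_alignment`) and `truth`: the
#'   implant `anchor`, expected half-open `windows`, per-region
#'   `mean_raw_value` under `scale`, and the generating `spec`.
#' @export
generate_family_alignment <- function(spec, scale = load_scale()) {
  stopifnot(inherits(spec, "vsd_family_spec"))
  aa <- amino_acids()
  L <- spec$length
  n <- spec$n_sequences
  motif_cols <- spec$implant_at:(spec$implant_at + 3L)
  pat <- default_motif_patterns()[[spec$motif]]
  m <- .with_seed(spec$seed, {
    m <- matrix("", nrow = n, ncol = L)
    for (j in seq_len(L)) {
      m[, j] <- sample(aa, n, replace = TRUE, prob = spec$composition[, j])
    }
    # implant: fixed first/fourth motif residues in every record
    m[, motif_cols[1]] <- pat$sets[[1]][1]
    m[, motif_cols[4]] <- "D"
    if (spec$noise_rate > 0) {
      flip <- matrix(stats::runif(n * L) < spec$noise_rate, n, L)
      flip[, motif_cols] <- FALSE
      if (any(flip)) m[flip] <- sample(aa, sum(flip), replace = TRUE)
    }
    m
  })
  rownames(m) <- sprintf("%s_seq%03d", spec$family_id, seq_len(n))
  aln <- as_alignment(m, family_id = spec$family_id)
  b <- spec$boundaries
  truth_windows <- list(
    s3 = if (!is.null(b$s3_end)) c(spec$implant_at, b$s3_end + 1L) else NULL,
    s3s4 = if (!is.null(b$s4_end)) c(spec$implant_at, b$s4_end + 1L) else NULL,
    s1s4 = if (!is.null(b$s4_end) && !is.null(b$s1_start))
      c(b$s1_start, b$s4_end + 1L) else NULL)
  region_mean <- function(w) {
    if (is.null(w)) return(NA_real_)
    cols <- w[1]:(w[2] - 1L)
    mean(colSums(spec$composition[, cols, drop = FALSE] *
                   scale$values[aa]))
  }
  truth <- list(
    anchor = spec$implant_at,
    windows = truth_windows,
    mean_raw_value = vapply(truth_windows, region_mean, numeric(1)),
    spec = spec)
  list(alignment = aln, truth = truth)
}

# Internal residue templates for toy structures: atom name -> offset (in
# Angstrom) from the residue's reference atom, chosen so that the reference
# donor/acceptor atom is strictly the closest one to the partner residue
# placed along +x / -x.
.toy_residues <- list(
  LYS = list(ref = "NZ",
             atoms = list(NZ = c(0, 0, 0), CE = c(-1.5, 0, 0),
                          CD = c(-2.6, 1.0, 0), CB = c(-4.0, 1.2, 0.4),
                          CA = c(-5.4, 0.6, 0), N = c(-6.2, 1.4, 0.8),
                          C = c(-6.1, -0.6, -0.6), O = c(-7.2, -1.0, -0.3))),
  ARG = list(ref = "NH1",
             atoms = list(NH1 = c(0, 0, 0), CZ = c(-1.33, 0.4, 0),
                          NH2 = c(-1.9, 1.6, 0), NE = c(-2.2, -0.7, 0),
                          CD = c(-3.6, -0.5, 0.3), CB = c(-4.9, -1.1, -0.2),
                          CA = c(-6.2, -0.5, 0.2), N = c(-7.0, -1.3, 1.0),
                          C = c(-6.9, 0.9, -0.4), O = c(-8.0, 1.1, 0.0))),
  ASP = list(ref = "OD1",
             atoms = list(OD1 = c(0, 0, 0), CG = c(1.25, 0.3, 0),
                          OD2 = c(1.9, 1.35, 0), CB = c(2.2, -0.9, 0.3),
                          CA = c(3.6, -0.5, 0.6), N = c(4.4, -1.4, 1.3),
                          C = c(4.3, 0.8, 0.0), O = c(5.4, 1.0, 0.5))),
  GLU = list(ref = "OE1",
             atoms = list(OE1 = c(0, 0, 0), CD = c(1.25, 0.3, 0),
                          OE2 = c(1.9, 1.35, 0), CG = c(2.2, -0.9, 0.3),
                          CB = c(3.6, -0.6, 0.5), CA = c(5.0, -1.0, 0.2),
                          N = c(5.8, -1.9, 1.0), C = c(5.7, 0.3, -0.4),
                          O = c(6.8, 0.5, 0.1))))

# One-letter codes for the toy residue names.
.aa3to1 <- c(LYS = "K", ARG = "R", ASP = "D", GLU = "E")

#' Specify a toy coordinate file
#'
#' A list of donor/acceptor residue pairs with prescribed minimum
#' donor-acceptor distances; used to exercise salt-bridge detection with a
#' known answer.
#'
#' @param pairs List of lists, each with `donor` (`"LYS"` or `"ARG"`),
#'   `acceptor` (`"ASP"` or `"GLU"`) and `distance` (Angstrom, > 0).
#' @param seed Optional seed for positional jitter of non-reference atoms.
#' @return A `vsd_structure_spec` object.
#' @export
#' @examples
#' toy_structure_spec(list(list(donor = "LYS", acceptor = "ASP",
#'                              distance = 3.5)))
toy_structure_spec <- function(pairs, seed = NULL) {
  for (p in pairs) {
    if (!(toupper(p$donor) %in% c("LYS", "ARG"))) {
      stop("donor must be LYS or ARG")
    }
    if (!(toupper(p$acceptor) %in% c("ASP", "GLU"))) {
      stop("acceptor must be ASP or GLU")
    }
    if (!is.numeric(p$distance) || p$distance <= 0) {
      stop("prescribed distance must be > 0")
    }
  }
  structure(list(pairs = pairs, seed = seed), class = "vsd_structure_spec")
}

#' Write a toy structure with prescribed donor-acceptor distances
#'
#' Places each donor/acceptor residue pair along the x axis so that the
#' minimum distance between the donor nitrogen set and the acceptor
#' carboxylate oxygen set equals the prescribed value; pairs are spaced far
#' apart so they cannot interact. Standard fixed-column PDB formatting,
#' occupancy 1.00; the B-factor column carries the raw scale value of each
#' residue (self-documentation of the flexibility scale in use). Re-reading
#' the file reproduces prescribed distances within coordinate-format
#' precision (1e-3 Angstrom).
#'
#' @param spec A `vsd_structure_spec`.
#' @param path Output PDB path.
#' @param scale Scale whose raw values fill the B-factor column.
#' @return `path` invisibly, with attribute `truth`: a `data.frame` of the
#'   prescribed pair geometry (donor/acceptor residue numbers and
#'   distances).
#' @export
generate_toy_structure <- function(spec, path = tempfile(fileext = ".pdb"),
                                   scale = load_scale()) {
  stopifnot(inherits(spec, "vsd_structure_spec"))
  lines <- character(0)
  truth <- list()
  serial <- 0L
  jitter <- if (!is.null(spec$seed)) {
    .with_seed(spec$seed, stats::runif(length(spec$pairs), -0.2, 0.2))
  } else rep(0, length(spec$pairs))
  for (i in seq_along(spec$pairs)) {
    p <- spec$pairs[[i]]
    donor <- toupper(p$donor); acceptor <- toupper(p$acceptor)
    base <- c(0, 50 * (i - 1), jitter[i])  # pairs well separated in y
    dres <- .toy_residues[[donor]]
    ares <- .toy_residues[[acceptor]]
    dno <- 2L * i - 1L
    ano <- 2L * i
    emit <- function(resname, resno, origin, atoms) {
      for (nm in names(atoms)) {
        serial <<- serial + 1L
        xyz <- origin + atoms[[nm]]
        bfac <- unname(scale$values[.aa3to1[resname]])
        lines <<- c(lines, sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", nm), resname, "A", resno,
          xyz[1], xyz[2], xyz[3], 1.00, bfac, substr(nm, 1, 1)))
      }
    }
    # donor reference atom at base, acceptor reference at base + (d, 0, 0);
    # acceptor template extends toward +x, donor toward -x, so the reference
    # atoms are the closest pair.
    emit(donor, dno, base, dres$atoms)
    emit(acceptor, ano, base + c(p$distance, 0, 0), ares$atoms)
    truth[[i]] <- data.frame(
      donor = donor, donor_resno = dno, acceptor = acceptor,
      acceptor_resno = ano, distance = p$distance,
      stringsAsFactors = FALSE)
  }
  writeLines(c(lines, "END"), path)
  out <- path
  attr(out, "truth") <- do.call(rbind, truth)
  invisible(out)
}

#' Generate a synthetic channel function table with known effect structure
#'
#' Simulates `n` channels split evenly over the three flexibility classes,
#' with per-class index bands matching the packaged channel table (rigid
#' 1.40-1.50, intermediate 1.51-1.62, flexible 1.63-1.80), a binary trait
#' drawn with per-class probabilities, and an optional deterministic
#' monotone map from index to a Q10-like coefficient. Deterministic given
#' the seed; used for power and null-calibration checks of
#' [class_association()] and [rank_correlation()].
#'
#' @param n Number of channels.
#' @param trait_prob Named numeric: trait probability per class
#'   (`rigid`, `intermediate`, `flexible`), all in \[0,1\].
#' @param q10_fun Optional function mapping index to a Q10 value.
#' @param seed Random seed.
#' @return List with `records` (`data.frame`: `channel`, `class`,
#'   `s3_index`, `trait`, optional `q10`) and `truth` (the generating
#'   parameters).
#' @export
generate_functional_table <- function(n,
                                      trait_prob = c(rigid = 0.9,
                                                     intermediate = 0.5,
                                                     flexible = 0.1),
                                      q10_fun = NULL, seed = 1L) {
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 channels")
  if (any(trait_prob < 0 | trait_prob > 1)) {
    stop("trait probabilities must be in [0, 1]")
  }
  lv <- c("rigid", "intermediate", "flexible")
  if (!all(lv %in% names(trait_prob))) {
    stop("trait_prob must be named rigid / intermediate / flexible")
  }
  bands <- list(rigid = c(1.40, 1.50), intermediate = c(1.51, 1.62),
                flexible = c(1.63, 1.80))
  cls <- rep(lv, length.out = n)
  rec <- .with_seed(seed, {
    idx <- vapply(cls, function(cl) {
      stats::runif(1, bands[[cl]][1], bands[[cl]][2])
    }, numeric(1))
    trait <- stats::runif(n) < trait_prob[cls]
    data.frame(channel = sprintf("chan%03d", seq_len(n)),
               class = factor(cls, levels = lv, ordered = TRUE),
               s3_index = unname(idx), trait = unname(trait),
               stringsAsFactors = FALSE)
  })
  if (!is.null(q10_fun)) rec$q10 <- q10_fun(rec$s3_index)
  list(records = rec,
       truth = list(trait_prob = trait_prob, classes = cls, seed = seed))
}
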