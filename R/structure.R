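#' Read an atomic structure model
#'
#' Parses a PDB or mmCIF coordinate file into a flat atom table. Only the
#' first model is kept; hydrogens are dropped; when alternate locations are
#' present a single conformer is retained per atom (highest occupancy,
#' alphabetically first altloc on ties, so conformer `A` wins by default).
#'
#' @param path Coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `vsd_structure` object: list with `atoms` (a `data.frame` with
#'   `chain`, `resno`, `resid` (3-letter residue name), `elety` (atom name),
#'   `elesy` (element), `alt`, `x`, `y`, `z`, `o` (occupancy), `b`) and
#'   `source`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  obj <- tryCatch(
    suppressWarnings(
      if (format == "pdb")
        bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- obj$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms in model: ", path)
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy))) {
    # fall back on the first letter of the atom name
    elesy <- sub("^[0-9]*", "", a$elety)
    elesy <- substr(elesy, 1, 1)
  }
  keep <- !(toupper(elesy) %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]
  elesy <- elesy[keep]
  alt <- a$alt
  alt[is.na(alt)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    resid = toupper(as.character(a$resid)),
    elety = toupper(as.character(a$elety)),
    elesy = toupper(as.character(elesy)), alt = as.character(alt),
    x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z),
    o = as.numeric(occ),
    b = if (!is.null(a$b)) as.numeric(a$b) else NA_real_,
    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  # resolve alternate locations: highest occupancy, then alphabetical altloc
  key <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$elety,
                                   sep = "\r")), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$elety), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = path), class = "vsd_structure")
}

#' @export
print.vsd_structure <- function(x, ...) {
  cat("<vsd_structure> ", nrow(x$atoms), " heavy atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues (",
      basename(x$source), ")\n", sep = "")
  invisible(x)
}

#' Salt-bridge donor/acceptor atom names of a residue type
#'
#' Lysine donates through its terminal amine nitrogen NZ; arginine through
#' the guanidinium nitrogens NE, NH1 and NH2 (published atom lists sometimes
#' write the arginine set with a zeta label, but arginine has no N-zeta atom;
#' the guanidinium nitrogens are used here). Aspartate accepts through both
#' carboxylate oxygens OD1/OD2, and glutamate, measured the same way,
#' through OE1/OE2.
#'
#' @param resname 3-letter residue name (`LYS`, `ARG`, `ASP` or `GLU`).
#' @return Character vector of atom names.
#' @export
#' @examples
#' donor_acceptor_atoms("LYS")
donor_acceptor_atoms <- function(resname) {
  resname <- toupper(resname)
  sets <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
               ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  if (length(resname) != 1L || !(resname %in% names(sets))) {
    stop("no donor/acceptor atom set for residue '", resname,
         "' (supported: LYS, ARG, ASP, GLU)")
  }
  sets[[resname]]
}

# Resolve a residue selector (list with resno and optional chain / resname)
# to the atom rows of exactly one residue.
.resolve_residue <- function(model, sel) {
  stopifnot(inherits(model, "vsd_structure"))
  if (is.numeric(sel)) sel <- list(resno = sel)
  a <- model$atoms
  hit <- a$resno == as.integer(sel$resno)
  if (!is.null(sel$chain) && !is.na(sel$chain)) hit <- hit & a$chain == sel$chain
  if (!is.null(sel$resname) && !is.na(sel$resname)) {
    hit <- hit & a$resid == toupper(sel$resname)
  }
  rows <- a[hit, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("selector matched no residue: resno ", sel$resno,
         if (!is.null(sel$chain)) paste0(" chain ", sel$chain) else "")
  }
  chains <- unique(rows$chain)
  if (length(chains) > 1L) {
    if (!is.null(sel$chain)) {
      stop("selector is ambiguous within chain ", sel$chain)
    }
    warning("residue ", sel$resno, " present in chains ",
            paste(chains, collapse = ", "), "; using chain ", chains[1])
    rows <- rows[rows$chain == chains[1], , drop = FALSE]
  }
  if (length(unique(rows$resid)) > 1L) {
    stop("selector resolves to more than one residue at resno ", sel$resno)
  }
  rows
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

#' Minimum inter-residue distance
#'
#' Minimum Euclidean distance between the atom sets of two residues. By
#' default, for charged residues with a defined donor/acceptor set
#' (LYS/ARG/ASP/GLU) only those atoms are used; otherwise all heavy atoms.
#'
#' @param model A `vsd_structure`.
#' @param resA,resB Residue selectors: a residue number, or a list with
#'   `resno` and optional `chain`, `resname`.
#' @param atomsA,atomsB Optional explicit atom-name filters.
#' @return Minimum distance in Angstrom, with attribute `pair` naming the
#'   closest atom pair.
#' @export
min_pair_distance <- function(model, resA, resB,
                              atomsA = NULL, atomsB = NULL) {
  ra <- .resolve_residue(model, resA)
  rb <- .resolve_residue(model, resB)
  pick <- function(rows, atoms) {
    if (is.null(atoms)) {
      resname <- rows$resid[1]
      if (resname %in% c("LYS", "ARG", "ASP", "GLU")) {
        atoms <- donor_acceptor_atoms(resname)
      } else {
        atoms <- rows$elety
      }
    }
    sel <- rows[rows$elety %in% toupper(atoms), , drop = FALSE]
    if (nrow(sel) == 0L) {
      stop("residue ", rows$resid[1], rows$resno[1],
           " has none of the requested atoms")
    }
    sel
  }
  sa <- pick(ra, atomsA)
  sb <- pick(rb, atomsB)
  best <- Inf
  best_pair <- c(NA_character_, NA_character_)
  for (i in seq_len(nrow(sa))) {
    for (j in seq_len(nrow(sb))) {
      d <- .dist3(as.numeric(sa[i, c("x", "y", "z")]),
                  as.numeric(sb[j, c("x", "y", "z")]))
      if (d < best) {
        best <- d
        best_pair <- c(sa$elety[i], sb$elety[j])
      }
    }
  }
  structure(best, pair = best_pair)
}

#' Detect charge-transfer-center salt bridges
#'
#' Measures every donor-nitrogen / acceptor-oxygen atom pair between the
#' given basic (LYS/ARG) and acidic (ASP/GLU) residues and flags pairs at or
#' below the cutoff as salt bridges. The cutoff is inclusive: a pair at
#' exactly 4.0 Angstrom is a bridge.
#'
#' @param model A `vsd_structure`.
#' @param donors,acceptors Residue selectors (see [min_pair_distance()]) or
#'   lists of selectors.
#' @param cutoff Salt-bridge distance cutoff in Angstrom (default 4.0).
#' @return A `data.frame` (class `vsd_saltbridges`) with one row per atom
#'   pair: donor/acceptor chain, residue number, residue name and atom name,
#'   `distance` and `is_bridge`.
#' @export
detect_salt_bridges <- function(model, donors, acceptors, cutoff = 4.0) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  norm <- function(x) {
    if (is.numeric(x)) return(lapply(x, function(r) list(resno = r)))
    if (!is.null(x$resno)) return(list(x))
    x
  }
  donors <- norm(donors); acceptors <- norm(acceptors)
  rows <- list()
  for (dsel in donors) {
    rd <- .resolve_residue(model, dsel)
    datoms <- donor_acceptor_atoms(rd$resid[1])
    if (!(rd$resid[1] %in% c("LYS", "ARG"))) {
      stop("donor must be LYS or ARG; got ", rd$resid[1])
    }
    rd <- rd[rd$elety %in% datoms, , drop = FALSE]
    for (asel in acceptors) {
      ra <- .resolve_residue(model, asel)
      if (!(ra$resid[1] %in% c("ASP", "GLU"))) {
        stop("acceptor must be ASP or GLU; got ", ra$resid[1])
      }
      aatoms <- donor_acceptor_atoms(ra$resid[1])
      ra <- ra[ra$elety %in% aatoms, , drop = FALSE]
      for (i in seq_len(nrow(rd))) {
        for (j in seq_len(nrow(ra))) {
          d <- .dist3(as.numeric(rd[i, c("x", "y", "z")]),
                      as.numeric(ra[j, c("x", "y", "z")]))
          rows[[length(rows) + 1L]] <- data.frame(
            donor_chain = rd$chain[i], donor_resno = rd$resno[i],
            donor_resid = rd$resid[i], donor_atom = rd$elety[i],
            acceptor_chain = ra$chain[j], acceptor_resno = ra$resno[j],
            acceptor_resid = ra$resid[j], acceptor_atom = ra$elety[j],
            distance = d, is_bridge = d <= cutoff,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("vsd_saltbridges", class(out))
  out
}

#' Write a salt-bridge report as TSV
#'
#' @param bridges Result of [detect_salt_bridges()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_salt_bridge_tsv <- function(bridges, path) {
  utils::write.table(as.data.frame(bridges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Least-squares rigid-body superposition (Kabsch, via SVD).
# A, B: n x 3 matrices of corresponding points. Returns list(rmsd, rotation).
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(t(B0) %*% A0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  list(rmsd = rmsd, rotation = R, center_fixed = ca, center_mobile = cb)
}

#' Motif-anchored C-alpha superposition RMSD
#'
#' Optimal least-squares rigid-body superposition of the C-alpha atoms of
#' corresponding residues (Kabsch algorithm), as used to compare anchor-motif
#' regions across structures. The RMSD is invariant under rigid motion of
#' either model.
#'
#' @param modelA,modelB `vsd_structure` objects.
#' @param correspondence `data.frame` with columns `resnoA`, `resnoB` and
#'   optional `chainA`, `chainB`; at least 3 residue pairs.
#' @return List with `rmsd` (Angstrom), `n` (pairs used) and the fitted
#'   `rotation` matrix.
#' @export
superpose_motif <- function(modelA, modelB, correspondence) {
  stopifnot(is.data.frame(correspondence))
  if (nrow(correspondence) < 3L) {
    stop("at least 3 corresponding residues are required")
  }
  ca_coord <- function(model, resno, chain) {
    rows <- .resolve_residue(model, list(resno = resno, chain = chain))
    rows <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(rows) == 0L) stop("no C-alpha atom for residue ", resno)
    as.numeric(rows[1, c("x", "y", "z")])
  }
  n <- nrow(correspondence)
  A <- matrix(0, n, 3); B <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    A[i, ] <- ca_coord(modelA, correspondence$resnoA[i],
                       correspondence$chainA[i] %||% NULL)
    B[i, ] <- ca_coord(modelB, correspondence$resnoB[i],
                       correspondence$chainB[i] %||% NULL)
  }
  k <- .kabsch(A, B)
  list(rmsd = k$rmsd, n = n, rotation = k$rotation)
}
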