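# A hand-written toy PDB exercising altlocs, hydrogens and two residues.
write_toy_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  NZ  LYS A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CE  LYS A   1      -1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  HZ1 LYS A   1       0.500   0.500   0.500  1.00  0.00           H",
    "ATOM      4  OD1AASP A   2       3.000   4.000   0.000  0.60  0.00           O",
    "ATOM      5  OD1BASP A   2       9.000   9.000   9.000  0.40  0.00           O",
    "ATOM      6  OD2 ASP A   2       6.000   8.000   0.000  1.00  0.00           O",
    "END"), path)
  path
}

test_that("structure reading keeps exact coordinates, drops hydrogens and resolves altlocs", {
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(f)
  m <- read_structure(f)
  expect_s3_class(m, "vsd_structure")
  # hydrogen dropped, one OD1 conformer retained
  expect_equal(nrow(m$atoms), 4L)
  expect_false(any(m$atoms$elesy == "H"))
  od1 <- m$atoms[m$atoms$elety == "OD1", ]
  expect_equal(nrow(od1), 1L)
  expect_equal(od1$alt, "A")  # the higher-occupancy conformer
  expect_equal(unname(unlist(od1[, c("x", "y", "z")])), c(3, 4, 0))
  nz <- m$atoms[m$atoms$elety == "NZ", ]
  expect_equal(unname(unlist(nz[, c("x", "y", "z")])), c(0, 0, 0))
  expect_error(read_structure(tempfile()), "not found")
})

test_that("the same model parses identically from PDB and mmCIF", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  NZ  LYS A   1       0.000   0.000   0.000  1.00  0.88           N",
    "ATOM      2  CE  LYS A   1      -1.500   0.000   0.000  1.00  0.88           C",
    "ATOM      3  OD1 ASP A   2       3.500   0.000   0.000  1.00  0.91           O",
    "END"), pdb)
  cif <- tempfile(fileext = ".cif")
  hdr <- paste0("_atom_site.",
                c("group_PDB", "id", "type_symbol", "label_atom_id",
                  "label_alt_id", "label_comp_id", "label_asym_id",
                  "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                  "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                  "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                  "auth_comp_id", "auth_asym_id", "auth_atom_id",
                  "pdbx_PDB_model_num"))
  writeLines(c(
    "data_toy", "loop_", hdr,
    "ATOM 1 N NZ . LYS A 1 1 ? 0.000 0.000 0.000 1.00 0.88 ? 1 LYS A NZ 1",
    "ATOM 2 C CE . LYS A 1 1 ? -1.500 0.000 0.000 1.00 0.88 ? 1 LYS A CE 1",
    "ATOM 3 O OD1 . ASP A 1 2 ? 3.500 0.000 0.000 1.00 0.91 ? 2 ASP A OD1 1"),
    cif)
  mp <- read_structure(pdb, "pdb")
  mc <- read_structure(cif, "mmcif")
  cols <- c("chain", "resno", "resid", "elety", "x", "y", "z", "o")
  expect_identical(mp$atoms[, cols], mc$atoms[, cols])
})

test_that("donor and acceptor atom sets follow the charge-transfer-center chemistry", {
  expect_equal(donor_acceptor_atoms("LYS"), "NZ")
  expect_setequal(donor_acceptor_atoms("ARG"), c("NE", "NH1", "NH2"))
  expect_setequal(donor_acceptor_atoms("ASP"), c("OD1", "OD2"))
  expect_setequal(donor_acceptor_atoms("GLU"), c("OE1", "OE2"))
  expect_error(donor_acceptor_atoms("GLY"), "no donor/acceptor")
})

test_that("minimum pair distance matches the closed form and a brute-force scan", {
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(f)
  m <- read_structure(f)
  # NZ at origin, OD1 at (3,4,0): the 3-4-5 triangle
  d <- min_pair_distance(m, 1, 2)
  expect_equal(as.numeric(d), 5)
  expect_equal(attr(d, "pair"), c("NZ", "OD1"))

  # brute force over all heavy-atom pairs of two multi-atom residues
  spec <- toy_structure_spec(list(list(donor = "ARG", acceptor = "GLU",
                                       distance = 3.7)))
  p <- generate_toy_structure(spec, tempfile(fileext = ".pdb"))
  mm <- read_structure(as.character(p))
  a1 <- mm$atoms[mm$atoms$resno == 1, ]
  a2 <- mm$atoms[mm$atoms$resno == 2, ]
  brute <- min(apply(a1[, c("x", "y", "z")], 1, function(u) {
    min(apply(a2[, c("x", "y", "z")], 1, function(v) sqrt(sum((u - v)^2))))
  }))
  got <- min_pair_distance(mm, 1, 2, atomsA = a1$elety, atomsB = a2$elety)
  expect_equal(as.numeric(got), brute, tolerance = 1e-12)
  expect_error(min_pair_distance(mm, 99, 2), "no residue")
})

test_that("salt-bridge detection equals brute force and is inclusive at the cutoff", {
  spec <- toy_structure_spec(list(
    list(donor = "LYS", acceptor = "ASP", distance = 3.5),
    list(donor = "LYS", acceptor = "ASP", distance = 4.0),
    list(donor = "LYS", acceptor = "ASP", distance = 4.001),
    list(donor = "ARG", acceptor = "GLU", distance = 2.9)))
  p <- generate_toy_structure(spec, tempfile(fileext = ".pdb"))
  m <- read_structure(as.character(p))
  truth <- attr(p, "truth")
  for (i in seq_len(nrow(truth))) {
    sb <- detect_salt_bridges(m, truth$donor_resno[i],
                              truth$acceptor_resno[i])
    # brute force: all donor-atom x acceptor-atom distances
    da <- m$atoms[m$atoms$resno == truth$donor_resno[i] &
                  m$atoms$elety %in% donor_acceptor_atoms(truth$donor[i]), ]
    ac <- m$atoms[m$atoms$resno == truth$acceptor_resno[i] &
                  m$atoms$elety %in%
                    donor_acceptor_atoms(truth$acceptor[i]), ]
    expect_equal(nrow(sb), nrow(da) * nrow(ac))
    for (j in seq_len(nrow(sb))) {
      u <- da[da$elety == sb$donor_atom[j], c("x", "y", "z")]
      v <- ac[ac$elety == sb$acceptor_atom[j], c("x", "y", "z")]
      expect_equal(sb$distance[j], sqrt(sum((u - v)^2)), tolerance = 1e-12)
      expect_identical(sb$is_bridge[j], sb$distance[j] <= 4.0)
    }
    # the prescribed minimum is reproduced within PDB precision
    expect_equal(min(sb$distance), truth$distance[i], tolerance = 1e-3)
  }
  # inclusive boundary behaviour
  sb4 <- detect_salt_bridges(m, 3, 4)     # prescribed 4.0
  expect_true(any(sb4$is_bridge))
  sb4001 <- detect_salt_bridges(m, 5, 6)  # prescribed 4.001
  expect_false(sb4001$is_bridge[which.min(sb4001$distance)])
  expect_error(detect_salt_bridges(m, 2, 1), "donor must be")
})

test_that("superposition RMSD is zero under rigid motion and matches the quaternion method", {
  set.seed(7)
  A <- matrix(rnorm(15, sd = 4), 5, 3)
  mA <- read_ca_structure(A)
  corr <- data.frame(resnoA = 1:5, resnoB = 1:5)
  expect_equal(superpose_motif(mA, mA, corr)$rmsd, 0, tolerance = 1e-6)

  # rotated + translated copy: still zero
  R <- random_rotation(3)
  B <- sweep(A %*% t(R), 2, c(10, -4, 2), "+")
  mB <- read_ca_structure(B)
  expect_equal(superpose_motif(mA, mB, corr)$rmsd, 0, tolerance = 1e-3)

  # noisy copy: agreement with the quaternion closed form
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(15, sd = 5), 5, 3)
    B <- A + matrix(rnorm(15, sd = 0.7), 5, 3)
    # work in coordinates rounded to PDB precision so both routes see
    # identical inputs
    A <- round(A, 3); B <- round(B, 3)
    got <- superpose_motif(read_ca_structure(A), read_ca_structure(B),
                           corr)$rmsd
    expect_equal(got, quaternion_rmsd(A, B), tolerance = 1e-6)
    # invariance under rigid motion of either model
    R <- random_rotation(seed + 50)
    B2 <- round(sweep(B %*% t(R), 2, c(5, 5, -9), "+"), 3)
    got2 <- superpose_motif(read_ca_structure(A), read_ca_structure(B2),
                            corr)$rmsd
    expect_equal(got2, got, tolerance = 1e-3)
  }
  expect_error(superpose_motif(mA, mA, corr[1:2, ]), "at least 3")
})
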