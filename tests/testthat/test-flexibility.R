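test_that("packaged scales satisfy the normalized-scale invariants", {
  expect_setequal(list_scales(),
                  c("rigidity", "vihinen", "karplus_schulz"))
  for (nm in list_scales()) {
    sc <- load_scale(nm)
    expect_setequal(names(sc$values), aa20)
    m <- mean(sc$values[aa20])
    expect_gte(m, 0.9); expect_lte(m, 1.1)
    expect_equal(sc$window_length, 9L)
    expect_equal(sc$window_weights, rev(sc$window_weights))
    expect_equal(sum(sc$window_weights), 1, tolerance = 1e-12)
  }
  expect_error(load_scale("nonexistent"), "available scales")
  expect_error(load_scale(window_length = 4), "odd")
})

test_that("smoothing reduces to the raw value on homopolymers and delta kernels", {
  sc <- load_scale("vihinen")
  prof <- smooth_profile("AAAAA", sc)
  expect_equal(as.numeric(prof), rep(unname(sc$values["A"]), 5))

  delta <- load_scale("vihinen", window_length = 9,
                      window_weights = c(0, 0, 0, 0, 1, 0, 0, 0, 0))
  s <- "KWNDFGH"
  expect_equal(as.numeric(smooth_profile(s, delta)),
               unname(delta$values[strsplit(s, "")[[1]]]))
})

test_that("smoothing equals the brute-force truncated windowed mean", {
  sc <- load_scale("rigidity")
  # 7-residue toy plus random sequences
  for (s in c("KWNDFGH", vapply(1:8, function(i) random_sequence(25, i),
                                character(1)))) {
    expect_equal(as.numeric(smooth_profile(s, sc)),
                 brute_smooth(s, sc$values, sc$window_weights),
                 tolerance = 1e-12)
  }
  # sentinel positions are skipped, the rest smoothed contiguously
  with_gaps <- c("K", "-", "W", NA, "N")
  prof <- smooth_profile(with_gaps, sc)
  expect_equal(attr(prof, "positions"), c(1L, 3L, 5L))
  expect_equal(as.numeric(prof),
               brute_smooth("KWN", sc$values, sc$window_weights))
  expect_error(smooth_profile(c("-", "-"), sc), "no standard residues")
})

test_that("mBf is the arithmetic mean and index its exact reciprocal", {
  expect_equal(mean_bfactor(c(1, 1, 1)), list(mBf = 1, index = 1))
  expect_equal(mean_bfactor(c(0.8, 1.2))$mBf, 1.0)
  set.seed(42)
  for (i in 1:20) {
    v <- runif(sample(3:30, 1), 0.5, 1.5)
    mb <- mean_bfactor(v)
    expect_identical(mb$index, 1 / mb$mBf)  # exact reciprocal by definition
    expect_equal(mb$index * mb$mBf, 1, tolerance = 1e-12)
    expect_equal(mb$mBf, mean(v))
  }
  expect_error(mean_bfactor(numeric(0)), "no values")
})

test_that("replacing residues with strictly more flexible ones raises mBf", {
  sc <- load_scale("vihinen")
  ord <- names(sort(sc$values))  # rigid -> flexible
  s_rigid <- paste(ord[1:8], collapse = "")
  s_flex <- paste(ord[13:20], collapse = "")
  expect_gt(flex_index(s_flex, sc)$mBf, flex_index(s_rigid, sc)$mBf)
  # single-site monotonicity
  base <- "LLLLLLLL"
  more_flex <- "LLLKLLLL"  # K more flexible than L on this scale
  expect_gt(flex_index(more_flex, sc)$mBf, flex_index(base, sc)$mBf)
})

test_that("consensus-weighted index reports rank dispersion as the population SD", {
  # identical ranks: dispersion zero
  m <- matrix("A", 3, 10)
  m[1, ] <- m[2, ] <- m[3, ] <- strsplit("KWNDFGHKWN", "")[[1]]
  aln <- as_alignment(rbind(m, m), family_id = "same")
  cs <- build_consensus_set(column_profiles(aln))
  w <- extract_windows(cs$ranks[1, ], 3,
                       list(s1_start = 1, s3_end = 8, s4_end = 10))
  fx <- consensus_weighted_index(cs, w)
  expect_true(all(fx$dispersion == 0))
  expect_equal(fx$index, 1 / fx$mBf)

  # constructed three-rank consensus with hand-computable dispersion:
  # counts 3/2/1 per column give rank1 "NKKD", rank2 "SWWE", rank3 "GAAH"
  sc <- load_scale("rigidity")
  aln2 <- as_alignment(c("NKKD", "NKKD", "NKKD", "SWWE", "SWWE", "GAAH"),
                       family_id = "ranks")
  cs2 <- build_consensus_set(column_profiles(aln2))
  expect_equal(paste(cs2$ranks[1, ], collapse = ""), "NKKD")
  expect_equal(paste(cs2$ranks[2, ], collapse = ""), "SWWE")
  expect_equal(paste(cs2$ranks[3, ], collapse = ""), "GAAH")
  w2 <- extract_windows(cs2$ranks[1, ], 1,
                        list(s1_start = 1, s3_end = 4, s4_end = 4))
  fx2 <- consensus_weighted_index(cs2, w2, sc)
  idx <- c(flex_index("NKKD", sc)$index, flex_index("SWWE", sc)$index,
           flex_index("GAAH", sc)$index)
  expect_equal(fx2$index[fx2$segment == "s3"], idx[1])
  expect_equal(fx2$dispersion[fx2$segment == "s3"],
               sqrt(mean((idx - mean(idx))^2)), tolerance = 1e-12)

  # window exceeding the consensus errors
  expect_error(
    consensus_weighted_index(cs2, extract_windows(strrep("A", 20), 1,
                                                  list(s1_start = 1,
                                                       s3_end = 20,
                                                       s4_end = 20)), sc),
    "exceeds")
})

test_that("families simulated from rigid vs flexible compositions are strictly ordered", {
  sc <- load_scale("rigidity")
  flex_truth <- load_scale("vihinen")
  mk <- function(res, seed) {
    spec <- family_spec(paste0("fam", seed), n_sequences = 80, length = 40,
                        composition = uniform_composition(res),
                        implant_at = 5,
                        boundaries = list(s1_start = 1, s3_end = 20,
                                          s4_end = 36),
                        noise_rate = 0.02, seed = seed)
    generate_family_alignment(spec, scale = flex_truth)
  }
  rigid <- mk(c("W", "F", "I", "V", "L"), 11)
  flex <- mk(c("K", "S", "N", "Q", "E"), 12)
  # generator ground truth orders the two families
  expect_gt(flex$truth$mean_raw_value[["s3"]],
            rigid$truth$mean_raw_value[["s3"]])
  idx_of <- function(fam) {
    cs <- build_consensus_set(column_profiles(fam$alignment))
    w <- extract_windows(cs$ranks[1, ], fam$truth$anchor,
                         fam$truth$spec$boundaries)
    fx <- consensus_weighted_index(cs, w, sc)
    fx$index[fx$segment == "s3"]
  }
  expect_gt(idx_of(flex), idx_of(rigid))
})

test_that("RSA index is the arithmetic mean exposure and orders glycine above tryptophan", {
  rsa <- load_rsa_scale()
  expect_true(all(rsa >= 0 & rsa <= 1))
  expect_equal(rsa_index("GGG", rsa), unname(rsa["G"]))
  expect_equal(rsa_index("GW", rsa), mean(rsa[c("G", "W")]))
  expect_gt(rsa_index("GGGG", rsa), rsa_index("WWWW", rsa))
  expect_error(rsa_index(""), "no standard residues")
})

test_that("three-class categorization reproduces the published family grouping", {
  tab <- load_functional_table()
  idx <- setNames(tab$s3_index, tab$channel)
  idx <- idx[!is.na(idx)]
  cls <- classify_flexibility(idx)  # packaged default thresholds
  expect_equal(as.character(cls[["hHv1"]]), "rigid")
  expect_equal(as.character(cls[["mHv1"]]), "rigid")
  expect_equal(as.character(cls[["TRPV1"]]), "rigid")
  expect_equal(as.character(cls[["TRPV2"]]), "rigid")
  expect_equal(as.character(cls[["Kv7.4 (KCNQ4)"]]), "rigid")
  expect_equal(as.character(cls[["CNGA1"]]), "flexible")
  expect_equal(as.character(cls[["CNGA2"]]), "flexible")

  # tertile mode puts the extremes in the right classes
  cls_t <- classify_flexibility(idx, thresholds = "tertile")
  expect_equal(as.character(cls_t[["hHv1"]]), "rigid")
  expect_equal(as.character(cls_t[["CNGA1"]]), "flexible")

  # a value exactly at a boundary goes to the lower class
  cls_b <- classify_flexibility(c(a = 1.0, b = 1.53, c = 1.63, d = 1.7),
                                thresholds = c(1.53, 1.63))
  expect_equal(as.character(cls_b[["b"]]), "rigid")
  expect_equal(as.character(cls_b[["c"]]), "intermediate")

  expect_error(classify_flexibility(c(a = 1, b = 2), thresholds = "tertile"),
               "at least 3")
})
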