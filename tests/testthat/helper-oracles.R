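# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written from scratch (brute force,
# enumeration, closed forms) so it cannot share a bug with the package code
# it checks.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

# Brute-force motif scan: checks every 4-residue window against positional
# allowed-sets, independent of find_anchor_motif()'s loop structure.
brute_motif_scan <- function(seq_str, sets) {
  s <- strsplit(seq_str, "")[[1]]
  hits <- integer(0)
  if (length(s) >= 4) {
    for (i in 1:(length(s) - 3)) {
      ok <- TRUE
      for (p in 1:4) {
        allowed <- sets[[p]]
        if (is.null(allowed)) allowed <- aa20
        if (!(s[i + p - 1] %in% allowed)) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# Brute-force truncated-and-renormalized windowed mean of raw scale values.
brute_smooth <- function(seq_str, values, weights) {
  s <- strsplit(seq_str, "")[[1]]
  raw <- unname(values[s])
  n <- length(raw)
  h <- (length(weights) - 1) / 2
  out <- numeric(n)
  for (i in 1:n) {
    acc <- 0; wacc <- 0
    for (k in -h:h) {
      j <- i + k
      if (j >= 1 && j <= n) {
        w <- weights[k + h + 1]
        acc <- acc + w * raw[j]
        wacc <- wacc + w
      }
    }
    out[i] <- acc / wacc
  }
  out
}

# Quaternion-method superposition RMSD (largest eigenvalue closed form),
# independent of the SVD-based Kabsch implementation.
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  S <- t(A0) %*% B0
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(0, e2))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Exhaustive two-sided permutation p-value for Spearman's rho.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

spearman_perm_p <- function(x, y) {
  rho <- stats::cor(x, y, method = "spearman")
  stats_all <- vapply(all_perms(length(y)), function(p) {
    stats::cor(x, y[p], method = "spearman")
  }, numeric(1))
  mean(abs(stats_all) >= abs(rho) - 1e-12)
}

# Exact fixed-margin enumeration p-value for an r x 2 contingency table
# (multivariate hypergeometric null), the Fisher-type definition.
fisher_enum_p <- function(tbl) {
  r <- rowSums(tbl)
  c2 <- sum(tbl[, 2])
  n <- sum(tbl)
  kgrid <- expand.grid(lapply(r, function(ri) 0:ri))
  kgrid <- kgrid[rowSums(kgrid) == c2, , drop = FALSE]
  prob <- apply(kgrid, 1, function(k) {
    prod(choose(r, k)) / choose(n, c2)
  })
  obs <- prod(choose(r, tbl[, 2])) / choose(n, c2)
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Coarse grid search + Nelder-Mead polish for the modified exponential,
# an optimizer-independent check on the Levenberg-Marquardt route.
grid_polish_fit <- function(x, y) {
  ss <- function(p) {
    if (min(x) + p[3] <= 0) return(1e12)
    sum((y - p[1] * exp(p[2] / (x + p[3])))^2)
  }
  best <- NULL
  for (a0 in seq(0.5, 2, length.out = 6) * max(y)) {
    for (b0 in c(-5, -1, -0.2, 0.2, 1, 5, 20, 80)) {
      for (c0 in c(0.2, 0.5, 1, 2, 5, 20, 80)) {
        v <- ss(c(a0, b0, c0))
        if (is.null(best) || v < best$value) {
          best <- list(par = c(a0, b0, c0), value = v)
        }
      }
    }
  }
  opt <- stats::optim(best$par, ss, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, ss, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(par = opt$par, ss = opt$value)
}

# Tiny PDB writer for C-alpha traces: one CA atom per residue.
write_ca_pdb <- function(coords, path, chain = "A") {
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, chain, i, coords[i, 1], coords[i, 2], coords[i, 3], 1, 0)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

read_ca_structure <- function(coords) {
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  read_structure(write_ca_pdb(coords, f))
}

# Random column profile over a subset of residues (frequencies sum to 1).
random_profile_alignment <- function(seed, n = 8, L = 15) {
  set.seed(seed)
  m <- matrix(sample(aa20, n * L, replace = TRUE), n, L)
  # sprinkle gaps
  gaps <- matrix(stats::runif(n * L) < 0.1, n, L)
  m[gaps] <- "-"
  as_alignment(m, family_id = paste0("rand", seed))
}
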