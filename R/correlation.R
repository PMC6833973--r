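#' Parse an interval-valued table entry
#'
#' Handles the notations used in the packaged channel tables: a plain number
#' (`"6"`), an approximate value (`"~ 9"`), a range (`"12 - 16"`, including
#' negative ranges `"~ -5 - -35"`), a mean with spread (`"-8.8 +/- 1.3"`,
#' parsed to `mean -/+ spread`), two listed values (`"4 ; 5.8"`), a bound
#' (`"> 100"`, lower end kept) and missing markers (`"n.d."`, `"-"`, `""`).
#'
#' @param s Character scalar.
#' @return Numeric `c(lower, upper)`; both `NA` when missing.
#' @export
#' @examples
#' parse_interval("12 - 16")
#' parse_interval("-8.8 +/- 1.3")
parse_interval <- function(s) {
  if (length(s) != 1L) stop("parse_interval() expects a single entry")
  s <- trimws(as.character(s))
  if (is.na(s) || s %in% c("", "-", "n.d.", "nd", "N.D.", "NA")) {
    return(c(NA_real_, NA_real_))
  }
  s <- gsub("~", "", s, fixed = TRUE)
  s <- trimws(s)
  num <- function(x) suppressWarnings(as.numeric(trimws(x)))
  if (grepl("+/-", s, fixed = TRUE)) {
    parts <- num(strsplit(s, "+/-", fixed = TRUE)[[1]])
    if (length(parts) != 2L || any(is.na(parts))) stop("bad entry: '", s, "'")
    return(sort(c(parts[1] - parts[2], parts[1] + parts[2])))
  }
  if (grepl(";", s, fixed = TRUE)) {
    parts <- num(strsplit(s, ";", fixed = TRUE)[[1]])
    if (any(is.na(parts))) stop("bad entry: '", s, "'")
    return(range(parts))
  }
  if (grepl("^>", s)) {
    v <- num(sub("^>", "", s))
    if (is.na(v)) stop("bad entry: '", s, "'")
    return(c(v, NA_real_))
  }
  # range separator is " - " (spaces required, so negative signs survive)
  if (grepl(" - ", s, fixed = TRUE)) {
    parts <- num(strsplit(s, " - ", fixed = TRUE)[[1]])
    if (length(parts) != 2L || any(is.na(parts))) stop("bad entry: '", s, "'")
    return(sort(parts))
  }
  v <- num(s)
  if (is.na(v)) stop("bad entry: '", s, "'")
  c(v, v)
}

.interval_mid <- function(lo, hi) {
  ifelse(is.na(lo) & is.na(hi), NA_real_,
         ifelse(is.na(hi), lo, ifelse(is.na(lo), hi, (lo + hi) / 2)))
}

#' Load the packaged channel function table
#'
#' Reads the transcription of the published channel comparison tables:
#' `"voltage_temperature"` (S3/S3-S4/S1-S4 flexibility indices, charge per
#' channel in elementary charges, Q10 of activation/inactivation kinetics)
#' or `"stretch"` (S3/S3-S4 indices, charge, stretch-induced shift of the
#' half-activation voltage). Interval notations are parsed to
#' `*_lo`/`*_hi` bounds plus a `*_mid` midpoint used for fitting; `n.d.` and
#' `-` become `NA`.
#'
#' @param which `"voltage_temperature"` or `"stretch"`.
#' @param path Optional TSV replacing the packaged fixture (same columns).
#' @return A `data.frame` of class `vsd_functional`, one row per
#'   channel/domain.
#' @export
#' @examples
#' tab <- load_functional_table()
#' tab[tab$channel == "hHv1", c("s3_index", "charge_lo", "charge_hi")]
load_functional_table <- function(which = c("voltage_temperature", "stretch"),
                                  path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    fn <- if (which == "voltage_temperature") "functional_table1.tsv"
          else "functional_table2.tsv"
    path <- system.file("extdata", fn, package = "vsdflex")
  }
  if (!file.exists(path)) stop("functional table not found: ", path)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!("channel" %in% names(raw))) stop("table lacks a 'channel' column")
  pint <- function(col, label) {
    out <- matrix(NA_real_, nrow = length(col), ncol = 2)
    for (i in seq_along(col)) {
      out[i, ] <- tryCatch(parse_interval(col[i]), error = function(e) {
        stop("row ", i, " (", raw$channel[i], "), column ", label, ": ",
             conditionMessage(e), call. = FALSE)
      })
    }
    out
  }
  out <- data.frame(channel = trimws(raw$channel),
                    domain = if ("domain" %in% names(raw))
                      ifelse(raw$domain %in% c("-", ""), NA_character_,
                             trimws(raw$domain))
                    else NA_character_,
                    stringsAsFactors = FALSE)
  for (nm in c("s3_index", "s3s4_index", "s1s4_index")) {
    if (nm %in% names(raw)) {
      out[[nm]] <- pint(raw[[nm]], nm)[, 1]  # indices are single values
    }
  }
  ch <- pint(raw$charge_e0, "charge_e0")
  out$charge_lo <- ch[, 1]; out$charge_hi <- ch[, 2]
  out$charge_mid <- .interval_mid(ch[, 1], ch[, 2])
  if ("q10_act" %in% names(raw)) {
    qa <- pint(raw$q10_act, "q10_act")
    qi <- pint(raw$q10_inact, "q10_inact")
    out$q10_act_lo <- qa[, 1]; out$q10_act_hi <- qa[, 2]
    out$q10_act_mid <- .interval_mid(qa[, 1], qa[, 2])
    out$q10_inact_lo <- qi[, 1]; out$q10_inact_hi <- qi[, 2]
    out$q10_inact_mid <- .interval_mid(qi[, 1], qi[, 2])
  }
  if ("dv12_shift" %in% names(raw)) {
    dv <- pint(raw$dv12_shift, "dv12_shift")
    out$dv12_lo <- dv[, 1]; out$dv12_hi <- dv[, 2]
    out$dv12_mid <- .interval_mid(dv[, 1], dv[, 2])
  }
  if ("mechanosensitive" %in% names(raw)) {
    out$mechanosensitive <- tolower(trimws(raw$mechanosensitive)) %in%
      c("yes", "true", "1")
  }
  class(out) <- c("vsd_functional", class(out))
  out
}

#' Write a parsed channel function table
#'
#' Writes the parsed (numeric-interval) representation back to TSV such that
#' [read_functional_table()] recovers it losslessly.
#'
#' @param x A `vsd_functional` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_functional_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a parsed channel function table
#'
#' Counterpart of [write_functional_table()].
#'
#' @param path TSV written by [write_functional_table()].
#' @return A `vsd_functional` data frame.
#' @export
read_functional_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("mechanosensitive" %in% names(out)) {
    out$mechanosensitive <- as.logical(out$mechanosensitive)
  }
  if ("domain" %in% names(out)) out$domain <- as.character(out$domain)
  class(out) <- c("vsd_functional", class(out))
  out
}

#' Fit the modified single exponential f(x) = a * exp(b / (x + c))
#'
#' Nonlinear least squares fit of the saturating curve used to summarize how
#' segment flexibility indices vary across the channel superfamily. The pole
#' `x = -c` is kept outside the data range by a box constraint during
#' iteration. Deterministic given data and start values.
#'
#' Default initialization: `a = max(y)`, `c = 1`, and `b` from the log-ratio
#' of the two x-extreme points
#' `b = log(y_first / y_last) / (1/(x_min + c) - 1/(x_max + c))`.
#'
#' @param x,y Numeric vectors (at least 4 complete pairs).
#' @param start Optional named list/vector with `a`, `b`, `c`.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A `vsd_fit` object: list with `a`, `b`, `c`, `r_squared`
#'   (`1 - SSres/SStot`), `n_points`, `fitted` and `residuals`.
#' @export
#' @examples
#' x <- 1:6; y <- 2 * exp(1 / (x + 0.5))
#' fit_modified_exponential(x, y)$r_squared
fit_modified_exponential <- function(x, y, start = NULL, max_iter = 200L) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 4L) stop("at least 4 complete (x, y) pairs are required; got ", n)
  if (is.null(start)) {
    c0 <- 1
    o <- order(x)
    denom <- 1 / (x[o][1] + c0) - 1 / (x[o][n] + c0)
    b0 <- if (abs(denom) > 1e-12 && y[o][n] > 0 && y[o][1] > 0) {
      log(y[o][1] / y[o][n]) / denom
    } else 0.1
    if (!is.finite(b0)) b0 <- 0.1
    start <- list(a = max(y), b = b0, c = c0)
  }
  start <- as.list(start)[c("a", "b", "c")]
  c_lower <- -min(x) + 1e-6  # keep x + c > 0 during iteration
  if (start$c <= c_lower) start$c <- c_lower + 1
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b / (x + c)), data = dat, start = start,
                      lower = c(a = -Inf, b = -Inf, c = c_lower),
                      control = minpack.lm::nls.lm.control(
                        maxiter = as.integer(max_iter))),
    error = function(e) {
      stop("modified-exponential fit did not converge (start a=",
           signif(start$a, 4), ", b=", signif(start$b, 4), ", c=",
           signif(start$c, 4), "): ", conditionMessage(e), call. = FALSE)
    })
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]),
         r_squared = r2, n_points = n, fitted = stats::fitted(fit),
         residuals = res, ss_res = ss_res),
    class = "vsd_fit")
}

#' @export
print.vsd_fit <- function(x, ...) {
  cat(sprintf(
    "<vsd_fit> f(x) = %.4g * exp(%.4g / (x + %.4g)); R^2 = %.4f (n = %d)\n",
    x$a, x$b, x$c, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit the flexibility-index curve of the channel table
#'
#' Convenience wrapper applying [fit_modified_exponential()] to the S3
#' flexibility indices of a channel function table against one of the two
#' candidate x-variables: `"rank"` (families ordered by decreasing index,
#' the order in which family distributions are plotted; x = 1..n) or
#' `"charge"` (gating-charge midpoints in elementary charges).
#'
#' @param functional A `vsd_functional` table (default: packaged table).
#' @param x_var `"rank"` or `"charge"`.
#' @param index_col Which index column to fit (default `"s3_index"`).
#' @return A `vsd_fit` with attribute `x_var`.
#' @export
fit_flexibility_curve <- function(functional = load_functional_table(),
                                  x_var = c("rank", "charge"),
                                  index_col = "s3_index") {
  x_var <- match.arg(x_var)
  y <- functional[[index_col]]
  if (x_var == "rank") {
    y <- sort(y[!is.na(y)], decreasing = TRUE)
    x <- seq_along(y)
  } else {
    ok <- !is.na(y) & !is.na(functional$charge_mid)
    x <- functional$charge_mid[ok]
    y <- y[ok]
  }
  # deterministic multi-start: the default start plus a small fixed grid;
  # keep the fit with the lowest residual sum of squares
  fit <- tryCatch(fit_modified_exponential(x, y), error = function(e) NULL)
  for (b0 in c(-0.5, 0.1, 0.5, 5)) {
    for (c0 in c(0.5, 1, 5, 20)) {
      cand <- tryCatch(
        fit_modified_exponential(x, y, start = list(a = max(y), b = b0,
                                                    c = c0)),
        error = function(e) NULL)
      if (!is.null(cand) &&
          (is.null(fit) || cand$ss_res < fit$ss_res - 1e-12)) {
        fit <- cand
      }
    }
  }
  if (is.null(fit)) stop("no start led to a converged fit")
  attr(fit, "x_var") <- x_var
  fit
}

# All permutations of 1..n as an (n! x n) matrix; n <= 8 by construction.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with a permutation p-value
#'
#' Spearman's rho between a flexibility index and a functional quantity,
#' with a two-sided permutation p-value: exhaustive enumeration of all
#' permutations when `n <= exhaustive_max` (default 8), Monte-Carlo sampling
#' with a fixed documented seed otherwise. The statistic is invariant under
#' strictly monotone transformations of either variable.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values are
#'   dropped; at least 3 complete pairs required).
#' @param n_mc Number of Monte-Carlo permutations (default 9999).
#' @param seed Seed for the Monte-Carlo branch (default 170).
#' @param exhaustive_max Largest n for exhaustive enumeration.
#' @return List with `rho`, `p_value`, `n` and `method`
#'   (`"exhaustive"` or `"monte carlo"`).
#' @export
#' @examples
#' rank_correlation(1:5, c(2, 4, 5, 7, 9))
rank_correlation <- function(x, y, n_mc = 9999L, seed = 170L,
                             exhaustive_max = 8L) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required; got ", n)
  rho <- stats::cor(x, y, method = "spearman")
  rx <- rank(x); ry <- rank(y)
  stat <- function(perm_ry) stats::cor(rx, perm_ry, method = "pearson")
  eps <- 1e-12
  if (n <= exhaustive_max) {
    perms <- .permutations(n)
    stats_all <- apply(perms, 1, function(p) stat(ry[p]))
    p_value <- mean(abs(stats_all) >= abs(rho) - eps)
    method <- "exhaustive"
  } else {
    stats_all <- .with_seed(seed, {
      vapply(seq_len(n_mc), function(i) stat(sample(ry)), numeric(1))
    })
    p_value <- (1 + sum(abs(stats_all) >= abs(rho) - eps)) / (1 + n_mc)
    method <- "monte carlo"
  }
  list(rho = rho, p_value = p_value, n = n, method = method)
}

#' Association between flexibility class and a binary trait
#'
#' Cross-tabulates the three flexibility classes against a binary functional
#' trait (e.g. reported mechanosensitivity) and computes the exact
#' (Fisher-type, fixed-margin enumeration) p-value.
#'
#' @param classes Named factor/character of flexibility classes per channel.
#' @param trait Named logical of the trait per channel; joined to `classes`
#'   by name.
#' @return List with `table` (classes x trait contingency table) and
#'   `p_value`.
#' @export
class_association <- function(classes, trait) {
  if (length(classes) == 0L || length(trait) == 0L) stop("empty input")
  if (!is.null(names(classes)) && !is.null(names(trait))) {
    common <- intersect(names(classes), names(trait))
    if (length(common) == 0L) stop("no channels shared between inputs")
    classes <- classes[common]; trait <- trait[common]
  } else if (length(classes) != length(trait)) {
    stop("unnamed inputs must have equal length")
  }
  classes <- factor(as.character(classes),
                    levels = intersect(c("rigid", "intermediate", "flexible"),
                                       unique(as.character(classes))))
  trait <- factor(as.logical(trait), levels = c(FALSE, TRUE))
  tbl <- table(class = classes, trait = trait)
  if (any(rowSums(tbl) == 0L)) stop("every compared class needs >= 1 channel")
  p <- stats::fisher.test(tbl)$p.value
  list(table = tbl, p_value = min(p, 1))
}
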