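#' Read a pipeline configuration file
#'
#' @param path YAML file whose keys mirror the arguments documented in
#'   [validate_config()].
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' Checks a run configuration and collects every problem instead of failing
#' at the first. Recognized fields: `alignments_dir` (directory of aligned
#' FASTA/Clustal files, required), `boundaries` (boundary TSV, required;
#' see [read_boundary_table()]), `scale` (scale name, default
#' `"rigidity"`), `classification` (`"tertile"` or a numeric pair, default
#' the packaged pair), `functional_table` (optional TSV overriding the
#' packaged channel table; `"packaged"` uses the fixture), `structures`
#' (optional `data.frame`/file of structure paths with donor/acceptor
#' residue numbers), `output_dir` (required), `seed` (default 1),
#' `log_level`.
#'
#' @param config Configuration list (e.g. from [read_config()]).
#' @return List with `config` (normalized, defaults filled), `errors`
#'   (character vector) and `valid` (logical).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  cfg <- config
  need_dir <- function(key) {
    v <- cfg[[key]]
    if (is.null(v)) errors <<- c(errors, paste0("missing field: ", key))
    else if (!dir.exists(v)) errors <<- c(errors, paste0(key, " does not exist: ", v))
  }
  need_file <- function(key, required = TRUE) {
    v <- cfg[[key]]
    if (is.null(v)) {
      if (required) errors <<- c(errors, paste0("missing field: ", key))
    } else if (!file.exists(v)) {
      errors <<- c(errors, paste0(key, " does not exist: ", v))
    }
  }
  need_dir("alignments_dir")
  need_file("boundaries")
  if (is.null(cfg$scale)) cfg$scale <- "rigidity"
  if (!(cfg$scale %in% list_scales())) {
    errors <- c(errors, paste0("unknown scale '", cfg$scale,
                               "'; available: ",
                               paste(list_scales(), collapse = ", ")))
  }
  if (is.null(cfg$classification)) cfg$classification <- c(1.53, 1.63)
  if (!identical(cfg$classification, "tertile")) {
    cl <- suppressWarnings(as.numeric(cfg$classification))
    if (length(cl) != 2L || any(is.na(cl)) || cl[1] > cl[2]) {
      errors <- c(errors,
                  "classification must be 'tertile' or an increasing pair")
    } else cfg$classification <- cl
  }
  if (!is.null(cfg$functional_table) &&
      !identical(cfg$functional_table, "packaged")) {
    need_file("functional_table", required = FALSE)
  }
  if (is.null(cfg$output_dir)) {
    errors <- c(errors, "missing field: output_dir")
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- suppressWarnings(as.integer(cfg$seed))
  if (is.na(cfg$seed)) errors <- c(errors, "seed must be an integer")
  list(config = cfg, errors = errors, valid = length(errors) == 0L)
}

# Pick the anchor for one family: the first motif match at or after the S1
# N-start that still lies inside the annotated S3 (anchor <= s3_end).
.pick_anchor <- function(sequence, boundary_row) {
  variant <- boundary_row$motif_variant
  pats <- default_motif_patterns()
  if (!is.null(variant) && !is.na(variant) && nzchar(variant) &&
      variant %in% names(pats)) {
    pats <- pats[variant]
  }
  seq_chr <- sequence
  seq_chr[is.na(seq_chr)] <- "-"
  hits <- find_anchor_motif(seq_chr, pats)
  if (nrow(hits) == 0L) return(NA_integer_)
  lo <- if (!is.na(boundary_row$s1_start)) boundary_row$s1_start else 1L
  hi <- if (!is.na(boundary_row$s3_end)) boundary_row$s3_end else Inf
  ok <- hits$position >= lo & hits$position <= hi
  if (!any(ok)) return(NA_integer_)
  min(hits$position[ok])
}

#' Run the sequence-to-flexibility pipeline
#'
#' Orchestrates the full analysis over a directory of family alignments:
#' per-family column profiles, ranked consensus, anchor-motif location,
#' window extraction, consensus-weighted flexibility indices, three-class
#' classification, and (when a channel function table is available)
#' correlation of the computed S3 indices with the table plus the
#' modified-exponential fits. Writes a per-family summary TSV, consensus
#' FASTA files, an optional correlation JSON and salt-bridge TSV, and a run
#' manifest recording versions, configuration hash and seed. Output is
#' deterministic given configuration and seed.
#'
#' @param config Configuration list or path to a YAML file; see
#'   [validate_config()].
#' @return Invisibly, a list with `summary` (the per-family segment table),
#'   `classes`, `correlations`, `manifest` and `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  val <- validate_config(config)
  if (!val$valid) {
    stop("invalid configuration:\n  - ",
         paste(val$errors, collapse = "\n  - "))
  }
  cfg <- val$config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) {
    if (!identical(cfg$log_level, "quiet")) message("[vsdflex] ", ...)
  }
  scale <- load_scale(cfg$scale)
  boundaries <- read_boundary_table(cfg$boundaries)
  files <- list.files(cfg$alignments_dir,
                      pattern = "\\.(fa|fasta|aln|clustal)$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no alignment files in ", cfg$alignments_dir)
  summaries <- list()
  failed <- character(0)
  for (f in sort(files)) {
    fam <- sub("\\.[^.]*$", "", basename(f))
    fmt <- if (grepl("\\.(aln|clustal)$", f)) "clustal" else "fasta"
    res <- tryCatch({
      aln <- read_alignment(f, fmt, family_id = fam)
      prof <- column_profiles(aln)
      cs <- build_consensus_set(prof)
      brow <- boundaries[boundaries$family_id == fam, , drop = FALSE]
      if (nrow(brow) == 0L) stop("no boundary annotation for family ", fam)
      brow <- as.list(brow[1, ])
      rank1 <- consensus_sequence(cs, 1L)
      anchor <- .pick_anchor(rank1, brow)
      if (is.na(anchor)) stop("no anchor motif found for family ", fam)
      seq1 <- rank1; seq1[is.na(seq1)] <- "-"
      win <- extract_windows(seq1, anchor, brow, family_id = fam,
                             boundary_source = basename(cfg$boundaries))
      write_consensus_fasta(cs, file.path(cfg$output_dir,
                                          paste0(fam, "_consensus.fasta")))
      fx <- consensus_weighted_index(cs, win, scale)
      merge(as.data.frame(fx),
            windows_table(win)[, c("segment", "start", "end", "anchor")],
            by = "segment")
    }, error = function(e) {
      log_msg("family ", fam, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, fam) else summaries[[fam]] <- res
  }
  if (length(summaries) == 0L) stop("every family failed; nothing to report")
  summary_df <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(summary_df) <- NULL
  s3 <- summary_df[summary_df$segment == "s3", ]
  classes <- classify_flexibility(
    stats::setNames(s3$index, s3$family_id),
    thresholds = cfg$classification)
  summary_df$class <- as.character(classes[summary_df$family_id])
  summary_path <- file.path(cfg$output_dir, "flexibility_summary.tsv")
  utils::write.table(summary_df, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  correlations <- NULL
  join_n <- NA_integer_
  if (!is.null(cfg$functional_table)) {
    ft <- if (identical(cfg$functional_table, "packaged"))
      load_functional_table() else
      load_functional_table(path = cfg$functional_table)
    joined <- merge(s3[, c("family_id", "index")], ft,
                    by.x = "family_id", by.y = "channel")
    join_n <- nrow(joined)
    log_msg("functional join: ", join_n, " families in both tables")
    correlations <- list(join_count = join_n)
    if (join_n >= 3L) {
      rc <- rank_correlation(joined$index, joined$charge_mid,
                             seed = cfg$seed)
      correlations$index_vs_charge <- rc[c("rho", "p_value", "n", "method")]
      if (!is.null(joined$q10_act_mid) &&
          sum(stats::complete.cases(joined$index, joined$q10_act_mid)) >= 3L) {
        rq <- rank_correlation(joined$index, joined$q10_act_mid,
                               seed = cfg$seed)
        correlations$index_vs_q10_act <- rq[c("rho", "p_value", "n", "method")]
      }
    }
    for (xv in c("rank", "charge")) {
      fit <- tryCatch(fit_flexibility_curve(ft, xv), error = function(e) NULL)
      if (!is.null(fit)) {
        correlations[[paste0("fit_", xv)]] <-
          fit[c("a", "b", "c", "r_squared", "n_points")]
      }
    }
    jsonlite::write_json(correlations,
                         file.path(cfg$output_dir, "correlations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package = "vsdflex",
    version = as.character(utils::packageVersion("vsdflex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    scale = cfg$scale,
    config_hash = .config_hash(cfg),
    families = names(summaries),
    failed_families = failed,
    functional_join_count = join_n,
    outputs = list.files(cfg$output_dir))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(failed) > 0L) {
    warning("stage failures for: ", paste(failed, collapse = ", "),
            " (flagged in manifest)")
  }
  invisible(list(summary = summary_df, classes = classes,
                 correlations = correlations, manifest = manifest,
                 output_dir = cfg$output_dir))
}

# Stable md5 of the normalized configuration.
.config_hash <- function(cfg) {
  cfg$output_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
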