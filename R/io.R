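#' Validate a probe-by-sample expression matrix
#'
#' Expression matrices are plain numeric matrices with unique probe
#' rownames and unique sample colnames, holding finite log2-scale
#' intensities. All pipeline stages accept and return this shape.
#'
#' @param x numeric matrix, probes as rows, samples as columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have probe rownames and sample colnames",
         call. = FALSE)
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup))
    stop("duplicate probe identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' First column holds probe identifiers, header row holds sample
#' identifiers. Ordering is preserved from the file.
#'
#' @param path file path.
#' @return validated numeric matrix (probes x samples).
#' @export
load_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression file needs probe ids plus >= 1 sample",
                           call. = FALSE)
  probes <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d (probe '%s'), column '%s'",
                 bad[1, 1], probes[bad[1, 1]], colnames(vals)[bad[1, 2]]),
         call. = FALSE)
  dimnames(num) <- list(probes, colnames(vals))
  validate_expression_matrix(num)
  num
}

#' Write an expression (or call) matrix to a tab-delimited file
#'
#' Numeric values are formatted with 6 significant digits so that a
#' write-then-read round trip is byte-stable.
#'
#' @param x matrix with probe rownames and sample colnames.
#' @param path output path.
#' @param id_col name of the identifier column in the header.
#' @export
write_matrix <- function(x, path, id_col = "probe_id") {
  out <- x
  if (is.numeric(out)) out <- signif(out, 6L)
  df <- data.frame(rownames(x), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a present/marginal/absent call matrix
#'
#' Same layout as the expression matrix; cells restricted to the
#' three-letter alphabet P/M/A.
#'
#' @param path file path.
#' @return character matrix of calls.
#' @export
load_calls <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  probes <- tab[[1L]]
  calls <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(calls) <- probes
  validate_calls(calls)
  calls
}

#' @rdname load_calls
#' @param calls character matrix to validate.
#' @export
validate_calls <- function(calls) {
  if (any(duplicated(rownames(calls))))
    stop("duplicate probe identifiers in call matrix", call. = FALSE)
  bad <- setdiff(unique(as.vector(calls)), c("P", "M", "A"))
  if (length(bad))
    stop("invalid call value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(calls)
}

.metadata_cols <- c("sample_id", "parity", "tslp_years", "age_years", "bmi",
                    "smoking_duration_years", "cycle_iud", "batch",
                    "replicate_of")

.cycle_levels <- c("luteal", "ovulatory", "follicular", "hormonal_IUD",
                   "missing")

#' Validate cohort metadata
#'
#' Enforces the cohort invariants: TSLP present iff parous, batch label on
#' every sample, replicate links resolving to existing samples, known
#' cycle/IUD categories.
#'
#' @param meta data.frame of per-sample metadata.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta) {
  missing_cols <- setdiff(.metadata_cols, names(meta))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(duplicated(meta$sample_id)))
    stop("duplicate sample identifiers in metadata", call. = FALSE)
  bad <- setdiff(unique(meta$parity), c("parous", "nulliparous"))
  if (length(bad))
    stop("unknown parity value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  par <- meta$parity == "parous"
  if (any(par & is.na(meta$tslp_years)))
    stop("parous sample(s) with missing TSLP: ",
         paste(meta$sample_id[par & is.na(meta$tslp_years)], collapse = ", "),
         call. = FALSE)
  if (any(!par & !is.na(meta$tslp_years)))
    stop("TSLP set for nulliparous sample(s): ",
         paste(meta$sample_id[!par & !is.na(meta$tslp_years)],
               collapse = ", "), call. = FALSE)
  if (any(meta$tslp_years < 0, na.rm = TRUE))
    stop("negative TSLP", call. = FALSE)
  if (any(is.na(meta$batch) | meta$batch == ""))
    stop("every sample needs a batch label", call. = FALSE)
  bad <- setdiff(unique(meta$cycle_iud), .cycle_levels)
  if (length(bad))
    stop("unknown cycle/IUD value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rep_set <- !is.na(meta$replicate_of) & meta$replicate_of != ""
  if (any(rep_set & !(meta$replicate_of %in% meta$sample_id)))
    stop("replicate_of names a sample absent from the metadata",
         call. = FALSE)
  invisible(meta)
}

#' Read a tab-delimited cohort metadata table
#'
#' @param path file path.
#' @return validated data.frame; nulliparous rows carry NA TSLP.
#' @export
load_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = c("NA"))
  for (col in c("tslp_years", "age_years", "bmi", "smoking_duration_years")) {
    if (col %in% names(meta)) {
      blank <- is.na(meta[[col]]) | meta[[col]] == ""
      num <- suppressWarnings(as.numeric(meta[[col]]))
      if (any(is.na(num) & !blank))
        stop("non-numeric value in metadata column '", col, "'",
             call. = FALSE)
      meta[[col]] <- num
    }
  }
  if ("replicate_of" %in% names(meta)) {
    meta$replicate_of[meta$replicate_of %in% c("", NA)] <- NA_character_
  }
  validate_metadata(meta)
  meta
}

#' Write a cohort metadata table
#'
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- signif(out[[col]], 6L)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Analysis configuration with the study's default thresholds
#'
#' Every tunable threshold of the pipeline, defaulted to the values used in
#' the source study design: presence-call filter at 75% with a 25%
#' group-difference rescue, CV first-quartile filter, discovery FDR 20%,
#' validation p 0.05 over 12 resampled pairs with a 2-pair consensus,
#' candidate selection at FDR 10% and 1.2-fold, GO alpha 0.01, paired-test
#' FDR 10% with 1.2-fold, RT-PCR significance at p 0.10 and 1.2-fold.
#'
#' @param ... name-value overrides of the defaults.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    presence_threshold = 0.75,
    presence_diff_threshold = 0.25,
    cv_quantile = 0.25,
    discovery_fdr = 0.20,
    validation_p = 0.05,
    n_pairs = 12L,
    min_pairs = 2L,
    dv_fraction = 2 / 3,
    candidate_fdr = 0.10,
    candidate_fc = 1.2,
    go_alpha = 0.01,
    paired_fdr = 0.10,
    paired_fc = 1.2,
    rtpcr_p = 0.10,
    rtpcr_fc = 1.2,
    pattern_delta = log2(1.1),
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
  cfg
}

#' @rdname default_config
#' @param cfg configuration list to validate.
#' @export
validate_config <- function(cfg) {
  probs <- c("presence_threshold", "presence_diff_threshold", "cv_quantile",
             "discovery_fdr", "validation_p", "candidate_fdr", "go_alpha",
             "paired_fdr", "rtpcr_p")
  for (key in probs) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("config '", key, "' must lie in (0, 1)", call. = FALSE)
  }
  for (key in c("candidate_fc", "paired_fc", "rtpcr_fc")) {
    if (cfg[[key]] < 1)
      stop("config '", key, "' must be >= 1", call. = FALSE)
  }
  if (cfg$dv_fraction <= 0 || cfg$dv_fraction >= 1)
    stop("config 'dv_fraction' must lie strictly inside (0, 1)",
         call. = FALSE)
  if (cfg$n_pairs < cfg$min_pairs || cfg$min_pairs < 1)
    stop("need n_pairs >= min_pairs >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' rejected, missing keys fall back to [default_config()] defaults.
#'
#' @param path file path.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[which(bad)[1]], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  parsed <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(parsed) <- keys
  do.call(default_config, parsed)
}

#' Write a configuration list as a key=value file
#' @param cfg configuration list.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, format, "", digits = 15L)), path)
  invisible(path)
}

#' Read/write generic tab-delimited result tables
#'
#' @param path file path.
#' @return data.frame.
#' @export
load_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname load_table
#' @param df data.frame to write.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
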