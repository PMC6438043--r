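#' Normalize Ct values to the endogenous control (delta Ct)
#'
#' `dCt(gene, sample) = Ct(gene, sample) - Ct(control, sample)`. Lower
#' delta-Ct means higher expression relative to the control.
#'
#' @param ct long Ct table: gene, sample_id, ct (optionally batch).
#' @param control control gene name (default "18S").
#' @return data.frame: gene, sample_id, delta_ct (plus batch if present).
#' @export
compute_delta_ct <- function(ct, control = "18S") {
  ctrl <- ct[ct$gene == control, ]
  if (!nrow(ctrl)) stop("control gene absent from the Ct table",
                        call. = FALSE)
  out <- ct[ct$gene != control, ]
  ctrl_ct <- ctrl$ct[match(out$sample_id, ctrl$sample_id)]
  if (any(is.na(ctrl_ct)))
    stop("missing control Ct for sample(s): ",
         paste(unique(out$sample_id[is.na(ctrl_ct)]), collapse = ", "),
         call. = FALSE)
  out$delta_ct <- out$ct - ctrl_ct
  out$ct <- NULL
  out
}

#' Group fold change from delta-Ct values (-ddCt method)
#'
#' `-ddCt = mean dCt(nulliparous) - mean dCt(parous)` so that a positive
#' value means higher expression in parous women; `fold_change =
#' 2^(-ddCt)`. Significance comes from a linear regression of dCt on
#' parity with batch as a categorical covariate (skipped, with a log
#' message, when only one batch is present).
#'
#' @param delta_ct output of [compute_delta_ct()].
#' @param metadata cohort metadata (parity per sample).
#' @param batch_adjust include batch in the regression (default TRUE).
#' @param p_cutoff,fc_cutoff significance rule (defaults 0.10 and 1.2,
#'   fold change in either direction).
#' @return data.frame per gene: mean_dct_parous, mean_dct_nulliparous,
#'   neg_ddct, fold_change, p_value, significant.
#' @export
group_fold_change <- function(delta_ct, metadata, batch_adjust = TRUE,
                              p_cutoff = 0.10, fc_cutoff = 1.2) {
  meta <- metadata[match(delta_ct$sample_id, metadata$sample_id), ]
  parity <- meta$parity
  if (!any(parity == "parous") || !any(parity == "nulliparous"))
    stop("both parity groups required", call. = FALSE)
  batch <- if ("batch" %in% names(delta_ct)) delta_ct$batch else meta$batch
  rows <- lapply(split(seq_len(nrow(delta_ct)), delta_ct$gene),
                 function(i) {
    dct <- delta_ct$delta_ct[i]
    par <- parity[i] == "parous"
    mp <- mean(dct[par]); mnp <- mean(dct[!par])
    neg_ddct <- mnp - mp
    b <- factor(batch[i])
    use_batch <- batch_adjust && nlevels(b) > 1L
    if (batch_adjust && !use_batch)
      message("single batch; batch adjustment skipped")
    fit <- if (use_batch) stats::lm(dct ~ par + b) else
      stats::lm(dct ~ par)
    pv <- summary(fit)$coefficients["parTRUE", 4L]
    fc <- 2^neg_ddct
    data.frame(gene = delta_ct$gene[i][1L], mean_dct_parous = mp,
               mean_dct_nulliparous = mnp, neg_ddct = neg_ddct,
               fold_change = fc, p_value = pv,
               significant = pv < p_cutoff & pmax(fc, 1 / fc) >= fc_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way random-effects intraclass correlation (single measure)
#'
#' ICC(1,1) from the one-way ANOVA decomposition over paired measurements:
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` with k = 2 raters per subject.
#'
#' @param x,y paired numeric vectors.
#' @return ICC in [-1, 1].
#' @export
icc_oneway <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  m <- cbind(x, y)
  grand <- mean(m)
  subj_means <- rowMeans(m)
  msb <- 2 * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((m - subj_means)^2) / n
  (msb - msw) / (msb + msw)
}

#' Cross-platform concordance of RT-PCR and array measurements
#'
#' Both series are standardized (zero mean, unit variance) before the
#' intraclass correlation, since -dCt and log2 intensity live on different
#' scales; Spearman rank correlation is computed on the raw paired values.
#' Pass `-dCt` (not dCt) so both platforms increase with expression.
#'
#' @param rtpcr_values per-sample -dCt values.
#' @param array_values per-sample log2 intensities, same sample order.
#' @return list: icc, spearman.
#' @export
platform_concordance <- function(rtpcr_values, array_values) {
  stopifnot(length(rtpcr_values) == length(array_values),
            length(rtpcr_values) >= 3L)
  if (stats::sd(rtpcr_values) == 0 || stats::sd(array_values) == 0)
    stop("zero variance in a series", call. = FALSE)
  zx <- as.numeric(scale(rtpcr_values))
  zy <- as.numeric(scale(array_values))
  list(icc = icc_oneway(zx, zy),
       spearman = stats::cor(rtpcr_values, array_values,
                             method = "spearman"))
}

#' Ratio of group medians
#'
#' @param values_a,values_b positive measurements for the two groups.
#' @return `median(values_a) / median(values_b)`.
#' @export
median_group_ratio <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be nonempty", call. = FALSE)
  if (any(values_a <= 0) || any(values_b <= 0))
    stop("measurements must be positive", call. = FALSE)
  mb <- stats::median(values_b)
  if (mb == 0) stop("zero median in denominator group", call. = FALSE)
  stats::median(values_a) / mb
}
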