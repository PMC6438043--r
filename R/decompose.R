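#' Whole-tissue linear mixture regression
#'
#' Fits, across probes, ordinary least squares of a subject's whole-tissue
#' expression on the matched epithelium and stroma profiles (with
#' intercept): `whole ~ epithelium + stroma`. The two coefficients estimate
#' the compartment mixing weights; R-squared measures how well the whole
#' tissue is explained as a weighted average of its compartments.
#'
#' @param triplet list with `subject_id`, `epithelium`, `stroma`, `whole`
#'   (aligned numeric vectors over a shared probe set).
#' @param min_probes minimum shared probes (default 100).
#' @return data.frame row: subject_id, beta_epithelium, beta_stroma,
#'   intercept, r_squared.
#' @export
fit_mixture_regression <- function(triplet, min_probes = 100L) {
  e <- triplet$epithelium; s <- triplet$stroma; w <- triplet$whole
  if (length(e) < min_probes || length(s) != length(e) ||
      length(w) != length(e))
    stop("triplet needs >= ", min_probes, " aligned probes", call. = FALSE)
  if (abs(stats::cor(e, s)) > 0.999)
    warning("epithelium and stroma are nearly collinear (|r| > 0.999)")
  fit <- stats::lm(w ~ e + s)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((w - mean(w))^2)
  data.frame(subject_id = triplet$subject_id,
             beta_epithelium = unname(stats::coef(fit)["e"]),
             beta_stroma = unname(stats::coef(fit)["s"]),
             intercept = unname(stats::coef(fit)["(Intercept)"]),
             r_squared = r2,
             stringsAsFactors = FALSE)
}

#' Fit the mixture regression for a list of triplets
#' @param triplets list of tissue triplets.
#' @param ... passed to [fit_mixture_regression()].
#' @return data.frame, one row per subject.
#' @export
fit_mixture_regressions <- function(triplets, ...) {
  do.call(rbind, lapply(triplets, fit_mixture_regression, ...))
}

#' Paired epithelium-vs-stroma differential expression
#'
#' Per probe: within-subject log2 ratio (epithelium minus stroma), paired
#' t-test across subjects, Benjamini-Hochberg FDR over probes, and fold
#' change as 2^(median within-subject log ratio). Significant iff q < `fdr`
#' and the fold change is at least `fc` in either direction.
#'
#' @param epithelium,stroma log2 expression matrices with identical probes
#'   and paired subject columns.
#' @param fdr q cutoff (default 0.10).
#' @param fc fold-change cutoff (default 1.2).
#' @return data.frame: probe_id, fold_change, t, p_value, q_value,
#'   significant.
#' @export
epithelium_stroma_de <- function(epithelium, stroma, fdr = 0.10, fc = 1.2) {
  if (!identical(rownames(epithelium), rownames(stroma)))
    stop("probe sets differ between tissues", call. = FALSE)
  if (!identical(colnames(epithelium), colnames(stroma)))
    stop("subject columns are not paired", call. = FALSE)
  n <- ncol(epithelium)
  if (n < 3L) stop(">= 3 subjects required", call. = FALSE)
  d <- epithelium - stroma
  mbar <- rowMeans(d)
  sdv <- apply(d, 1L, stats::sd)
  tstat <- mbar / (sdv / sqrt(n))
  tstat[sdv == 0 & mbar == 0] <- 0  # identical tissues: no evidence
  p <- 2 * stats::pt(abs(tstat), df = n - 1L, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  fold <- 2^apply(d, 1L, stats::median)
  data.frame(probe_id = rownames(d), fold_change = fold, t = tstat,
             p_value = p, q_value = q,
             significant = q < fdr & pmax(fold, 1 / fold) >= fc,
             row.names = NULL, stringsAsFactors = FALSE)
}
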