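#' Per-probe regression of expression on parity
#'
#' Ordinary least squares of each probe's log2 expression on a parity
#' indicator (parous = 1), optionally adjusted for covariates (age, BMI,
#' smoking duration as linear terms; cycle/IUD as a 5-level categorical
#' with "missing" as its own level). The design matrix is shared across
#' probes, so the fits are vectorized through a single QR decomposition.
#' Technical replicate samples (non-empty `replicate_of`) are excluded so
#' that no subject is counted twice. Two-sided p-values come from the t
#' statistic of the parity coefficient; `fold_change = 2^beta_parity`.
#'
#' @param expr log2 expression matrix.
#' @param metadata cohort metadata.
#' @param covariates character vector among `age_years`, `bmi`,
#'   `smoking_duration_years`, `cycle_iud`; NULL or empty for the
#'   single-regression model.
#' @param comparison `"all_P_vs_NP"` (all samples) or `"TSLP<=5_vs_NP"`
#'   (parous restricted to TSLP <= 5 years).
#' @param add_q append Storey q-values via [estimate_qvalues()].
#' @return data.frame: probe_id, beta_parity, fold_change, p_value,
#'   (q_value), model, comparison.
#' @export
fit_probe_model <- function(expr, metadata, covariates = NULL,
                            comparison = c("all_P_vs_NP", "TSLP<=5_vs_NP"),
                            add_q = TRUE) {
  comparison <- match.arg(comparison)
  metadata <- metadata[match(colnames(expr), metadata$sample_id), ]
  if (any(is.na(metadata$sample_id)))
    stop("metadata does not cover every expression sample", call. = FALSE)
  allowed <- c("age_years", "bmi", "smoking_duration_years", "cycle_iud")
  if (length(covariates)) {
    bad <- setdiff(covariates, allowed)
    if (length(bad))
      stop("unknown covariate(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  keep <- is.na(metadata$replicate_of)
  if (comparison == "TSLP<=5_vs_NP")
    keep <- keep & (metadata$parity == "nulliparous" |
                      (!is.na(metadata$tslp_years) &
                         metadata$tslp_years <= 5))
  meta <- metadata[keep, ]
  y <- t(expr[, keep, drop = FALSE])  # samples x probes

  parity <- as.numeric(meta$parity == "parous")
  X <- cbind(`(Intercept)` = 1, parity = parity)
  for (cv in covariates) {
    if (cv == "cycle_iud") {
      f <- factor(meta$cycle_iud, levels = .cycle_levels)
      f <- droplevels(f)
      if (nlevels(f) > 1L)
        X <- cbind(X, stats::model.matrix(~f)[, -1L, drop = FALSE])
    } else {
      X <- cbind(X, stats::setNames(list(meta[[cv]]), cv)[[1]])
      colnames(X)[ncol(X)] <- cv
    }
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  coef <- qr.coef(qrx, y)
  res <- y - X %*% coef
  sigma2 <- colSums(res^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qrx))
  c_par <- xtx_inv[2L, 2L]
  beta <- coef["parity", ]
  se <- sqrt(sigma2 * c_par)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  out <- data.frame(probe_id = colnames(y), beta_parity = unname(beta),
                    fold_change = unname(2^beta), p_value = unname(pval),
                    model = if (length(covariates)) "multiple" else "single",
                    comparison = comparison, stringsAsFactors = FALSE)
  if (add_q) out$q_value <- estimate_qvalues(out$p_value)
  out
}

#' Storey pi0 estimate and q-values
#'
#' Estimates the null proportion pi0 by the natural-cubic-smoother method:
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over the lambda grid
#' 0.05, 0.10, ..., 0.95 is smoothed with a df = 3 spline and evaluated at
#' the largest lambda. When the smoothed estimate falls outside (0, 1] the
#' estimator falls back to `min(1, max(pi0(0.5), 0.05))`. Q-values are
#' `q_i = pi0 * min_{p_j >= p_i} (m p_j / rank_j)`, clipped to [0, 1];
#' with `pi0 = 1` this is exactly Benjamini-Hochberg.
#'
#' @param p p-values in [0, 1].
#' @param pi0 optional fixed pi0 override (e.g. 1 for plain BH).
#' @param lambda grid for the pi0 smoother.
#' @return q-values in the input order.
#' @export
estimate_qvalues <- function(p, pi0 = NULL,
                             lambda = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE) || any(is.na(p)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (is.null(pi0)) pi0 <- estimate_pi0(p, lambda)
  o <- order(p)
  ranked <- p[o]
  q <- pi0 * m * ranked / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' @rdname estimate_qvalues
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) {
    pi0 <- min(1, max(pi0_l[which.min(abs(lambda - 0.5))], 0.05))
  }
  pi0
}
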