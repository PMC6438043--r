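#' Present-call probe filter
#'
#' A probe is removed iff the overall fraction of present ('P') calls is
#' below `overall_threshold` AND the absolute difference in present-call
#' fraction between parous and nulliparous samples is below
#' `diff_threshold`; a large between-group difference rescues a probe that
#' is detectably expressed in only one group. Marginal ('M') calls are not
#' counted as present. The "overall" clause uses the proportion across all
#' samples; both readings of the published rule are recorded in the report
#' header fields.
#'
#' @param calls P/M/A call matrix.
#' @param metadata cohort metadata covering the call matrix's samples.
#' @param overall_threshold present-fraction cutoff (default 0.75).
#' @param diff_threshold group-difference rescue cutoff (default 0.25).
#' @return list: kept_probe_ids, removed_probe_ids, and per-probe fractions
#'   (overall, parous, nulliparous).
#' @export
filter_by_presence <- function(calls, metadata, overall_threshold = 0.75,
                               diff_threshold = 0.25) {
  metadata <- metadata[match(colnames(calls), metadata$sample_id), ]
  if (any(is.na(metadata$sample_id)))
    stop("metadata does not cover every sample in the call matrix",
         call. = FALSE)
  par <- metadata$parity == "parous"
  if (!any(par) || all(par))
    stop("both parity groups must be represented", call. = FALSE)
  is_p <- calls == "P"
  frac_all <- rowMeans(is_p)
  frac_par <- rowMeans(is_p[, par, drop = FALSE])
  frac_np <- rowMeans(is_p[, !par, drop = FALSE])
  removed <- frac_all < overall_threshold &
    abs(frac_par - frac_np) < diff_threshold
  list(kept_probe_ids = rownames(calls)[!removed],
       removed_probe_ids = rownames(calls)[removed],
       presence_overall = frac_all, presence_parous = frac_par,
       presence_nulliparous = frac_np)
}

#' Coefficient-of-variation probe filter
#'
#' Among the probes surviving the presence filter, the CV (SD / mean) is
#' computed on linear-scale intensities (2^log2 value); probes whose CV
#' falls strictly below the first quartile of the surviving probes' CVs are
#' removed. The quartile uses type-7 linear interpolation; exact ties at
#' the quartile survive.
#'
#' @param expr log2 expression matrix.
#' @param kept probe ids surviving the presence filter.
#' @param cv_quantile quantile cutoff (default 0.25).
#' @return list: kept_probe_ids, removed_probe_ids, cv (per surviving
#'   probe), cv_cutoff.
#' @export
filter_by_cv <- function(expr, kept, cv_quantile = 0.25) {
  if (!length(kept)) stop("no probes to filter", call. = FALSE)
  lin <- 2^expr[kept, , drop = FALSE]
  mu <- rowMeans(lin)
  if (any(mu <= 0)) stop("nonpositive linear mean", call. = FALSE)
  sdv <- apply(lin, 1L, stats::sd)
  cv <- sdv / mu
  cutoff <- stats::quantile(cv, cv_quantile, type = 7, names = FALSE)
  keep <- cv >= cutoff
  list(kept_probe_ids = kept[keep], removed_probe_ids = kept[!keep],
       cv = cv, cv_cutoff = cutoff)
}

#' Run both probe filters in order and assemble a filter report
#'
#' The filters are order-dependent: the presence filter runs first and the
#' CV quartile is computed on its survivors. With `combine = "or"` (the
#' variant used for the tissue-compartment substudy) a probe is removed if
#' it fails the presence rule OR has first-quartile CV, the CV quartile
#' being computed on all probes.
#'
#' @param expr log2 expression matrix.
#' @param calls matching call matrix.
#' @param metadata cohort metadata.
#' @param config configuration list ([default_config()]).
#' @param combine "and" (main-study rule) or "or" (substudy variant).
#' @return FilterReport list with counts, kept ids and per-probe stats.
#' @export
filter_probes <- function(expr, calls, metadata, config = default_config(),
                          combine = c("and", "or")) {
  combine <- match.arg(combine)
  stopifnot(identical(rownames(expr), rownames(calls)),
            identical(colnames(expr), colnames(calls)))
  pres <- filter_by_presence(calls, metadata,
                             config$presence_threshold,
                             config$presence_diff_threshold)
  if (combine == "and") {
    cvres <- filter_by_cv(expr, pres$kept_probe_ids, config$cv_quantile)
    kept <- cvres$kept_probe_ids
  } else {
    cvres <- filter_by_cv(expr, rownames(expr), config$cv_quantile)
    kept <- intersect(pres$kept_probe_ids, cvres$kept_probe_ids)
  }
  list(n_input_probes = nrow(expr),
       n_after_presence = length(pres$kept_probe_ids),
       n_after_cv = length(kept),
       kept_probe_ids = kept,
       presence = pres, cv = cvres, combine = combine)
}

#' Parametric empirical-Bayes batch adjustment (ComBat-style)
#'
#' Per probe, the data are standardized against the batch-mean model;
#' per-batch location (gamma) and scale (delta^2) estimates are shrunk
#' toward pooled priors - a normal prior for locations and an
#' inverse-gamma prior for scales, hyperparameters by method of moments -
#' and the matrix is reconstructed with batch means and variances
#' homogenized and the grand mean restored. Parametric priors only; no
#' covariates in the batch model (covariates are handled downstream in the
#' regression stage).
#'
#' @param expr log2 expression matrix.
#' @param batches batch label per column of `expr`.
#' @param conv convergence tolerance of the EB fixed-point iteration.
#' @return list: adjusted (matrix), gamma_star, delta2_star (probe x batch
#'   matrices), hyper (per-batch hyperparameter estimates).
#' @export
combat_adjust <- function(expr, batches, conv = 1e-6) {
  batches <- as.character(batches)
  if (length(batches) != ncol(expr))
    stop("one batch label per sample is required", call. = FALSE)
  tab <- table(batches)
  if (length(tab) < 2L) stop(">= 2 batches required", call. = FALSE)
  if (any(tab < 2L))
    stop("batch with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  b_levels <- names(tab)
  n <- ncol(expr)
  n_b <- as.integer(tab[b_levels])

  # batch-mean model: grand mean = size-weighted batch means, pooled
  # variance with 1/n denominator (method-of-moments scaling)
  idx <- lapply(b_levels, function(b) which(batches == b))
  bmeans <- vapply(idx, function(j) rowMeans(expr[, j, drop = FALSE]),
                   numeric(nrow(expr)))
  alpha <- as.vector(bmeans %*% (n_b / n))
  fitted <- bmeans[, match(batches, b_levels), drop = FALSE]
  resid <- expr - fitted
  sigma2 <- rowSums(resid^2) / n
  if (any(sigma2 <= 0))
    stop("probe with zero residual variance; cannot standardize",
         call. = FALSE)
  z <- (expr - alpha) / sqrt(sigma2)

  g_hat <- vapply(idx, function(j) rowMeans(z[, j, drop = FALSE]),
                  numeric(nrow(expr)))
  d_hat <- vapply(seq_along(idx), function(k) {
    j <- idx[[k]]
    rowSums((z[, j, drop = FALSE] - g_hat[, k])^2) / n_b[k]
  }, numeric(nrow(expr)))

  g_star <- g_hat
  d_star <- d_hat
  hyper <- data.frame(batch = b_levels, gamma_bar = NA_real_,
                      tau2 = NA_real_, lambda = NA_real_, theta = NA_real_)
  for (k in seq_along(b_levels)) {
    gbar <- mean(g_hat[, k])
    tau2 <- stats::var(g_hat[, k])
    m <- mean(d_hat[, k])
    s2 <- stats::var(d_hat[, k])
    hyper[k, 2:3] <- c(gbar, tau2)
    if (!is.finite(tau2) || tau2 < conv || !is.finite(s2) || s2 < conv) {
      # no spread across probes: priors are point masses, keep the
      # per-probe estimates (makes "no batch signal" a fixed point)
      next
    }
    lambda <- (2 * s2 + m^2) / s2
    theta <- (m * s2 + m^3) / s2
    hyper[k, 4:5] <- c(lambda, theta)
    g <- g_hat[, k]
    d <- d_hat[, k]
    zk <- z[, idx[[k]], drop = FALSE]
    repeat {
      g_new <- (n_b[k] * tau2 * g_hat[, k] + d * gbar) /
        (n_b[k] * tau2 + d)
      ss <- rowSums((zk - g_new)^2)
      d_new <- (theta + 0.5 * ss) / (n_b[k] / 2 + lambda - 1)
      if (max(abs(g_new - g), abs(d_new - d)) < conv) {
        g <- g_new; d <- d_new; break
      }
      g <- g_new; d <- d_new
    }
    g_star[, k] <- g
    d_star[, k] <- d
  }

  adj <- z
  for (k in seq_along(b_levels)) {
    j <- idx[[k]]
    adj[, j] <- (z[, j, drop = FALSE] - g_star[, k]) / sqrt(d_star[, k])
  }
  adjusted <- adj * sqrt(sigma2) + alpha
  # EB shrinkage is not exactly mean-preserving; restore each probe's
  # grand mean explicitly
  adjusted <- adjusted - rowMeans(adjusted) + rowMeans(expr)
  dimnames(adjusted) <- dimnames(expr)
  colnames(g_star) <- colnames(d_star) <- b_levels
  list(adjusted = adjusted, gamma_star = g_star, delta2_star = d_star,
       hyper = hyper)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' measuring agreement with the identity line.
#'
#' @param x,y paired numeric vectors.
#' @return CCC in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  # population (1/n) moments, per Lin's definition
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Replicate-pair concordance QC
#'
#' Computes Lin's CCC over probes for every technical replicate pair
#' declared in the metadata and flags pairs below the QC gate.
#'
#' @param expr expression matrix.
#' @param metadata cohort metadata with `replicate_of` links.
#' @param gate QC threshold (default 0.98).
#' @return data.frame: sample_id, replicate_of, ccc, pass.
#' @export
replicate_concordance <- function(expr, metadata, gate = 0.98) {
  pairs <- metadata[!is.na(metadata$replicate_of), c("sample_id",
                                                     "replicate_of")]
  if (!nrow(pairs)) stop("no replicate pairs in metadata", call. = FALSE)
  missing <- setdiff(unique(c(pairs$sample_id, pairs$replicate_of)),
                     colnames(expr))
  if (length(missing))
    stop("replicate link to sample absent from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ccc <- mapply(function(a, b) lin_ccc(expr[, a], expr[, b]),
                pairs$sample_id, pairs$replicate_of)
  data.frame(sample_id = pairs$sample_id,
             replicate_of = pairs$replicate_of,
             ccc = unname(ccc), pass = unname(ccc) >= gate,
             stringsAsFactors = FALSE)
}
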