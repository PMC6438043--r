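#' Stratified discovery/validation partition pairs
#'
#' Each pair splits every cohort record into a discovery set holding a
#' fixed fraction of each parity stratum (round-half-up sizing) and the
#' complementary validation set. Technical replicate records participate
#' in the split but are dropped inside the model fits, so they cannot leak
#' a subject across the discovery/validation boundary. Splits are
#' independent across pairs and reproducible given the seed.
#'
#' @param metadata cohort metadata.
#' @param n_pairs number of independent splits (default 12).
#' @param fraction discovery fraction per stratum (default 2/3).
#' @param seed integer RNG seed.
#' @return list of pairs, each a list(pair_index, discovery, validation) of
#'   sample-id vectors.
#' @export
make_partition_pairs <- function(metadata, n_pairs = 12L, fraction = 2 / 3,
                                 seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly inside (0, 1)", call. = FALSE)
  meta <- metadata
  strata <- split(meta$sample_id, meta$parity)
  if (length(strata) < 2L || any(lengths(strata) < 3L))
    stop("each parity stratum needs >= 3 samples", call. = FALSE)
  sizes <- lapply(strata, function(ids) {
    k <- round_half_up(fraction * length(ids))
    if (k < 1L || k >= length(ids))
      stop("degenerate stratum split", call. = FALSE)
    k
  })
  with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      disc <- unlist(lapply(names(strata), function(s)
        sample(strata[[s]], sizes[[s]])), use.names = FALSE)
      list(pair_index = i, discovery = disc,
           validation = setdiff(meta$sample_id, disc))
    })
  })
}

#' Resampling discovery/validation probe selection
#'
#' For each partition pair, probe models are fitted on the discovery
#' samples and q-values computed within that discovery set; probes with
#' discovery q below `discovery_fdr` are carried into a fit on the
#' validation samples. A probe validates in a pair iff its validation p is
#' below `validation_p` AND the effect direction agrees between discovery
#' and validation. The final selection holds probes validating in at least
#' `min_pairs` of the pairs.
#'
#' @param expr log2 expression matrix (batch-adjusted).
#' @param metadata cohort metadata.
#' @param pairs partition pairs from [make_partition_pairs()].
#' @param discovery_fdr discovery q-value cutoff (default 0.20).
#' @param validation_p validation p cutoff (default 0.05).
#' @param min_pairs consensus threshold (default 2).
#' @param covariates passed to [fit_probe_model()].
#' @return list: `per_probe` data.frame (probe_id, n_validated, validated),
#'   `validated_ids`, and `per_pair` bookkeeping.
#' @export
run_discovery_validation <- function(expr, metadata, pairs,
                                     discovery_fdr = 0.20,
                                     validation_p = 0.05, min_pairs = 2L,
                                     covariates = c("age_years", "bmi",
                                                    "smoking_duration_years",
                                                    "cycle_iud")) {
  universe <- unlist(lapply(pairs, function(p) c(p$discovery, p$validation)))
  if (!all(universe %in% colnames(expr)))
    stop("partition pairs reference samples absent from the matrix",
         call. = FALSE)
  probes <- rownames(expr)
  n_validated <- stats::setNames(integer(length(probes)), probes)
  per_pair <- vector("list", length(pairs))
  for (p in pairs) {
    disc <- fit_probe_model(expr[, p$discovery, drop = FALSE], metadata,
                            covariates = covariates)
    hits <- disc$probe_id[disc$q_value < discovery_fdr]
    ok <- character(0)
    if (length(hits)) {
      val <- fit_probe_model(expr[hits, p$validation, drop = FALSE],
                             metadata, covariates = covariates,
                             add_q = FALSE)
      agree <- sign(val$beta_parity) ==
        sign(disc$beta_parity[match(hits, disc$probe_id)])
      ok <- hits[val$p_value < validation_p & agree]
      n_validated[ok] <- n_validated[ok] + 1L
    }
    per_pair[[p$pair_index]] <- list(pair_index = p$pair_index,
                                     discovery_hits = hits,
                                     validated = ok)
  }
  per_probe <- data.frame(probe_id = probes,
                          n_validated = unname(n_validated),
                          validated = unname(n_validated) >= min_pairs,
                          stringsAsFactors = FALSE)
  list(per_probe = per_probe,
       validated_ids = per_probe$probe_id[per_probe$validated],
       per_pair = per_pair)
}
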