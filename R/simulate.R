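#' Simulate a study cohort
#'
#' Draws per-sample metadata emulating the structure of a parous /
#' nulliparous breast-biopsy cohort. Parous time-since-last-pregnancy
#' (TSLP) is drawn from three strata with probabilities (0.39, 0.37, 0.25)
#' and uniform within stratum (<=5y: U(1,5); 6-10y: U(5,10); >10y:
#' U(10,20)). Ages, BMI and smoking duration bracket the cohort medians,
#' with smoking duration deliberately longer among nulliparous women so
#' that smoking confounds parity. Samples are assigned to hybridization
#' batches of 9-12; from the second batch onward one sample per batch is a
#' blinded cross-batch technical replicate, flagged via `replicate_of` and
#' carrying its source sample's subject covariates.
#'
#' @param n_parous,n_nulliparous group sizes (>= 1).
#' @param seed integer RNG seed (required; all randomness is seeded).
#' @param batch_sizes integer range of batch sizes.
#' @return metadata data.frame (see [validate_metadata()]).
#' @export
simulate_cohort <- function(n_parous, n_nulliparous, seed,
                            batch_sizes = c(9L, 12L)) {
  if (n_parous < 1 || n_nulliparous < 1)
    stop("group sizes must be >= 1", call. = FALSE)
  n <- n_parous + n_nulliparous
  with_seed(seed, {
    parity <- sample(rep(c("parous", "nulliparous"),
                         c(n_parous, n_nulliparous)))
    sample_id <- sprintf("S%03d", seq_len(n))
    tslp <- rep(NA_real_, n)
    par <- parity == "parous"
    stratum <- sample(1:3, sum(par), replace = TRUE,
                      prob = c(0.39, 0.37, 0.25))
    lo <- c(1, 5, 10)[stratum]
    hi <- c(5, 10, 20)[stratum]
    tslp[par] <- stats::runif(sum(par), lo, hi)
    age <- ifelse(par, stats::runif(n, 30, 47.5), stats::runif(n, 30, 46))
    bmi <- stats::runif(n, 18.7, 38)
    # ~2/3 never smoked (duration 0); ever-smoker durations are longer in
    # nulliparous women, so smoking confounds parity among smokers
    ever <- stats::runif(n) < ifelse(par, 0.36, 0.33)
    smoking <- ifelse(ever,
                      ifelse(par, stats::runif(n, 0.5, 20),
                             stats::runif(n, 7, 30)),
                      0)
    cyc <- character(n)
    cyc[par] <- sample(.cycle_levels, sum(par), replace = TRUE,
                       prob = c(0.27, 0.13, 0.27, 0.29, 0.04))
    cyc[!par] <- sample(.cycle_levels, sum(!par), replace = TRUE,
                        prob = c(0.47, 0.13, 0.23, 0.07, 0.10))

    # near-equal batches sized to stay inside the 9-12 range
    ord <- sample.int(n)
    n_batches <- max(1L, round_half_up(n / mean(batch_sizes)))
    while (n_batches > 1L && n / n_batches < batch_sizes[1])
      n_batches <- n_batches - 1L
    while (ceiling(n / n_batches) > batch_sizes[2] &&
           n / (n_batches + 1L) >= batch_sizes[1])
      n_batches <- n_batches + 1L
    sizes <- rep(n %/% n_batches, n_batches)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    batch <- character(n)
    batch[ord] <- rep(sprintf("B%02d", seq_along(sizes)), sizes)

    meta <- data.frame(sample_id = sample_id, parity = parity,
                       tslp_years = tslp, age_years = age, bmi = bmi,
                       smoking_duration_years = smoking, cycle_iud = cyc,
                       batch = batch, replicate_of = NA_character_,
                       stringsAsFactors = FALSE)

    # one cross-batch blinded duplicate per batch (from batch 2 on): the
    # chosen record becomes a re-assay of a same-parity sample from an
    # earlier batch, inheriting all subject covariates
    batches <- sprintf("B%02d", seq_along(sizes))
    used <- character(0)
    for (b in seq_along(batches)[-1]) {
      in_b <- which(meta$batch == batches[b] &
                      !(meta$sample_id %in% used))
      if (!length(in_b)) next
      j <- in_b[sample.int(length(in_b), 1L)]
      src <- which(meta$batch %in% batches[seq_len(b - 1L)] &
                     meta$parity == meta$parity[j] &
                     is.na(meta$replicate_of) &
                     !(meta$sample_id %in% used))
      if (!length(src)) next
      k <- src[sample.int(length(src), 1L)]
      keep <- c("parity", "tslp_years", "age_years", "bmi",
                "smoking_duration_years", "cycle_iud")
      meta[j, keep] <- meta[k, keep]
      meta$replicate_of[j] <- meta$sample_id[k]
      used <- c(used, meta$sample_id[j], meta$sample_id[k])
    }
    validate_metadata(meta)
    meta
  })
}

.pattern_levels <- c("null", "up_transient", "up_longterm_changing",
                     "up_longterm_constant", "down_constant",
                     "down_transient")

#' Default per-pattern generator parameters
#'
#' Base log2 fold change at TSLP = 0, exponential decay rate per year and
#' plateau fraction (fraction of the base effect retained as TSLP grows)
#' for the five planted temporal patterns. The single formula
#' `base * (plateau + (1 - plateau) * exp(-decay * tslp))` covers all
#' patterns: transient patterns have plateau 0, constant patterns plateau 1
#' (decay irrelevant), and the long-term changing pattern an intermediate
#' plateau.
#'
#' @return data.frame with columns pattern, base_log2fc, decay_rate,
#'   plateau_fraction.
#' @export
default_pattern_params <- function() {
  data.frame(
    pattern = c("up_transient", "up_longterm_changing",
                "up_longterm_constant", "down_constant", "down_transient"),
    base_log2fc = c(1.5, 1.2, 1.0, -1.0, -1.5),
    decay_rate = c(0.35, 0.35, 0, 0, 0.35),
    plateau_fraction = c(0, 0.35, 1, 1, 0),
    stringsAsFactors = FALSE
  )
}

#' Planted parity effect as a function of TSLP
#'
#' @param base_log2fc effect at TSLP = 0 (log2 units).
#' @param decay_rate per-year exponential decay.
#' @param plateau_fraction fraction of base retained as TSLP grows.
#' @param tslp years since last pregnancy (NA / nulliparous -> 0).
#' @return log2 effect.
#' @export
parity_effect <- function(base_log2fc, decay_rate, plateau_fraction, tslp) {
  eff <- base_log2fc * (plateau_fraction +
                          (1 - plateau_fraction) * exp(-decay_rate * tslp))
  eff[is.na(tslp)] <- 0
  eff
}

#' Build a per-probe simulation truth table
#'
#' @param n_probes total probe count.
#' @param n_per_pattern planted probes per non-null pattern.
#' @param params per-pattern parameters (see [default_pattern_params()]).
#' @param covariate_coef_sd SD of per-probe covariate coefficients on the
#'   standardized covariate scale.
#' @param seed integer RNG seed.
#' @return truth data.frame: probe_id, pattern, base_log2fc, decay_rate,
#'   plateau_fraction, mu, coef_age, coef_bmi, coef_smoking.
#' @export
simulate_truth <- function(n_probes, n_per_pattern = 20L,
                           params = default_pattern_params(),
                           covariate_coef_sd = 0.05, seed = 1L) {
  n_planted <- n_per_pattern * nrow(params)
  if (n_probes < n_planted)
    stop("n_probes smaller than the number of planted probes", call. = FALSE)
  with_seed(seed, {
    pattern <- c(rep(params$pattern, each = n_per_pattern),
                 rep("null", n_probes - n_planted))
    idx <- match(pattern, params$pattern)
    truth <- data.frame(
      probe_id = sprintf("probe_%05d", seq_len(n_probes)),
      pattern = pattern,
      base_log2fc = ifelse(is.na(idx), 0, params$base_log2fc[idx]),
      decay_rate = ifelse(is.na(idx), 0, params$decay_rate[idx]),
      plateau_fraction = ifelse(is.na(idx), 1, params$plateau_fraction[idx]),
      stringsAsFactors = FALSE
    )
    # planted probes are expressed genes: higher baseline so they pass
    # detection-call filtering, as differentially expressed transcripts do
    truth$mu <- ifelse(truth$pattern == "null",
                       stats::rnorm(n_probes, 7, 2),
                       stats::rnorm(n_probes, 9, 1))
    truth$coef_age <- stats::rnorm(n_probes, 0, covariate_coef_sd)
    truth$coef_bmi <- stats::rnorm(n_probes, 0, covariate_coef_sd)
    truth$coef_smoking <- stats::rnorm(n_probes, 0, covariate_coef_sd)
    truth
  })
}

#' Simulate an expression matrix with batch effects and planted patterns
#'
#' Generates `value(i, j) = mu_i + gamma_b(j) + delta_b(j) * eps +
#' covariate terms + parity_effect_i(TSLP_j)`, with batch locations drawn
#' N(0, `batch_location_sd`) and batch scale factors U(0.8, 1.25).
#' Technical replicate samples share their source's signal (covariates are
#' already copied in the cohort) but receive their own batch effect and
#' independent noise. Present/marginal/absent calls are generated from a
#' logistic function of baseline intensity.
#'
#' @param cohort metadata from [simulate_cohort()].
#' @param n_probes probe count.
#' @param truth optional truth table from [simulate_truth()]; built with
#'   defaults when NULL.
#' @param noise_sd residual SD in log2 units.
#' @param batch_location_sd SD of per-batch location shifts.
#' @param batch_scale_range range of per-batch scale factors.
#' @param presence_center,presence_scale logistic presence-call parameters:
#'   P(present) = plogis((mu - center) / scale).
#' @param marginal_rate probability that a non-present call is M not A.
#' @param seed integer RNG seed (required).
#' @param ... passed to [simulate_truth()] when `truth` is NULL.
#' @return list with `expr` (matrix), `calls` (matrix), `truth`
#'   (data.frame).
#' @export
simulate_expression <- function(cohort, n_probes, truth = NULL,
                                noise_sd = 0.5, batch_location_sd = 0.3,
                                batch_scale_range = c(0.8, 1.25),
                                presence_center = 6.6, presence_scale = 1,
                                marginal_rate = 0.03, seed, ...) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(truth)) truth <- simulate_truth(n_probes, seed = seed, ...)
  if (nrow(truth) != n_probes)
    stop("truth table size does not match n_probes", call. = FALSE)
  n <- nrow(cohort)
  with_seed(seed + 1L, {
    batches <- unique(cohort$batch)
    gamma <- stats::rnorm(length(batches), 0, batch_location_sd)
    delta <- stats::runif(length(batches), batch_scale_range[1],
                          batch_scale_range[2])
    names(gamma) <- names(delta) <- batches

    z <- function(x) as.numeric(scale(x))
    z_age <- z(cohort$age_years)
    z_bmi <- z(cohort$bmi)
    z_smk <- z(cohort$smoking_duration_years)

    eff <- outer(seq_len(n_probes), seq_len(n), function(i, j)
      parity_effect(truth$base_log2fc[i], truth$decay_rate[i],
                    truth$plateau_fraction[i], cohort$tslp_years[j]))
    signal <- truth$mu +
      outer(truth$coef_age, z_age) +
      outer(truth$coef_bmi, z_bmi) +
      outer(truth$coef_smoking, z_smk) +
      eff
    noise <- matrix(stats::rnorm(n_probes * n, 0, noise_sd), n_probes, n)
    expr <- signal +
      matrix(gamma[cohort$batch], n_probes, n, byrow = TRUE) +
      noise * matrix(delta[cohort$batch], n_probes, n, byrow = TRUE)
    dimnames(expr) <- list(truth$probe_id, cohort$sample_id)

    p_present <- stats::plogis((truth$mu - presence_center) / presence_scale)
    pres <- matrix(stats::runif(n_probes * n) < p_present, n_probes, n)
    calls <- matrix("A", n_probes, n, dimnames = dimnames(expr))
    calls[pres] <- "P"
    marg <- !pres & matrix(stats::runif(n_probes * n) < marginal_rate,
                           n_probes, n)
    calls[marg] <- "M"

    list(expr = expr, calls = calls, truth = truth)
  })
}

#' Simulate matched whole/epithelium/stroma tissue triplets
#'
#' Each subject's whole-tissue profile is `w * epithelium + (1 - w) *
#' stroma + N(0, noise_sd)`, with epithelium and stroma drawn around
#' independent probe-level means so the compartments are distinguishable.
#' Default mixing weights are drawn uniformly over the 0.09-0.68 range the
#' compartment proportions span across subjects.
#'
#' @param n_subjects subject count.
#' @param weights epithelial mixing fractions in `[0, 1]` (recycled); NULL
#'   draws them from U(0.09, 0.68).
#' @param noise_sd residual SD of the whole-tissue profile.
#' @param n_probes shared probe count.
#' @param seed integer RNG seed.
#' @return list of triplets, each a list(subject_id, epithelium, stroma,
#'   whole, true_weight).
#' @export
simulate_tissue_triplets <- function(n_subjects, weights = NULL,
                                     noise_sd = 0.1, n_probes = 2000L,
                                     seed = 1L) {
  with_seed(seed, {
    if (is.null(weights)) weights <- stats::runif(n_subjects, 0.09, 0.68)
    weights <- rep_len(weights, n_subjects)
    if (any(weights < 0 | weights > 1))
      stop("mixing weights must lie in [0, 1]", call. = FALSE)
    probes <- sprintf("probe_%05d", seq_len(n_probes))
    lapply(seq_len(n_subjects), function(s) {
      epi <- stats::rnorm(n_probes, 7, 1.5) + stats::rnorm(n_probes, 0, 0.3)
      str <- stats::rnorm(n_probes, 7, 1.5) + stats::rnorm(n_probes, 0, 0.3)
      names(epi) <- names(str) <- probes
      w <- weights[s]
      whole <- w * epi + (1 - w) * str + stats::rnorm(n_probes, 0, noise_sd)
      names(whole) <- probes
      list(subject_id = sprintf("LCM%02d", s), epithelium = epi,
           stroma = str, whole = whole, true_weight = w)
    })
  })
}

#' Simulate a toy GO-like ontology and gene annotation
#'
#' Builds a rooted DAG with three top branches (developmental process,
#' immune response, other), each carrying `n_terms_per_branch` leaf terms.
#' Genes are annotated to 1-3 random leaves; ancestor propagation is done
#' downstream by [propagate_annotation()].
#'
#' @param n_terms_per_branch leaf terms per branch.
#' @param n_genes genes to annotate.
#' @param seed integer RNG seed.
#' @return list(ontology = list(terms, edges, branch_roots), annotation =
#'   data.frame(gene, term)).
#' @export
simulate_toy_ontology <- function(n_terms_per_branch, n_genes, seed = 1L) {
  if (n_terms_per_branch < 1 || n_genes < 1)
    stop("counts must be >= 1", call. = FALSE)
  with_seed(seed, {
    branches <- c(DEV = "developmental process", IMM = "immune response",
                  OTH = "other")
    branch_ids <- sprintf("GO:%s", names(branches))
    leaf_ids <- unlist(lapply(names(branches), function(b)
      sprintf("GO:%s%03d", b, seq_len(n_terms_per_branch))))
    terms <- data.frame(
      term_id = c("GO:ROOT", branch_ids, leaf_ids),
      name = c("biological process", unname(branches),
               sprintf("%s leaf term", rep(unname(branches),
                                           each = n_terms_per_branch))),
      stringsAsFactors = FALSE
    )
    edges <- rbind(
      data.frame(parent = "GO:ROOT", child = branch_ids,
                 stringsAsFactors = FALSE),
      data.frame(parent = rep(branch_ids, each = n_terms_per_branch),
                 child = leaf_ids, stringsAsFactors = FALSE)
    )
    ontology <- list(terms = terms, edges = edges,
                     branch_roots = stats::setNames(branch_ids,
                                                    unname(branches)))
    validate_ontology(ontology)
    genes <- sprintf("G%04d", seq_len(n_genes))
    annotation <- do.call(rbind, lapply(genes, function(g) {
      k <- sample(1:min(3L, length(leaf_ids)), 1L)
      data.frame(gene = g, term = sample(leaf_ids, k),
                 stringsAsFactors = FALSE)
    }))
    list(ontology = ontology, annotation = annotation)
  })
}

#' Simulate an RT-PCR Ct table from planted truth
#'
#' `Ct(gene, sample) = c_gene - planted_parity_effect + N(0, noise_sd)`:
#' lower Ct means higher expression. An 18S control row with near-constant
#' Ct is included for every sample.
#'
#' @param truth truth table from [simulate_truth()].
#' @param cohort metadata.
#' @param genes probe ids to assay (subset of the truth's probes).
#' @param noise_sd Ct noise SD (cycles).
#' @param control_ct mean Ct of the 18S control.
#' @param control_sd SD of the control row.
#' @param seed integer RNG seed.
#' @return long data.frame: gene, sample_id, ct, batch.
#' @export
simulate_rtpcr <- function(truth, cohort, genes, noise_sd = 0.3,
                           control_ct = 18, control_sd = 0.05, seed = 1L) {
  bad <- setdiff(genes, truth$probe_id)
  if (length(bad))
    stop("unknown gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    rows <- lapply(genes, function(g) {
      i <- match(g, truth$probe_id)
      eff <- parity_effect(truth$base_log2fc[i], truth$decay_rate[i],
                           truth$plateau_fraction[i], cohort$tslp_years)
      cg <- stats::runif(1, 22, 28)
      data.frame(gene = g, sample_id = cohort$sample_id,
                 ct = cg - eff + stats::rnorm(nrow(cohort), 0, noise_sd),
                 batch = cohort$batch, stringsAsFactors = FALSE)
    })
    ctrl <- data.frame(gene = "18S", sample_id = cohort$sample_id,
                       ct = control_ct + stats::rnorm(nrow(cohort), 0,
                                                      control_sd),
                       batch = cohort$batch, stringsAsFactors = FALSE)
    out <- rbind(do.call(rbind, rows), ctrl)
    rownames(out) <- NULL
    out
  })
}
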