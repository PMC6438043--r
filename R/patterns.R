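#' TSLP group labels
#'
#' Parous samples are grouped by time since last pregnancy: g1 (TSLP <=
#' 5y), g2 (5 < TSLP <= 10), g3 (TSLP > 10); nulliparous samples are
#' labeled NP.
#'
#' @param metadata cohort metadata.
#' @return character vector of labels, named by sample id.
#' @export
assign_tslp_group <- function(metadata) {
  if (any(metadata$tslp_years < 0, na.rm = TRUE))
    stop("negative TSLP", call. = FALSE)
  t <- metadata$tslp_years
  lab <- ifelse(metadata$parity == "nulliparous", "NP",
                ifelse(t <= 5, "g1", ifelse(t <= 10, "g2", "g3")))
  stats::setNames(lab, metadata$sample_id)
}

#' Per-probe TSLP-group fold-change profiles
#'
#' For each probe, the log2 fold change versus nulliparous in each TSLP
#' group: mean expression of the group's parous samples minus mean of the
#' nulliparous samples. Technical replicates are excluded.
#'
#' @param expr log2 expression matrix.
#' @param metadata cohort metadata.
#' @param probes optional probe subset.
#' @return matrix (probes x 3) with columns g1, g2, g3.
#' @export
tslp_group_profiles <- function(expr, metadata, probes = rownames(expr)) {
  meta <- metadata[match(colnames(expr), metadata$sample_id), ]
  keep <- is.na(meta$replicate_of)
  grp <- assign_tslp_group(meta)[keep]
  sub <- expr[probes, keep, drop = FALSE]
  np_mean <- rowMeans(sub[, grp == "NP", drop = FALSE])
  prof <- vapply(c("g1", "g2", "g3"), function(g) {
    if (!any(grp == g)) stop("empty TSLP group ", g, call. = FALSE)
    rowMeans(sub[, grp == g, drop = FALSE]) - np_mean
  }, numeric(length(probes)))
  rownames(prof) <- probes
  prof
}

#' Candidate probe selection for the TSLP pattern analysis
#'
#' Union of probes differentially expressed in the overall parous vs
#' nulliparous comparison and in the subgroup comparison restricted to
#' parous women with TSLP <= 5 years, each arm requiring q below `fdr` and
#' a fold change of at least `fc` in either direction (reciprocal fold
#' changes qualify down-regulated candidates).
#'
#' @param overall,subgroup [fit_probe_model()] results over the same probe
#'   universe.
#' @param fdr q-value cutoff (default 0.10).
#' @param fc fold-change cutoff (default 1.2).
#' @return character vector of candidate probe ids.
#' @export
select_candidates <- function(overall, subgroup, fdr = 0.10, fc = 1.2) {
  pick <- function(res) {
    two_sided_fc <- pmax(res$fold_change, 1 / res$fold_change)
    res$probe_id[res$q_value < fdr & two_sided_fc >= fc]
  }
  union(pick(subgroup), pick(overall))
}

#' Uncentered Pearson distance
#'
#' `1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))`: zero for proportional
#' profiles (any positive scaling), 1 for orthogonal ones, 2 for perfectly
#' anti-correlated ones.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return distance in [0, 2].
#' @export
uncentered_pearson_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm vector", call. = FALSE)
  d <- 1 - sum(x * y) / (nx * ny)
  min(max(d, 0), 2)
}

#' K-means under the uncentered Pearson distance
#'
#' Lloyd iterations with assignment by nearest centroid under
#' [uncentered_pearson_distance()] and centroids taken as the arithmetic
#' mean of members, renormalized to unit length. An emptied cluster is
#' re-seeded from the point farthest from its centroid. The best of
#' `nstart` seeded restarts (lowest total within-cluster distance) is kept.
#'
#' @param profiles numeric matrix, rows are items to cluster.
#' @param K number of clusters, between 2 and 5.
#' @param seed integer RNG seed.
#' @param nstart random restarts.
#' @param max_iter iteration cap per restart.
#' @return list: cluster (integer vector), centers (K x ncol matrix),
#'   tot_withinss.
#' @export
kmeans_uncentered <- function(profiles, K, seed = 1L, nstart = 10L,
                              max_iter = 100L) {
  if (!(K %in% 2:5)) stop("K must be one of 2, 3, 4, 5", call. = FALSE)
  n <- nrow(profiles)
  if (n < K) stop("need at least K profiles", call. = FALSE)
  norms <- sqrt(rowSums(profiles^2))
  if (any(norms == 0)) stop("zero-norm profile", call. = FALSE)
  U <- profiles / norms  # unit rows: distance = 1 - U %*% t(c_unit)

  run_once <- function() {
    centers <- U[sample.int(n, K), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      sims <- U %*% t(centers)  # centers kept unit-normalized
      assign_new <- max.col(sims, ties.method = "first")
      for (k in seq_len(K)) {
        if (!any(assign_new == k)) {
          d_own <- 1 - sims[cbind(seq_len(n), assign_new)]
          far <- which.max(d_own)
          assign_new[far] <- k
        }
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      for (k in seq_len(K)) {
        m <- colMeans(U[assign_new == k, , drop = FALSE])
        nm <- sqrt(sum(m^2))
        if (nm > 0) centers[k, ] <- m / nm
      }
    }
    sims <- U %*% t(centers)
    d_own <- 1 - sims[cbind(seq_len(n), assign_old)]
    list(cluster = assign_old, centers = centers,
         tot_withinss = sum(d_own))
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      res <- run_once()
      if (is.null(best) || res$tot_withinss < best$tot_withinss) best <- res
    }
    best$cluster <- stats::setNames(best$cluster, rownames(profiles))
    best
  })
}

.up_patterns <- c("transient", "long_term_changing", "long_term_constant")
.down_patterns <- c("down_constant", "down_transient")

#' Classify a TSLP fold-change profile into a temporal pattern
#'
#' Makes the cluster-to-pattern mapping algorithmic with a tolerance band
#' `delta` (default log2(1.1): a 10% band counts as "returned to the
#' nulliparous level"). For upregulated profiles: transient iff
#' `FC_g3 < delta` (no longer elevated by more than the band - a profile
#' that declines past the nulliparous level is still transient); long-term
#' constant iff `FC_g3 >= delta` and `|FC_g1 - FC_g3| <= delta`; long-term
#' changing iff `FC_g3 >= delta` and `FC_g1 - FC_g3 > delta`. Down
#' profiles mirror: down-transient iff `FC_g3 > -delta`, else
#' down-constant. Profiles matching no rule (elevated late and rising)
#' are labeled "unstable".
#'
#' @param profile numeric length-3 vector (g1, g2, g3 log2 fold changes) or
#'   a matrix with three columns.
#' @param direction "up" or "down".
#' @param delta tolerance band in log2 units.
#' @return pattern label(s).
#' @export
classify_pattern <- function(profile, direction = c("up", "down"),
                             delta = log2(1.1)) {
  direction <- match.arg(direction)
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1L)
  g1 <- profile[, 1L]; g3 <- profile[, 3L]
  if (direction == "up") {
    out <- ifelse(g3 < delta, "transient",
           ifelse(g3 >= delta & abs(g1 - g3) <= delta, "long_term_constant",
           ifelse(g3 >= delta & g1 - g3 > delta, "long_term_changing",
                  "unstable")))
  } else {
    out <- ifelse(g3 > -delta, "down_transient", "down_constant")
  }
  out
}

#' Cluster candidate profiles and label them with temporal patterns
#'
#' Splits candidate probes by direction (sign of the g1 fold change),
#' clusters each direction's profiles with [kmeans_uncentered()], and
#' assigns each cluster the pattern of its centroid profile (the average of
#' member profiles on the original fold-change scale) under
#' [classify_pattern()]; probes inherit their cluster's label. K is chosen
#' per direction as the smallest value in `K_range` whose clusters map to
#' distinct pattern labels; if none does, the K with the most distinct
#' labels is used.
#'
#' @param profiles matrix from [tslp_group_profiles()], candidates only.
#' @param K_range candidate cluster counts (subset of 2:5).
#' @param delta passed to [classify_pattern()].
#' @param seed integer RNG seed.
#' @return data.frame: probe_id, direction, cluster_id, pattern.
#' @export
assign_patterns <- function(profiles, K_range = 2:5, delta = log2(1.1),
                            seed = 1L) {
  direction <- ifelse(profiles[, 1L] >= 0, "up", "down")
  out <- lapply(c("up", "down"), function(dir) {
    sub <- profiles[direction == dir, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    if (nrow(sub) < min(K_range)) {
      patt <- classify_pattern(sub, dir, delta)
      return(data.frame(probe_id = rownames(sub), direction = dir,
                        cluster_id = seq_len(nrow(sub)), pattern = patt,
                        stringsAsFactors = FALSE))
    }
    ks <- K_range[K_range <= nrow(sub)]
    fits <- lapply(ks, function(K) {
      km <- kmeans_uncentered(sub, K, seed = seed)
      cent_fc <- t(vapply(seq_len(K), function(k)
        colMeans(sub[km$cluster == k, , drop = FALSE]),
        numeric(ncol(sub))))
      labels <- classify_pattern(cent_fc, dir, delta)
      list(km = km, labels = labels,
           n_distinct = length(setdiff(unique(labels), "unstable")),
           K = K)
    })
    # keep the K exposing the most distinct patterns (clusters sharing a
    # label are merged into one pattern); ties go to the smallest K
    best <- fits[[which.max(vapply(fits, `[[`, 0L, "n_distinct"))]]
    data.frame(probe_id = rownames(sub), direction = dir,
               cluster_id = unname(best$km$cluster),
               pattern = best$labels[best$km$cluster],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[match(rownames(profiles), res$probe_id), , drop = FALSE]
}
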