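test_that("simulate_cohort matches the requested group structure", {
  cohort <- simulate_cohort(79, 30, seed = 1)
  expect_equal(nrow(cohort), 109L)
  expect_equal(sum(!is.na(cohort$tslp_years)), 79L)
  expect_true(all(table(cohort$batch) >= 9 & table(cohort$batch) <= 12))
  # one cross-batch replicate per batch after the first
  reps <- cohort[!is.na(cohort$replicate_of), ]
  expect_equal(nrow(reps), length(unique(cohort$batch)) - 1L)
  src_batch <- cohort$batch[match(reps$replicate_of, cohort$sample_id)]
  expect_true(all(src_batch != reps$batch))

  tiny <- simulate_cohort(1, 1, seed = 99)
  expect_equal(nrow(tiny), 2L)
  expect_equal(sum(!is.na(tiny$tslp_years)), 1L)

  expect_error(simulate_cohort(0, 5, seed = 1), ">= 1")
  expect_identical(simulate_cohort(20, 10, seed = 7),
                   simulate_cohort(20, 10, seed = 7))
})

test_that("TSLP strata frequencies converge to their probabilities", {
  big <- simulate_cohort(790, 300, seed = 7)
  tslp <- big$tslp_years[big$parity == "parous" & is.na(big$replicate_of)]
  expect_lt(abs(mean(tslp <= 5) - 0.39), 0.05)
})

test_that("simulate_expression plants the stated generative model", {
  expect_error(simulate_expression(make_meta("parous"), 10), "seed")

  # null-only truth: parous-minus-nulliparous differences center on zero
  cohort <- simulate_cohort(40, 40, seed = 3)
  sim <- simulate_expression(cohort, 1000, n_per_pattern = 0L,
                             noise_sd = 0.5, seed = 3)
  keep <- is.na(cohort$replicate_of)
  par <- cohort$parity[keep] == "parous"
  d <- rowMeans(sim$expr[, keep][, par]) - rowMeans(sim$expr[, keep][, !par])
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)

  # noiseless constant probe: exact 1-log2-unit group difference
  truth <- simulate_truth(1, n_per_pattern = 0L, seed = 1)
  truth$pattern <- "up_longterm_constant"
  truth$base_log2fc <- 1; truth$plateau_fraction <- 1
  truth$coef_age <- truth$coef_bmi <- truth$coef_smoking <- 0
  clean <- simulate_expression(cohort, 1, truth = truth, noise_sd = 1e-12,
                               batch_location_sd = 0,
                               batch_scale_range = c(1, 1), seed = 4)
  d <- mean(clean$expr[1, keep][par]) - mean(clean$expr[1, keep][!par])
  expect_equal(d, 1, tolerance = 1e-8)

  # closed form of the transient decay
  expect_equal(parity_effect(1, 0.5, 0, 10), exp(-5))
  expect_equal(parity_effect(1, 0.5, 0, NA), 0)  # nulliparous

  # replicates share signal but not noise
  cohort109 <- simulate_cohort(79, 30, seed = 5)
  sim2 <- simulate_expression(cohort109, 50, n_per_pattern = 5L, seed = 5)
  rep_row <- which(!is.na(cohort109$replicate_of))[1]
  src <- cohort109$replicate_of[rep_row]
  expect_gt(cor(sim2$expr[, rep_row], sim2$expr[, src]), 0.9)
  expect_gt(sd(sim2$expr[, rep_row] - sim2$expr[, src]), 0)
})

test_that("presence calls couple to baseline intensity and M is rare", {
  cohort <- simulate_cohort(20, 10, seed = 6)
  sim <- simulate_expression(cohort, 2000, seed = 6)
  frac_p <- rowMeans(sim$calls == "P")
  expect_gt(cor(sim$truth$mu, frac_p), 0.8)
  expect_lte(mean(sim$calls == "M"), 0.02)
})

test_that("tissue triplets realize the planted mixture", {
  tri <- simulate_tissue_triplets(2, weights = c(0.3, 1), noise_sd = 0,
                                  seed = 2)
  expect_equal(tri[[1]]$whole,
               0.3 * tri[[1]]$epithelium + 0.7 * tri[[1]]$stroma)
  expect_equal(tri[[2]]$whole, tri[[2]]$epithelium)

  noisy <- simulate_tissue_triplets(1, weights = 0.5, noise_sd = 0.1,
                                    n_probes = 10000L, seed = 3)[[1]]
  resid <- noisy$whole - 0.5 * noisy$epithelium - 0.5 * noisy$stroma
  expect_lt(abs(sd(resid) - 0.1) / 0.1, 0.05)

  expect_error(simulate_tissue_triplets(1, weights = 1.2, seed = 1),
               "\\[0, 1\\]")
})

test_that("toy ontology is a rooted DAG with three branches", {
  toy <- simulate_toy_ontology(1, 10, seed = 4)
  expect_equal(nrow(toy$ontology$terms), 1L + 3L + 3L)

  toy2 <- simulate_toy_ontology(4, 30, seed = 5)
  genes_of <- propagate_annotation(toy2$annotation, toy2$ontology)
  expect_setequal(genes_of[["GO:ROOT"]], unique(toy2$annotation$gene))

  expect_identical(simulate_toy_ontology(3, 20, seed = 8),
                   simulate_toy_ontology(3, 20, seed = 8))
})

test_that("simulated Ct tables encode expression as lower Ct", {
  cohort <- simulate_cohort(10, 10, seed = 9)
  truth <- simulate_truth(20, n_per_pattern = 1L, seed = 9)
  # up_longterm_constant probe has base 1: planted difference of 1 log2
  g_const <- truth$probe_id[truth$pattern == "up_longterm_constant"]
  g_null <- truth$probe_id[truth$pattern == "null"][1]
  ct <- simulate_rtpcr(truth, cohort, c(g_const, g_null), noise_sd = 0,
                       control_sd = 0, seed = 9)
  ctrl <- ct[ct$gene == "18S", ]
  expect_equal(sd(ctrl$ct), 0)
  dct <- compute_delta_ct(ct)
  par <- cohort$parity[match(dct$sample_id, cohort$sample_id)] == "parous"
  g <- dct$gene == g_const
  expect_equal(mean(dct$delta_ct[g & par]) - mean(dct$delta_ct[g & !par]),
               -1, tolerance = 1e-12)
  fc <- suppressWarnings(group_fold_change(dct[dct$gene == g_null, ],
                                           cohort, batch_adjust = FALSE))
  expect_equal(fc$fold_change, 1)

  expect_error(simulate_rtpcr(truth, cohort, "nope", seed = 1), "unknown")
})
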