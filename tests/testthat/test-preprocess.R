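test_that("presence filter applies the two-clause removal rule", {
  # 10 samples: 5 parous, 5 nulliparous
  meta <- make_meta(rep(c("parous", "nulliparous"), each = 5))
  calls <- rbind(
    # 70% present overall, 80% vs 60% by group (diff 20%): removed
    low_even = c("P", "P", "P", "A", "P", "P", "P", "A", "A", "P"),
    # 80% present overall: kept regardless of group difference
    high = c("P", "P", "P", "P", "P", "P", "P", "P", "A", "A"),
    # 60% overall but group difference 100%: rescued
    low_diff = c("P", "P", "P", "P", "P", "P", "A", "A", "A", "A")
  )
  calls[3, 6] <- "P"  # parous 100%, nulliparous 20% -> 60% overall
  calls[3, 7:10] <- "A"
  colnames(calls) <- meta$sample_id
  res <- filter_by_presence(calls, meta)
  expect_setequal(res$removed_probe_ids, "low_even")
  expect_setequal(res$kept_probe_ids, c("high", "low_diff"))

  expect_error(filter_by_presence(calls, make_meta(rep("parous", 10))),
               "parity")
})

test_that("CV filter removes the strict first quartile on linear scale", {
  # two-point probes with exact linear CVs 0.1, 0.2, 0.3, 0.4
  cvs <- c(0.1, 0.2, 0.3, 0.4)
  lin <- t(sapply(cvs, function(cv) {
    c <- cv / sqrt(2)
    100 * c(1 - c, 1 + c)
  }))
  expr <- make_expr(log2(lin))
  res <- filter_by_cv(expr, rownames(expr))
  expect_equal(res$removed_probe_ids, "p01")
  expect_equal(length(res$kept_probe_ids), 3L)

  # identical CVs: nothing is strictly below the quartile
  same <- make_expr(log2(rbind(c(90, 110), c(180, 220), c(45, 55))))
  res2 <- filter_by_cv(same, rownames(same))
  expect_equal(length(res2$removed_probe_ids), 0L)
})

test_that("joint filters retain about 27% of probes at cohort scale", {
  # scaled-down analogue of the full-array filtering (probe count reduced
  # for runtime; the retained fraction is probe-count invariant)
  cohort <- simulate_cohort(79, 30, seed = 21)
  sim <- simulate_expression(cohort, 8000, seed = 21)
  rep <- filter_probes(sim$expr, sim$calls, cohort)
  expect_lt(abs(rep$n_after_cv / rep$n_input_probes - 0.27), 0.03)
  # order dependence: CV survivors are nested in presence survivors
  expect_true(all(rep$kept_probe_ids %in% rep$presence$kept_probe_ids))
})

test_that("combat_adjust removes a pure location batch effect", {
  # identical within-batch structure, batch 2 shifted +1 on every probe
  base <- make_expr(outer(rnorm(50, 7), rep(1, 6)) +
                      outer(rep(1, 50), rnorm(6)))
  shifted <- cbind(base, base + 1)
  colnames(shifted) <- sprintf("S%02d", 1:12)
  batches <- rep(c("b1", "b2"), each = 6)
  adj <- combat_adjust(shifted, batches)$adjusted
  m1 <- rowMeans(adj[, 1:6]); m2 <- rowMeans(adj[, 7:12])
  expect_lt(max(abs(m1 - m2)), 1e-6)
})

test_that("combat_adjust is the identity when batches carry no signal", {
  half <- make_expr(matrix(rnorm(400, 8), 40, 10))
  both <- cbind(half, half)
  colnames(both) <- sprintf("S%02d", 1:20)
  adj <- combat_adjust(both, rep(c("b1", "b2"), each = 10))$adjusted
  expect_lt(max(abs(adj - both)), 1e-6)
})

test_that("combat_adjust homogenizes simulated batch structure", {
  cohort <- simulate_cohort(40, 20, seed = 31)
  sim <- simulate_expression(cohort, 1000, n_per_pattern = 0L, seed = 31)
  adj <- combat_adjust(sim$expr, cohort$batch)
  batch_f <- function(mat) {
    b <- factor(cohort$batch)
    mean(apply(mat, 1L, function(y)
      summary(stats::aov(y ~ b))[[1]][1, "F value"]))
  }
  expect_gt(batch_f(sim$expr), 2)     # visible structure before
  expect_lte(batch_f(adj$adjusted), 1.2)  # homogenized after
  expect_true(all(adj$delta2_star > 0))

  # grand mean preserved with equal batch sizes
  eq <- make_expr(matrix(rnorm(600, 5), 30, 20))
  adj_eq <- combat_adjust(eq, rep(c("b1", "b2"), each = 10))$adjusted
  expect_lt(max(abs(rowMeans(adj_eq) - rowMeans(eq))), 1e-6)

  expect_error(combat_adjust(eq, c("a", rep("b", 19))), "single sample")
})

test_that("Lin's CCC matches its closed form and flags discordance", {
  expect_equal(lin_ccc(1:10, 1:10), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)

  # symmetry and joint-permutation invariance
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.3)
  expect_equal(lin_ccc(x, y), lin_ccc(y, x))
  perm <- sample(50)
  expect_equal(lin_ccc(x[perm], y[perm]), lin_ccc(x, y))

  # noise_sd 0.1 on signal SD 1: expected CCC ~ 1/(1 + 0.01) = 0.990
  s <- rnorm(5000, 0, 1)
  ccc <- lin_ccc(s + rnorm(5000, 0, 0.1), s + rnorm(5000, 0, 0.1))
  expect_gt(ccc, 0.98)
})

test_that("replicate_concordance evaluates declared pairs", {
  cohort <- simulate_cohort(30, 15, seed = 41)
  sim <- simulate_expression(cohort, 500, noise_sd = 0.1, seed = 41)
  adj <- combat_adjust(sim$expr, cohort$batch)
  cc <- replicate_concordance(adj$adjusted, cohort)
  expect_equal(nrow(cc), sum(!is.na(cohort$replicate_of)))
  expect_true(all(cc$ccc > 0.98))
  expect_true(all(cc$pass))

  bad <- cohort
  bad$replicate_of[which(!is.na(bad$replicate_of))[1]] <- "missing"
  expect_error(replicate_concordance(adj$adjusted, bad), "absent")
})
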