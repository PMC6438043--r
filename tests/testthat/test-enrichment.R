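test_that("hypergeometric tail matches exact enumeration", {
  # spec worked example: universe 10, term 4, selection 5, overlap 4
  universe <- sprintf("g%02d", 1:10)
  term <- universe[1:4]
  sel <- universe[c(1:4, 9)]
  expect_equal(hypergeometric_enrichment(sel, universe, term), 6 / 252)

  expect_equal(hypergeometric_enrichment(sel, universe, character(0)), 1)
  expect_equal(hypergeometric_enrichment(universe, universe, term), 1)
  expect_error(hypergeometric_enrichment(c(sel, "zz"), universe, term),
               "universe")

  # brute-force oracle: enumerate all subsets of small universes
  set.seed(13)
  for (i in 1:15) {
    N <- sample(5:12, 1)
    uni <- sprintf("u%02d", seq_len(N))
    term <- sample(uni, sample(0:N, 1))
    sel <- sample(uni, sample(1:N, 1))
    k <- length(intersect(sel, term))
    combos <- combn(N, length(sel))
    tail_p <- mean(apply(combos, 2L, function(ix)
      length(intersect(uni[ix], term)) >= k))
    expect_equal(hypergeometric_enrichment(sel, uni, term), tail_p)
  }
})

test_that("conditioning discounts genes explained by significant children", {
  # parent whose genes are exactly its one significant child's genes
  ontology <- list(
    terms = data.frame(term_id = c("root", "parent", "child"),
                       name = c("r", "p", "c"), stringsAsFactors = FALSE),
    edges = data.frame(parent = c("root", "parent"),
                       child = c("parent", "child"),
                       stringsAsFactors = FALSE),
    branch_roots = c(other = "root"))
  universe <- sprintf("g%02d", 1:40)
  annotation <- data.frame(gene = universe[1:5], term = "child",
                           stringsAsFactors = FALSE)
  sel <- universe[1:5]
  res <- conditional_go_enrichment(sel, universe, ontology, annotation,
                                   alpha = 0.01)
  expect_true(res$enriched[res$term_id == "child"])
  expect_false(res$enriched[res$term_id == "parent"])
  expect_equal(res$n_term[res$term_id == "parent"], 0L)
})

test_that("a flat ontology reduces to plain hypergeometric tests", {
  set.seed(17)
  terms <- sprintf("t%02d", 1:8)
  ontology <- list(
    terms = data.frame(term_id = terms, name = terms,
                       stringsAsFactors = FALSE),
    edges = data.frame(parent = character(0), child = character(0),
                       stringsAsFactors = FALSE),
    branch_roots = character(0))
  universe <- sprintf("g%02d", 1:50)
  annotation <- data.frame(
    gene = sample(universe, 120, replace = TRUE),
    term = sample(terms, 120, replace = TRUE), stringsAsFactors = FALSE)
  annotation <- unique(annotation)
  sel <- sample(universe, 12)
  res <- conditional_go_enrichment(sel, universe, ontology, annotation)
  genes_of <- propagate_annotation(annotation, ontology)
  for (t in terms) {
    expect_equal(res$p_value[res$term_id == t],
                 hypergeometric_enrichment(sel, universe, genes_of[[t]]))
  }
})

test_that("planted immune signal enriches only the immune branch", {
  toy <- simulate_toy_ontology(5, 100, seed = 19)
  genes_of <- propagate_annotation(toy$annotation, toy$ontology)
  universe <- unique(toy$annotation$gene)
  sel <- head(genes_of[["GO:IMM"]], 20)
  res <- conditional_go_enrichment(sel, universe, toy$ontology,
                                   toy$annotation, alpha = 0.01)
  hit <- res[res$enriched, ]
  expect_gte(sum(hit$branch == "immune response"), 1L)
  expect_equal(sum(hit$branch == "developmental process"), 0L)
})

test_that("broad-category rollup counts annotated genes per branch", {
  toy <- simulate_toy_ontology(2, 30, seed = 23)
  genes_of <- propagate_annotation(toy$annotation, toy$ontology)
  imm_genes <- genes_of[["GO:IMM"]]
  enriched <- data.frame(term_id = "GO:IMM", enriched = TRUE,
                         branch = "immune response",
                         stringsAsFactors = FALSE)
  roll <- rollup_broad_categories(enriched,
                                  list(c1 = imm_genes), toy$ontology,
                                  toy$annotation)
  expect_equal(roll$pct_immune, 100)
  expect_equal(roll$n_annotated, length(imm_genes))

  # invariant to duplicated annotation records and gene order
  dup <- rbind(toy$annotation, toy$annotation)
  roll2 <- rollup_broad_categories(enriched,
                                   list(c1 = rev(imm_genes)), toy$ontology,
                                   dup)
  expect_equal(roll2$pct_immune, roll$pct_immune)
  expect_equal(roll2$n_developmental, roll$n_developmental)
})

test_that("chi-squared statistic matches the brute-force oracle", {
  res <- category_association_test(matrix(10, 3, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(29)
  for (i in 1:100) {
    tab <- matrix(rpois(6, 20) + 1, 3, 2)
    got <- category_association_test(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((tab - expected)^2 / expected)
    expect_equal(got$statistic, oracle)
    expect_equal(got$df, 2L)
    expect_equal(got$p_value, pchisq(oracle, 2, lower.tail = FALSE))
  }

  # sparse table falls back to a permutation test
  expect_warning(
    res2 <- category_association_test(matrix(c(3, 0, 0, 0, 0, 3), 3, 2),
                                      n_perm = 200L, seed = 4),
    "permutation")
  expect_true(res2$p_value > 0 && res2$p_value <= 1)
})

test_that("cyclic ontologies are rejected", {
  bad <- list(
    terms = data.frame(term_id = c("a", "b"), name = c("a", "b"),
                       stringsAsFactors = FALSE),
    edges = data.frame(parent = c("a", "b"), child = c("b", "a"),
                       stringsAsFactors = FALSE),
    branch_roots = character(0))
  expect_error(validate_ontology(bad), "cycle")
})
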