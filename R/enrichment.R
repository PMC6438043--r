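#' Validate an ontology (rooted DAG with three branch roots)
#'
#' An ontology is a list with `terms` (term_id, name), `edges` (parent,
#' child) and `branch_roots` (named character vector mapping the broad
#' categories - developmental process, immune response, other - to term
#' ids). The edge set must be acyclic and every term must reach the root.
#'
#' @param ontology ontology list.
#' @return the ontology, invisibly.
#' @export
validate_ontology <- function(ontology) {
  terms <- ontology$terms$term_id
  edges <- ontology$edges
  bad <- setdiff(unique(c(edges$parent, edges$child)), terms)
  if (length(bad))
    stop("edge references unknown term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(.topo_order(ontology)))
    stop("ontology contains a cycle", call. = FALSE)
  invisible(ontology)
}

# topological order, children before parents; NULL if cyclic
.topo_order <- function(ontology) {
  terms <- ontology$terms$term_id
  kids <- split(ontology$edges$child, ontology$edges$parent)
  n_unresolved <- vapply(terms, function(t)
    length(kids[[t]] %||% character(0)), 0L)
  parents_of <- split(ontology$edges$parent, ontology$edges$child)
  order <- character(0)
  ready <- terms[n_unresolved == 0L]
  n_left <- stats::setNames(n_unresolved, terms)
  while (length(ready)) {
    t <- ready[1L]; ready <- ready[-1L]
    order <- c(order, t)
    for (p in parents_of[[t]] %||% character(0)) {
      n_left[p] <- n_left[p] - 1L
      if (n_left[p] == 0L) ready <- c(ready, p)
    }
  }
  if (length(order) != length(terms)) return(NULL)
  order
}

# term -> all ancestor term ids (excluding itself)
.ancestors <- function(ontology) {
  parents_of <- split(ontology$edges$parent, ontology$edges$child)
  ord <- .topo_order(ontology)  # children first: parents resolved later
  anc <- stats::setNames(vector("list", length(ord)), ord)
  for (t in rev(ord)) {  # parents first
    ps <- parents_of[[t]] %||% character(0)
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Propagate gene annotations to ancestor terms
#'
#' @param annotation data.frame(gene, term) of direct annotations.
#' @param ontology ontology list.
#' @return named list: term id -> character vector of annotated genes
#'   (direct or via any descendant).
#' @export
propagate_annotation <- function(annotation, ontology) {
  validate_ontology(ontology)
  anc <- .ancestors(ontology)
  direct <- split(annotation$gene, annotation$term)
  genes_of <- stats::setNames(
    vector("list", nrow(ontology$terms)), ontology$terms$term_id)
  for (t in names(genes_of)) genes_of[[t]] <- unique(direct[[t]]) %||%
      character(0)
  for (t in names(direct)) {
    for (a in anc[[t]]) genes_of[[a]] <- union(genes_of[[a]], direct[[t]])
  }
  genes_of
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least the attained overlap between a
#' selection and a term's gene set when drawing `|selection|` genes from
#' the universe without replacement.
#'
#' @param selection,universe,term_genes gene sets with `selection` and
#'   `term_genes` inside `universe`.
#' @return p-value in [0, 1].
#' @export
hypergeometric_enrichment <- function(selection, universe, term_genes) {
  if (!all(selection %in% universe) || !all(term_genes %in% universe))
    stop("selection and term genes must lie inside the universe",
         call. = FALSE)
  k <- length(intersect(selection, term_genes))
  K <- length(unique(term_genes))
  N <- length(unique(universe))
  n <- length(unique(selection))
  if (K == 0L || n == 0L) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Conditional hypergeometric GO enrichment over a DAG
#'
#' Terms are processed leaves-upward; when a term is tested, genes already
#' attributed to its significant (conditional p < alpha) descendants are
#' removed from its gene set, so parents are only called enriched on
#' evidence their significant children do not explain.
#'
#' @param selection gene set of interest (subset of universe).
#' @param universe background gene set.
#' @param ontology ontology list.
#' @param annotation data.frame(gene, term) of direct annotations.
#' @param alpha significance cutoff (default 0.01).
#' @return data.frame: term_id, n_selection, n_term, p_value, enriched,
#'   branch.
#' @export
conditional_go_enrichment <- function(selection, universe, ontology,
                                      annotation, alpha = 0.01) {
  genes_of <- propagate_annotation(annotation, ontology)
  genes_of <- lapply(genes_of, intersect, universe)
  ord <- .topo_order(ontology)  # children before parents
  desc_sig_genes <- stats::setNames(vector("list", length(ord)), ord)
  kids <- split(ontology$edges$child, ontology$edges$parent)
  pvals <- stats::setNames(numeric(length(ord)), ord)
  nsel <- nterm <- stats::setNames(integer(length(ord)), ord)
  sig <- stats::setNames(logical(length(ord)), ord)
  for (t in ord) {
    ch <- kids[[t]] %||% character(0)
    cond_remove <- unique(unlist(lapply(ch, function(c)
      c(if (sig[[c]]) genes_of[[c]], desc_sig_genes[[c]])),
      use.names = FALSE))
    gset <- setdiff(genes_of[[t]], cond_remove)
    p <- hypergeometric_enrichment(intersect(selection, universe),
                                   universe, gset)
    pvals[t] <- p
    nterm[t] <- length(gset)
    nsel[t] <- length(intersect(selection, gset))
    sig[t] <- p < alpha
    desc_sig_genes[[t]] <- cond_remove
  }
  branch <- term_branch(ontology)
  data.frame(term_id = ord, n_selection = unname(nsel),
             n_term = unname(nterm), p_value = unname(pvals),
             enriched = unname(sig),
             branch = unname(branch[ord]), stringsAsFactors = FALSE)
}

#' Broad-category membership of each term
#'
#' Assigns each term to the branch root (developmental process, immune
#' response, other) whose subtree contains it; terms reachable from no
#' branch root (e.g. the root itself) fall into "other".
#'
#' @param ontology ontology list.
#' @return named character vector: term id -> branch name.
#' @export
term_branch <- function(ontology) {
  anc <- .ancestors(ontology)
  roots <- ontology$branch_roots
  out <- vapply(ontology$terms$term_id, function(t) {
    up <- c(t, anc[[t]])
    hit <- names(roots)[roots %in% up]
    if (length(hit)) hit[1L] else "other"
  }, "")
  out["GO:ROOT" == names(out)] <- "other"
  out
}

#' Roll enriched terms up into broad-category percentages per cluster
#'
#' A gene counts toward a broad category iff it is annotated (directly or
#' through descendants) to at least one enriched term under that branch
#' root; a gene may count in both categories. The denominator
#' `n_annotated` is the number of cluster genes carrying at least one
#' annotation of any kind (it may be supplied when the annotation table is
#' partial). Percentages are whole percents, rounded half away from zero.
#'
#' @param enriched result of [conditional_go_enrichment()] (or any
#'   data.frame with term_id, enriched, branch).
#' @param cluster_genes named list of per-cluster gene vectors.
#' @param ontology ontology list.
#' @param annotation data.frame(gene, term).
#' @param n_annotated optional named vector overriding the per-cluster
#'   denominators.
#' @return data.frame per cluster: n_annotated, n_developmental, n_immune,
#'   pct_developmental, pct_immune.
#' @export
rollup_broad_categories <- function(enriched, cluster_genes, ontology,
                                    annotation, n_annotated = NULL) {
  genes_of <- propagate_annotation(annotation, ontology)
  cat_genes <- lapply(c(developmental = "developmental process",
                        immune = "immune response"), function(br) {
    ids <- enriched$term_id[enriched$enriched & enriched$branch == br]
    unique(unlist(genes_of[ids], use.names = FALSE))
  })
  annotated_genes <- unique(annotation$gene)
  rows <- lapply(names(cluster_genes), function(cl) {
    g <- unique(cluster_genes[[cl]])
    denom <- if (!is.null(n_annotated)) n_annotated[[cl]] else
      length(intersect(g, annotated_genes))
    ndev <- length(intersect(g, cat_genes$developmental))
    nimm <- length(intersect(g, cat_genes$immune))
    data.frame(cluster = cl, n_annotated = denom, n_developmental = ndev,
               n_immune = nimm,
               pct_developmental = round_half_away(100 * ndev / denom),
               pct_immune = round_half_away(100 * nimm / denom),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Chi-squared test of category composition across clusters
#'
#' Pearson chi-squared (no continuity correction) on the clusters x
#' categories count table, df = (r - 1)(c - 1). If any expected cell falls
#' below 1 a seeded permutation test of the category labels replaces the
#' asymptotic p-value (with a warning).
#'
#' @param counts matrix of nonnegative counts (clusters x categories).
#' @param n_perm permutations for the exact fallback.
#' @param seed RNG seed for the fallback.
#' @return list: statistic, df, p_value, expected, method.
#' @export
category_association_test <- function(counts, n_perm = 10000L, seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / total
  stat_of <- function(obs) {
    e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    sum(ifelse(e > 0, (obs - e)^2 / e, 0))
  }
  stat <- stat_of(counts)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  if (all(expected >= 1)) {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    method <- "pearson"
  } else {
    warning("expected cell below 1; using permutation p-value")
    rows <- rep(seq_len(nrow(counts)), rowSums(counts))
    cols <- rep.int(rep(seq_len(ncol(counts)), nrow(counts)),
                    as.vector(t(counts)))
    p <- with_seed(seed, {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        perm <- table(factor(rows, seq_len(nrow(counts))),
                      factor(sample(cols), seq_len(ncol(counts))))
        if (stat_of(unclass(perm)) >= stat - 1e-12) hits <- hits + 1L
      }
      (hits + 1L) / (n_perm + 1L)
    })
    method <- "permutation"
  }
  list(statistic = stat, df = df, p_value = p, expected = expected,
       method = method)
}
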