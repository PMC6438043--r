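# shared fixture builders; everything is generated in code, no files

# tiny named expression matrix
make_expr <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("p%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal valid metadata for a vector of parity labels
make_meta <- function(parity, tslp = NULL, batch = NULL) {
  n <- length(parity)
  if (is.null(tslp))
    tslp <- ifelse(parity == "parous", 3, NA_real_)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)), parity = parity,
             tslp_years = tslp, age_years = 35 + seq_len(n) %% 10,
             bmi = 24, smoking_duration_years = 0,
             cycle_iud = "luteal",
             batch = batch %||% rep("B1", n),
             replicate_of = NA_character_, stringsAsFactors = FALSE)
}

# adjusted Rand index, used to compare clusterings to planted truth
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# mapping from generator pattern names to classifier labels
pattern_label_map <- c(
  up_transient = "transient",
  up_longterm_changing = "long_term_changing",
  up_longterm_constant = "long_term_constant",
  down_constant = "down_constant",
  down_transient = "down_transient"
)
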