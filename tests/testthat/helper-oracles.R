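# Independent oracles, deliberately coded naively and separately from the
# package's vectorized paths.

# Textbook Welch two-sample t p-value for a single gene.
welch_oracle <- function(s, c) {
  ns <- length(s); nc <- length(c)
  vs <- sum((s - mean(s))^2) / (ns - 1)
  vc <- sum((c - mean(c))^2) / (nc - 1)
  se2 <- vs / ns + vc / nc
  tt <- (mean(s) - mean(c)) / sqrt(se2)
  df <- se2^2 / ((vs / ns)^2 / (ns - 1) + (vc / nc)^2 / (nc - 1))
  2 * pt(-abs(tt), df)
}

# Pearson correlation through the raw covariance formula.
cor_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Term-by-term RIF sums, no vectorization.
rif1_loop <- function(de, dc_by_target) {
  acc <- 0
  for (j in seq_len(nrow(de)))
    acc <- acc + de$x_j[j] * de$d_j[j] * dc_by_target[[de$gene_id[j]]]^2
  acc / nrow(de)
}

rif2_loop <- function(de, rs_by_target, rc_by_target) {
  acc <- 0
  for (j in seq_len(nrow(de))) {
    g <- de$gene_id[j]
    acc <- acc + (de$x_jS[j] * rs_by_target[[g]])^2 -
      (de$x_jC[j] * rc_by_target[[g]])^2
  }
  acc / nrow(de)
}

# Upper hypergeometric tail by direct pmf summation.
hyper_tail_oracle <- function(b, B, N, n) {
  ks <- b:min(B, n)
  if (b > min(B, n)) return(0)
  sum(choose(B, ks) * choose(N - B, n - ks) / choose(N, n))
}

# Random Gaussian two-condition study with S/C labels.
random_study <- function(n_genes = 20, n_s = 5, n_c = 5, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * (n_s + n_c), mean = 8), nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 c(sprintf("S%02d", seq_len(n_s)),
                                   sprintf("C%02d", seq_len(n_c)))))
  cond <- setNames(rep(c("S", "C"), c(n_s, n_c)), colnames(vals))
  expression_study(vals, cond, treated_label = "S", control_label = "C")
}

# Same study with the condition roles exchanged.
swap_roles <- function(study) {
  expression_study(study$values,
                   setNames(ifelse(study$condition_of == "S", "C", "S"),
                            study$sample_ids),
                   treated_label = "S", control_label = "C")
}
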