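# Fixtures are built in code at test time.

# Small genotype matrix with known dosages
makeToyGenotypes <- function(n = 6L, m = 4L, seed = 1L) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  rownames(d) <- sprintf("ind%02d", seq_len(n))
  colnames(d) <- sprintf("snp%02d", seq_len(m))
  genotypeMatrix(d)
}

# Write a genotype CSV (header of marker IDs, first column sample IDs);
# entries may include NA
writeToyCsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}

# Independent largest-remainder apportionment (no caps), used as an oracle
oracleLargestRemainder <- function(weights, total) {
  t <- total * weights / sum(weights)
  q <- floor(t)
  left <- total - sum(q)
  ord <- order(-(t - q), seq_along(t))
  for (j in ord) {
    if (left <= 0) break
    q[j] <- q[j] + 1
    left <- left - 1
  }
  as.integer(q)
}

# Key a holdout subset for frequency counting
subsetKey <- function(idx) paste(sort(idx), collapse = "-")
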