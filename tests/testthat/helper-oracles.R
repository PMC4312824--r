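# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# Benjamini-Hochberg step-up by the definition: q_(i) = min_{j>=i} m p_(j)/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# AUC by counting concordant pairs (ties = 1/2)
auc_pairs_oracle <- function(scores, is_case) {
  cs <- scores[is_case]
  ct <- scores[!is_case]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cs) * length(ct))
}

# Pearson chi-square from first principles
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# non-EB batch standardization: remove per-batch mean/sd of the standardized
# data directly, no shrinkage (large-n limit of the EB adjustment)
combat_nonparam_oracle <- function(x, batch) {
  batch <- factor(batch)
  out <- x
  for (j in seq_len(ncol(x))) {
    y <- x[, j]
    bm <- tapply(y, batch, mean)
    alpha <- sum(table(batch) / length(y) * bm)
    resid <- y - bm[batch]
    sigma <- sqrt(mean(resid^2))
    z <- (y - alpha) / sigma
    zm <- tapply(z, batch, mean)
    zs <- tapply(z, batch, sd)
    out[, j] <- sigma * (z - zm[batch]) / zs[batch] + alpha
  }
  out
}

# tiny complete matrix with dimnames
toy_matrix <- function(values, n, p, scale = "raw",
                       samples = sprintf("S%02d", seq_len(n)),
                       features = sprintf("f%02d", seq_len(p))) {
  feature_matrix(matrix(values, n, p, dimnames = list(samples, features)),
                 scale)
}

toy_meta <- function(n, diagnosis, batch = rep(1L, n),
                     ids = sprintf("S%02d", seq_len(n))) {
  tibble::tibble(
    sample_id = ids, diagnosis = diagnosis, batch = batch,
    age = seq(70, 85, length.out = n),
    sex = rep(c("F", "M"), length.out = n),
    apoe4 = rep(0:2, length.out = n),
    mmse = seq(20, 30, length.out = n),
    statin = rep(0:1, length.out = n), smoking = rep(0L, n))
}
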