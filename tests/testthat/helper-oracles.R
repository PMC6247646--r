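# Independent brute-force oracles, written straight from the definitions and
# kept free of the package's code paths.

# Pincus ApEn by the double loop over templates (self-matches counted)
apen_brute <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    counts <- numeric(nt)
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) counts[i] <- counts[i] + 1
      }
    }
    mean(log(counts / nt))
  }
  phi(m) - phi(m + 1)
}

# the twelve window features recomputed from their definitions
features_brute <- function(w) {
  zn <- if (sd(w) > 0) (w - mean(w)) / sd(w) else rep(0, length(w))
  fd <- w[-1] - w[-length(w)]
  sd2 <- fd[-1] - fd[-length(fd)]
  fdn <- zn[-1] - zn[-length(zn)]
  sdn <- fdn[-1] - fdn[-length(fdn)]
  q <- quantile(w, c(0.25, 0.75), names = FALSE)
  c(MAV = sum(abs(w)) / length(w),
    RMS = sqrt(sum(w^2) / length(w)),
    PEAK = max(w),
    MAVSDN = sum(abs(sdn)) / length(sdn),
    MAVSD = sum(abs(sd2)) / length(sd2),
    MAVFDN = sum(abs(fdn)) / length(fdn),
    MAVFD = sum(abs(fd)) / length(fd),
    INTERQ_RANGE = q[2] - q[1],
    RANGE = max(w) - min(w),
    STD = sqrt(sum((w - mean(w))^2) / (length(w) - 1)),
    VAR = sum((w - mean(w))^2) / (length(w) - 1),
    ApEn = apen_brute(w, 2, 0.2 * sd(w)))
}

# AUC as the pairwise concordance count (Mann-Whitney; ties worth 1/2)
auc_brute <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# two-sample KS statistic as the maximal ECDF gap
ks_brute <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

# KL divergence by an explicit element loop
kl_brute <- function(p, q) {
  tot <- 0
  for (i in seq_along(p)) if (p[i] > 0) tot <- tot + p[i] * log(p[i] / q[i])
  tot
}

# Shannon entropy (bits) of one affinity row, for the perplexity oracle
row_perplexity <- function(p) {
  p <- p[p > 0]
  2^(-sum(p * log2(p)))
}

# leave-one-out 1-nearest-neighbor accuracy
nn1_loocv <- function(X, labels) {
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  mean(labels[apply(D, 1, which.min)] == labels)
}
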