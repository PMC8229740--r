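# Independent brute-force oracles used to validate the fast implementations.
# These re-derive each quantity from first principles and must stay
# independent of the package's computational path.

# the 13 unique distance-1 3D offsets, in the package's direction order
ORACLE_DIRS <- list(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# exhaustive symmetric co-occurrence probabilities by enumerating every
# voxel pair; levels: integer array, 0 outside the ROI
oracle_glcm <- function(levels) {
  d <- dim(levels)
  out <- list()
  for (di in seq_along(ORACLE_DIRS)) {
    off <- ORACLE_DIRS[[di]]
    counts <- list()
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      a <- levels[i, j, k]
      if (a == 0) next
      p2 <- c(i, j, k) + off
      if (any(p2 < 1) || any(p2 > d)) next
      b <- levels[p2[1], p2[2], p2[3]]
      if (b == 0) next
      for (key in c(paste(a, b), paste(b, a))) {
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
    if (length(counts) == 0) next
    tot <- sum(unlist(counts))
    ij <- do.call(rbind, lapply(strsplit(names(counts), " "), as.integer))
    out[[length(out) + 1]] <- data.frame(
      direction = di, i = ij[, 1], j = ij[, 2],
      p = unlist(counts) / tot, row.names = NULL)
  }
  df <- do.call(rbind, out)
  df[order(df$direction, (df$i - 1) * max(df$j) * 0 + df$i, df$j), ]
}

# exhaustive run enumeration and the 16 run-length features from it
oracle_glrlm_runs <- function(levels, off) {
  d <- dim(levels)
  runs <- list()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- levels[i, j, k]
    if (a == 0) next
    prev <- c(i, j, k) - off
    if (!(any(prev < 1) || any(prev > d)) &&
        levels[prev[1], prev[2], prev[3]] == a) next  # not a run start
    len <- 1
    cur <- c(i, j, k) + off
    while (!(any(cur < 1) || any(cur > d)) &&
           levels[cur[1], cur[2], cur[3]] == a) {
      len <- len + 1
      cur <- cur + off
    }
    runs[[length(runs) + 1]] <- c(level = a, length = len)
  }
  do.call(rbind, runs)
}

oracle_glrlm_features <- function(levels) {
  np <- sum(levels > 0)
  feats <- NULL
  for (off in ORACLE_DIRS) {
    runs <- oracle_glrlm_runs(levels, off)
    if (is.null(runs)) next
    i <- runs[, "level"]; j <- runs[, "length"]
    nr <- nrow(runs)
    gl <- tapply(rep(1, nr), i, sum)          # runs per grey level
    rl <- tapply(rep(1, nr), j, sum)          # runs per length
    cell <- tapply(rep(1, nr), paste(i, j), sum)   # P(i,j) counts
    pcell <- cell / nr
    p <- rep(1 / nr, nr)
    f <- c(
      ShortRunEmphasis = sum(1 / j^2) / nr,
      LongRunEmphasis = sum(j^2) / nr,
      GrayLevelNonUniformity = sum(gl^2) / nr,
      GrayLevelNonUniformityNormalized = sum(gl^2) / nr^2,
      RunLengthNonUniformity = sum(rl^2) / nr,
      RunLengthNonUniformityNormalized = sum(rl^2) / nr^2,
      RunPercentage = nr / np,
      GrayLevelVariance = sum(p * (i - sum(p * i))^2),
      RunVariance = sum(p * (j - sum(p * j))^2),
      RunEntropy = -sum(pcell * log2(pcell)),
      LowGrayLevelRunEmphasis = sum(1 / i^2) / nr,
      HighGrayLevelRunEmphasis = sum(i^2) / nr,
      ShortRunLowGrayLevelEmphasis = sum(1 / (i^2 * j^2)) / nr,
      ShortRunHighGrayLevelEmphasis = sum(i^2 / j^2) / nr,
      LongRunLowGrayLevelEmphasis = sum(j^2 / i^2) / nr,
      LongRunHighGrayLevelEmphasis = sum(i^2 * j^2) / nr)
    feats <- rbind(feats, f)
  }
  colMeans(feats)
}

# one-way variance-components ICC via aov mean squares
oracle_icc <- function(values) {
  long <- data.frame(
    y = as.vector(t(values)),
    subject = factor(rep(seq_len(nrow(values)), each = ncol(values))))
  ms <- summary(aov(y ~ subject, data = long))[[1]]$`Mean Sq`
  k <- ncol(values)
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

# U-statistic AUC by explicit pair counting (half credit for ties)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  gr <- outer(pos, neg, `>`)
  eq <- outer(pos, neg, `==`)
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# exhaustive permutation test for the Spearman correlation (small n)
oracle_spearman_perm <- function(x, y) {
  n <- length(x)
  perms <- gtools_permutations(n)
  obs <- cor(rank(x), rank(y))
  stats <- apply(perms, 1, function(p) cor(rank(x), rank(y[p])))
  list(rho = obs, p = mean(abs(stats) >= abs(obs) - 1e-12))
}

# all permutations of 1..n (n <= 8)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
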