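# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-derivations (explicit normal equations,
# textbook covariance formula, exhaustive window enumeration, Welch's
# formula written out) and must stay independent of the package code
# paths they check.

# explicit (X'X)^-1 X'y least squares with per-coefficient t inference
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  beta <- drop(XtXinv %*% t(X) %*% y)
  resid <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(XtXinv) * s2)
  tval <- beta / se
  list(coefficients = beta, se = se, t = tval,
       p = 2 * pt(abs(tval), df, lower.tail = FALSE), df = df)
}

# textbook Pearson correlation, p via the t transform, slope of y on x
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tt), n - 2, lower.tail = FALSE),
       slope = sxy / sxx)
}

# exhaustive both-strand window scan using the package's similarity
# definition evaluated position by position on raw strings
scan_oracle <- function(seq, mat, threshold) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score1 <- function(win) {
    b <- strsplit(win, "")[[1]]
    num <- 0
    for (i in seq_len(mat$width)) {
      f <- mat$freq[i, ]
      num <- num + mat$weights[i] * ifelse(b[i] %in% names(f), f[b[i]], 0)
    }
    num / sum(mat$weights * apply(mat$freq, 1, max))
  }
  L <- nchar(seq); w <- mat$width
  out <- list()
  for (st in seq_len(L - w + 1)) {
    win <- substr(seq, st, st + w - 1)
    s_f <- score1(win)
    if (s_f >= threshold)
      out[[length(out) + 1]] <- data.frame(start = st - 1L, strand = "+",
                                           similarity = s_f)
    s_r <- score1(revcomp(win))
    if (s_r >= threshold)
      out[[length(out) + 1]] <- data.frame(start = st - 1L, strand = "-",
                                           similarity = s_r)
  }
  if (!length(out)) return(data.frame(start = integer(), strand = character(),
                                      similarity = numeric()))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# Welch's two-sample t written out from the formulas
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tt, df = df, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

# random full-rank design for oracle-equivalence checks
random_design <- function(n, p, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  X
}

study_types <- c("tumor", "stroma", "BPH")
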