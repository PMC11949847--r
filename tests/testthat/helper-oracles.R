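# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with naive loops, never calling the package's own
# vectorized implementations.

# grayscale + quantization exactly as documented (shared preprocessing, not
# the quantity under test)
oracle_quantize <- function(block, levels) {
  gray <- if (length(dim(block)) == 3) {
    0.2989 * block[, , 1] + 0.5870 * block[, , 2] + 0.1140 * block[, , 3]
  } else block
  q <- floor(gray * levels) + 1L
  q[q > levels] <- levels
  q
}

# double-loop co-occurrence counter over every pixel pair, one offset
oracle_glcm_counts <- function(q, dr, dc, levels) {
  out <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        out[q[r, cc], q[r2, c2]] <- out[q[r, cc], q[r2, c2]] + 1
      }
    }
  }
  out
}

# full direction-averaged symmetric normalized GLCM by brute force
oracle_glcm <- function(block, levels) {
  q <- oracle_quantize(block, levels)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- matrix(0, levels, levels)
  for (o in offs) {
    p <- oracle_glcm_counts(q, o[1], o[2], levels)
    acc <- acc + p + t(p)
  }
  acc <- acc / 4
  acc / sum(acc)
}

# naive loop evaluation of the 16 texture descriptors
oracle_haralick <- function(p) {
  ng <- nrow(p)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p)
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]

  ent <- en <- inert <- corr <- hom <- diss <- ssq <- idm <- 0
  cs <- cp <- 0
  pxy_s <- rep(0, 2 * ng)
  pxy_d <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    ent <- ent - v * lg(v)
    en <- en + v^2
    inert <- inert + (i - j)^2 * v
    hom <- hom + v / (1 + abs(i - j))
    diss <- diss + abs(i - j) * v
    ssq <- ssq + (i - mu)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    cs <- cs + (i + j - 2 * mu)^3 * v
    cp <- cp + (i + j - 2 * mu)^4 * v
    if (sig2 >= 1e-12) corr <- corr + (i - mu) * (j - mu) * v / sig2
    pxy_s[i + j] <- pxy_s[i + j] + v
    pxy_d[abs(i - j) + 1] <- pxy_d[abs(i - j) + 1] + v
  }
  sa <- sv <- se <- 0
  for (k in 2:(2 * ng)) sa <- sa + k * pxy_s[k]
  for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * pxy_s[k]
  for (k in 2:(2 * ng)) se <- se - pxy_s[k] * lg(pxy_s[k])
  dm <- dv <- de <- 0
  for (k in 0:(ng - 1)) dm <- dm + k * pxy_d[k + 1]
  for (k in 0:(ng - 1)) dv <- dv + (k - dm)^2 * pxy_d[k + 1]
  for (k in 0:(ng - 1)) de <- de - pxy_d[k + 1] * lg(pxy_d[k + 1])

  c(Entropy = ent, Energy = en, Inertia = inert, Correlation = corr,
    Homogeneity = hom, Dissimilarity = diss, Sum_of_squares = ssq,
    Sum_average = sa, Sum_variance = sv, Sum_entropy = se,
    Difference_variance = dv, Difference_entropy = de,
    Cluster_shade = cs, Cluster_prominence = cp,
    Inverse_difference_moment = idm, Maximum_probability = max(p))
}

# per-pixel accumulation of channel moments
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- m3 <- m4 <- ss <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2 / n; m3 <- m3 + d^3 / n; m4 <- m4 + d^4 / n
    ss <- ss + d^2
  }
  if (m2 < 1e-12) c(mu, sqrt(ss / (n - 1)), 0, 0)
  else c(mu, sqrt(ss / (n - 1)), m3 / m2^1.5, m4 / m2^2)
}

# direct entropy-based correlation quantities, independent of the package
oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

oracle_su <- function(x, y) {
  hx <- oracle_entropy(x); hy <- oracle_entropy(y)
  if (hx + hy == 0) return(0)
  hxy <- oracle_entropy(paste(x, y))
  2 * (hx + hy - hxy) / (hx + hy)
}

# direct Eq.-style merit from explicit correlation values
oracle_merit <- function(rcf_vals, rff_mat) {
  k <- length(rcf_vals)
  rcf <- mean(rcf_vals)
  rff <- if (k == 1) 0 else {
    s <- 0; cnt <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      s <- s + rff_mat[a, b]; cnt <- cnt + 1
    }
    s / cnt
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# exhaustive CFS optimum over all non-empty subsets, built from the raw
# table with the oracle's own discretization-free SU on pre-binned columns
oracle_exhaustive_cfs <- function(disc_cols, y) {
  feats <- names(disc_cols)
  rcf <- vapply(disc_cols, function(x) oracle_su(x, y), numeric(1))
  nf <- length(feats)
  rff <- diag(1, nf)
  for (a in seq_len(nf - 1)) for (b in (a + 1):nf) {
    rff[a, b] <- rff[b, a] <- oracle_su(disc_cols[[a]], disc_cols[[b]])
  }
  best <- -Inf; best_set <- NULL
  for (mask in 1:(2^nf - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(nf) - 1)) > 0)
    m <- oracle_merit(rcf[idx], rff[idx, idx, drop = FALSE])
    if (m > best + 1e-12) { best <- m; best_set <- feats[idx] }
  }
  list(merit = best, subset = sort(best_set))
}
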