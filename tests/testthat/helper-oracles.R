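# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct formulas, dense grid search, exhaustive
# enumeration, and closed-form factor-model covariance.

# Pearson chi-square from first principles: sum (O - E)^2 / E
chisqOracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# iterated dense grid search over the soft-threshold level: smallest d with
# ||w(d)||_1 <= c, w(d) = S(x, d)/||S(x, d)||_2; three refinement passes give
# ~1e-9 resolution on d
gridProjectOracle <- function(x, c, levels = 3, npts = 800) {
  softg <- function(x, d) sign(x) * pmax(abs(x) - d, 0)
  wof <- function(d) {
    s <- softg(x, d)
    n2 <- sqrt(sum(s^2))
    if (n2 == 0) rep(0, length(x)) else s / n2
  }
  feasible <- function(d) sum(abs(wof(d))) <= c + 1e-12
  if (feasible(0)) return(wof(0))
  lo <- 0
  hi <- max(abs(x))
  for (lev in seq_len(levels)) {
    ds <- seq(lo, hi, length.out = npts)
    ok <- vapply(ds, feasible, logical(1))
    i <- which(ok)[1]
    hi <- ds[i]
    lo <- ds[max(i - 1, 1)]
  }
  wof(hi)
}

# exhaustive search over one-hot weight pairs for two blocks at c = 1
oneHotOracle <- function(C12) {
  best <- c(NA, NA)
  bestval <- -Inf
  for (i in seq_len(nrow(C12))) {
    for (j in seq_len(ncol(C12))) {
      if (abs(C12[i, j]) > bestval) {
        bestval <- abs(C12[i, j])
        best <- c(i, j)
      }
    }
  }
  best
}

# closed-form covariance of the factor model the generator implements:
# f_d = lambda_d * sTilde + latentSd_d * g_d, continuous u = sum_d beta_ud
# f_d + noiseSd * eps_u, sex binary with P(1) = pMale. Returns the
# population correlation matrix over `vars` plus the covariance on the
# analysis scale (continuous variables unit-variance, sex raw 0/1).
popCovOracle <- function(effects, vars, noiseSd = 1, pMale = 10 / 24) {
  D <- length(effects)
  lam <- vapply(effects, function(pd) {
    if ("sex" %in% names(pd$loadings)) pd$loadings[["sex"]] else 0
  }, numeric(1))
  lsd <- vapply(effects, function(pd) pd$latentSd, numeric(1))
  Vf <- outer(lam, lam)
  diag(Vf) <- lam^2 + lsd^2
  B <- matrix(0, length(vars), D, dimnames = list(vars, NULL))
  for (d in seq_len(D)) {
    l <- effects[[d]]$loadings
    cont <- setdiff(names(l), "sex")
    B[cont, d] <- l[cont]
  }
  Sig <- B %*% Vf %*% t(B)
  diag(Sig) <- diag(Sig) + noiseSd^2
  sdsex <- sqrt(pMale * (1 - pMale))
  if ("sex" %in% vars) {
    cvec <- as.vector(B %*% lam) * sdsex
    Sig["sex", ] <- cvec
    Sig[, "sex"] <- cvec
    Sig["sex", "sex"] <- pMale * (1 - pMale)
  }
  sds <- sqrt(diag(Sig))
  R <- Sig / outer(sds, sds)
  scl <- ifelse(vars == "sex", 1, sds)
  list(cor = R, covAnalysis = Sig / outer(scl, scl))
}

# aligned random standardized blocks for solver tests
randBlocks <- function(n, p, seed) {
  set.seed(seed)
  out <- lapply(seq_along(p), function(i) {
    m <- scale(matrix(rnorm(n * p[i]), n))
    colnames(m) <- paste0("v", i, "_", seq_len(p[i]))
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    m
  })
  names(out) <- paste0("block", seq_along(p))
  out
}

# analysis-scale model-implied correlation of two block scores
modelScoreCor <- function(covA, vars, wi, wj, idxI, idxJ) {
  Cij <- covA[idxI, idxJ, drop = FALSE]
  Cii <- covA[idxI, idxI, drop = FALSE]
  Cjj <- covA[idxJ, idxJ, drop = FALSE]
  drop(t(wi) %*% Cij %*% wj) /
    sqrt(drop(t(wi) %*% Cii %*% wi) * drop(t(wj) %*% Cjj %*% wj))
}
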