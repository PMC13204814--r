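# internal helpers shared across modules

# bias-adjusted Fisher-Pearson sample skewness
# G1 = sqrt(n(n-1))/(n-2) * m3 / m2^{3/2}
sampleSkewness <- function(x) {
  n <- length(x)
  if (n < 3) stop("skewness requires at least 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(structure(0, degenerate = TRUE))
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  structure(sqrt(n * (n - 1)) / (n - 2) * g1, degenerate = FALSE)
}

# add-one empirical p-value: (1 + #{null >= observed}) / (B + 1)
empiricalP <- function(observed, nulls) {
  (1 + sum(nulls >= observed)) / (length(nulls) + 1)
}

# deterministic fan-out of one top-level seed into named stage substreams,
# kept below 2^31 so set.seed() accepts the result
stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, features = 17L, assemble = 23L, tune = 29L,
               fit = 37L, test = 47L, stability = 83L, misc = 97L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 131 + offsets[[stage]]) %% 2147483647)
}

pairLabels <- function(blockNames) {
  K <- length(blockNames)
  out <- character(0)
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      out <- c(out, paste(blockNames[i], blockNames[j], sep = ":"))
    }
  }
  out
}

# coerce a BlockSet or a bare list of matrices to a list of matrices
asBlockMatrices <- function(x) {
  if (is(x, "BlockSet")) return(blocks(x))
  if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) return(x)
  stop("expected a BlockSet or a list of numeric matrices")
}

checkPenalties <- function(pen, p) {
  if (length(pen) != length(p)) {
    stop("need one penalty per block (", length(p), ")")
  }
  ub <- sqrt(p)
  bad <- pen < 1 - 1e-9 | pen > ub + 1e-9
  if (any(bad)) {
    stop(sprintf("penalty for block %s outside [1, sqrt(p)] = [1, %.3f]",
                 paste(which(bad), collapse = ","), ub[which(bad)[1]]))
  }
  invisible(pmin(pmax(pen, 1), ub))
}
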