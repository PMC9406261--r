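# Shared fixtures, built in code.

# a small, quick-to-render phantom spec
smallSpec <- function(seed, rbcCount = 8L, noise = noNoise(), ...) {
  PhantomSpec(seed = seed, width = 128L, height = 128L,
              rbcCount = rbcCount, noise = noise, ...)
}

# default-geometry phantom at full size (used where the acceptance
# conditions call for the default field)
defaultPhantom <- function(seed, noise = noNoise(), ...) {
  renderPhantom(PhantomSpec(seed = seed, noise = noise, ...))
}

# modal value of a discrete vector
modalValue <- function(v) {
  v <- v[!is.na(v)]
  as.numeric(names(which.max(table(v))))
}

# independent brute-force Huang oracle: re-derives the fuzzy entropy for
# every candidate threshold with naive loops, no shared code with the
# implementation
huangOracle <- function(counts) {
  g <- 0:255
  occ <- g[counts > 0]
  gmin <- min(occ); gmax <- max(occ)
  C <- gmax - gmin
  total <- sum(counts)
  S <- function(u) if (u <= 0 || u >= 1) 0 else -u*log(u) - (1-u)*log(1-u)
  bestT <- NA; bestE <- Inf
  for (t in gmin:(gmax - 1)) {
    lo <- g <= t
    mu0 <- sum(g[lo] * counts[lo]) / sum(counts[lo])
    mu1 <- sum(g[!lo] * counts[!lo]) / sum(counts[!lo])
    E <- 0
    for (gi in occ) {
      mu <- if (gi <= t) mu0 else mu1
      u <- 1 / (1 + abs(gi - mu) / C)
      E <- E + counts[gi + 1] * S(u)
    }
    E <- E / total
    if (E < bestE - 1e-12) { bestE <- E; bestT <- t }
  }
  list(threshold = bestT, fuzziness = bestE)
}

# random occupied histogram for property tests
randomHistogram <- function() {
  counts <- integer(256)
  nlev <- sample(2:40, 1)
  levels <- sample(0:255, nlev)
  counts[levels + 1] <- sample(1:500, nlev, replace = TRUE)
  counts
}
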