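# small shared fixtures, built in code

tinyConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, grid = c(12L, 12L, 12L), nRegions = 12L,
         nLeakRegionsImpacted = 3L, nLeakRegionsSham = 1L),
    list(...))
  do.call(simConfig, args)
}

tinyAtlas <- function(cfg = tinyConfig()) makePhantomAtlas(cfg)

# independent Floyd-Warshall shortest paths for the graph-metric oracle
floydWarshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# straightforward re-implementation of the two-stage adaptive FDR
# procedure, kept deliberately naive (p.adjust-based) as an oracle
bkyOracle <- function(p, q = 0.1) {
  m <- length(p)
  qp <- q / (1 + q)
  r1 <- sum(stats::p.adjust(p, "BH") <= qp)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  stats::p.adjust(p, "BH") <= qp * m / (m - r1)
}

# exact two-sided rank-sum p by enumerating all group assignments
rankSumExactP <- function(x, y) {
  v <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(v), n)
  r <- rank(v)
  wObs <- sum(r[seq_len(n)])
  wAll <- apply(idx, 2, function(i) sum(r[i]))
  mu <- mean(wAll)
  mean(abs(wAll - mu) >= abs(wObs - mu) - 1e-12)
}
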