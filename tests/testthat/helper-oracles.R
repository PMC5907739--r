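# Independent brute-force oracles. Deliberately literal (explicit loops,
# no shared code with the package) so they can vouch for the vectorized
# implementations.

oracleHwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

oraclePrevalence <- function(maf1, maf2, pen) {
  w1 <- oracleHwe(maf1)
  w2 <- oracleHwe(maf2)
  K <- 0
  for (i in 1:3) for (j in 1:3) K <- K + w1[i] * w2[j] * pen[i, j]
  K
}

oracleHeritability <- function(maf1, maf2, pen) {
  w1 <- oracleHwe(maf1)
  w2 <- oracleHwe(maf2)
  K <- oraclePrevalence(maf1, maf2, pen)
  v <- 0
  for (i in 1:3) for (j in 1:3) v <- v + w1[i] * w2[j] * (pen[i, j] - K)^2
  v / (K * (1 - K))
}

oracleMarginal1 <- function(maf2, pen) {
  w2 <- oracleHwe(maf2)
  m <- numeric(3)
  for (i in 1:3) for (j in 1:3) m[i] <- m[i] + w2[j] * pen[i, j]
  m
}

# sup_t (ECDF_b(t) - ECDF_a(t)) over the pooled points, by double loop.
oracleKsD <- function(a, b) {
  best <- 0
  for (t in c(a, b)) {
    d <- mean(b <= t) - mean(a <= t)
    if (d > best) best <- d
  }
  best
}

randomModel <- function() {
  PenetranceModel(runif(1, 0.05, 0.5), runif(1, 0.05, 0.5),
                  matrix(runif(9, 0.05, 0.95), 3, 3))
}
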