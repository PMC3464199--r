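# Independent oracles, coded along different algebraic routes than the
# package implementation.

# G via the entropy decomposition 2*(sum O ln O - rows - cols + N ln N),
# not via observed/expected ratios.
g_oracle <- function(k1, n1, k2, n2) {
  O <- c(k1, n1 - k1, k2, n2 - k2)
  xlx <- function(x) sum(ifelse(x == 0, 0, x * log(x)))
  2 * (xlx(O) - xlx(c(n1, n2)) - xlx(c(k1 + k2, n1 + n2 - k1 - k2)) +
         xlx(n1 + n2))
}

# Upper-tail chi-square probability at 1 df via the normal closed form.
p_oracle_df1 <- function(g) 2 * stats::pnorm(-sqrt(g))

# Random 2x2 tables with all expected counts >= 5.
random_tables <- function(n, seed) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 1
  while (i <= n) {
    n1 <- sample(50:5000, 1)
    n2 <- sample(50:5000, 1)
    p <- stats::runif(1, 0.05, 0.95)
    k1 <- stats::rbinom(1, n1, p)
    k2 <- stats::rbinom(1, n2, min(0.95, p * stats::runif(1, 0.5, 1.5)))
    E <- outer(c(n1, n2), c(k1 + k2, n1 + n2 - k1 - k2)) / (n1 + n2)
    if (any(E < 5)) next
    out[[i]] <- c(k1 = k1, n1 = n1, k2 = k2, n2 = n2)
    i <- i + 1
  }
  out
}

# 4-grain phenotype data.frame from a pattern matrix (rows = grains,
# cols = red, yellow, cyan).
make_tetrad <- function(m, id = "t1") {
  data.frame(tetrad_id = id, grain = 1:4,
             red = m[, 1], yellow = m[, 2], cyan = m[, 3],
             stringsAsFactors = FALSE)
}
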