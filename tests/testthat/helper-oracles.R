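# Independent oracles used across the suite.  These deliberately avoid the
# package's own numerical paths.

# stable fixed points of the 1-D self-activation dA/dt = k1/(1+k2 e^{-k3 q A}) - d A,
# by dense sign-change enumeration with a stability (slope) check
stable_roots_selfact <- function(k1, k2, k3, d, q = 1, a_max = 6000,
                                 step = 0.02) {
  g <- function(A) k1 / (1 + k2 * exp(-k3 * q * A)) - d * A
  As <- seq(0, a_max, by = step)
  gs <- g(As)
  idx <- which(diff(sign(gs)) != 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(g, c(As[i], As[i + 1]))$root, 0)
  eps <- 1e-4
  stable <- vapply(roots, function(r) g(r + eps) < g(r - eps) &&
                     g(r - eps) > 0 && g(r + eps) < 0, TRUE)
  sort(unique(round(roots[stable], 6)))
}

# hand-rolled two-sample Kolmogorov-Smirnov statistic and asymptotic p-value
ks2_hand <- function(x, y) {
  z <- sort(unique(c(x, y)))
  Fx <- vapply(z, function(v) mean(x <= v), 0)
  Fy <- vapply(z, function(v) mean(y <= v), 0)
  D <- max(abs(Fx - Fy))
  n <- length(x) * length(y) / (length(x) + length(y))
  lam <- sqrt(n) * D
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * lam^2 * j^2))
  list(D = D, p = min(max(p, 0), 1))
}

# fixed-step classical Runge-Kutta integrator, evaluated on a fine subgrid
rk4_traj <- function(rhs, y0, t_grid, substeps = 200) {
  out <- matrix(NA_real_, length(t_grid), length(y0))
  out[1, ] <- y0
  y <- y0
  for (i in seq_along(t_grid)[-1L]) {
    h <- (t_grid[i] - t_grid[i - 1L]) / substeps
    t <- t_grid[i - 1L]
    for (s in seq_len(substeps)) {
      k1 <- rhs(t, y)
      k2 <- rhs(t + h / 2, y + h / 2 * k1)
      k3 <- rhs(t + h / 2, y + h / 2 * k2)
      k4 <- rhs(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  out
}

# tiny two-gene toy model shared by several tests
toy_two_gene <- function(q_self = 1, k1A = 30) {
  net <- regulatory_network(
    c("gA", "gB"),
    rbind(regulation("gA", "gA", 1), regulation("gA", "gB", 1)))
  kin <- gene_kinetics(c("gA", "gB"), k1 = c(k1A, 30),
                       k2 = c(150, 1), k3 = c(0.05, 0.02),
                       d = c(0.12, 0.3))
  w <- weight_vector(net, q = c(q_self, 1))
  grn_model(net, kin, w)
}

# write a small expression table to a temp file
write_temp_table <- function(tab, ext = ".tsv", sep = "\t") {
  f <- tempfile(fileext = ext)
  utils::write.table(tab, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}
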