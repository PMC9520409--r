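# Independent reference implementations used as oracles.  These are written
# naively (event list scanned linearly, O(N^2) metric loops, pooled-point KS)
# and deliberately share no code with the package internals.

# Naive event-driven simulation of the dual-pathway network.  Maintains a
# plain data-frame event list re-sorted on every step.
oracle_simulate <- function(aa, params, n_per_chain = 10) {
  L <- n_per_chain
  n_nodes <- 2L * L + 1L
  cn_id <- n_nodes
  nb <- vector("list", n_nodes) # 1-based adjacency
  link <- function(a, b) {
    nb[[a]] <<- c(nb[[a]], b)
    nb[[b]] <<- c(nb[[b]], a)
  }
  if (L > 1) for (i in 1:(L - 1)) {
    link(i, i + 1L)
    link(L + i, L + i + 1L)
  }
  link(L, 2L * L)
  link(L, cn_id)
  link(2L * L, cn_id)
  pathway <- function(id) {
    if (id <= L) params$sp else if (id <= 2L * L) params$fp else params$cn
  }
  ev <- data.frame(t = numeric(0), seq = numeric(0), node = integer(0))
  sq <- 0
  push <- function(t, node) {
    sq <<- sq + 1
    ev <<- rbind(ev, data.frame(t = t, seq = sq, node = node))
  }
  for (t in aa) {
    push(t, 1L)
    push(t, L + 1L)
  }
  last_t <- rep(NA_real_, n_nodes)
  r_prev <- rep(NA_real_, n_nodes)
  out <- numeric(0)
  while (nrow(ev) > 0) {
    o <- order(ev$t, ev$seq)
    e <- ev[o[1], ]
    ev <- ev[o[-1], ]
    p <- pathway(e$node)
    fresh <- is.na(last_t[e$node])
    if (!fresh) {
      gap <- e$t - last_t[e$node] - r_prev[e$node]
      if (gap <= 0) next
      R <- params$a_r * (p$r_min + p$delta_r * (1 - exp(-gap / p$tau_r)))
      D <- params$a_d * (p$d_min + p$delta_d * exp(-gap / p$tau_d))
    } else {
      R <- params$a_r * (p$r_min + p$delta_r)
      D <- params$a_d * p$d_min
    }
    last_t[e$node] <- e$t
    r_prev[e$node] <- R
    if (e$node == cn_id) out <- c(out, e$t)
    for (b in nb[[e$node]]) push(e$t + D, b)
  }
  out
}

# Vectorized brute-force sample entropy on a fully valid series (matrix of
# pairwise distances; raw-sum ratio, strict "<", n-1 sd).
oracle_sampen <- function(x, m = 2, r = 0.2) {
  N <- length(x)
  tol <- r * sd(x)
  A <- abs(outer(x, x, "-")) < tol
  M <- N - m
  bm <- A[1:M, 1:M, drop = FALSE]
  for (k in 1:(m - 1)) bm <- bm & A[1:M + k, 1:M + k, drop = FALSE]
  bm1 <- bm & A[1:M + m, 1:M + m, drop = FALSE]
  diag(bm) <- FALSE
  diag(bm1) <- FALSE
  -log(sum(bm1) / sum(bm))
}

# Brute-force RMSSD via an explicit loop.
oracle_rmssd <- function(x) {
  acc <- c()
  for (i in 1:(length(x) - 1)) acc <- c(acc, (x[i + 1] - x[i])^2)
  sqrt(mean(acc))
}

# Brute-force two-sample KS over pooled evaluation points.
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}

# Convenience fixtures
fx_sp <- function() pathway_params(339, 232, 160, 20, 39, 171)
fx_fp <- function() pathway_params(493, 369, 162, 7, 23, 163)
fx_model <- function(...) model_params(fx_sp(), fx_fp(), ...)
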