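# Independent oracles: every routine here recomputes a quantity the package
# provides, using a different algorithm (dense algebra, enumeration, brute
# force), so agreement is evidence rather than tautology.

# classical two-way ANOVA-with-interaction F against the intercept-only model
ols_anova_f <- function(y, design) {
  full <- lm(y ~ age * fetal_genotype, data = design)
  rss1 <- sum(residuals(full)^2)
  rss0 <- sum((y - mean(y))^2)
  p1 <- full$rank
  df1 <- p1 - 1
  df2 <- length(y) - p1
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# profile ML log-likelihood maximum by two-stage dense grid over the
# sow/residual variance ratio, using generic dense linear algebra
# (cholesky of the full n x n covariance; no blockwise shortcuts)
grid_profile_loglik <- function(y, X, sow, n_coarse = 1001, n_fine = 2001) {
  Z <- model.matrix(~ 0 + factor(sow))
  ZZt <- tcrossprod(Z)
  n <- length(y)
  ll_at <- function(lam) {
    R <- chol(diag(n) + lam * ZZt)
    yw <- backsolve(R, y, transpose = TRUE)
    Xw <- backsolve(R, X, transpose = TRUE)
    rss <- sum(qr.resid(qr(Xw), yw)^2)
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n) - sum(log(diag(R)))
  }
  tg <- seq(-12, 8, length.out = n_coarse)
  lam <- c(0, exp(tg))
  ll <- vapply(lam, ll_at, numeric(1))
  i <- which.max(ll)
  if (i == 1) {
    # boundary: refine near zero as well, in case the max sits just inside
    tfine <- seq(-14, -10, length.out = n_fine)
  } else {
    lo <- tg[max(1, i - 2)]
    hi <- tg[min(n_coarse, i)]
    tfine <- seq(lo, hi, length.out = n_fine)
  }
  max(ll, vapply(exp(tfine), ll_at, numeric(1)))
}

# exhaustive upper-tail hypergeometric by combinatorial enumeration
enum_hypergeom <- function(k, n, K, N) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up from its definition
bh_stepup_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# connected components by union-find on an adjacency matrix
components_unionfind <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (A[i, j] != 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Newman-Girvan modularity of a membership vector on an edge list
modularity_of <- function(memb, edges, deg, m) {
  if (m == 0) return(0)
  comm <- sort(unique(memb))
  e_c <- vapply(comm, function(c) {
    sum(memb[edges[, 1]] == c & memb[edges[, 2]] == c)
  }, numeric(1)) / m
  a_c <- vapply(comm, function(c) sum(deg[memb == c]), numeric(1)) / (2 * m)
  sum(e_c - a_c^2)
}

# maximum modularity over all set partitions (restricted growth strings)
exhaustive_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- as.numeric(igraph::degree(g))
  m <- nrow(el)
  a <- rep(1L, n)
  b <- rep(1L, n)
  best <- modularity_of(a, el, deg, m)
  repeat {
    # next restricted growth string
    i <- n
    while (i > 1 && a[i] == b[i] + 1L) i <- i - 1L
    if (i == 1) break
    a[i] <- a[i] + 1L
    if (i < n) {
      for (j in (i + 1L):n) {
        b[j] <- max(b[i], a[i])
        a[j] <- 1L
      }
    }
    q <- modularity_of(a, el, deg, m)
    if (q > best) best <- q
  }
  best
}

# betweenness by explicit shortest-path counting (BFS sigma from every
# source; pair contribution sigma_sv * sigma_vt / sigma_st)
betweenness_enum <- function(g) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  bfs_counts <- function(s) {
    dist <- rep(Inf, n); sigma <- rep(0, n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ] != 0)) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  B <- lapply(seq_len(n), bfs_counts)
  bt <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(B[[s]]$dist[t])) next
      d <- B[[s]]$dist[t]
      sig_st <- B[[s]]$sigma[t]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (B[[s]]$dist[v] + B[[t]]$dist[v] == d) {
          bt[v] <- bt[v] + B[[s]]$sigma[v] * B[[t]]$sigma[v] / sig_st
        }
      }
    }
  }
  setNames(bt, igraph::V(g)$name)
}

# random graphs for the oracle suites
random_graph <- function(n, p, prefix = "n") {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(paste0(prefix, seq_len(n)), paste0(prefix, seq_len(n)))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

planted_two_block_graph <- function(n1, n2, p_in = 0.9, p_out = 0.1) {
  n <- n1 + n2
  block <- rep(1:2, c(n1, n2))
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (block[i] == block[j]) p_in else p_out
      A[i, j] <- A[j, i] <- rbinom(1, 1, p)
    }
  }
  dimnames(A) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# delta-delta-Ct relative quantification (valid when all efficiencies = 2)
ddct_oracle <- function(ct_t_cal, ct_t_s, ct_r_cal, ct_r_s) {
  2^-((ct_t_s - ct_t_cal) - (ct_r_s - ct_r_cal))
}

# a small fully-crossed design with one fetus per sow (8 conditions x reps)
one_fetus_per_sow_design <- function(reps = 2) {
  cells <- expand.grid(
    age = c("d90", "d110"),
    fetal_genotype = c("LW", "MS", "LWMS", "MSLW"),
    rep = seq_len(reps),
    stringsAsFactors = FALSE
  )
  complete_design(tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(nrow(cells))),
    sow_id = sprintf("sow%02d", seq_len(nrow(cells))),
    age = cells$age,
    fetal_genotype = cells$fetal_genotype
  ))
}
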