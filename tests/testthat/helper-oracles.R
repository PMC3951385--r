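# Independent brute-force oracles, coded with plain loops and base R so they
# share no code path with the package implementation.

# random positive gene x sample long table + its matrix
rand_expr <- function(n_genes, n_samples, sd = 0.7) {
  genes <- paste0("g", seq_len(n_genes))
  samples <- paste0("s", seq_len(n_samples))
  m <- matrix(2^rnorm(n_genes * n_samples, 0, sd), n_genes, n_samples,
    dimnames = list(genes, samples))
  long <- data.frame(
    gene = rep(genes, times = n_samples),
    sample = rep(samples, each = n_genes),
    relative_quantity = as.vector(m)
  )
  list(long = long, m = m)
}

oracle_pairwise_sd <- function(a, b) {
  r <- log(a / b) / log(2)
  sqrt(sum((r - mean(r))^2) / (length(r) - 1))
}

oracle_m <- function(m) {
  g <- nrow(m)
  out <- numeric(g)
  for (j in seq_len(g)) {
    acc <- 0
    for (k in seq_len(g)) {
      if (k != j) acc <- acc + oracle_pairwise_sd(m[j, ], m[k, ])
    }
    out[j] <- acc / (g - 1)
  }
  stats::setNames(out, rownames(m))
}

oracle_geomean_nf <- function(m, genes) {
  apply(m[genes, , drop = FALSE], 2, function(v) prod(v)^(1 / length(v)))
}

oracle_v_series <- function(m, ranking) {
  g <- length(ranking)
  v <- numeric(g - 2)
  for (n in 2:(g - 1)) {
    nf_n <- oracle_geomean_nf(m, ranking[1:n])
    nf_n1 <- oracle_geomean_nf(m, ranking[1:(n + 1)])
    r <- log(nf_n / nf_n1) / log(2)
    v[n - 1] <- sqrt(sum((r - mean(r))^2) / (length(r) - 1))
  }
  v
}

# literal step-by-step recomputation of the variance-decomposition model
oracle_normfinder <- function(m, groups) {
  y <- log2(m)
  L <- nrow(y)
  z <- y
  for (j in seq_len(ncol(y))) z[, j] <- y[, j] - mean(y[, j])
  gl <- unique(groups)
  G <- length(gl)
  n_g <- vapply(gl, function(g) sum(groups == g), integer(1))
  d <- s2 <- matrix(0, L, G, dimnames = list(rownames(y), gl))
  for (i in seq_len(L)) {
    for (gi in seq_len(G)) {
      zg <- z[i, groups == gl[gi]]
      d[i, gi] <- mean(zg)
      s2[i, gi] <- stats::var(zg) * L / (L - 1)
    }
    d[i, ] <- d[i, ] - sum(d[i, ] * n_g) / sum(n_g)
  }
  s2 <- pmax(s2, 0)
  samp <- s2
  for (gi in seq_len(G)) samp[, gi] <- s2[, gi] / n_g[gi]
  g2 <- max(0, stats::var(as.vector(d)) - mean(samp))
  rho_of <- function(dv, s2v) {
    acc <- 0
    for (gi in seq_len(G)) {
      sh <- if (g2 > 0) g2 / (g2 + s2v[gi] / n_g[gi]) else 0
      acc <- acc + abs(dv[gi] * sh) + sqrt(s2v[gi] / n_g[gi])
    }
    as.numeric(acc / G)
  }
  rho <- numeric(L)
  for (i in seq_len(L)) rho[i] <- rho_of(d[i, ], s2[i, ])
  # exhaustive best pair
  best <- NULL
  for (i in seq_len(L - 1)) {
    for (k in (i + 1):L) {
      rp <- rho_of((d[i, ] + d[k, ]) / 2, (s2[i, ] + s2[k, ]) / 4)
      if (is.null(best) || rp < best$rho) {
        best <- list(pair = sort(rownames(y)[c(i, k)]), rho = rp)
      }
    }
  }
  list(
    d = d, s2 = s2, g2 = g2,
    rho = stats::setNames(rho, rownames(y)),
    best_pair = best
  )
}
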