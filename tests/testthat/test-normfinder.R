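test_that("sample-effect removal centers every column", {
  # perfectly co-regulated genes leave nothing behind
  v <- rnorm(6)
  y <- rbind(v, v, v)
  expect_equal(remove_sample_effect(y), 0 * y, ignore_attr = TRUE)

  set.seed(21)
  y2 <- matrix(rnorm(60), 5, 12)
  z <- remove_sample_effect(y2)
  expect_equal(colSums(z), rep(0, 12), tolerance = 1e-12)

  # a constant added to one sample is absorbed entirely
  y3 <- y2
  y3[, 4] <- y3[, 4] + 7
  expect_equal(remove_sample_effect(y3), z, tolerance = 1e-12)
})

test_that("group statistics match the hand-worked shifted-gene case", {
  # 3 genes, 2 groups of 3 samples, gene A shifted +1 log2 unit in group 2,
  # zero noise; under per-sample centering and group-size-weighted
  # inter-group centering: d_A = -/+ 1/3, d_B = d_C = +/- 1/6
  y <- rbind(
    A = c(0, 0, 0, 1, 1, 1),
    B = rep(0, 6),
    C = rep(0, 6)
  )
  z <- remove_sample_effect(y)
  gs <- group_statistics(z, rep(c("g1", "g2"), each = 3))
  expect_equal(gs$d["A", ], c(g1 = -1 / 3, g2 = 1 / 3), tolerance = 1e-12)
  expect_equal(gs$d["B", ], c(g1 = 1 / 6, g2 = -1 / 6), tolerance = 1e-12)
  expect_equal(unname(colSums(gs$d)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(gs$sigma2), matrix(0, 3, 2))
  expect_equal(gs$gamma2, (2 / 9 + 4 / 36) / 5, tolerance = 1e-12)
})

test_that("zero-noise stability values follow from the shrunk differences", {
  long <- data.frame(
    gene = rep(c("A", "B", "C"), each = 6),
    sample = rep(paste0("s", 1:6), 3),
    relative_quantity = 2^c(0, 0, 0, 1, 1, 1, rep(0, 12))
  )
  groups <- data.frame(sample = paste0("s", 1:6),
    group = rep(c("g1", "g2"), each = 3))
  fit <- normfinder(long, groups = groups)
  # sigma2 = 0 everywhere, so shrinkage keeps d intact and rho = mean |d|
  st <- fit$stability
  expect_equal(st$rho[st$gene == "A"], 1 / 3, tolerance = 1e-12)
  expect_equal(st$rho[st$gene == "B"], 1 / 6, tolerance = 1e-12)
  expect_identical(st$gene[3], "A")
})

test_that("an ideal gene gets rho 0 and first rank", {
  set.seed(22)
  s <- paste0("s", 1:8)
  shared <- rnorm(8)
  long <- data.frame(
    gene = rep(c("ideal", "noisyA", "noisyB"), each = 8),
    sample = rep(s, 3),
    relative_quantity = 2^c(
      shared,
      shared + rnorm(8, 0, 1),
      shared + rnorm(8, 0, 1)
    )
  )
  groups <- data.frame(sample = s, group = rep(c("x", "y"), each = 4))
  fit <- normfinder(long, groups = groups)
  expect_identical(fit$stability$gene[1], "ideal")
  # centering couples the ideal gene to the noisy ones, but it must still
  # be clearly the most stable
  expect_lt(fit$stability$rho[1], fit$stability$rho[2])
})

test_that("stability values match the literal-formula recomputation", {
  set.seed(23)
  x <- rand_expr(4, 6)
  groups <- rep(c("g1", "g2"), each = 3)
  fit <- normfinder(x$long,
    groups = data.frame(sample = paste0("s", 1:6), group = groups))
  oracle <- oracle_normfinder(x$m, groups)
  st <- fit$stability
  expect_equal(st$rho, unname(oracle$rho[st$gene]), tolerance = 1e-9)
  expect_equal(fit$gamma2, oracle$g2, tolerance = 1e-9)
})

test_that("estimated rho tracks configured gene stability", {
  sds <- c(0.05, 0.10, 0.20, 0.30, 0.40, 0.55, 0.10, 0.30)
  shifts <- c(0, 0, 0, 0, 0, 0, 0.8, -0.8) # zero-mean: survives centering
  genes <- paste0("g", 1:8)
  n_g <- 15
  L <- length(sds)
  # per-sample centering mixes a 1/L share of every gene into each row:
  # var(z_i) = (1 - 2/L) sd_i^2 + sum(sd^2)/L^2; the true composite
  # stability is |shift|/2 + sd(z_i)/sqrt(n_g)
  sd_z <- sqrt((1 - 2 / L) * sds^2 + sum(sds^2) / L^2)
  truth <- abs(shifts) / 2 + sd_z / sqrt(n_g)
  cors <- numeric(20)
  for (seed in 1:20) {
    set.seed(seed)
    y <- matrix(rnorm(8 * 2 * n_g, 0, rep(sds, 2 * n_g)), 8, 2 * n_g,
      dimnames = list(genes, paste0("s", 1:(2 * n_g))))
    y[, (n_g + 1):(2 * n_g)] <- y[, (n_g + 1):(2 * n_g)] + shifts
    long <- data.frame(
      gene = rep(genes, times = 2 * n_g),
      sample = rep(colnames(y), each = 8),
      relative_quantity = 2^as.vector(y)
    )
    groups <- data.frame(sample = colnames(y),
      group = rep(c("a", "b"), each = n_g))
    st <- normfinder(long, groups = groups)$stability
    est <- stats::setNames(st$rho, st$gene)[genes]
    cors[seed] <- stats::cor(est, truth, method = "spearman")
  }
  expect_gte(mean(cors), 0.9)
})

test_that("the best pair equals the exhaustive-search optimum", {
  set.seed(24)
  for (i in 1:5) {
    x <- rand_expr(6, 10)
    groups <- rep(c("g1", "g2"), each = 5)
    fit <- normfinder(x$long,
      groups = data.frame(sample = paste0("s", 1:10), group = groups))
    oracle <- oracle_normfinder(x$m, groups)
    expect_identical(fit$best_pair, oracle$best_pair$pair)
    expect_equal(fit$best_pair_rho, oracle$best_pair$rho, tolerance = 1e-9)
  }
})

test_that("duplicate stable genes win the pair search", {
  set.seed(25)
  s <- paste0("s", 1:10)
  stable <- rnorm(10, 0, 0.05)
  long <- data.frame(
    gene = rep(c("dupA", "dupB", "noisy1", "noisy2"), each = 10),
    sample = rep(s, 4),
    relative_quantity = 2^c(stable, stable + rnorm(10, 0, 0.01),
      rnorm(10, 0, 1), rnorm(10, 0, 1))
  )
  groups <- data.frame(sample = s, group = rep(c("x", "y"), each = 5))
  fit <- normfinder(long, groups = groups)
  expect_identical(fit$best_pair, c("dupA", "dupB"))
})

test_that("mirrored group shifts cancel in a pair", {
  # genes P and Q move in opposite directions between the groups with no
  # noise; their average is perfectly stable, so the pair beats any single
  s <- paste0("s", 1:8)
  g <- rep(c("g1", "g2"), each = 4)
  p <- c(rep(0.5, 4), rep(-0.5, 4))
  r <- c(rep(0.2, 4), rep(-0.2, 4))
  long <- data.frame(
    gene = rep(c("P", "Q", "R", "S"), each = 8),
    sample = rep(s, 4),
    relative_quantity = 2^c(p, -p, r, -r)
  )
  fit <- normfinder(long, groups = data.frame(sample = s, group = g))
  expect_identical(fit$best_pair, c("P", "Q"))
  expect_equal(fit$best_pair_rho, 0, tolerance = 1e-12)
  expect_lt(fit$best_pair_rho, min(fit$stability$rho))
})

test_that("ungrouped mode ranks by residual variance", {
  set.seed(26)
  x <- rand_expr(5, 12)
  fit <- normfinder(x$long, groups = NULL)
  expect_identical(fit$mode, "ungrouped")
  y <- log2(x$m)
  z <- sweep(y, 2, colMeans(y))
  v <- apply(z, 1, stats::var) * 5 / 4
  expect_equal(fit$stability$rho,
    unname(sqrt(v)[fit$stability$gene]), tolerance = 1e-12)
  expect_identical(fit$stability$gene, names(sort(v)))
})

test_that("rho is invariant to per-gene rescaling", {
  set.seed(27)
  x <- rand_expr(5, 10)
  groups <- data.frame(sample = paste0("s", 1:10),
    group = rep(c("g1", "g2"), each = 5))
  fit <- normfinder(x$long, groups = groups)
  scaled <- x$long
  scale_by <- stats::setNames(10^runif(5, -3, 3), paste0("g", 1:5))
  scaled$relative_quantity <-
    scaled$relative_quantity * scale_by[scaled$gene]
  fit2 <- normfinder(scaled, groups = groups)
  expect_equal(fit$stability, fit2$stability, tolerance = 1e-9)
})

test_that("rank positions are unbiased when all genes are equally stable", {
  set.seed(28)
  n_genes <- 6
  rank_sum <- stats::setNames(numeric(n_genes), paste0("g", 1:n_genes))
  for (rep in 1:200) {
    x <- rand_expr(n_genes, 10, sd = 0.3)
    st <- normfinder(x$long,
      groups = data.frame(sample = paste0("s", 1:10),
        group = rep(c("a", "b"), each = 5)))$stability
    rank_sum[st$gene] <- rank_sum[st$gene] + st$rank
  }
  mean_rank <- rank_sum / 200
  expect_true(all(abs(mean_rank - 3.5) < 0.5))
})
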