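make_trace <- function(r0 = 1e-8, eff = 1, cycles = 1:40, baseline = 0,
                       plateau = Inf) {
  x <- r0 * (1 + eff)^cycles
  if (is.finite(plateau)) {
    x <- plateau * (x / plateau) / sqrt(1 + (x / plateau)^2)
  }
  baseline + x
}

test_that("Ct is the interpolated threshold crossing", {
  f <- c(rep(0.01, 19), 1, 2, 4, 8, rep(10, 17))
  expect_equal(determine_ct(1:40, f, threshold = 1), 20)

  # half the threshold one cycle before, 1.5x after: midpoint crossing
  f2 <- c(rep(0.1, 18), 0.5, 1.5, rep(2, 20))
  expect_equal(determine_ct(1:40, f2, threshold = 1), 19.5)
})

test_that("Ct matches a root-finding oracle on the linear interpolant", {
  set.seed(42)
  for (i in 1:10) {
    eff <- runif(1, 0.9, 1.1)
    r0 <- 10^runif(1, -9, -7)
    f <- make_trace(r0, eff, plateau = 2)
    thr <- 0.2
    ct <- determine_ct(1:40, f, thr)
    interp <- stats::approxfun(1:40, f)
    oracle <- stats::uniroot(function(c) interp(c) - thr,
      interval = c(1, 40), tol = 1e-12)$root
    expect_equal(ct, oracle, tolerance = 1e-6)
  }
})

test_that("Ct determination surfaces degenerate traces as errors", {
  expect_error(
    determine_ct(1:20, rep(0.1, 20), threshold = 1),
    "no amplification"
  )
  expect_error(
    determine_ct(1:20, seq(2, 40, 2), threshold = 1),
    "threshold below baseline"
  )
  expect_error(determine_ct(1:5, 1:5, threshold = 3), "at least 10")
})

test_that("efficiency fit recovers a perfect doubling exactly", {
  f <- 1e-8 * 2^(1:35)
  fit <- fit_efficiency(1:35, f, baseline_cycles = NULL)
  expect_equal(fit$efficiency, 1, tolerance = 1e-9)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-9)
})

test_that("efficiency fit recovers the generating gain on plateaued traces", {
  # per-cycle gain 1.9 (E = 0.9) saturating into a plateau
  f <- make_trace(1e-8, 0.9, baseline = 0.01, plateau = 2)
  fit <- fit_efficiency(1:40, f)
  expect_lt(abs(fit$efficiency - 0.9), 0.02)
  expect_gt(fit$fit_r2, 0.999)
})

test_that("flat and featureless traces are rejected", {
  expect_error(fit_efficiency(1:20, rep(1, 20)), "flat trace")
  expect_error(
    fit_efficiency(1:20, seq(1, 0.6, length.out = 20)),
    "insufficient exponential phase"
  )
})

test_that("R0 follows the efficiency-corrected back-calculation", {
  expect_equal(compute_r0(10, 1, 1), 2^-10)
  expect_equal(compute_r0(0, 0.85, 0.2), 0.2)
  # log-domain independent evaluation
  ct <- 20; eff <- 1.028; r_ct <- 0.2
  oracle <- exp(log(r_ct) - ct * log1p(eff))
  expect_equal(compute_r0(ct, eff, r_ct), oracle, tolerance = 1e-12)
  expect_error(compute_r0(10, 1, 0), "r_ct")
  expect_error(compute_r0(10, -1.5, 1), "efficiency")
})

test_that("R0 round-trips back to the threshold cycle", {
  set.seed(7)
  for (i in 1:20) {
    ct <- runif(1, 15, 35)
    eff <- runif(1, 0.9, 1.1)
    r_ct <- runif(1, 0.1, 1)
    r0 <- compute_r0(ct, eff, r_ct)
    ct_back <- -log(r0 / r_ct) / log1p(eff)
    expect_equal(ct_back, ct, tolerance = 1e-9)
  }
})

test_that("rescaling a trace leaves E and Ct invariant and scales R0", {
  f <- make_trace(2e-8, 0.95, baseline = 0.01, plateau = 2)
  tr1 <- data.frame(well = "w", gene = "g", sample = "s",
    cycle = 1:40, fluorescence = f)
  tr2 <- tr1
  tr2$fluorescence <- 5 * f
  q1 <- quantify_traces(tr1, threshold = 0.2)
  q2 <- quantify_traces(tr2, threshold = 1.0) # threshold scaled too
  expect_equal(q1$efficiency, q2$efficiency, tolerance = 1e-9)
  expect_equal(q1$ct, q2$ct, tolerance = 1e-9)
  expect_equal(q2$r0, 5 * q1$r0, tolerance = 1e-9)
})

test_that("outlier screening flags a discordant well and only that well", {
  eff <- c(rep(c(0.995, 1.000, 1.005), 4), 0.995, 1.000, 0.70)
  wells <- data.frame(
    gene = "g1",
    sample = rep(paste0("s", 1:5), each = 3),
    efficiency = eff
  )
  flagged <- detect_outliers(wells, alpha = 0.05)
  expect_identical(which(flagged$outlier), 15L)

  # the one-way ANOVA model underlying the screen matches the textbook
  # hand computation on the same numbers
  groups <- rep(1:5, each = 3)
  gm <- tapply(eff, groups, mean)
  ssb <- sum(3 * (gm - mean(eff))^2)
  ssw <- sum((eff - gm[groups])^2)
  f_hand <- (ssb / 4) / (ssw / 10)
  fit <- stats::lm(eff ~ factor(groups))
  expect_equal(unname(stats::anova(fit)$`F value`[1]), f_hand,
    tolerance = 1e-9)
  # and the flagged well is a gross outlier by the studentized-residual
  # test even though it masks the F statistic itself
  expect_gt(max(abs(stats::rstudent(fit))), 5)
  expect_lt(stats::pf(f_hand, 4, 10, lower.tail = FALSE), 1)
})

test_that("outlier screening stays quiet in null configurations", {
  # identical efficiencies: no variance anywhere, nothing to flag
  wells <- data.frame(gene = "g", sample = rep(c("a", "b"), each = 3),
    efficiency = rep(1, 6))
  expect_false(any(detect_outliers(wells)$outlier))

  # equal means, equal spread
  wells2 <- data.frame(
    gene = "g",
    sample = rep(c("a", "b"), each = 3),
    efficiency = c(0.99, 1.00, 1.01, 0.99, 1.00, 1.01)
  )
  expect_false(any(detect_outliers(wells2, alpha = 0.05)$outlier))
})

test_that("outlier flag rate under the null matches the test level", {
  set.seed(11)
  n_sets <- 500
  wells <- data.frame(
    gene = rep(paste0("set", seq_len(n_sets)), each = 15),
    sample = rep(rep(paste0("s", 1:5), each = 3), times = n_sets),
    efficiency = rnorm(15 * n_sets, 1, 0.005)
  )
  flagged <- detect_outliers(wells, alpha = 0.05)
  per_set <- tapply(flagged$outlier, flagged$gene, any)
  expect_lt(abs(mean(per_set) - 0.05), 0.03)
})

test_that("relative quantities are calibrated to the per-gene maximum", {
  wells <- data.frame(
    gene = "g1", sample = c("a", "b", "c"),
    ct = c(20, 21, 22), efficiency = 1, r0 = c(2e-8, 1e-8, 5e-9)
  )
  rq <- relative_quantities(wells)
  expect_equal(rq$relative_quantity, c(1, 0.5, 0.25))

  single <- data.frame(gene = "g2", sample = "a", ct = 20,
    efficiency = 1, r0 = 3e-8)
  expect_equal(relative_quantities(single)$relative_quantity, 1)
})

test_that("aggregation is the geometric mean over technical replicates", {
  set.seed(3)
  wells <- data.frame(
    gene = rep(c("g1", "g2"), each = 6),
    sample = rep(rep(c("a", "b"), each = 3), 2),
    ct = runif(12, 20, 25), efficiency = 1,
    r0 = 10^runif(12, -9, -7)
  )
  rq <- relative_quantities(wells)
  for (i in seq_len(nrow(rq))) {
    member <- wells$r0[wells$gene == rq$gene[i] & wells$sample == rq$sample[i]]
    expect_equal(rq$r0[i], prod(member)^(1 / 3), tolerance = 1e-12)
  }
  # per-gene maximum is exactly 1
  expect_equal(as.numeric(tapply(rq$relative_quantity, rq$gene, max)),
    c(1, 1))
})

test_that("genes with no surviving wells are dropped with a warning", {
  wells <- data.frame(
    gene = c("g1", "g1", "g2"), sample = c("a", "b", "a"),
    ct = c(20, 21, 22), efficiency = 1,
    r0 = c(1e-8, 2e-8, 1e-8),
    outlier = c(FALSE, FALSE, TRUE)
  )
  expect_warning(rq <- relative_quantities(wells), "g2")
  expect_identical(unique(rq$gene), "g1")
})
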