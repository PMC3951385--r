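#' Pairwise variation between two candidate reference genes
#'
#' Standard deviation (n-1 denominator) of the log2 expression ratio of two
#' genes over their shared samples. Two ideal control genes have an identical
#' ratio in every sample, so their pairwise variation is 0; the measure grows
#' as the genes' expression patterns diverge.
#'
#' @param a,b Positive numeric vectors of relative quantities for the two
#'   genes over the same samples (missing values allowed).
#' @return The sample standard deviation of `log2(a/b)` over samples where
#'   both are present.
#' @examples
#' pairwise_sd(c(1, 2, 4), c(1, 1, 1)) # 1
#' @export
pairwise_sd <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("`a` and `b` must have the same length")
  }
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2L) {
    rlang::abort("undefined pair: fewer than 2 shared samples")
  }
  if (any(a[keep] <= 0) || any(b[keep] <= 0)) {
    rlang::abort("relative quantities must be strictly positive")
  }
  stats::sd(log2(a[keep] / b[keep]))
}

pairwise_sd_matrix <- function(m) {
  g <- nrow(m)
  v <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(g - 1L)) {
    for (k in (j + 1L):g) {
      v[j, k] <- v[k, j] <- pairwise_sd(m[j, ], m[k, ])
    }
  }
  v
}

#' Expression stability values (M)
#'
#' A gene's M value is its average pairwise variation ([pairwise_sd()]) with
#' every other candidate gene in the panel; lower M means more stable
#' expression. With exactly two genes both M values equal the single pairwise
#' standard deviation.
#'
#' @param x Long data frame of relative quantities with columns `gene`,
#'   `sample` and the value column.
#' @param value Name of the value column (default `"relative_quantity"`).
#' @return A tibble with columns `gene`, `m`.
#' @export
m_values <- function(x, value = "relative_quantity") {
  m <- as_expr_matrix(x, value)
  if (nrow(m) < 2L) {
    rlang::abort("M values need at least 2 genes")
  }
  v <- pairwise_sd_matrix(m)
  denom <- nrow(m) - 1L
  tibble::tibble(
    gene = rownames(m),
    m = unname(rowSums(v)) / denom
  )
}

#' Geometric-mean normalization factor
#'
#' The per-sample normalization factor NF is the geometric mean of the
#' relative quantities of the chosen reference genes. Samples missing any of
#' the listed genes get `NA` (reported via a warning).
#'
#' @inheritParams m_values
#' @param genes Character vector of reference genes to combine.
#' @return A tibble with columns `sample`, `nf`.
#' @export
normalization_factor <- function(x, genes, value = "relative_quantity") {
  m <- as_expr_matrix(x, value)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    rlang::abort(paste0(
      "gene(s) not in the matrix: ", paste(missing, collapse = ", ")
    ))
  }
  sub <- m[genes, , drop = FALSE]
  nf <- apply(sub, 2, function(col) {
    if (anyNA(col)) NA_real_ else geomean(col)
  })
  if (anyNA(nf)) {
    rlang::warn(paste0(
      "NF undefined (missing reference values) for sample(s): ",
      paste(names(nf)[is.na(nf)], collapse = ", ")
    ))
  }
  tibble::tibble(sample = colnames(sub), nf = unname(nf))
}

#' Recommended number of reference genes from a pairwise-variation series
#'
#' Applies the V cutoff rule: the optimal number of reference genes is the
#' smallest n whose pairwise variation V_n/V_n+1 is at or below the cutoff
#' (default 0.15); values above it mean the (n+1)-th gene still has a
#' significant effect on the normalization factor and should be included. If
#' no entry qualifies the full panel size is returned, flagged via the
#' `exceeds_cutoff` attribute.
#'
#' @param v Numeric series of pairwise variations V_n/V_n+1 for
#'   n = 2..(G-1), in order.
#' @param cutoff Acceptability cutoff (default 0.15); comparison is `<=`.
#' @return Integer: recommended number of reference genes, with attribute
#'   `exceeds_cutoff` (TRUE when no entry passed the cutoff).
#' @examples
#' recommend_count(c(0.213, 0.15)) # 3
#' @export
recommend_count <- function(v, cutoff = 0.15) {
  if (!length(v)) {
    rlang::abort("`v` must be a non-empty numeric series")
  }
  if (cutoff <= 0 || cutoff >= 1) {
    rlang::abort("`cutoff` must be in (0, 1)")
  }
  ok <- which(v <= cutoff)
  if (length(ok)) {
    structure(ok[1L] + 1L, exceeds_cutoff = FALSE)
  } else {
    # series covers n = 2..G-1, so the panel has length(v) + 2 genes
    structure(length(v) + 2L, exceeds_cutoff = TRUE)
  }
}

#' Pairwise variation between successive normalization factors
#'
#' For n = 2..(G-1), V_n is the standard deviation over samples of
#' log2(NF_n / NF_(n+1)), where NF_n is the geometric-mean normalization
#' factor built from the n most stable genes. A small V_n means adding the
#' (n+1)-th gene barely changes the normalization factor.
#'
#' @inheritParams m_values
#' @param ranking Character vector of genes ordered most stable first
#'   (e.g. from [genorm()]); defaults to the ranking computed from `x`.
#' @return A tibble with columns `n`, `v`.
#' @export
pairwise_variation <- function(x, ranking = NULL,
                               value = "relative_quantity") {
  m <- as_expr_matrix(x, value)
  if (is.null(ranking)) {
    ranking <- genorm_ranking(m)$stability_order
  }
  if (length(ranking) < 3L) {
    rlang::abort("pairwise variation needs a ranking of at least 3 genes")
  }
  g <- length(ranking)
  v <- purrr::map_dbl(2:(g - 1L), function(n) {
    nf_n <- log_nf(m, ranking[seq_len(n)])
    nf_n1 <- log_nf(m, ranking[seq_len(n + 1L)])
    keep <- !is.na(nf_n) & !is.na(nf_n1)
    stats::sd(nf_n[keep] - nf_n1[keep])
  })
  tibble::tibble(n = 2:(g - 1L), v = v)
}

# log2 NF per sample; NA where any member gene is missing
log_nf <- function(m, genes) {
  sub <- log2(m[genes, , drop = FALSE])
  colMeans(sub)
}

# Iterative elimination on a genes x samples matrix. Returns the M
# trajectory, elimination order (least stable first) and stability order
# (most stable first, final two tied in rank).
genorm_ranking <- function(m) {
  genes <- rownames(m)
  input_order <- stats::setNames(seq_along(genes), genes)
  remaining <- genes
  trajectory <- list()
  eliminated <- character()
  tie_rounds <- integer()
  round <- 0L
  while (length(remaining) > 2L) {
    round <- round + 1L
    v <- pairwise_sd_matrix(m[remaining, , drop = FALSE])
    mv <- rowSums(v) / (length(remaining) - 1L)
    trajectory[[round]] <- tibble::tibble(
      round = round, gene = remaining, m = unname(mv)
    )
    worst_val <- max(mv)
    worst <- names(mv)[mv == worst_val]
    if (length(worst) > 1L) {
      tie_rounds <- c(tie_rounds, round)
      # tie: remove the gene appearing later in input order
      worst <- worst[which.max(input_order[worst])]
    }
    eliminated <- c(eliminated, worst)
    remaining <- setdiff(remaining, worst)
  }
  round <- round + 1L
  final_sd <- pairwise_sd(m[remaining[1L], ], m[remaining[2L], ])
  trajectory[[round]] <- tibble::tibble(
    round = round, gene = remaining, m = final_sd
  )
  stability_order <- c(remaining[order(input_order[remaining])],
    rev(eliminated))
  list(
    trajectory = dplyr::bind_rows(trajectory),
    elimination_order = c(eliminated, remaining),
    stability_order = stability_order,
    final_pair = remaining,
    tie_rounds = tie_rounds
  )
}

#' Rank reference genes by stepwise exclusion of the least stable gene
#'
#' Runs the full iterative stability analysis: M values are computed for all
#' candidates, the gene with the highest M (least stable) is removed, and M
#' is recomputed until two genes remain; those two cannot be ranked against
#' each other (pairwise variation is symmetric) and are reported as the tied
#' most-stable pair. The pairwise-variation series V_n/V_n+1 between
#' successive normalization factors then gives the recommended number of
#' reference genes under the cutoff rule (default 0.15).
#'
#' @inheritParams m_values
#' @param cutoff Cutoff for the V_n/V_n+1 rule (default 0.15).
#' @return An object of class `"genorm"` with components:
#'   \describe{
#'     \item{ranking}{tibble `gene`, `m` (M at the round the gene was
#'       eliminated; final-round M for the tied pair), `rank` (1.5 for the
#'       tied pair), `eliminated_round`.}
#'     \item{trajectory}{tibble `round`, `gene`, `m` for every round.}
#'     \item{v_series}{tibble `n`, `v`.}
#'     \item{recommended_n}{integer, with `exceeds_cutoff` attribute.}
#'     \item{best_genes}{the recommended_n most stable genes.}
#'   }
#'   Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()].
#' @examples
#' x <- expand.grid(gene = c("a", "b", "c"), sample = paste0("s", 1:6))
#' set.seed(1)
#' x$relative_quantity <- exp(rnorm(nrow(x)))
#' fit <- genorm(x)
#' tidy(fit)
#' glance(fit)
#' @export
genorm <- function(x, value = "relative_quantity", cutoff = 0.15) {
  m <- as_expr_matrix(x, value)
  if (nrow(m) < 3L) {
    rlang::abort("the stepwise ranking needs at least 3 genes")
  }
  rk <- genorm_ranking(m)
  g <- nrow(m)
  # M at elimination for each gene; final pair keeps the last-round value
  elim_m <- rk$trajectory |>
    dplyr::group_by(.data$gene) |>
    dplyr::filter(.data$round == max(.data$round)) |>
    dplyr::ungroup()
  rank_tbl <- tibble::tibble(
    gene = rk$stability_order,
    rank = c(1.5, 1.5, seq(3, g))[seq_len(g)]
  ) |>
    dplyr::left_join(elim_m[c("gene", "m", "round")], by = "gene") |>
    dplyr::rename(eliminated_round = "round") |>
    dplyr::arrange(.data$rank, .data$gene)
  v_series <- pairwise_variation(x, ranking = rk$stability_order,
    value = value)
  rec <- recommend_count(v_series$v, cutoff = cutoff)
  structure(
    list(
      ranking = rank_tbl,
      trajectory = rk$trajectory,
      final_pair = rk$final_pair,
      tie_rounds = rk$tie_rounds,
      v_series = v_series,
      recommended_n = rec,
      best_genes = rk$stability_order[seq_len(as.integer(rec))],
      cutoff = cutoff,
      n_genes = g,
      n_samples = ncol(m)
    ),
    class = "genorm"
  )
}

#' @export
print.genorm <- function(x, ...) {
  cat("Reference gene stability ranking (stepwise pairwise variation)\n")
  cat(sprintf("  %d genes x %d samples; V cutoff %.2f\n",
    x$n_genes, x$n_samples, x$cutoff))
  cat("  Most stable (tied pair):", paste(x$final_pair, collapse = " / "),
    "\n")
  cat(sprintf("  Recommended number of reference genes: %d%s\n",
    as.integer(x$recommended_n),
    if (isTRUE(attr(x$recommended_n, "exceeds_cutoff"))) {
      " (no V_n at or below the cutoff)"
    } else {
      ""
    }))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname genorm
#' @param type For `tidy.genorm`: `"ranking"` (default), `"trajectory"` or
#'   `"v_series"`.
#' @param ... Unused.
#' @export
tidy.genorm <- function(x, type = c("ranking", "trajectory", "v_series"),
                        ...) {
  type <- match.arg(type)
  switch(type,
    ranking = x$ranking,
    trajectory = x$trajectory,
    v_series = x$v_series
  )
}

#' @rdname genorm
#' @export
glance.genorm <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_genes,
    n_samples = x$n_samples,
    recommended_n = as.integer(x$recommended_n),
    exceeds_cutoff = isTRUE(attr(x$recommended_n, "exceeds_cutoff")),
    cutoff = x$cutoff,
    best_genes = paste(x$best_genes, collapse = ", "),
    most_stable_pair = paste(sort(x$final_pair), collapse = ", "),
    least_stable = x$ranking$gene[which.max(x$ranking$rank)]
  )
}
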