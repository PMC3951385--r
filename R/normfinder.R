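#' Remove the per-sample (column) effect from a log2 expression matrix
#'
#' Subtracts from each column its mean across genes, absorbing global
#' sample-to-sample differences (loading, cDNA input) that are shared by all
#' genes. The result is the matrix of gene-specific deviations the
#' variance-decomposition model works on.
#'
#' @param y Numeric genes x samples matrix of log2 expression values.
#' @return Matrix of the same shape with zero column means.
#' @export
remove_sample_effect <- function(y) {
  if (!is.matrix(y) || !is.numeric(y)) {
    rlang::abort("`y` must be a numeric matrix (genes x samples)")
  }
  if (anyNA(y)) {
    rlang::abort("`y` must be complete; impute or drop missing values upstream")
  }
  sweep(y, 2, colMeans(y))
}

#' Intra- and inter-group variance components
#'
#' From the sample-effect-removed matrix `z`, estimates for each gene i and
#' group g the inter-group expression difference d_ig (group mean deviation
#' from the group-size-weighted overall mean) and the intra-group variance
#' sigma2_ig (sample variance within the group, scaled by L/(L-1) to undo
#' the variance soaked up by the per-sample centering across the L genes).
#' gamma2 is the method-of-moments estimate of the between-(gene, group)
#' dispersion of the true differences:
#' max(0, Var(d_ig) - mean(sigma2_ig / n_g)).
#'
#' @param z Centered matrix from [remove_sample_effect()].
#' @param groups Character/factor vector of group labels, one per column of
#'   `z` (in column order), or `NULL` for ungrouped analysis.
#' @return A list with `d` (genes x groups), `sigma2` (genes x groups),
#'   `gamma2`, `n_g` (named group sizes), and `mode` (`"grouped"` or
#'   `"ungrouped"`).
#' @export
group_statistics <- function(z, groups = NULL) {
  L <- nrow(z)
  if (L < 2L) {
    rlang::abort("need at least 2 genes")
  }
  if (is.null(groups) || length(unique(groups)) < 2L) {
    # single group: no inter-group terms
    sigma2 <- apply(z, 1, stats::var) * L / (L - 1)
    return(list(
      d = matrix(0, L, 1L, dimnames = list(rownames(z), "all")),
      sigma2 = matrix(pmax(sigma2, 0), L, 1L,
        dimnames = list(rownames(z), "all")),
      gamma2 = 0,
      n_g = c(all = ncol(z)),
      mode = "ungrouped"
    ))
  }
  if (length(groups) != ncol(z)) {
    rlang::abort("`groups` must have one label per sample (column)")
  }
  groups <- as.character(groups)
  glev <- unique(groups)
  n_g <- vapply(glev, function(g) sum(groups == g), integer(1))
  if (any(n_g < 2L)) {
    rlang::abort("every group needs at least 2 samples")
  }
  gmean <- vapply(glev, function(g) {
    rowMeans(z[, groups == g, drop = FALSE])
  }, numeric(L))
  overall <- as.vector(gmean %*% n_g) / sum(n_g)
  d <- gmean - overall
  sigma2 <- vapply(glev, function(g) {
    apply(z[, groups == g, drop = FALSE], 1, stats::var)
  }, numeric(L)) * L / (L - 1)
  sigma2 <- pmax(sigma2, 0)
  dimnames(d) <- dimnames(sigma2) <- list(rownames(z), glev)
  samp_var <- sweep(sigma2, 2, n_g, "/")
  gamma2 <- max(0, stats::var(as.vector(d)) - mean(samp_var))
  list(d = d, sigma2 = sigma2, gamma2 = gamma2, n_g = n_g, mode = "grouped")
}

normfinder_rho <- function(d, sigma2, gamma2, n_g) {
  shrink <- if (gamma2 > 0) {
    gamma2 / (gamma2 + sweep(sigma2, 2, n_g, "/"))
  } else {
    0 * sigma2
  }
  dstar <- d * shrink
  rowMeans(abs(dstar) + sqrt(sweep(sigma2, 2, n_g, "/")))
}

#' Model-based reference gene stability (intra/inter-group decomposition)
#'
#' Ranks candidate reference genes by a stability value rho that combines,
#' for each gene, the magnitude of its systematic expression difference
#' between sample groups (shrunk towards zero in proportion to how much of
#' the observed difference is attributable to sampling error) and its
#' intra-group sampling error:
#' rho_i = mean over groups of ( |d*_ig| + sqrt(sigma2_ig / n_g) ).
#' Lower rho means more stable. Without groups, rho reduces to the gene's
#' standard deviation after sample-effect removal. The best two-gene
#' combination is found by treating each pair as a pseudo-gene with averaged
#' differences and quartered variance sums; opposite-sign group differences
#' can cancel, which is why a pair often beats the best single gene.
#'
#' @param x Long data frame of relative quantities with columns `gene`,
#'   `sample` and the value column (log2 transform is applied internally).
#' @param groups Sample grouping: a data frame with columns `sample`,
#'   `group`, a named character vector (names = samples), or `NULL` for
#'   ungrouped analysis.
#' @param value Name of the value column (default `"relative_quantity"`).
#' @return An object of class `"normfinder"` with components `stability`
#'   (tibble `gene`, `rho`, `rank`), `group_stats` (tibble `gene`, `group`,
#'   `n`, `d`, `d_shrunk`, `sigma2`), `gamma2`, `best_gene`, `best_pair`,
#'   `best_pair_rho`, `mode`. Supports [generics::tidy()],
#'   [generics::glance()], [ggplot2::autoplot()].
#' @export
normfinder <- function(x, groups = NULL, value = "relative_quantity") {
  m <- as_expr_matrix(x, value)
  if (anyNA(m)) {
    drop <- colnames(m)[colSums(is.na(m)) > 0]
    rlang::warn(paste0(
      "dropping sample(s) with missing values: ", paste(drop, collapse = ", ")
    ))
    m <- m[, setdiff(colnames(m), drop), drop = FALSE]
  }
  grp <- resolve_groups(groups, colnames(m))
  y <- log2(m)
  z <- remove_sample_effect(y)
  gs <- group_statistics(z, grp)
  if (gs$mode == "ungrouped") {
    rho <- sqrt(gs$sigma2[, 1L])
    shrink_d <- gs$d
  } else {
    rho <- normfinder_rho(gs$d, gs$sigma2, gs$gamma2, gs$n_g)
    shrink <- if (gs$gamma2 > 0) {
      gs$gamma2 / (gs$gamma2 + sweep(gs$sigma2, 2, gs$n_g, "/"))
    } else {
      0 * gs$sigma2
    }
    shrink_d <- gs$d * shrink
  }
  ord <- order(rho, rownames(z))
  stability <- tibble::tibble(
    gene = rownames(z)[ord],
    rho = unname(rho[ord]),
    rank = seq_along(rho)
  )
  pair <- normfinder_best_pair(gs)
  group_stats <- tibble::tibble(
    gene = rep(rownames(z), times = ncol(gs$d)),
    group = rep(colnames(gs$d), each = nrow(gs$d)),
    n = rep(unname(gs$n_g), each = nrow(gs$d)),
    d = as.vector(gs$d),
    d_shrunk = as.vector(shrink_d),
    sigma2 = as.vector(gs$sigma2)
  )
  structure(
    list(
      stability = stability,
      group_stats = group_stats,
      gamma2 = gs$gamma2,
      z = z,
      best_gene = stability$gene[1L],
      best_pair = pair$pair,
      best_pair_rho = pair$rho,
      mode = gs$mode,
      n_genes = nrow(z),
      n_samples = ncol(z)
    ),
    class = "normfinder"
  )
}

resolve_groups <- function(groups, samples) {
  if (is.null(groups)) {
    return(NULL)
  }
  if (is.data.frame(groups)) {
    assert_cols(groups, c("sample", "group"), "groups")
    map <- stats::setNames(as.character(groups$group), groups$sample)
  } else if (!is.null(names(groups))) {
    map <- stats::setNames(as.character(groups), names(groups))
  } else {
    if (length(groups) != length(samples)) {
      rlang::abort("unnamed `groups` must have one label per sample")
    }
    return(as.character(groups))
  }
  missing <- setdiff(samples, names(map))
  if (length(missing)) {
    rlang::abort(paste0(
      "no group assignment for sample(s): ", paste(missing, collapse = ", ")
    ))
  }
  unname(map[samples])
}

# exhaustive best two-gene combination from the fitted group statistics
normfinder_best_pair <- function(gs) {
  genes <- rownames(gs$d)
  L <- length(genes)
  if (L < 2L) {
    return(list(pair = genes, rho = NA_real_))
  }
  best <- NULL
  for (i in seq_len(L - 1L)) {
    for (k in (i + 1L):L) {
      d_p <- (gs$d[i, ] + gs$d[k, ]) / 2
      s2_p <- (gs$sigma2[i, ] + gs$sigma2[k, ]) / 4
      if (gs$mode == "ungrouped") {
        rho_p <- sqrt(s2_p[[1L]])
      } else {
        rho_p <- normfinder_rho(
          matrix(d_p, 1L), matrix(s2_p, 1L), gs$gamma2, gs$n_g
        )
      }
      cand <- list(pair = sort(c(genes[i], genes[k])), rho = unname(rho_p))
      if (is.null(best) || cand$rho < best$rho ||
        (cand$rho == best$rho &&
          paste(cand$pair, collapse = " ") <
            paste(best$pair, collapse = " "))) {
        best <- cand
      }
    }
  }
  best
}

#' @export
print.normfinder <- function(x, ...) {
  cat("Reference gene stability (intra/inter-group variance decomposition)\n")
  cat(sprintf("  %d genes x %d samples (%s)\n", x$n_genes, x$n_samples,
    x$mode))
  cat(sprintf("  Best gene: %s (rho = %.3f)\n", x$best_gene,
    x$stability$rho[1L]))
  cat(sprintf("  Best pair: %s (combined rho = %.3f)\n",
    paste(x$best_pair, collapse = " + "), x$best_pair_rho))
  invisible(x)
}

#' @rdname normfinder
#' @param type For `tidy.normfinder`: `"stability"` (default) or `"groups"`.
#' @param ... Unused.
#' @export
tidy.normfinder <- function(x, type = c("stability", "groups"), ...) {
  type <- match.arg(type)
  switch(type,
    stability = x$stability,
    groups = x$group_stats
  )
}

#' @rdname normfinder
#' @export
glance.normfinder <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_genes,
    n_samples = x$n_samples,
    mode = x$mode,
    gamma2 = x$gamma2,
    best_gene = x$best_gene,
    best_rho = x$stability$rho[1L],
    best_pair = paste(x$best_pair, collapse = ", "),
    best_pair_rho = x$best_pair_rho,
    least_stable = x$stability$gene[x$n_genes]
  )
}
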