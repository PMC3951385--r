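#' Normalize target genes by a normalization factor
#'
#' Divides each target gene's starting quantity by the per-sample
#' normalization factor (geometric mean of the chosen reference genes'
#' quantities). Samples without a defined NF yield `NA` and are reported.
#'
#' @param targets Long data frame of target quantities with columns `gene`,
#'   `sample` and the value column (typically `r0`).
#' @param nf Data frame with columns `sample`, `nf` as returned by
#'   [normalization_factor()].
#' @param value Name of the value column in `targets` (default `"r0"`).
#' @return A tibble `gene`, `sample`, `value`, `nf`, `normalized`.
#' @export
normalize_targets <- function(targets, nf, value = "r0") {
  assert_cols(targets, c("gene", "sample", value), "targets")
  assert_cols(nf, c("sample", "nf"), "nf")
  if (any(nf$nf <= 0, na.rm = TRUE)) {
    rlang::abort("normalization factors must be strictly positive")
  }
  out <- tibble::tibble(
    gene = targets$gene,
    sample = targets$sample,
    value = targets[[value]]
  ) |>
    dplyr::left_join(nf[c("sample", "nf")], by = "sample") |>
    dplyr::mutate(normalized = .data$value / .data$nf)
  und <- unique(out$sample[is.na(out$nf)])
  if (length(und)) {
    rlang::warn(paste0(
      "no normalization factor for sample(s): ", paste(und, collapse = ", ")
    ))
  }
  out
}

#' Relative percent difference between two normalization factors
#'
#' For each shared sample, the relative difference between the two NFs,
#' expressed as a percentage of the larger one:
#' 100 * (max - min) / max. Because normalized expression is target / NF,
#' this equals the relative difference in normalized expression induced by
#' switching from one reference-gene set to the other. Symmetric in its
#' arguments and bounded in [0, 100).
#'
#' @param nf_a,nf_b Data frames with columns `sample`, `nf`.
#' @return A tibble `sample`, `nf_a`, `nf_b`, `pct_difference`. Disjoint
#'   sample coverage gives an empty tibble with a warning.
#' @examples
#' a <- data.frame(sample = "flooding_1", nf = 1.24e-8)
#' b <- data.frame(sample = "flooding_1", nf = 8.50e-9)
#' compare_normalizations(a, b)$pct_difference # ~31.5
#' @export
compare_normalizations <- function(nf_a, nf_b) {
  assert_cols(nf_a, c("sample", "nf"), "nf_a")
  assert_cols(nf_b, c("sample", "nf"), "nf_b")
  joined <- dplyr::inner_join(
    dplyr::rename(nf_a[c("sample", "nf")], nf_a = "nf"),
    dplyr::rename(nf_b[c("sample", "nf")], nf_b = "nf"),
    by = "sample"
  ) |>
    dplyr::filter(!is.na(.data$nf_a), !is.na(.data$nf_b))
  if (!nrow(joined)) {
    rlang::warn("no shared samples between the two normalization factors")
    return(tibble::tibble(
      sample = character(), nf_a = numeric(), nf_b = numeric(),
      pct_difference = numeric()
    ))
  }
  if (any(joined$nf_a <= 0) || any(joined$nf_b <= 0)) {
    rlang::abort("normalization factors must be strictly positive")
  }
  hi <- pmax(joined$nf_a, joined$nf_b)
  lo <- pmin(joined$nf_a, joined$nf_b)
  dplyr::mutate(joined, pct_difference = 100 * (hi - lo) / hi)
}

#' Compare normalization strategies across sample subsets
#'
#' For each named sample subset, ranks the candidate reference genes with
#' both stability methods, builds three normalization factors — the stepwise
#' method's recommended best set, the variance-decomposition method's best
#' pair, and the least stable gene(s) flagged by the two methods — and
#' normalizes the target genes with each. The per-sample percent difference
#' between the two best-set NFs quantifies how much the choice of algorithm
#' moves the normalized expression values.
#'
#' @param references Long tibble of candidate reference gene quantities
#'   (`gene`, `sample`, `relative_quantity`, and `r0` if available).
#' @param targets Long tibble of target gene quantities (`gene`, `sample`,
#'   and the `target_value` column).
#' @param annotation Data frame with columns `sample`, `group` used for the
#'   grouped stability analysis within each subset.
#' @param subsets Named list of character vectors of sample ids. Subsets
#'   with fewer than 3 samples are skipped with a warning. Default: one
#'   subset `"all"` containing every annotated sample.
#' @param cutoff V_n/V_n+1 cutoff passed to [genorm()].
#' @param value Column of `references` holding the quantities used for
#'   stability analysis and NFs (default `"relative_quantity"`).
#' @param target_value Column of `targets` to normalize (default `"r0"`).
#' @return An object of class `"qpcr_validation"`: a list with
#'   `profiles` (tibble subset, method, reference_genes, gene, sample,
#'   normalized), `nf` (tibble subset, method, sample, nf),
#'   `comparisons` (tibble subset, sample, nf_a, nf_b, pct_difference for
#'   the two best-set NFs), and `selections` (tibble subset, method,
#'   reference_genes, least_stable).
#' @export
run_validation <- function(references, targets, annotation,
                           subsets = NULL, cutoff = 0.15,
                           value = "relative_quantity",
                           target_value = "r0") {
  assert_cols(annotation, c("sample", "group"), "annotation")
  if (is.null(subsets)) {
    subsets <- list(all = unique(annotation$sample))
  }
  profiles <- list()
  nfs <- list()
  comparisons <- list()
  selections <- list()
  for (nm in names(subsets)) {
    samples <- subsets[[nm]]
    if (length(unique(samples)) < 3L) {
      rlang::warn(paste0("subset '", nm, "' has fewer than 3 samples; skipped"))
      next
    }
    ref_sub <- dplyr::filter(references, .data$sample %in% samples)
    tar_sub <- dplyr::filter(targets, .data$sample %in% samples)
    ann_sub <- dplyr::filter(annotation, .data$sample %in% samples)
    gn <- genorm(ref_sub, value = value, cutoff = cutoff)
    grp <- if (length(unique(ann_sub$group)) >= 2L) ann_sub else NULL
    nf_fit <- normfinder(ref_sub, groups = grp, value = value)
    worst <- unique(c(
      gn$ranking$gene[which.max(gn$ranking$rank)],
      nf_fit$stability$gene[nf_fit$n_genes]
    ))
    sets <- list(
      genorm_best = gn$best_genes,
      normfinder_best = nf_fit$best_pair,
      least_stable = worst
    )
    for (method in names(sets)) {
      ref_label <- paste(sets[[method]], collapse = "+")
      nf <- normalization_factor(ref_sub, sets[[method]], value = value)
      nfs[[paste(nm, method)]] <- dplyr::mutate(nf,
        subset = nm, method = !!method, .before = 1)
      prof <- normalize_targets(tar_sub, nf, value = target_value)
      profiles[[paste(nm, method)]] <- dplyr::mutate(prof,
        subset = nm, method = !!method, reference_genes = ref_label,
        .before = 1)
      selections[[paste(nm, method)]] <- tibble::tibble(
        subset = nm, method = method,
        reference_genes = ref_label,
        least_stable = paste(worst, collapse = "+")
      )
    }
    cmp <- compare_normalizations(
      nfs[[paste(nm, "genorm_best")]][c("sample", "nf")],
      nfs[[paste(nm, "normfinder_best")]][c("sample", "nf")]
    )
    comparisons[[nm]] <- dplyr::mutate(cmp, subset = nm, .before = 1)
  }
  structure(
    list(
      profiles = dplyr::bind_rows(profiles),
      nf = dplyr::bind_rows(nfs),
      comparisons = dplyr::bind_rows(comparisons),
      selections = dplyr::bind_rows(selections)
    ),
    class = "qpcr_validation"
  )
}

#' @export
print.qpcr_validation <- function(x, ...) {
  cat("Normalization-strategy comparison\n")
  sel <- unique(x$selections)
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("  %-10s %-16s refs: %s\n", sel$subset[i], sel$method[i],
      sel$reference_genes[i]))
  }
  if (nrow(x$comparisons)) {
    s <- x$comparisons |>
      dplyr::group_by(.data$subset) |>
      dplyr::summarise(mean_pct = mean(.data$pct_difference),
        .groups = "drop")
    cat("  Mean |NF| percent difference (stepwise best vs model-based pair):\n")
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-10s %.1f%%\n", s$subset[i], s$mean_pct[i]))
    }
  }
  invisible(x)
}
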