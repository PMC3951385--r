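#' Threshold cycle from a single amplification trace
#'
#' Finds the fractional cycle at which the fluorescence first reaches the
#' quantification threshold, by linear interpolation between the two cycles
#' that bracket the crossing. This is the Ct (threshold cycle): the point at
#' which the signal rises significantly above background; a lower Ct means
#' more starting template.
#'
#' @param cycle Integer vector of cycle numbers (1-based, strictly
#'   increasing, as instruments report them).
#' @param fluorescence Non-negative numeric vector, same length as `cycle`.
#' @param threshold Positive fluorescence threshold.
#' @return Fractional cycle number at the first threshold crossing.
#' @examples
#' determine_ct(1:30, (1:30) / 20, threshold = 1) # exact crossing at 20
#' @export
determine_ct <- function(cycle, fluorescence, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    rlang::abort("`threshold` must be a single positive number")
  }
  validate_trace(cycle, fluorescence)
  if (fluorescence[1L] >= threshold) {
    rlang::abort("threshold below baseline: fluorescence at cycle 1 already exceeds it")
  }
  above <- which(fluorescence >= threshold)
  if (!length(above)) {
    rlang::abort("no amplification: trace never reaches the threshold")
  }
  i <- above[1L]
  f0 <- fluorescence[i - 1L]
  f1 <- fluorescence[i]
  if (f1 == threshold) {
    return(as.numeric(cycle[i]))
  }
  cycle[i - 1L] + (threshold - f0) / (f1 - f0) * (cycle[i] - cycle[i - 1L])
}

validate_trace <- function(cycle, fluorescence) {
  if (length(cycle) != length(fluorescence)) {
    rlang::abort("`cycle` and `fluorescence` must have the same length")
  }
  if (length(cycle) < 10L) {
    rlang::abort("a trace needs at least 10 cycles")
  }
  if (any(diff(cycle) <= 0)) {
    rlang::abort("`cycle` must be strictly increasing")
  }
  if (any(!is.finite(fluorescence)) || any(fluorescence < 0)) {
    rlang::abort("`fluorescence` must be finite and non-negative")
  }
  invisible(TRUE)
}

#' Amplification efficiency from the exponential phase of a trace
#'
#' Fits a log-linear regression of baseline-corrected fluorescence on cycle
#' over a sliding window, keeping the window (within the rising, exponential
#' phase) that maximizes R-squared. The per-cycle amplification efficiency is
#' the base of the fitted exponential minus one, so E = 1 corresponds to
#' perfect doubling each cycle.
#'
#' @inheritParams determine_ct
#' @param window Window length in cycles (default 4, minimum 3).
#' @param baseline_cycles Cycles whose mean fluorescence is subtracted as
#'   background before log-linear fitting (default 3:8). Use `NULL` to skip
#'   baseline correction.
#' @return A list with `efficiency`, `fit_from`, `fit_to` (cycle bounds of
#'   the chosen window) and `fit_r2`.
#' @export
fit_efficiency <- function(cycle, fluorescence, window = 4L,
                           baseline_cycles = 3:8) {
  validate_trace(cycle, fluorescence)
  if (window < 3L) {
    rlang::abort("`window` must be at least 3 cycles")
  }
  if (stats::sd(fluorescence) == 0) {
    rlang::abort("flat trace: fluorescence has zero variance")
  }
  f <- fluorescence
  if (!is.null(baseline_cycles)) {
    base_idx <- which(cycle %in% baseline_cycles)
    if (length(base_idx)) {
      f <- f - mean(fluorescence[base_idx])
    }
  }
  n <- length(cycle)
  best <- NULL
  for (start in seq_len(n - window + 1L)) {
    idx <- start:(start + window - 1L)
    fw <- f[idx]
    if (any(fw <= 0)) next
    y <- log(fw)
    x <- cycle[idx]
    slope <- stats::cov(x, y) / stats::var(x)
    if (!is.finite(slope) || slope <= 0) next
    fitted <- mean(y) + slope * (x - mean(x))
    ss_res <- sum((y - fitted)^2)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) next # flat window: no exponential growth
    r2 <- 1 - ss_res / ss_tot
    if (is.null(best) || r2 > best$fit_r2) {
      best <- list(
        efficiency = exp(slope) - 1,
        fit_from = x[1L],
        fit_to = x[window],
        fit_r2 = r2
      )
    }
  }
  if (is.null(best)) {
    rlang::abort("insufficient exponential phase: no rising window with positive fluorescence")
  }
  best
}

#' Efficiency-corrected starting quantity
#'
#' Back-calculates the starting fluorescence R0, which is proportional to the
#' starting template quantity, from the threshold cycle, the amplification
#' efficiency and the fluorescence at threshold:
#' R0 = R_Ct * (1 + E)^(-Ct).
#'
#' @param ct Threshold cycle(s), >= 0.
#' @param efficiency Per-cycle amplification efficiency E (> -1); E = 1 is
#'   perfect doubling.
#' @param r_ct Fluorescence at the threshold (> 0). When working from a Ct
#'   table without traces, use `r_ct = 1`: the unknown threshold fluorescence
#'   cancels in all within-gene ratios.
#' @return Numeric vector of starting quantities, same units as `r_ct`.
#' @examples
#' compute_r0(10, 1, 1) # 2^-10
#' @export
compute_r0 <- function(ct, efficiency, r_ct = 1) {
  if (any(r_ct <= 0)) {
    rlang::abort("`r_ct` must be positive")
  }
  if (any(efficiency <= -1)) {
    rlang::abort("`efficiency` must be greater than -1")
  }
  if (any(ct < 0, na.rm = TRUE)) {
    rlang::abort("`ct` must be non-negative")
  }
  r_ct * (1 + efficiency)^(-ct)
}

#' Quantify a plate of raw amplification traces
#'
#' Per-well pipeline: baseline correction, exponential-window efficiency fit,
#' threshold-cycle determination, and back-calculation of the starting
#' quantity R0 = R_Ct * (1+E)^(-Ct). Wells that fail (no amplification, flat
#' trace, no exponential phase) are kept in the output with `NA` values and
#' the failure reason in `qc_note`.
#'
#' @param traces Long data frame with columns `well`, `gene`, `sample`,
#'   `cycle`, `fluorescence` (one row per cycle per well).
#' @param threshold Quantification threshold on the baseline-corrected
#'   fluorescence scale. Default (`NULL`): 10% of the median per-well plateau
#'   (maximum baseline-corrected fluorescence) across the plate.
#' @inheritParams fit_efficiency
#' @return A tibble with one row per well: `well`, `gene`, `sample`, `ct`,
#'   `efficiency`, `r_ct`, `r0`, `fit_from`, `fit_to`, `fit_r2`, `qc_note`.
#' @seealso [quantify_ct_table()] for the pre-computed Ct input path,
#'   [detect_outliers()], [relative_quantities()].
#' @export
quantify_traces <- function(traces, threshold = NULL, window = 4L,
                            baseline_cycles = 3:8) {
  assert_cols(traces, c("well", "gene", "sample", "cycle", "fluorescence"),
    "traces")
  wells <- dplyr::group_split(dplyr::group_by(traces, .data$well))
  corrected <- purrr::map(wells, function(w) {
    w <- dplyr::arrange(w, .data$cycle)
    f <- w$fluorescence
    if (!is.null(baseline_cycles)) {
      base_idx <- which(w$cycle %in% baseline_cycles)
      if (length(base_idx)) f <- f - mean(f[base_idx])
    }
    list(df = w, f = f)
  })
  if (is.null(threshold)) {
    plateaus <- purrr::map_dbl(corrected, ~ max(.x$f))
    threshold <- 0.1 * stats::median(plateaus)
    if (!is.finite(threshold) || threshold <= 0) {
      rlang::abort("could not derive a positive default threshold; supply one")
    }
  }
  purrr::map_dfr(corrected, function(w) {
    df <- w$df
    out <- tibble::tibble(
      well = df$well[1L], gene = df$gene[1L], sample = df$sample[1L],
      ct = NA_real_, efficiency = NA_real_, r_ct = threshold, r0 = NA_real_,
      fit_from = NA_real_, fit_to = NA_real_, fit_r2 = NA_real_,
      qc_note = NA_character_
    )
    res <- tryCatch(
      {
        eff <- fit_efficiency(df$cycle, df$fluorescence,
          window = window, baseline_cycles = baseline_cycles
        )
        ct <- determine_ct(df$cycle, pmax(w$f, 0), threshold)
        list(eff = eff, ct = ct)
      },
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      out$qc_note <- res
    } else {
      out$ct <- res$ct
      out$efficiency <- res$eff$efficiency
      out$r0 <- compute_r0(res$ct, res$eff$efficiency, threshold)
      out$fit_from <- res$eff$fit_from
      out$fit_to <- res$eff$fit_to
      out$fit_r2 <- res$eff$fit_r2
    }
    out
  })
}

#' Quantify from a Ct table with per-primer efficiencies
#'
#' Input path for instruments that export Ct values rather than raw traces.
#' R0 is computed with a unit threshold fluorescence (`r_ct = 1`), which
#' cancels in all within-gene ratios downstream.
#'
#' @param ct_table Long data frame with columns `gene`, `sample`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @param efficiencies Data frame with columns `gene`, `efficiency`
#'   (fractions, e.g. 1.028 for 102.8%).
#' @return A per-well tibble with the same columns as [quantify_traces()].
#' @export
quantify_ct_table <- function(ct_table, efficiencies) {
  assert_cols(ct_table, c("gene", "sample", "ct"), "ct_table")
  assert_cols(efficiencies, c("gene", "efficiency"), "efficiencies")
  missing <- setdiff(unique(ct_table$gene), efficiencies$gene)
  if (length(missing)) {
    rlang::abort(paste0(
      "no primer efficiency for gene(s): ", paste(missing, collapse = ", ")
    ))
  }
  x <- dplyr::left_join(ct_table, efficiencies[c("gene", "efficiency")],
    by = "gene")
  if (!"tech_rep" %in% names(x)) x$tech_rep <- 1L
  well <- paste(x$gene, x$sample, x$tech_rep, sep = ".")
  tibble::tibble(
    well = well, gene = x$gene, sample = x$sample,
    ct = x$ct, efficiency = x$efficiency, r_ct = 1,
    r0 = compute_r0(x$ct, x$efficiency, 1),
    fit_from = NA_real_, fit_to = NA_real_, fit_r2 = NA_real_,
    qc_note = NA_character_
  )
}

#' Flag wells with outlying amplification efficiencies
#'
#' For each gene, fits the one-way ANOVA model of amplification efficiency
#' against replicate group (sample) and applies the standard outlier test on
#' its studentized deleted residuals: the well with the largest absolute
#' studentized residual is flagged when its Bonferroni-corrected two-sided
#' p-value falls below `alpha`, the model is refit without it, and the test
#' repeats until nothing more is flagged. (A gross outlier inflates the
#' within-group mean square, so gating on the ANOVA F statistic itself would
#' mask exactly the wells this screen is for.) Flagged wells should be
#' excluded from downstream quantification. Groups with a single well are
#' left unflagged (recorded in the `qc_note` column).
#'
#' @param wells Per-well tibble as returned by [quantify_traces()] or
#'   [quantify_ct_table()]; needs `gene`, `efficiency` and a grouping column.
#' @param alpha ANOVA significance level (default 0.05).
#' @param group Name of the column defining replicate groups (default
#'   `"sample"`).
#' @return `wells` with a logical `outlier` column added (and `qc_note`
#'   annotated for untestable singleton groups).
#' @export
detect_outliers <- function(wells, alpha = 0.05, group = "sample") {
  assert_cols(wells, c("gene", "efficiency", group), "wells")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be in (0, 1)")
  }
  if (!"qc_note" %in% names(wells)) wells$qc_note <- NA_character_
  wells$outlier <- FALSE
  wells$.row <- seq_len(nrow(wells))
  for (g in unique(wells$gene)) {
    idx <- which(wells$gene == g & !is.na(wells$efficiency))
    sizes <- table(wells[[group]][idx])
    singletons <- names(sizes)[sizes < 2L]
    if (length(singletons)) {
      s_idx <- idx[wells[[group]][idx] %in% singletons]
      wells$qc_note[s_idx] <- ifelse(is.na(wells$qc_note[s_idx]),
        "single replicate: efficiency not testable",
        wells$qc_note[s_idx]
      )
      idx <- setdiff(idx, s_idx)
    }
    active <- idx
    repeat {
      grp <- factor(wells[[group]][active])
      n <- length(active)
      k <- nlevels(grp)
      if (n < 3L || k < 2L || n - k - 1L < 1L) break
      # no efficiency spread at all (e.g. per-primer constants from a Ct
      # table): nothing to test, nothing to flag
      if (stats::var(wells$efficiency[active]) < .Machine$double.eps) break
      fit <- stats::lm(wells$efficiency[active] ~ grp)
      rs <- suppressWarnings(stats::rstudent(fit))
      rs[!is.finite(rs)] <- 0
      worst <- which.max(abs(rs))
      p_bonf <- 2 * stats::pt(-abs(rs[worst]), df = n - k - 1L) * n
      if (!is.finite(p_bonf) || p_bonf >= alpha) break
      wells$outlier[active[worst]] <- TRUE
      active <- active[-worst]
    }
  }
  wells$.row <- NULL
  wells
}

#' Aggregate wells and compute calibrated relative quantities
#'
#' Aggregates technical replicates within each gene/sample (geometric mean of
#' R0, arithmetic mean of Ct), excluding flagged outlier wells, then scales
#' each gene by its maximum so the highest-expressing sample is the
#' calibrator: relative quantities lie in (0, 1] with at least one exact 1
#' per gene. Genes with no surviving wells are dropped with a warning.
#'
#' @param wells Per-well tibble with `gene`, `sample`, `ct`, `efficiency`,
#'   `r0`, and optionally `outlier`.
#' @return A tibble with one row per gene/sample: `gene`, `sample`,
#'   `ct_mean`, `efficiency`, `r0`, `relative_quantity`, `outlier_excluded`
#'   (wells dropped), `n_wells`.
#' @export
relative_quantities <- function(wells) {
  assert_cols(wells, c("gene", "sample", "ct", "efficiency", "r0"), "wells")
  if (!"outlier" %in% names(wells)) wells$outlier <- FALSE
  genes_in <- unique(wells$gene)
  ok <- !wells$outlier & !is.na(wells$r0)
  kept <- wells[ok, ]
  dropped <- dplyr::count(wells[!ok, ], .data$gene, .data$sample,
    name = "outlier_excluded")
  out <- kept |>
    dplyr::group_by(.data$gene, .data$sample) |>
    dplyr::summarise(
      ct_mean = mean(.data$ct),
      efficiency = mean(.data$efficiency),
      r0 = geomean(.data$r0),
      n_wells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(dropped, by = c("gene", "sample")) |>
    dplyr::mutate(
      outlier_excluded = dplyr::coalesce(.data$outlier_excluded, 0L)
    ) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(relative_quantity = .data$r0 / max(.data$r0)) |>
    dplyr::ungroup() |>
    dplyr::relocate(
      "gene", "sample", "ct_mean", "efficiency",
      "r0", "relative_quantity", "outlier_excluded"
    )
  lost <- setdiff(genes_in, out$gene)
  if (length(lost)) {
    rlang::warn(paste0(
      "gene(s) dropped with no surviving wells: ",
      paste(lost, collapse = ", ")
    ))
  }
  out
}
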