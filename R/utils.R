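#' Geometric mean
#'
#' @param x Positive numeric vector.
#' @param na.rm Drop missing values before averaging?
#' @return The geometric mean, `exp(mean(log(x)))`.
#' @examples
#' geomean(c(2, 8)) # 4
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (any(x <= 0, na.rm = TRUE)) {
    rlang::abort("geometric mean requires strictly positive values")
  }
  exp(mean(log(x), na.rm = na.rm))
}

assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    rlang::abort(paste0("`", what, "` must be a data frame"))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    rlang::abort(paste0(
      "`", what, "` is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Long (gene, sample, value) table -> genes x samples numeric matrix.
# Duplicated gene/sample cells are an error: aggregation (technical
# replicates) belongs upstream in relative_quantities().
as_expr_matrix <- function(x, value = "relative_quantity") {
  assert_cols(x, c("gene", "sample", value), "x")
  if (anyDuplicated(x[c("gene", "sample")])) {
    rlang::abort(
      "duplicated gene/sample cells; aggregate technical replicates first"
    )
  }
  v <- x[[value]]
  if (any(v[!is.na(v)] <= 0)) {
    rlang::abort("expression values must be strictly positive")
  }
  genes <- unique(x$gene)
  samples <- unique(x$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
    dimnames = list(genes, samples)
  )
  m[cbind(match(x$gene, genes), match(x$sample, samples))] <- v
  m
}

matrix_to_long <- function(m, value = "value") {
  out <- tibble::tibble(
    gene = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m))
  )
  out[[value]] <- as.vector(m)
  out
}
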