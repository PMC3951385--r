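#' Read raw amplification traces
#'
#' Long CSV with header `well,gene,sample,cycle,fluorescence`, one row per
#' cycle per well (the layout common instrument exports reduce to).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_traces <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(x, c("well", "gene", "sample", "cycle", "fluorescence"),
    "trace file")
  x
}

#' Read a Ct table
#'
#' Long CSV with header `gene,sample,bio_rep,tech_rep,ct`.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_ct_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(x, c("gene", "sample", "ct"), "Ct file")
  x
}

#' Read a primer efficiency table
#'
#' CSV with header `gene,efficiency`; efficiencies are fractions (1.028 for
#' 102.8%).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_efficiencies <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(x, c("gene", "efficiency"), "efficiency file")
  x
}

#' Read a sample annotation table
#'
#' CSV with at least `sample,group`; `condition`, `class`, `bio_rep` are
#' carried through when present.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_annotation <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(x, c("sample", "group"), "annotation file")
  x
}

write_run_manifest <- function(dir, inputs, seed = NULL) {
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("qpcrstab")),
    r_version = as.character(getRversion()),
    seed = seed,
    inputs = inputs,
    input_hash = rlang::hash(inputs)
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Run the full reference-gene validation pipeline
#'
#' Orchestrates quantification, dual stability ranking per sample subset,
#' normalization-factor construction and target normalization, writing all
#' artifacts (CSV tables, JSON summaries, a run manifest) to `outdir`.
#' Either supply a simulated experiment / instrument data, or leave `sim`
#' `NULL` to simulate the default design with `seed`.
#'
#' @param sim A `"qpcr_sim"` object (default: simulate with [sim_config()]
#'   and `seed`). Alternatively pass `ct_table` + `efficiencies` +
#'   `annotation` directly.
#' @param ct_table,efficiencies,annotation Instrument-data path: well-level
#'   Ct tibble, per-primer efficiencies, and sample annotation
#'   (`sample`, `group`, optionally `condition`, `class`). Ignored when
#'   `sim` is given.
#' @param target_genes Character vector naming target genes in the Ct table
#'   (rows not listed are treated as candidate references). For simulated
#'   input the roles are taken from the simulation.
#' @param subsets Named list of sample subsets; default: the four standard
#'   subsets when `condition`/`class` columns are available, otherwise just
#'   `all`.
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @param cutoff,alpha V_n/V_n+1 cutoff and outlier-ANOVA level.
#' @param seed Seed used when simulating and recorded in the manifest.
#' @return A list with `quantities`, `genorm`, `normfinder` (per-subset
#'   fits), `validation`, `subsets`, invisibly writing artifacts to
#'   `outdir`.
#' @export
run_pipeline <- function(sim = NULL, ct_table = NULL, efficiencies = NULL,
                         annotation = NULL, target_genes = NULL,
                         subsets = NULL, outdir = NULL, cutoff = 0.15,
                         alpha = 0.05, seed = NULL) {
  if (is.null(sim) && is.null(ct_table)) {
    sim <- simulate_experiment(sim_config(), seed = seed)
  }
  if (!is.null(sim)) {
    ct_table <- sim$ct
    efficiencies <- sim$efficiencies
    annotation <- sim$annotation
    target_genes <- sim$efficiencies$gene[sim$efficiencies$role == "target"]
  }
  assert_cols(annotation, c("sample", "group"), "annotation")
  if (is.null(target_genes)) target_genes <- character()

  wells <- quantify_ct_table(ct_table, efficiencies)
  wells <- detect_outliers(wells, alpha = alpha)
  quantities <- relative_quantities(wells)
  refs <- dplyr::filter(quantities, !.data$gene %in% target_genes)
  targets <- dplyr::filter(quantities, .data$gene %in% target_genes)

  if (is.null(subsets)) {
    subsets <- if (all(c("condition", "class") %in% names(annotation))) {
      default_subsets(annotation)
    } else {
      list(all = unique(annotation$sample))
    }
  }
  bad <- setdiff(unlist(subsets), annotation$sample)
  if (length(bad)) {
    rlang::abort(paste0(
      "subset(s) reference unknown sample(s): ",
      paste(unique(bad), collapse = ", ")
    ))
  }

  gn <- purrr::map(subsets, function(s) {
    genorm(dplyr::filter(refs, .data$sample %in% s), cutoff = cutoff)
  })
  nf <- purrr::map(subsets, function(s) {
    ann <- dplyr::filter(annotation, .data$sample %in% s)
    grp <- if (length(unique(ann$group)) >= 2L) ann else NULL
    normfinder(dplyr::filter(refs, .data$sample %in% s), groups = grp)
  })
  validation <- if (nrow(targets)) {
    run_validation(refs, targets, annotation, subsets = subsets,
      cutoff = cutoff)
  } else {
    NULL
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(quantities, file.path(outdir, "quantities.csv"))
    for (nm in names(gn)) {
      readr::write_csv(tidy(gn[[nm]], "trajectory"),
        file.path(outdir, paste0("genorm_m_", nm, ".csv")))
      readr::write_csv(tidy(gn[[nm]], "v_series"),
        file.path(outdir, paste0("genorm_v_", nm, ".csv")))
      readr::write_csv(tidy(nf[[nm]]),
        file.path(outdir, paste0("normfinder_", nm, ".csv")))
    }
    summary <- purrr::imap(gn, function(fit, nm) {
      list(
        genorm = as.list(glance(fit)),
        normfinder = as.list(glance(nf[[nm]]))
      )
    })
    jsonlite::write_json(summary, file.path(outdir, "stability_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(validation)) {
      readr::write_csv(validation$profiles,
        file.path(outdir, "normalized_profiles.csv"))
      readr::write_csv(validation$comparisons,
        file.path(outdir, "nf_comparisons.csv"))
      jsonlite::write_json(
        purrr::transpose(as.list(validation$selections)),
        file.path(outdir, "reference_selections.json"),
        auto_unbox = TRUE, pretty = TRUE
      )
    }
    write_run_manifest(outdir,
      inputs = list(
        n_wells = nrow(ct_table),
        genes = sort(unique(ct_table$gene)),
        subsets = purrr::map(subsets, length),
        cutoff = cutoff, alpha = alpha
      ),
      seed = seed
    )
  }
  invisible(list(
    quantities = quantities,
    genorm = gn,
    normfinder = nf,
    validation = validation,
    subsets = subsets
  ))
}
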