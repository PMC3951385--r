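#' Default synthetic qPCR experiment configuration
#'
#' Builds the configuration for a simulated reference-gene validation study
#' modelled on a multi-tissue, multi-stress plant design: 10 conditions
#' (4 tissues from well-watered plants, 6 abiotic stress treatments applied
#' to leaves) x 3 biological replicates = 30 samples, each measured in 3
#' technical replicates; 11 candidate reference genes with baseline Ct
#' values between 21 and 27 (the most abundant near Ct 21, the least
#' abundant near Ct 27), per-gene biological SDs from ~0.2 to ~0.9 log2
#' units plus condition-specific shifts on the least stable genes (so their
#' effective across-sample dispersion reaches ~1.1 log2 units, i.e. per-gene
#' Ct ranges from under 1 up to ~5 cycles); primer efficiencies between
#' 0.967 and 1.079; and 7 cellulose-synthase-like target genes with strong
#' tissue- and stress-specific expression.
#'
#' @param bio_reps Biological replicates per condition (default 3).
#' @param tech_reps Technical replicates per sample (default 3).
#' @param tech_sd SD of technical Ct noise in cycles (default 0.15).
#' @param r_ct Fluorescence at the quantification threshold (default 0.2).
#' @param plateau Saturation fluorescence of simulated traces (default 2).
#' @param baseline_fluor Constant background fluorescence (default 0.01).
#' @param cycles Number of PCR cycles for trace output (default 40).
#' @return An object of class `"sim_config"`: a list with `conditions`,
#'   `ref_genes`, `ref_shifts`, `target_genes`, `target_effects` tibbles and
#'   the scalar settings above.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(bio_reps = 3L, tech_reps = 3L, tech_sd = 0.15,
                       r_ct = 0.2, plateau = 2, baseline_fluor = 0.01,
                       cycles = 40L) {
  conditions <- tibble::tibble(
    condition = c(
      "leaf", "stem", "rachis", "root",
      "drought", "salt", "cold", "heat", "wounding", "flooding"
    ),
    class = rep(c("tissue", "abiotic"), c(4L, 6L))
  )
  ref_genes <- tibble::tribble(
    ~gene,     ~base_ct, ~bio_sd, ~efficiency,
    "UBQ6",     21.0,     0.45,    1.020,
    "SAMDC",    21.2,     0.50,    1.079,
    "eEF-1a",   22.0,     0.50,    1.028,
    "ACT12",    22.5,     0.55,    0.990,
    "FTSH4",    22.8,     0.40,    1.046,
    "GAPDH",    23.0,     0.42,    0.993,
    "TUA6",     23.2,     0.80,    1.047,
    "TUB6",     23.8,     0.90,    1.017,
    "CYP5",     23.9,     0.45,    1.039,
    "U2AF",     24.2,     0.15,    0.968,
    "eIF-4a",   26.7,     0.26,    0.967
  )
  # log2 expression shifts that make a gene condition-dependent (unstable):
  # stress-responsive repression of SAMDC, wounding/flooding repression and
  # cold induction of TUB6
  ref_shifts <- tibble::tribble(
    ~gene,    ~condition, ~shift,
    "SAMDC",  "drought",  -1.0,
    "SAMDC",  "salt",     -0.8,
    "SAMDC",  "heat",     -0.9,
    "SAMDC",  "cold",     -0.6,
    "TUB6",   "wounding", -1.2,
    "TUB6",   "flooding", -1.0,
    "TUB6",   "cold",      0.9
  )
  target_genes <- tibble::tribble(
    ~gene,      ~base_ct, ~bio_sd, ~efficiency,
    "SGCesA1",   29.0,     0.45,    1.00,
    "SGCesA2",   29.5,     0.45,    1.02,
    "SGCesA3",   29.0,     0.45,    0.98,
    "SGCesA4",   29.5,     0.45,    1.01,
    "SGCesA5",   29.0,     0.45,    1.03,
    "SGCesA6",   29.5,     0.45,    0.99,
    "SGCesA7",   28.5,     0.45,    1.04
  )
  target_effects <- tibble::tribble(
    ~gene,      ~condition,  ~shift,
    "SGCesA1",  "stem",       3.0,
    "SGCesA1",  "root",       1.0,
    "SGCesA2",  "root",       2.5,
    "SGCesA2",  "stem",       1.0,
    "SGCesA3",  "stem",       1.5,
    "SGCesA4",  "stem",       1.2,
    "SGCesA4",  "root",       0.8,
    "SGCesA5",  "flooding",   3.0,
    "SGCesA5",  "wounding",   2.5,
    "SGCesA5",  "drought",    1.0,
    "SGCesA5",  "salt",       1.0,
    "SGCesA5",  "heat",       0.8,
    "SGCesA5",  "cold",       0.8,
    "SGCesA6",  "flooding",   1.5,
    "SGCesA6",  "wounding",   1.5,
    "SGCesA6",  "drought",    1.2,
    "SGCesA6",  "salt",       1.0,
    "SGCesA7",  "stem",       3.0,
    "SGCesA7",  "root",       2.5,
    "SGCesA7",  "flooding",   3.0,
    "SGCesA7",  "wounding",   2.5
  )
  cfg <- list(
    conditions = conditions,
    ref_genes = ref_genes,
    ref_shifts = ref_shifts,
    target_genes = target_genes,
    target_effects = target_effects,
    bio_reps = as.integer(bio_reps),
    tech_reps = as.integer(tech_reps),
    tech_sd = tech_sd,
    r_ct = r_ct,
    plateau = plateau,
    baseline_fluor = baseline_fluor,
    cycles = as.integer(cycles)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (tbl in list(cfg$ref_genes, cfg$target_genes)) {
    assert_cols(tbl, c("gene", "base_ct", "bio_sd", "efficiency"), "genes")
    if (any(tbl$bio_sd < 0)) rlang::abort("biological SDs must be >= 0")
    if (any(tbl$efficiency < 0.9 | tbl$efficiency > 1.15)) {
      rlang::abort("primer efficiencies must lie in (0.9, 1.15)")
    }
  }
  if (cfg$bio_reps < 1L || cfg$tech_reps < 1L) {
    rlang::abort("bio_reps and tech_reps must be >= 1")
  }
  if (cfg$tech_sd < 0) rlang::abort("tech_sd must be >= 0")
  if (cfg$r_ct <= 0 || cfg$plateau <= cfg$r_ct) {
    rlang::abort("need 0 < r_ct < plateau")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic qPCR design: %d conditions x %d bio reps x %d tech reps\n",
    nrow(x$conditions), x$bio_reps, x$tech_reps
  ))
  cat(sprintf("  %d candidate reference genes, %d target genes\n",
    nrow(x$ref_genes), nrow(x$target_genes)))
  cat(sprintf("  technical Ct SD %.2f cycles; r_ct %.2g; plateau %.2g\n",
    x$tech_sd, x$r_ct, x$plateau))
  invisible(x)
}

# per-gene effective across-sample log2 SD (biological noise + spread of
# condition shifts), defining the true stability ordering
true_stability <- function(cfg) {
  shifts <- cfg$ref_shifts
  n_cond <- nrow(cfg$conditions)
  purrr::pmap_dfr(cfg$ref_genes, function(gene, base_ct, bio_sd,
                                          efficiency) {
    s <- shifts$shift[shifts$gene == gene]
    s <- c(s, rep(0, n_cond - length(s)))
    shift_var <- sum((s - mean(s))^2) / n_cond
    tibble::tibble(gene = gene, true_sd = sqrt(bio_sd^2 + shift_var))
  }) |>
    dplyr::arrange(.data$true_sd)
}

#' Simulate a qPCR reference-gene validation experiment
#'
#' Draws a complete synthetic experiment from a [sim_config()]: for every
#' gene and biological sample a log2 expression deviation (condition shift
#' plus Normal biological noise), converted to a true threshold cycle via
#' the amplification model Ct = base_ct - deviation / log2(1 + E); each
#' technical replicate then adds Normal Ct noise. The implied starting
#' quantity is R0 = r_ct * (1+E)^(-Ct), so the generator is the exact
#' inverse of [compute_r0()]. Optionally emits full fluorescence traces
#' shaped as an exponential saturating into a plateau,
#' F(c) = baseline + plateau * x / sqrt(1 + x^2) with
#' x = R0 (1+E)^c / plateau; the knee of this saturation is sharp enough
#' that the curve is still purely exponential at the default quantification
#' threshold (10% of the plateau), which is what the trace-fitting contract
#' relies on.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; recorded in the output. `NULL` leaves the RNG
#'   state untouched.
#' @param traces Also build per-well fluorescence traces? (default FALSE;
#'   the Ct table is always produced).
#' @return An object of class `"qpcr_sim"`: list with
#'   \describe{
#'     \item{ct}{well-level tibble `gene`, `sample`, `bio_rep`, `tech_rep`,
#'       `ct`, `role` ("reference"/"target").}
#'     \item{traces}{long trace tibble (`well`, `gene`, `sample`, `cycle`,
#'       `fluorescence`) when `traces = TRUE`.}
#'     \item{annotation}{tibble `sample`, `condition`, `class`, `group`,
#'       `bio_rep` (group = tissue vs abiotic).}
#'     \item{efficiencies}{tibble `gene`, `efficiency`, `role`.}
#'     \item{truth}{list: `r0` (true per gene/sample starting quantities
#'       before technical noise), `stability` (reference genes ordered most
#'       stable first with their true effective SD), `config`, `seed`.}
#'   }
#' @export
simulate_experiment <- function(config = sim_config(), seed = NULL,
                                traces = FALSE) {
  config <- validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  ann <- tidyr::expand_grid(
    config$conditions,
    bio_rep = seq_len(config$bio_reps)
  ) |>
    dplyr::mutate(
      sample = paste(.data$condition, .data$bio_rep, sep = "_"),
      group = .data$class
    ) |>
    dplyr::select("sample", "condition", "class", "group", "bio_rep")
  genes <- dplyr::bind_rows(
    dplyr::mutate(config$ref_genes, role = "reference"),
    dplyr::mutate(config$target_genes, role = "target")
  )
  shifts <- dplyr::bind_rows(config$ref_shifts, config$target_effects)
  grid <- tidyr::expand_grid(
    genes,
    ann[c("sample", "condition", "bio_rep")]
  ) |>
    dplyr::left_join(shifts, by = c("gene", "condition")) |>
    dplyr::mutate(
      shift = dplyr::coalesce(.data$shift, 0),
      dev = .data$shift + stats::rnorm(dplyr::n(), 0, .data$bio_sd),
      true_ct = .data$base_ct - .data$dev / log2(1 + .data$efficiency),
      true_r0 = compute_r0(.data$true_ct, .data$efficiency, config$r_ct)
    )
  wells <- tidyr::expand_grid(
    grid,
    tech_rep = seq_len(config$tech_reps)
  ) |>
    dplyr::mutate(
      ct = .data$true_ct + stats::rnorm(dplyr::n(), 0, config$tech_sd)
    )
  ct_tbl <- wells |>
    dplyr::select("gene", "sample", "bio_rep", "tech_rep", "ct", "role")
  trace_tbl <- NULL
  if (traces) {
    cyc <- seq_len(config$cycles)
    trace_tbl <- wells |>
      dplyr::mutate(
        well = paste(.data$gene, .data$sample, .data$tech_rep, sep = "."),
        r0_well = compute_r0(.data$ct, .data$efficiency, config$r_ct)
      ) |>
      dplyr::select("well", "gene", "sample", "r0_well", "efficiency") |>
      tidyr::expand_grid(cycle = cyc) |>
      dplyr::mutate(
        x = .data$r0_well * (1 + .data$efficiency)^.data$cycle /
          config$plateau,
        fluorescence = config$baseline_fluor +
          config$plateau * .data$x / sqrt(1 + .data$x^2)
      ) |>
      dplyr::select("well", "gene", "sample", "cycle", "fluorescence")
  }
  truth <- list(
    r0 = dplyr::select(grid, "gene", "sample", "role",
      r0 = "true_r0", ct = "true_ct"),
    stability = true_stability(config),
    config = config,
    seed = seed
  )
  structure(
    list(
      ct = ct_tbl,
      traces = trace_tbl,
      annotation = ann,
      efficiencies = dplyr::select(genes, "gene", "efficiency", "role"),
      truth = truth
    ),
    class = "qpcr_sim"
  )
}

#' @export
print.qpcr_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated qPCR experiment: %d wells (%d genes x %d samples x %d tech reps)%s\n",
    nrow(x$ct), length(unique(x$ct$gene)), nrow(x$annotation),
    max(x$ct$tech_rep),
    if (is.null(x$traces)) "" else "; raw traces attached"
  ))
  if (!is.null(x$truth$seed)) cat("  seed:", x$truth$seed, "\n")
  invisible(x)
}

#' Named sample subsets for the standard four-way stability analysis
#'
#' Builds the conventional analysis subsets from a sample annotation table:
#' all samples, abiotic-stress samples, tissue samples, and the leaf + stem
#' tissue samples.
#'
#' @param annotation Tibble with columns `sample`, `condition`, `class`.
#' @return Named list of sample-id character vectors
#'   (`all`, `abiotic`, `tissue`, `leaf_stem`).
#' @export
default_subsets <- function(annotation) {
  assert_cols(annotation, c("sample", "condition", "class"), "annotation")
  list(
    all = annotation$sample,
    abiotic = annotation$sample[annotation$class == "abiotic"],
    tissue = annotation$sample[annotation$class == "tissue"],
    leaf_stem = annotation$sample[annotation$condition %in% c("leaf", "stem")]
  )
}
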