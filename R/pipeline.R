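#' Pipeline run configuration
#'
#' Bundles inputs, thresholds and the comparison list for
#' [run_pipeline()]. Inputs may be file paths (read with the dialect) or
#' in-memory tibbles. Every threshold default matches the package-wide
#' conventions: SIFT 0.05, gene prevalence 5 samples, gene-test alpha 0.001,
#' SNV fold gate 2, SNV Fisher p 0.05.
#'
#' @param variants Variant tibble or path to a variant TSV.
#' @param design Design tibble or path.
#' @param domains Optional domain tibble or path.
#' @param comparisons List of comparison specs; each a list/row with
#'   `dimension`, `class_a`, `class_b`, and optionally `fc_numerator`
#'   (`"class_a"`/`"class_b"`) and `samples` (character vector restricting
#'   the design, e.g. to one population).
#' @param dialect Column dialect for reading a variants path.
#' @param sift_threshold,min_samples,alpha,or_fold,p_max,nk_mode,var_equal
#'   Stage thresholds, see [score_matrix()], [filter_low_prevalence()],
#'   [compare_classes()], [select_differential_snvs()].
#' @param require_domain Apply the domain gate when selecting SNVs (needs
#'   `domains`).
#' @param out_dir Optional directory; when set, every result table is
#'   written as TSV plus a JSON run manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(variants, design, domains = NULL,
                       comparisons = list(),
                       dialect = variant_dialect(),
                       sift_threshold = 0.05, min_samples = 5, alpha = 0.001,
                       or_fold = 2, p_max = 0.05,
                       nk_mode = "filtered", var_equal = TRUE,
                       require_domain = TRUE, out_dir = NULL) {
  if (length(comparisons) == 0) abort("at least one comparison is required")
  comparisons <- lapply(comparisons, function(cmp) {
    if (!all(c("dimension", "class_a", "class_b") %in% names(cmp))) {
      abort("each comparison needs `dimension`, `class_a` and `class_b`")
    }
    cmp$fc_numerator <- cmp$fc_numerator %||% "class_a"
    cmp
  })
  structure(list(
    variants = variants, design = design, domains = domains,
    comparisons = comparisons, dialect = dialect,
    sift_threshold = sift_threshold, min_samples = min_samples,
    alpha = alpha, or_fold = or_fold, p_max = p_max, nk_mode = nk_mode,
    var_equal = var_equal, require_domain = require_domain,
    out_dir = out_dir
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]: top-level `variants`,
#' `design`, `domains` paths, a `comparisons` sequence of
#' dimension/class_a/class_b mappings, an optional `dialect` mapping, and
#' threshold keys (`sift_threshold`, `min_samples`, `alpha`, `or_fold`,
#' `p_max`, `nk_mode`, `var_equal`, `require_domain`, `out_dir`).
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (key in c("variants", "design")) {
    if (is.null(raw[[key]])) abort(sprintf("config `%s` lacks required key `%s`", path, key))
  }
  dialect <- do.call(variant_dialect, as.list(unlist(raw$dialect %||% list())))
  args <- list(
    variants = raw$variants, design = raw$design, domains = raw$domains,
    comparisons = raw$comparisons %||% list(), dialect = dialect
  )
  for (key in c("sift_threshold", "min_samples", "alpha", "or_fold", "p_max",
                "nk_mode", "var_equal", "require_domain", "out_dir")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  do.call(run_config, args)
}

#' Run the full differential mutation pipeline
#'
#' Executes filter, score, gene comparison and SNV contrast for every
#' configured comparison: deleterious filtering at the SIFT threshold, the
#' gene-by-sample score matrix, the prevalence filter, per-comparison
#' differentially mutated genes, and per-comparison SNV contrasts restricted
#' to those genes with the fold/significance/domain gates applied. Stage
#' record counts are logged via `message()`; outputs are deterministic for a
#' fixed config.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return A list of class `dmg_pipeline`: `matrix` (prevalence-filtered
#'   score matrix), `dmg` and `snv` (named per-comparison lists of results),
#'   `counts` (stage record counts), and `manifest` (run metadata, also
#'   written as JSON when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  variants <- stage("read_variants", {
    if (is.character(config$variants)) {
      read_variants(config$variants, dialect = config$dialect)
    } else {
      check_variants(tibble::as_tibble(config$variants))
    }
  })
  design <- stage("read_design", {
    if (is.character(config$design)) read_design(config$design)
    else check_design(tibble::as_tibble(config$design))
  })
  domains <- stage("read_domains", {
    if (is.null(config$domains)) NULL
    else if (is.character(config$domains)) read_domains(config$domains)
    else tibble::as_tibble(config$domains)
  })
  message(sprintf("pipeline: %d annotation rows, %d samples", nrow(variants), nrow(design)))

  retained <- stage("filter_deleterious",
                    filter_deleterious(variants, threshold = config$sift_threshold))
  message(sprintf("pipeline: %d deleterious rows at SIFT <= %g",
                  nrow(retained), config$sift_threshold))

  mat <- stage("score_matrix",
               score_matrix(variants, design, sift_threshold = config$sift_threshold,
                            nk_mode = config$nk_mode))
  mat_f <- stage("filter_low_prevalence",
                 filter_low_prevalence(mat, min_samples = config$min_samples))
  message(sprintf("pipeline: score matrix %d genes x %d samples (%d after prevalence >= %d)",
                  nrow(mat), nrow(design), nrow(mat_f), config$min_samples))

  dmg <- list()
  snv <- list()
  for (cmp in config$comparisons) {
    tag <- sprintf("%s_%s_vs_%s", cmp$dimension, cmp$class_a, cmp$class_b)
    cmp_design <- design
    if (!is.null(cmp$samples)) {
      cmp_design <- cmp_design[cmp_design$sample_id %in% cmp$samples, , drop = FALSE]
    }
    dmg[[tag]] <- stage(paste0("compare_classes:", tag),
      compare_classes(mat_f, cmp_design, cmp$dimension, cmp$class_a, cmp$class_b,
                      alpha = config$alpha, var_equal = config$var_equal,
                      fc_numerator = cmp$fc_numerator))
    message(sprintf("pipeline: %s -> %d differentially mutated gene(s)",
                    tag, nrow(dmg[[tag]])))
    contrasts <- stage(paste0("snv_contrasts:", tag),
      snv_contrasts(retained, cmp_design, cmp$dimension, cmp$class_a, cmp$class_b,
                    domains = domains, genes = dmg[[tag]]$gene_symbol))
    snv[[tag]] <- stage(paste0("select_differential_snvs:", tag),
      select_differential_snvs(contrasts, or_fold = config$or_fold,
                               p_max = config$p_max,
                               require_domain = config$require_domain &&
                                 !is.null(domains)))
    message(sprintf("pipeline: %s -> %d candidate SNV(s), %d retained",
                    tag, nrow(contrasts), nrow(snv[[tag]])))
  }

  counts <- tibble::tibble(
    stage = c("annotation_rows", "deleterious_rows", "genes_scored",
              "genes_prevalent", "samples"),
    n = c(nrow(variants), nrow(retained), nrow(mat), nrow(mat_f), nrow(design))
  )
  manifest <- list(
    tool = "dmgscan",
    version = as.character(utils::packageVersion("dmgscan")),
    thresholds = config[c("sift_threshold", "min_samples", "alpha", "or_fold",
                          "p_max", "nk_mode", "var_equal", "require_domain")],
    comparisons = lapply(config$comparisons, function(cmp)
      cmp[c("dimension", "class_a", "class_b", "fc_numerator")]),
    counts = setNames(as.list(counts$n), counts$stage),
    results = lapply(dmg, nrow)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(tibble::as_tibble(mat_f),
                       file.path(config$out_dir, "score_matrix.tsv"))
    for (tag in names(dmg)) {
      write_result_table(tibble::as_tibble(dmg[[tag]]),
                         file.path(config$out_dir, paste0("dmg_", tag, ".tsv")))
      write_result_table(tibble::as_tibble(snv[[tag]]),
                         file.path(config$out_dir, paste0("snv_", tag, ".tsv")))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(matrix = mat_f, dmg = dmg, snv = snv, counts = counts,
                 manifest = manifest),
            class = "dmg_pipeline")
}
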