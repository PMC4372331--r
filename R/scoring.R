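#' Keep only deleterious isoform annotations
#'
#' A substitution is called deleterious when its SIFT score is less than or
#' equal to the threshold (0.05 by convention). Records with a missing SIFT
#' score are dropped: no prediction, no evidence of deleteriousness.
#'
#' @param variants A variant tibble (see [read_variants()]).
#' @param threshold SIFT cut-off in \[0, 1\]; annotations with
#'   `sift_score <= threshold` are retained.
#' @return The retained rows of `variants`.
#' @export
#' @examples
#' v <- tibble::tibble(
#'   sample_id = "S1", gene_symbol = "G", transcript_id = "T1",
#'   chrom = "chr1", pos = 1:4, ref_allele = "A", alt_allele = "C",
#'   sift_score = c(0, 0.05, 0.06, NA)
#' )
#' filter_deleterious(v)$sift_score
filter_deleterious <- function(variants, threshold = 0.05) {
  check_variants(variants)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single value in [0, 1]")
  }
  dplyr::filter(variants, !is.na(.data$sift_score), .data$sift_score <= threshold)
}

#' Deleterious mutation score for one gene in one sample
#'
#' The score combines all retained (deleterious) mutations of a gene in a
#' sample, normalising over transcript isoforms: annotations are grouped by
#' genomic mutation (chrom, pos, ref, alt), and each mutation k contributes
#' the mean of (1 - SIFT) over its N_k isoform annotations,
#' \deqn{D = \sum_k \frac{\sum_x (1 - S_{kx})}{N_k}.}
#' A single deleterious mutation therefore contributes between 0.95 and 1
#' regardless of how many isoforms it is annotated on.
#'
#' @param records Variant tibble rows, all for one gene and one sample, all
#'   with a present SIFT score at or below the deleterious threshold.
#' @return A single non-negative score.
#' @export
score_gene_sample <- function(records) {
  check_variants(records, arg = "records")
  if (nrow(records) == 0) return(0)
  if (dplyr::n_distinct(records$gene_symbol) != 1 ||
      dplyr::n_distinct(records$sample_id) != 1) {
    abort("`records` must all share one gene_symbol and one sample_id")
  }
  if (anyNA(records$sift_score)) {
    abort("`records` contains missing SIFT scores; filter_deleterious() first")
  }
  contrib <- records |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref_allele, .data$alt_allele) |>
    dplyr::summarise(score = sum(1 - .data$sift_score) / dplyr::n(), .groups = "drop")
  sum(contrib$score)
}

#' Build the gene-by-sample deleterious score matrix
#'
#' Applies the deleterious filter and computes the score of
#' [score_gene_sample()] for every (gene, sample) cell, returning a wide
#' tibble with one row per gene and one column per design sample. Samples
#' without retained mutations in a gene score 0.
#'
#' The isoform normaliser N_k can count either the isoform annotations that
#' survived the deleterious filter (`nk_mode = "filtered"`, the default) or
#' all isoform annotations of the mutation present in the input
#' (`nk_mode = "all_annotated"`); the two coincide when the input is already
#' filtered.
#'
#' @param variants A variant tibble; may contain non-deleterious records,
#'   which are filtered out at `sift_threshold`.
#' @param design Design tibble with a `sample_id` column; its samples define
#'   the matrix columns.
#' @param sift_threshold Deleterious SIFT cut-off, see [filter_deleterious()].
#' @param nk_mode `"filtered"` or `"all_annotated"` (see Details).
#' @param gene_universe Optional character vector of gene symbols fixing the
#'   row set; genes never mutated in the cohort appear as all-zero rows.
#'   Defaults to the genes observed among retained records.
#' @return A tibble of class `dmg_score_matrix`: column `gene_symbol`, then
#'   one numeric column per sample, rows sorted by gene symbol.
#' @export
score_matrix <- function(variants, design, sift_threshold = 0.05,
                         nk_mode = c("filtered", "all_annotated"),
                         gene_universe = NULL) {
  nk_mode <- match.arg(nk_mode)
  check_variants(variants)
  check_design(design)
  orphans <- setdiff(unique(variants$sample_id), design$sample_id)
  if (length(orphans) > 0) {
    abort(sprintf("variant sample(s) absent from design: %s",
                  paste(orphans, collapse = ", ")))
  }
  retained <- filter_deleterious(variants, threshold = sift_threshold)

  nk_source <- if (nk_mode == "all_annotated") variants else retained
  nk <- nk_source |>
    dplyr::count(.data$sample_id, .data$gene_symbol, .data$chrom, .data$pos,
                 .data$ref_allele, .data$alt_allele, name = "n_isoforms")

  cells <- retained |>
    dplyr::group_by(.data$sample_id, .data$gene_symbol, .data$chrom, .data$pos,
                    .data$ref_allele, .data$alt_allele) |>
    dplyr::summarise(numerator = sum(1 - .data$sift_score), .groups = "drop") |>
    dplyr::left_join(nk, by = c("sample_id", "gene_symbol", "chrom", "pos",
                                "ref_allele", "alt_allele")) |>
    dplyr::group_by(.data$gene_symbol, .data$sample_id) |>
    dplyr::summarise(score = sum(.data$numerator / .data$n_isoforms),
                     .groups = "drop")

  genes <- sort(unique(c(gene_universe, cells$gene_symbol)))
  wide <- cells |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "score",
                       values_fill = 0)
  full <- tibble::tibble(gene_symbol = genes) |>
    dplyr::left_join(wide, by = "gene_symbol")
  missing_samples <- setdiff(design$sample_id, names(full))
  for (s in missing_samples) full[[s]] <- 0
  full <- full[, c("gene_symbol", design$sample_id)]
  full <- dplyr::mutate(full, dplyr::across(-"gene_symbol", ~ tidyr::replace_na(.x, 0)))
  new_score_matrix(full)
}

new_score_matrix <- function(x) {
  class(x) <- c("dmg_score_matrix", class(tibble::tibble()))
  x
}

#' Drop genes deleteriously mutated in too few samples
#'
#' Rarely mutated genes carry little information for a class comparison and
#' inflate the multiple-testing burden; genes with a positive score in fewer
#' than `min_samples` samples are removed. The column (sample) set is
#' unchanged.
#'
#' @param matrix A score matrix from [score_matrix()].
#' @param min_samples Minimum number of samples with a positive score for a
#'   gene to be retained (default 5, the convention for a ~100-sample
#'   cohort).
#' @return The filtered score matrix.
#' @export
filter_low_prevalence <- function(matrix, min_samples = 5) {
  stopifnot(is.data.frame(matrix), "gene_symbol" %in% names(matrix),
            min_samples >= 1)
  scores <- as.matrix(matrix[, setdiff(names(matrix), "gene_symbol")])
  keep <- rowSums(scores > 0) >= min_samples
  new_score_matrix(matrix[keep, , drop = FALSE])
}

#' Heatmap of a deleterious score matrix
#'
#' @param object A `dmg_score_matrix`.
#' @param max_genes Cap on the number of rows drawn (the most prevalent
#'   genes are kept); heatmaps beyond a few hundred rows are unreadable.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot dmg_score_matrix
#' @export
autoplot.dmg_score_matrix <- function(object, max_genes = 50, ...) {
  scores <- as.matrix(object[, setdiff(names(object), "gene_symbol")])
  ord <- order(rowSums(scores > 0), decreasing = TRUE)
  keep <- head(ord, max_genes)
  long <- object[keep, , drop = FALSE] |>
    tidyr::pivot_longer(-"gene_symbol", names_to = "sample_id",
                        values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_symbol,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "D score") +
    ggplot2::labs(x = "sample", y = "gene") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
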