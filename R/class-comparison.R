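#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (delegating to
#' [stats::p.adjust()]), with the input contract checked: p-values must lie
#' in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values, elementwise at or above the input, at most 1.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    abort("all p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Fold change between two class means
#'
#' Ratio of mean scores, with the numerator class chosen by the comparison's
#' reporting direction (conventionally the worse-prognosis class). A positive
#' numerator over a zero denominator is reported as `Inf`; 0/0 is an error
#' since no direction is defined.
#'
#' @param mean_num,mean_den Non-negative class means (vectorised).
#' @return Numeric vector of fold changes (possibly `Inf` or 0).
#' @export
#' @examples
#' fold_change(c(0.33, 0.5), c(0, 0.5))
fold_change <- function(mean_num, mean_den) {
  if (any(mean_num < 0 | mean_den < 0)) abort("class means must be non-negative")
  both_zero <- mean_num == 0 & mean_den == 0
  if (any(both_zero)) {
    abort("fold change undefined: both class means are zero")
  }
  ifelse(mean_den == 0, Inf, mean_num / mean_den)
}

#' Differentially mutated genes between two classes
#'
#' For every gene in the (prevalence-filtered) score matrix, compares the
#' deleterious score distributions of the two classes with a two-sided
#' two-sample t-test — pooled variance by default, matching the
#' class-comparison convention of gene-screening tools; Welch via
#' `var_equal = FALSE`. Benjamini-Hochberg FDRs are computed over all tested
#' genes; genes with unadjusted `p <= alpha` are returned (selection is on
#' the raw p-value, with the FDR reported alongside).
#'
#' Genes with zero variance in both classes have an undefined t statistic:
#' equal means yield p = 1; unequal means are reported at the smallest
#' positive double and flagged in the `degenerate` column so they cannot pass
#' silently.
#'
#' A class with fewer than 2 samples is an error; fewer than 10 triggers a
#' warning (rare mutations dominate such small classes), but the comparison
#' proceeds.
#'
#' @param matrix Score matrix from [score_matrix()], ideally after
#'   [filter_low_prevalence()].
#' @param design Design tibble.
#' @param dimension Design column to compare on (e.g. `"ER"`).
#' @param class_a,class_b The two compared labels; samples with other or
#'   missing labels are excluded.
#' @param alpha Two-sided significance level for reporting (default 0.001).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @param fc_numerator Which class mean forms the fold-change numerator:
#'   `"class_a"` (default) or `"class_b"`. Report the worse-prognosis class
#'   as numerator by passing it as `class_a` or flipping this switch.
#' @return A tibble of class `dmg_result` with columns `gene_symbol`,
#'   `p_value`, `fdr`, `mean_a`, `mean_b`, `fold_change`, `n_a`, `n_b`,
#'   `degenerate`, sorted by p ascending, restricted to `p <= alpha`. The
#'   full per-gene table is available via [tidy()], a one-row summary via
#'   [glance()].
#' @export
compare_classes <- function(matrix, design, dimension, class_a, class_b,
                            alpha = 0.001, var_equal = TRUE,
                            fc_numerator = c("class_a", "class_b")) {
  fc_numerator <- match.arg(fc_numerator)
  stopifnot(is.data.frame(matrix), "gene_symbol" %in% names(matrix))
  cls <- design_classes(design, dimension, class_a, class_b)
  for (side in c("a", "b")) {
    lab <- if (side == "a") class_a else class_b
    n <- length(cls[[side]])
    if (n < 2) {
      abort(sprintf("class `%s` has %d sample(s) in the matrix; need at least 2", lab, n))
    }
    if (n < 10) {
      warn(sprintf("class `%s` has only %d samples; rare mutations may dominate", lab, n))
    }
  }
  missing <- setdiff(c(cls$a, cls$b), names(matrix))
  if (length(missing) > 0) {
    abort(sprintf("design sample(s) absent from matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  xa <- as.matrix(matrix[, cls$a, drop = FALSE])
  xb <- as.matrix(matrix[, cls$b, drop = FALSE])

  test_one <- function(a, b) {
    if (var(a) == 0 && var(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else .Machine$double.xmin
      return(c(p, 1))
    }
    c(t.test(a, b, var.equal = var_equal)$p.value, 0)
  }
  res <- vapply(seq_len(nrow(matrix)),
                function(i) test_one(xa[i, ], xb[i, ]), numeric(2))

  all_genes <- tibble::tibble(
    gene_symbol = matrix$gene_symbol,
    p_value = res[1, ],
    mean_a = rowMeans(xa),
    mean_b = rowMeans(xb),
    n_a = length(cls$a),
    n_b = length(cls$b),
    degenerate = res[2, ] == 1
  )
  all_genes$fdr <- if (nrow(all_genes) > 0) bh_fdr(all_genes$p_value) else numeric(0)
  num <- if (fc_numerator == "class_a") all_genes$mean_a else all_genes$mean_b
  den <- if (fc_numerator == "class_a") all_genes$mean_b else all_genes$mean_a
  fc <- rep(NA_real_, nrow(all_genes))
  defined <- !(num == 0 & den == 0)
  fc[defined] <- fold_change(num[defined], den[defined])
  all_genes$fold_change <- fc
  all_genes <- all_genes[, c("gene_symbol", "p_value", "fdr", "mean_a", "mean_b",
                             "fold_change", "n_a", "n_b", "degenerate")]

  out <- all_genes |>
    dplyr::filter(.data$p_value <= alpha) |>
    dplyr::arrange(.data$p_value, .data$gene_symbol)
  structure(out,
            class = c("dmg_result", class(tibble::tibble())),
            all_genes = dplyr::arrange(all_genes, .data$p_value, .data$gene_symbol),
            dimension = dimension, class_a = class_a, class_b = class_b,
            alpha = alpha, var_equal = var_equal, fc_numerator = fc_numerator)
}

#' @describeIn compare_classes Full per-gene test table (all tested genes,
#'   not only those passing `alpha`).
#' @param x A `dmg_result`.
#' @param ... Ignored.
#' @method tidy dmg_result
#' @export
tidy.dmg_result <- function(x, ...) {
  tibble::as_tibble(attr(x, "all_genes"))
}

#' @describeIn compare_classes One-row summary of the comparison.
#' @method glance dmg_result
#' @export
glance.dmg_result <- function(x, ...) {
  all_genes <- attr(x, "all_genes")
  tibble::tibble(
    dimension = attr(x, "dimension"),
    class_a = attr(x, "class_a"),
    class_b = attr(x, "class_b"),
    n_a = if (nrow(all_genes) > 0) all_genes$n_a[1] else NA_integer_,
    n_b = if (nrow(all_genes) > 0) all_genes$n_b[1] else NA_integer_,
    n_genes_tested = nrow(all_genes),
    n_significant = nrow(x),
    alpha = attr(x, "alpha")
  )
}

#' Volcano plot of a two-class gene comparison
#'
#' @param object A `dmg_result` from [compare_classes()].
#' @param ... Ignored.
#' @return A ggplot object: log2 fold change (infinite values capped at the
#'   plot margin) against -log10 p, significant genes highlighted.
#' @method autoplot dmg_result
#' @export
autoplot.dmg_result <- function(object, ...) {
  all_genes <- tidy(object)
  fc_labels <- c(attr(object, "class_a"), attr(object, "class_b"))
  if (attr(object, "fc_numerator") == "class_b") fc_labels <- rev(fc_labels)
  finite_fc <- all_genes$fold_change[is.finite(all_genes$fold_change) &
                                       all_genes$fold_change > 0]
  cap <- if (length(finite_fc) > 0) max(abs(log2(finite_fc))) + 1 else 5
  df <- all_genes |>
    dplyr::mutate(
      log2_fc = dplyr::case_when(
        is.infinite(.data$fold_change) ~ cap,
        .data$fold_change == 0 ~ -cap,
        TRUE ~ log2(.data$fold_change)
      ),
      significant = .data$p_value <= attr(object, "alpha")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s/%s)", fc_labels[1], fc_labels[2]),
      y = expression(-log[10] ~ p), colour = "reported"
    ) +
    ggplot2::theme_minimal()
}

#' Composition balance of a comparison along a stratifier
#'
#' Checks whether a comparison dimension is confounded with another binary
#' design variable (typically population): builds the 2x2 table of
#' stratifier level by class label and runs the two-sided Fisher exact test.
#'
#' @param design Design tibble.
#' @param dimension Comparison dimension (must have exactly two observed
#'   labels after dropping missing ones, or supply `classes`).
#' @param stratifier Design column to stratify by (default `"population"`);
#'   must be binary after dropping missing labels.
#' @param classes Optional length-2 character vector restricting `dimension`
#'   to two labels when more are present.
#' @return A one-row tibble: the four cell counts (`a`,`b` = stratum 1 in
#'   class 1/2; `c`,`d` = stratum 2), the level names, and `fisher_p`.
#' @export
composition_test <- function(design, dimension, stratifier = "population",
                             classes = NULL) {
  check_design(design)
  for (col in c(dimension, stratifier)) {
    if (!col %in% names(design)) abort(sprintf("unknown design column `%s`", col))
  }
  d <- design[!is.na(design[[dimension]]) & !is.na(design[[stratifier]]), ]
  if (!is.null(classes)) d <- d[d[[dimension]] %in% classes, ]
  dim_levels <- sort(unique(d[[dimension]]))
  strat_levels <- sort(unique(d[[stratifier]]))
  if (length(dim_levels) != 2) {
    abort(sprintf("dimension `%s` must be binary; observed labels: %s",
                  dimension, paste(dim_levels, collapse = ", ")))
  }
  if (length(strat_levels) != 2) {
    abort(sprintf("stratifier `%s` must be binary; observed labels: %s",
                  stratifier, paste(strat_levels, collapse = ", ")))
  }
  n <- function(s, cl) sum(d[[stratifier]] == s & d[[dimension]] == cl)
  a <- n(strat_levels[1], dim_levels[1]); b <- n(strat_levels[1], dim_levels[2])
  cc <- n(strat_levels[2], dim_levels[1]); dd <- n(strat_levels[2], dim_levels[2])
  tibble::tibble(
    dimension = dimension, stratifier = stratifier,
    class_1 = dim_levels[1], class_2 = dim_levels[2],
    stratum_1 = strat_levels[1], stratum_2 = strat_levels[2],
    a = a, b = b, c = cc, d = dd,
    fisher_p = fisher_exact_two_sided(a, b, cc, dd)
  )
}
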