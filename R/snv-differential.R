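#' Carrier odds ratio from a 2x2 table
#'
#' Raw cross-product odds ratio `(a*d) / (b*c)` with the zero-cell
#' conventions used for carrier tables: `b*c == 0` with `a*d > 0` gives
#' `Inf`, `a*d == 0` with `b*c > 0` gives 0, and a table with both products
#' zero has no defined direction and is an error. No continuity (Haldane)
#' correction is applied unless requested.
#'
#' @param a,b,c,d Non-negative cell counts (vectorised): `a` carriers and `b`
#'   non-carriers in the first class, `c` carriers and `d` non-carriers in
#'   the second.
#' @param haldane Add 0.5 to every cell before forming the ratio (off by
#'   default; zero cells then report 0/Inf as above).
#' @return Numeric vector of odds ratios.
#' @export
#' @examples
#' odds_ratio(23, 4, 13, 27)
#' odds_ratio(8, 22, 0, 37)
odds_ratio <- function(a, b, c, d, haldane = FALSE) {
  counts <- cbind(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("cell counts must be non-negative integers")
  }
  if (any(a + b == 0) || any(c + d == 0)) {
    abort("each class must contain at least one sample")
  }
  if (haldane) {
    return((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
  }
  num <- a * d
  den <- b * c
  undefined <- num == 0 & den == 0
  if (any(undefined)) {
    abort("odds ratio undefined: both a*d and b*c are zero")
  }
  ifelse(den == 0, Inf, num / den)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration: with margins fixed, sums the
#' probabilities of all tables whose point probability does not exceed that
#' of the observed table (the minimum-likelihood two-sided convention of
#' mainstream statistical software; a relative tolerance of 1e-7 guards the
#' comparison against rounding, as in [stats::fisher.test()]). Vectorised
#' over tables.
#'
#' @inheritParams odds_ratio
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_sided(23, 4, 13, 27)
#' fisher_exact_two_sided(35, 14, 5, 13)
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("cell counts must be non-negative integers")
  }
  if (any(rowSums(counts) < 1)) {
    abort("table total must be at least 1")
  }
  one <- function(a, b, c, d) {
    m <- a + b
    n <- c + d
    k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p0 <- dhyper(a, m, n, k)
    min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
  }
  as.numeric(mapply(one, a, b, c, d))
}

#' Per-SNV carrier counts between two classes
#'
#' A sample carries an SNV when it has at least one retained annotation row
#' with that mutation key, on any transcript isoform; genotype (het/hom) is
#' not considered. Counts carriers of every SNV in each of the two classes.
#'
#' @param variants Deleterious-filtered variant tibble (see
#'   [filter_deleterious()]).
#' @param design Design tibble.
#' @param dimension,class_a,class_b Comparison definition as in
#'   [compare_classes()].
#' @return A tibble with one row per (gene, mutation key): `gene_symbol`,
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `dbsnp_id`, `aa_change`,
#'   `transcript_id` (first annotated isoform, for domain lookup),
#'   `carriers_a`, `n_a`, `carriers_b`, `n_b`.
#' @export
carrier_counts <- function(variants, design, dimension, class_a, class_b) {
  check_variants(variants)
  cls <- design_classes(design, dimension, class_a, class_b)
  v <- variants[variants$sample_id %in% c(cls$a, cls$b), , drop = FALSE]
  carriers <- v |>
    dplyr::distinct(.data$sample_id, .data$gene_symbol, .data$chrom, .data$pos,
                    .data$ref_allele, .data$alt_allele)
  meta <- v |>
    dplyr::group_by(.data$gene_symbol, .data$chrom, .data$pos,
                    .data$ref_allele, .data$alt_allele) |>
    dplyr::summarise(
      dbsnp_id = dplyr::first(.data$dbsnp_id[!is.na(.data$dbsnp_id)], default = NA_character_),
      aa_change = dplyr::first(.data$aa_change[!is.na(.data$aa_change)], default = NA_character_),
      transcript_id = dplyr::first(.data$transcript_id),
      .groups = "drop"
    )
  carriers |>
    dplyr::group_by(.data$gene_symbol, .data$chrom, .data$pos,
                    .data$ref_allele, .data$alt_allele) |>
    dplyr::summarise(
      carriers_a = sum(.data$sample_id %in% cls$a),
      carriers_b = sum(.data$sample_id %in% cls$b),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_a = length(cls$a), n_b = length(cls$b)) |>
    dplyr::left_join(meta, by = c("gene_symbol", "chrom", "pos",
                                  "ref_allele", "alt_allele")) |>
    dplyr::arrange(.data$gene_symbol, .data$chrom, .data$pos, .data$alt_allele)
}

#' Does a variant fall inside an annotated protein domain?
#'
#' True where the amino-acid position parsed from `aa_change` lies inside any
#' domain interval (inclusive on both ends) annotated for the variant's
#' transcript. Variants whose `aa_change` cannot be parsed are flagged
#' `FALSE` with a warning when domain intervals exist for their transcript.
#'
#' @param variants A tibble with `transcript_id` and `aa_change` columns
#'   (variant tibble or carrier-count table).
#' @param domains Domain interval tibble from [read_domains()].
#' @return Logical vector along the rows of `variants`.
#' @export
annotate_domain_membership <- function(variants, domains) {
  stopifnot(all(c("transcript_id", "aa_change") %in% names(variants)))
  pos <- aa_position(variants$aa_change)
  has_domain <- variants$transcript_id %in% domains$transcript_id
  unparseable <- is.na(pos) & has_domain
  if (any(unparseable)) {
    warn(sprintf("%d variant(s) with domain annotations but unparseable aa_change; flagged not-in-domain",
                 sum(unparseable)))
  }
  vapply(seq_len(nrow(variants)), function(i) {
    if (is.na(pos[i])) return(FALSE)
    dom <- domains[domains$transcript_id == variants$transcript_id[i], , drop = FALSE]
    any(dom$aa_start <= pos[i] & pos[i] <= dom$aa_end)
  }, logical(1))
}

#' SNV-level differential carrier analysis
#'
#' Combines [carrier_counts()], [odds_ratio()] and
#' [fisher_exact_two_sided()] into a per-SNV contrast table, optionally
#' restricted to a gene set (typically the differentially mutated genes) and
#' annotated with protein-domain membership.
#'
#' The odds ratio is oriented class_a over class_b; SNVs carried by no
#' sample in one class report 0 or `Inf` accordingly.
#'
#' @inheritParams carrier_counts
#' @param domains Optional domain interval tibble; when supplied an
#'   `in_domain` flag is computed, otherwise it is `NA`.
#' @param genes Optional character vector restricting the analysis to SNVs
#'   in these genes.
#' @return A tibble of class `snv_contrast`, sorted by Fisher p:
#'   carrier counts per class, `odds_ratio`, `fisher_p`, `in_domain`, plus
#'   identification columns.
#' @export
snv_contrasts <- function(variants, design, dimension, class_a, class_b,
                          domains = NULL, genes = NULL) {
  counts <- carrier_counts(variants, design, dimension, class_a, class_b)
  if (!is.null(genes)) {
    counts <- counts[counts$gene_symbol %in% genes, , drop = FALSE]
  }
  a <- counts$carriers_a
  b <- counts$n_a - counts$carriers_a
  cc <- counts$carriers_b
  d <- counts$n_b - counts$carriers_b
  counts$odds_ratio <- if (nrow(counts) > 0) odds_ratio(a, b, cc, d) else numeric(0)
  counts$fisher_p <- if (nrow(counts) > 0) fisher_exact_two_sided(a, b, cc, d) else numeric(0)
  counts$in_domain <- if (is.null(domains)) {
    NA
  } else if (nrow(counts) > 0) {
    annotate_domain_membership(counts, domains)
  } else {
    logical(0)
  }
  out <- dplyr::arrange(counts, .data$fisher_p, .data$gene_symbol, .data$pos)
  structure(out,
            class = c("snv_contrast", class(tibble::tibble())),
            dimension = dimension, class_a = class_a, class_b = class_b)
}

#' Select differentially occurring SNVs
#'
#' Applies the reporting gates to an SNV contrast table: at least
#' `or_fold`-fold carrier enrichment in either direction (`OR >= or_fold` or
#' `OR <= 1/or_fold`; 0 and `Inf` pass), Fisher `p <= p_max`, and — when
#' `require_domain` — location inside an annotated protein domain.
#'
#' @param contrasts An `snv_contrast` tibble from [snv_contrasts()].
#' @param or_fold Minimum fold enrichment (default 2).
#' @param p_max Fisher p-value cut-off (default 0.05).
#' @param require_domain Keep only SNVs inside domain regions (default
#'   `TRUE`); requires domain annotation to have been computed.
#' @return The retained rows, sorted by Fisher p.
#' @export
select_differential_snvs <- function(contrasts, or_fold = 2, p_max = 0.05,
                                     require_domain = TRUE) {
  stopifnot(or_fold >= 1)
  if (require_domain && anyNA(contrasts$in_domain)) {
    abort("`require_domain = TRUE` but domain membership was not annotated; pass `domains` to snv_contrasts()")
  }
  keep <- (contrasts$odds_ratio >= or_fold | contrasts$odds_ratio <= 1 / or_fold) &
    contrasts$fisher_p <= p_max
  if (require_domain) keep <- keep & contrasts$in_domain
  out <- contrasts[keep, , drop = FALSE]
  dplyr::arrange(out, .data$fisher_p, .data$gene_symbol, .data$pos)
}

#' @describeIn snv_contrasts Plain tibble of the contrast table.
#' @param x An `snv_contrast`.
#' @param ... Ignored.
#' @method tidy snv_contrast
#' @export
tidy.snv_contrast <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn snv_contrasts One-row summary of the SNV contrast.
#' @method glance snv_contrast
#' @export
glance.snv_contrast <- function(x, ...) {
  tibble::tibble(
    dimension = attr(x, "dimension"),
    class_a = attr(x, "class_a"),
    class_b = attr(x, "class_b"),
    n_snvs = nrow(x),
    n_in_domain = sum(x$in_domain %in% TRUE),
    n_fisher_le_0.05 = sum(x$fisher_p <= 0.05)
  )
}

#' Carrier-frequency plot of an SNV contrast
#'
#' @param object An `snv_contrast`.
#' @param max_snvs Number of top SNVs (by Fisher p) to draw.
#' @param ... Ignored.
#' @return A ggplot object comparing per-class carrier frequencies.
#' @method autoplot snv_contrast
#' @export
autoplot.snv_contrast <- function(object, max_snvs = 25, ...) {
  df <- head(tibble::as_tibble(object), max_snvs) |>
    dplyr::mutate(label = paste0(.data$gene_symbol, " ",
                                 mutation_key(.data$chrom, .data$pos,
                                              .data$ref_allele, .data$alt_allele))) |>
    tidyr::pivot_longer(
      cols = c("carriers_a", "carriers_b"),
      names_to = "class", values_to = "carriers"
    ) |>
    dplyr::mutate(
      total = ifelse(.data$class == "carriers_a", .data$n_a, .data$n_b),
      freq = .data$carriers / .data$total,
      class = ifelse(.data$class == "carriers_a",
                     attr(object, "class_a"), attr(object, "class_b"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq,
                                   y = stats::reorder(.data$label, .data$freq),
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "carrier frequency", y = NULL, fill = "class") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Consensus call on protein-stability predictions
#'
#' Majority vote over three categorical stability predictions (e.g. from
#' sequence- and structure-based predictors): when at least two tools agree
#' on `"destabilizing"` or `"stabilizing"`, that label is the consensus;
#' otherwise the call is `"indeterminate"`. `"no_call"` votes never form a
#' consensus.
#'
#' @param p1,p2,p3 Character vectors (vectorised in parallel), each element
#'   one of `"destabilizing"`, `"stabilizing"`, `"no_call"`.
#' @return Character vector of consensus labels.
#' @export
#' @examples
#' stability_consensus("destabilizing", "destabilizing", "stabilizing")
#' stability_consensus("destabilizing", "stabilizing", "no_call")
stability_consensus <- function(p1, p2, p3) {
  valid <- c("destabilizing", "stabilizing", "no_call")
  votes <- cbind(p1, p2, p3)
  if (!all(votes %in% valid)) {
    abort(sprintf("predictions must be one of: %s", paste(valid, collapse = ", ")))
  }
  apply(votes, 1, function(v) {
    for (label in c("destabilizing", "stabilizing")) {
      if (sum(v == label) >= 2) return(label)
    }
    "indeterminate"
  })
}
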