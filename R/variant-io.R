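#' Column dialects for annotated variant tables
#'
#' Annotation pipelines name their columns differently; a dialect maps the
#' canonical field names used throughout dmgscan onto the column headers of a
#' particular file format. `variant_dialect()` is the identity mapping (files
#' already use canonical names); `annovar_dialect()` matches ANNOVAR
#' multianno-style output. Any entry can be overridden.
#'
#' Canonical fields: `sample_id`, `gene_symbol`, `transcript_id`, `chrom`,
#' `pos`, `ref_allele`, `alt_allele`, `sift_score`, `dbsnp_id`, `aa_change`.
#' `sample_id`, `dbsnp_id` and `aa_change` are optional in the file;
#' `sample_id` may instead be supplied per file via `read_variants()`.
#'
#' @param ... Named overrides, canonical name = file column name.
#' @return Named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' annovar_dialect()
#' variant_dialect(sift_score = "SIFT")
variant_dialect <- function(...) {
  base <- c(
    sample_id = "sample_id", gene_symbol = "gene_symbol",
    transcript_id = "transcript_id", chrom = "chrom", pos = "pos",
    ref_allele = "ref_allele", alt_allele = "alt_allele",
    sift_score = "sift_score", dbsnp_id = "dbsnp_id", aa_change = "aa_change"
  )
  override <- c(...)
  if (length(override) > 0) {
    unknown <- setdiff(names(override), names(base))
    if (length(unknown) > 0) {
      abort(sprintf("unknown dialect field(s): %s", paste(unknown, collapse = ", ")))
    }
    base[names(override)] <- override
  }
  base
}

#' @rdname variant_dialect
#' @export
annovar_dialect <- function(...) {
  variant_dialect(
    sample_id = "Sample", gene_symbol = "Gene.refGene",
    transcript_id = "Transcript", chrom = "Chr", pos = "Start",
    ref_allele = "Ref", alt_allele = "Alt", sift_score = "SIFT_score",
    dbsnp_id = "avsnp", aa_change = "AAChange",
    ...
  )
}

#' Read an annotated variant table
#'
#' Parses a TSV of isoform-level SNV annotations into the canonical variant
#' tibble. Each row is one (sample, variant, transcript isoform) annotation
#' carrying a SIFT score. Unparseable SIFT fields (e.g. `"."`) become missing
#' scores, not errors; rows whose alleles are not single nucleotides (indels,
#' MNVs) are dropped with a message; duplicated (sample, variant, transcript)
#' rows are collapsed keeping the minimum SIFT score, with a message.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Column mapping, see [variant_dialect()].
#' @param sample_id Sample identifier to assign to every row, for per-sample
#'   files that carry no sample column. Ignored when the file has one.
#' @return A tibble with columns `sample_id`, `gene_symbol`, `transcript_id`,
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `sift_score`, `dbsnp_id`,
#'   `aa_change`, sorted by sample, position and transcript.
#' @export
read_variants <- function(path, dialect = variant_dialect(), sample_id = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("gene_symbol", "transcript_id", "chrom", "pos",
                "ref_allele", "alt_allele", "sift_score")
  for (field in required) {
    if (!dialect[[field]] %in% names(raw)) {
      abort(sprintf("variant table `%s` lacks the `%s` column (expected header `%s`)",
                    path, field, dialect[[field]]))
    }
  }
  out <- tibble::tibble(
    sample_id = if (dialect[["sample_id"]] %in% names(raw)) {
      raw[[dialect[["sample_id"]]]]
    } else if (!is.null(sample_id)) {
      rep(as.character(sample_id), nrow(raw))
    } else {
      abort(sprintf("no sample column `%s` in `%s` and no `sample_id` given",
                    dialect[["sample_id"]], path))
    },
    gene_symbol = raw[[dialect[["gene_symbol"]]]],
    transcript_id = raw[[dialect[["transcript_id"]]]],
    chrom = raw[[dialect[["chrom"]]]],
    pos_raw = raw[[dialect[["pos"]]]],
    ref_allele = raw[[dialect[["ref_allele"]]]],
    alt_allele = raw[[dialect[["alt_allele"]]]],
    sift_score = suppressWarnings(as.numeric(raw[[dialect[["sift_score"]]]])),
    dbsnp_id = if (dialect[["dbsnp_id"]] %in% names(raw)) raw[[dialect[["dbsnp_id"]]]] else NA_character_,
    aa_change = if (dialect[["aa_change"]] %in% names(raw)) raw[[dialect[["aa_change"]]]] else NA_character_
  )
  pos <- suppressWarnings(as.integer(out$pos_raw))
  bad_pos <- which(is.na(pos) | pos < 1)
  if (length(bad_pos) > 0) {
    abort(sprintf("malformed coordinate in `%s` at data line(s): %s",
                  path, paste(head(bad_pos, 10), collapse = ", ")))
  }
  out$pos <- pos
  out$pos_raw <- NULL

  snv <- nchar(out$ref_allele) == 1 & nchar(out$alt_allele) == 1 &
    out$ref_allele != out$alt_allele
  if (any(!snv)) {
    inform(sprintf("read_variants: dropped %d non-SNV row(s) (indels/MNVs)", sum(!snv)))
    out <- out[snv, , drop = FALSE]
  }
  out <- dedupe_variants(out)
  check_variants(out)
  dplyr::arrange(out[, variant_columns()],
                 .data$sample_id, .data$chrom, .data$pos,
                 .data$alt_allele, .data$transcript_id)
}

# collapse repeated (sample, variant, transcript) annotations, keep min SIFT
dedupe_variants <- function(variants) {
  key <- paste(variants$sample_id, variants$chrom, variants$pos,
               variants$ref_allele, variants$alt_allele,
               variants$transcript_id, variants$gene_symbol, sep = "\r")
  if (!anyDuplicated(key)) {
    return(variants)
  }
  n0 <- nrow(variants)
  out <- variants |>
    dplyr::group_by(.data$sample_id, .data$gene_symbol, .data$transcript_id,
                    .data$chrom, .data$pos, .data$ref_allele, .data$alt_allele) |>
    dplyr::summarise(
      sift_score = if (all(is.na(.data$sift_score))) NA_real_ else min(.data$sift_score, na.rm = TRUE),
      dbsnp_id = dplyr::first(.data$dbsnp_id[!is.na(.data$dbsnp_id)], default = NA_character_),
      aa_change = dplyr::first(.data$aa_change[!is.na(.data$aa_change)], default = NA_character_),
      .groups = "drop"
    )
  inform(sprintf("read_variants: collapsed %d duplicate annotation row(s)", n0 - nrow(out)))
  out
}

#' Read an annotated VCF into the canonical variant tibble
#'
#' Thin adapter for VCFs whose INFO field carries the annotation: the named
#' INFO keys are mapped onto gene symbol, transcript, SIFT score, dbSNP id and
#' amino-acid change. One record per alternate allele; multi-allelic sites
#' must be split beforehand (e.g. `bcftools norm -m-`). Requires the vcfR
#' package.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param sample_id Sample identifier for the records.
#' @param info_keys Named character vector mapping canonical fields
#'   (`gene_symbol`, `transcript_id`, `sift_score`, optionally `dbsnp_id`,
#'   `aa_change`) to INFO keys.
#' @return A variant tibble as from [read_variants()].
#' @export
read_annotated_vcf <- function(path, sample_id,
                               info_keys = c(gene_symbol = "GENE",
                                             transcript_id = "TRANSCRIPT",
                                             sift_score = "SIFT",
                                             dbsnp_id = "DBSNP",
                                             aa_change = "AACHANGE")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_annotated_vcf() requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  grab <- function(field) {
    if (is.na(info_keys[field])) return(rep(NA_character_, nrow(fix)))
    vcfR::extract.info(vcf, element = info_keys[[field]])
  }
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    gene_symbol = grab("gene_symbol"),
    transcript_id = grab("transcript_id"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    sift_score = suppressWarnings(as.numeric(grab("sift_score"))),
    dbsnp_id = {
      ids <- if ("dbsnp_id" %in% names(info_keys)) grab("dbsnp_id") else NA
      fallback <- dplyr::if_else(fix$ID == ".", NA_character_, fix$ID)
      dplyr::coalesce(as.character(ids), fallback)
    },
    aa_change = grab("aa_change")
  )
  snv <- nchar(out$ref_allele) == 1 & nchar(out$alt_allele) == 1 &
    out$ref_allele != out$alt_allele
  if (any(!snv)) {
    inform(sprintf("read_annotated_vcf: dropped %d non-SNV record(s)", sum(!snv)))
    out <- out[snv, , drop = FALSE]
  }
  out <- dedupe_variants(out)
  check_variants(out)
  dplyr::arrange(out[, variant_columns()],
                 .data$sample_id, .data$chrom, .data$pos,
                 .data$alt_allele, .data$transcript_id)
}

#' Read a cohort design table
#'
#' The design maps each sample to its class labels along the comparison
#' dimensions (for the breast-cancer application: ER, PR and HER2 status,
#' grade, stage, population). Any column other than `sample_id` is treated as
#' a dimension; empty cells become missing labels and exclude the sample from
#' comparisons along that dimension.
#'
#' @param path Path to a TSV or CSV file with a `sample_id` column.
#' @return A tibble, one row per sample.
#' @export
read_design <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  design <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                   progress = FALSE)
  design <- dplyr::mutate(design, dplyr::across(
    dplyr::everything(), ~ dplyr::if_else(.x == "", NA_character_, .x)
  ))
  check_design(design, arg = path)
  design
}

#' Read a protein domain interval table
#'
#' Domain intervals are inclusive on both ends, in protein (amino-acid)
#' coordinates, keyed by transcript. Expected columns: `transcript_id`,
#' `domain_db` (e.g. PfamA, PfamB, Panther), `domain_id`, `aa_start`,
#' `aa_end`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of domain intervals.
#' @export
read_domains <- function(path) {
  dom <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    domain_db = readr::col_character(),
    domain_id = readr::col_character(),
    aa_start = readr::col_integer(),
    aa_end = readr::col_integer()
  ), progress = FALSE)
  bad <- dom$aa_start < 1 | dom$aa_end < dom$aa_start
  if (any(bad)) {
    abort(sprintf("`%s` has %d invalid domain interval(s) (need 1 <= aa_start <= aa_end)",
                  path, sum(bad)))
  }
  dom
}

#' Write a result table deterministically
#'
#' Writes any dmgscan result tibble as TSV with a header. Output is
#' byte-reproducible: columns keep their order, rows are sorted by the
#' table's natural key (p-value ascending for gene results, Fisher p for SNV
#' contrasts, sample/position for variant tables; otherwise all columns left
#' to right), and floating-point columns are formatted at 6 significant
#' digits.
#'
#' @param records A tibble (may be empty; a header-only file is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- tibble::as_tibble(records)
  sort_keys <- intersect(
    c("p_value", "fisher_p", "sample_id", "chrom", "pos", "alt_allele",
      "transcript_id", "gene_symbol"),
    names(out)
  )
  if (length(sort_keys) == 0) sort_keys <- names(out)
  if (nrow(out) > 0) {
    out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(sort_keys)))
  }
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.double), ~ num_fmt(.x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
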