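#' Compose a mutation key from genomic coordinates and alleles
#'
#' A mutation key identifies a single-nucleotide substitution independently of
#' the transcript isoform it is annotated on: all isoform-level annotation rows
#' sharing the key describe one genomic event. Each alternate allele at a
#' multi-allelic site gets its own key.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based genomic position.
#' @param ref_allele,alt_allele Single-nucleotide reference and alternate
#'   alleles.
#' @return Character vector, e.g. `"chr17_37884037_C_G"`.
#' @export
#' @examples
#' mutation_key("chr17", 37884037, "C", "G")
mutation_key <- function(chrom, pos, ref_allele, alt_allele) {
  paste(chrom, pos, ref_allele, alt_allele, sep = "_")
}

#' Extract the protein position from an amino-acid change string
#'
#' Parses HGVS-style protein annotations such as `"p.P1140A"` or `"p.R448H"`
#' and returns the substituted residue's position.
#'
#' @param aa_change Character vector of amino-acid change strings.
#' @return Integer vector; `NA` where no position can be parsed.
#' @export
#' @examples
#' aa_position(c("p.P1140A", "p.E690K", "frameshift", NA))
aa_position <- function(aa_change) {
  suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", aa_change)))
}

# canonical column set for a variant tibble
variant_columns <- function() {
  c("sample_id", "gene_symbol", "transcript_id", "chrom", "pos",
    "ref_allele", "alt_allele", "sift_score", "dbsnp_id", "aa_change")
}

check_variants <- function(variants, arg = "variants") {
  required <- c("sample_id", "gene_symbol", "transcript_id", "chrom", "pos",
                "ref_allele", "alt_allele", "sift_score")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0) {
    abort(sprintf("`%s` lacks required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  bad <- !is.na(variants$sift_score) &
    (variants$sift_score < 0 | variants$sift_score > 1)
  if (any(bad)) {
    abort(sprintf("`%s` has %d SIFT score(s) outside [0, 1]", arg, sum(bad)))
  }
  invisible(variants)
}

check_design <- function(design, arg = "design") {
  if (!"sample_id" %in% names(design)) {
    abort(sprintf("`%s` must have a `sample_id` column", arg))
  }
  dup <- unique(design$sample_id[duplicated(design$sample_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample_id(s) in `%s`: %s",
                  arg, paste(dup, collapse = ", ")))
  }
  invisible(design)
}

# Split a design into the two compared classes along one dimension.
# Samples with other or missing labels are excluded from the comparison.
design_classes <- function(design, dimension, class_a, class_b) {
  check_design(design)
  if (!dimension %in% names(design)) {
    abort(sprintf("unknown comparison dimension `%s` (design has: %s)",
                  dimension, paste(setdiff(names(design), "sample_id"),
                                   collapse = ", ")))
  }
  lab <- design[[dimension]]
  list(
    a = design$sample_id[!is.na(lab) & lab == class_a],
    b = design$sample_id[!is.na(lab) & lab == class_b]
  )
}

num_fmt <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_,
         ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                formatC(x, digits = digits, format = "g")))
}
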