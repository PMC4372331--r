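# fixture builders and independent reference implementations (deliberately
# plain base R, no reuse of package internals)

variant_row <- function(sample = "S1", gene = "G1", tx = "T1", chrom = "chr1",
                        pos = 100L, ref = "A", alt = "C", sift = 0.01,
                        dbsnp = NA_character_, aa = NA_character_) {
  tibble::tibble(
    sample_id = sample, gene_symbol = gene, transcript_id = tx,
    chrom = chrom, pos = as.integer(pos), ref_allele = ref, alt_allele = alt,
    sift_score = sift, dbsnp_id = dbsnp, aa_change = aa
  )
}

variants_tbl <- function(...) dplyr::bind_rows(...)

two_class_design <- function(n_a, n_b, dimension = "class") {
  d <- tibble::tibble(
    sample_id = c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b))),
    population = "POP"
  )
  d[[dimension]] <- rep(c("A", "B"), c(n_a, n_b))
  d
}

# brute-force deleterious score for one (gene, sample): loop over mutation
# groups, mean of (1 - SIFT) within each
ref_gene_sample_score <- function(df) {
  key <- paste(df$chrom, df$pos, df$ref_allele, df$alt_allele)
  total <- 0
  for (k in unique(key)) {
    s <- df$sift_score[key == k]
    total <- total + sum(1 - s) / length(s)
  }
  total
}

# textbook pooled-variance two-sample t-test p-value
ref_pooled_t_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), n1 + n2 - 2)
}

# hand step-up Benjamini-Hochberg
ref_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# random small variant cohort for property tests
random_variants <- function(seed, n_samples = 4, n_genes = 3, n_rows = 40) {
  withr::with_seed(seed, {
    tibble::tibble(
      sample_id = sample(sprintf("S%d", seq_len(n_samples)), n_rows, replace = TRUE),
      gene_symbol = sample(sprintf("G%d", seq_len(n_genes)), n_rows, replace = TRUE),
      transcript_id = sample(c("T1", "T2", "T3"), n_rows, replace = TRUE),
      chrom = "chr1",
      pos = sample(1:12, n_rows, replace = TRUE) * 10L,
      ref_allele = "A", alt_allele = "G",
      sift_score = round(runif(n_rows, 0, 0.05), 4),
      dbsnp_id = NA_character_, aa_change = NA_character_
    ) |>
      dplyr::distinct(sample_id, gene_symbol, transcript_id,
                      chrom, pos, ref_allele, alt_allele,
                      .keep_all = TRUE)
  })
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "dmgscan")
  if (path == "") path <- file.path("..", "..", "inst", "extdata", file)
  path
}

# expand a (class, population, n) count table into a per-sample design
counts_to_design <- function(counts, dimension) {
  counts <- counts[counts$dimension == dimension & counts$n > 0, , drop = FALSE]
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(class = counts$class[i], population = counts$population[i],
               idx = seq_len(counts$n[i]))
  }))
  d <- tibble::tibble(
    sample_id = sprintf("SYN%04d", seq_len(nrow(rows))),
    population = rows$population
  )
  d[[dimension]] <- rows$class
  d
}
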