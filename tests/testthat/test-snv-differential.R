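test_that("odds ratios follow the cross-product with zero-cell conventions", {
  expect_equal(round(odds_ratio(23, 4, 13, 27), 2), 11.94)
  expect_equal(odds_ratio(10, 20, 1, 36), 18)
  expect_equal(odds_ratio(1, 1, 1, 1), 1)
  expect_equal(odds_ratio(8, 22, 0, 37), Inf)
  expect_equal(odds_ratio(0, 25, 4, 9), 0)
  expect_error(odds_ratio(0, 5, 0, 5), "undefined")
  expect_error(odds_ratio(-1, 2, 3, 4), "non-negative")
  # Haldane correction stays finite on zero cells
  expect_true(is.finite(odds_ratio(8, 22, 0, 37, haldane = TRUE)))
})

test_that("finite nonzero odds ratios invert when the table rows swap", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      cells <- rbinom(4, 15, 0.5) + 1  # all positive, so both ORs finite
      or1 <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
      or2 <- odds_ratio(cells[3], cells[4], cells[1], cells[2])
      expect_equal(or1 * or2, 1)
    }
  })
})

test_that("the two-sided Fisher p matches published examples and degenerate margins", {
  expect_equal(fisher_exact_two_sided(23, 4, 13, 27), 2.11e-5, tolerance = 5e-3)
  expect_equal(fisher_exact_two_sided(35, 14, 5, 13), 0.001892, tolerance = 5e-4)
  expect_equal(fisher_exact_two_sided(0, 10, 0, 12), 1)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("the Fisher p is invariant under simultaneous row and column swap", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      cells <- rbinom(4, 12, 0.4)
      if (sum(cells) == 0) next
      expect_equal(
        fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4]),
        fisher_exact_two_sided(cells[4], cells[3], cells[2], cells[1])
      )
    }
  })
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  withr::with_seed(55, {
    for (rep in 1:50) {
      cells <- rbinom(4, 20, runif(1, 0.1, 0.9))
      if (sum(cells) == 0) next
      expect_equal(
        fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4]),
        fisher.test(matrix(cells, 2))$p.value,
        tolerance = 1e-12
      )
    }
  })
})

snv_fixture <- function() {
  # SNV1 in G1: 3 carriers in A (one annotated on 2 isoforms), 1 in B
  # SNV2 in G2: only class B
  v <- variants_tbl(
    variant_row(sample = "A01", gene = "G1", tx = "T1", pos = 100, aa = "p.K287R"),
    variant_row(sample = "A01", gene = "G1", tx = "T2", pos = 100, aa = "p.K287R"),
    variant_row(sample = "A02", gene = "G1", tx = "T1", pos = 100, aa = "p.K287R"),
    variant_row(sample = "A03", gene = "G1", tx = "T1", pos = 100, aa = "p.K287R"),
    variant_row(sample = "B01", gene = "G1", tx = "T1", pos = 100, aa = "p.K287R"),
    variant_row(sample = "B02", gene = "G2", tx = "T9", pos = 500, aa = "p.L10F"),
    variant_row(sample = "B03", gene = "G2", tx = "T9", pos = 500, aa = "p.L10F")
  )
  list(v = v, design = two_class_design(4, 4))
}

test_that("carrier counts are per-sample (isoforms counted once) and per-class", {
  fx <- snv_fixture()
  cc <- carrier_counts(fx$v, fx$design, "class", "A", "B")
  snv1 <- cc[cc$gene_symbol == "G1", ]
  expect_equal(snv1$carriers_a, 3)  # A01 carries on 2 isoforms, counted once
  expect_equal(snv1$carriers_b, 1)
  snv2 <- cc[cc$gene_symbol == "G2", ]
  expect_equal(snv2$carriers_a, 0)
  expect_equal(snv2$carriers_b, 2)
  expect_equal(unique(cc$n_a), 4)
  expect_equal(unique(cc$n_b), 4)
})

test_that("carrier counts equal a brute-force scan over (sample, key) pairs", {
  v <- random_variants(23, n_samples = 6, n_genes = 4, n_rows = 60)
  design <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                           class = rep(c("A", "B"), each = 3))
  cc <- carrier_counts(v, design, "class", "A", "B")
  for (i in seq_len(nrow(cc))) {
    hits <- v[v$gene_symbol == cc$gene_symbol[i] & v$chrom == cc$chrom[i] &
                v$pos == cc$pos[i] & v$ref_allele == cc$ref_allele[i] &
                v$alt_allele == cc$alt_allele[i], ]
    carriers <- unique(hits$sample_id)
    expect_equal(cc$carriers_a[i],
                 length(intersect(carriers, design$sample_id[design$class == "A"])))
    expect_equal(cc$carriers_b[i],
                 length(intersect(carriers, design$sample_id[design$class == "B"])))
  }
})

test_that("domain membership is inclusive on both interval ends", {
  domains <- tibble::tibble(transcript_id = "T1", domain_db = "PfamA",
                            domain_id = "PF1", aa_start = 200L, aa_end = 400L)
  probe <- function(aa) {
    annotate_domain_membership(
      tibble::tibble(transcript_id = "T1", aa_change = aa), domains
    )
  }
  expect_true(probe("p.S287L"))
  expect_false(probe("p.A199V"))
  expect_true(probe("p.Q400*"))
  expect_true(probe("p.G200D"))
  expect_false(probe("p.V401I"))
  expect_warning(res <- probe("nonsense"), "unparseable")
  expect_false(res)
  # transcript without domain annotation is not in-domain, no warning
  expect_false(annotate_domain_membership(
    tibble::tibble(transcript_id = "T2", aa_change = "p.S287L"), domains
  ))
})

test_that("the selection gates apply fold, significance and domain filters", {
  contrasts <- structure(tibble::tibble(
    gene_symbol = c("W", "X", "Y", "Z"),
    chrom = "chr1", pos = 1:4, ref_allele = "A", alt_allele = "G",
    n_a = 30, n_b = 30, carriers_a = c(10, 10, 10, 10), carriers_b = 5,
    dbsnp_id = NA_character_, aa_change = NA_character_,
    transcript_id = "T1",
    odds_ratio = c(1.5, Inf, 5.5, 3.0),
    fisher_p = c(0.01, 0.04, 8.63e-3, 0.2),
    in_domain = c(TRUE, TRUE, TRUE, TRUE)
  ), class = c("snv_contrast", class(tibble::tibble())))
  kept <- select_differential_snvs(contrasts)
  expect_setequal(kept$gene_symbol, c("X", "Y"))   # W fails fold, Z fails p
  expect_equal(kept$gene_symbol, c("Y", "X"))      # sorted by fisher_p
  # reciprocal depletion passes the fold gate
  contrasts$odds_ratio[1] <- 0.4
  expect_true("W" %in% select_differential_snvs(contrasts)$gene_symbol)
  # domain gate
  contrasts$in_domain[2] <- FALSE
  expect_false("X" %in% select_differential_snvs(contrasts)$gene_symbol)
  expect_true("X" %in%
    select_differential_snvs(contrasts, require_domain = FALSE)$gene_symbol)
})

test_that("snv_contrasts wires counts, tests and domain flags together", {
  fx <- snv_fixture()
  domains <- tibble::tibble(transcript_id = "T1", domain_db = "PfamA",
                            domain_id = "PF1", aa_start = 200L, aa_end = 400L)
  sc <- snv_contrasts(fx$v, fx$design, "class", "A", "B", domains = domains)
  expect_s3_class(sc, "snv_contrast")
  g1 <- sc[sc$gene_symbol == "G1", ]
  expect_equal(g1$odds_ratio, odds_ratio(3, 1, 1, 3))
  expect_equal(g1$fisher_p, fisher_exact_two_sided(3, 1, 1, 3))
  expect_true(g1$in_domain)     # p.K287R inside [200, 400] on T1
  g2 <- sc[sc$gene_symbol == "G2", ]
  expect_equal(g2$odds_ratio, 0)
  expect_false(g2$in_domain)    # T9 has no domain annotation
  # gene restriction drops G2
  expect_equal(
    snv_contrasts(fx$v, fx$design, "class", "A", "B", genes = "G1")$gene_symbol,
    "G1"
  )
  expect_error(select_differential_snvs(
    snv_contrasts(fx$v, fx$design, "class", "A", "B")
  ), "domain membership")
  glanced <- glance(sc)
  expect_equal(glanced$n_snvs, 2)
})

test_that("the stability consensus requires two agreeing informative votes", {
  expect_equal(stability_consensus("destabilizing", "destabilizing", "stabilizing"),
               "destabilizing")
  expect_equal(stability_consensus("destabilizing", "stabilizing", "no_call"),
               "indeterminate")
  expect_equal(stability_consensus("destabilizing", "destabilizing", "destabilizing"),
               "destabilizing")
  expect_equal(stability_consensus("stabilizing", "no_call", "stabilizing"),
               "stabilizing")
  expect_equal(stability_consensus("no_call", "no_call", "no_call"),
               "indeterminate")
  expect_equal(
    stability_consensus(c("destabilizing", "no_call"),
                        c("destabilizing", "stabilizing"),
                        c("no_call", "stabilizing")),
    c("destabilizing", "stabilizing")
  )
  expect_error(stability_consensus("bad", "no_call", "no_call"), "must be one of")
})
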