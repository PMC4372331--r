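#' Configuration for a synthetic annotated SNV cohort
#'
#' Defines a two-class cohort of sparse per-sample mutation profiles with
#' known ground truth, emulating the structure of SIFT-annotated tumour
#' exome data: each gene carries a catalogue of candidate SNV sites, each
#' site is annotated on one or more transcript isoforms with a fixed
#' per-isoform SIFT score (deleterious sites in \[0, 0.05\], tolerated sites
#' in (0.05, 1\]), and samples carry sites sparsely at random.
#'
#' Defaults describe a sparse exome cohort: 0.2 expected deleterious
#' mutations per gene per sample spread over half of 8 candidate sites, and
#' isoform counts uniform on 1..5.
#'
#' @param n_samples_a,n_samples_b Samples per class (classes `"A"`, `"B"`).
#' @param n_genes Number of background genes.
#' @param background_rate Expected deleterious mutations per gene per sample.
#' @param nondeleterious_rate Expected tolerated (SIFT > 0.05) annotations
#'   per gene per sample, included so the deleterious filter has work to do.
#' @param sites_per_gene Candidate SNV sites per gene.
#' @param deleterious_fraction Fraction of candidate sites that are
#'   deleterious.
#' @param isoform_counts Integer vector the per-gene isoform count is drawn
#'   from uniformly.
#' @param planted_genes Optional tibble/data.frame with columns `gene`
#'   (name for the planted gene), `class` (`"A"` or `"B"`), `burden_delta`
#'   (added mean deleterious score in that class, in \[0, 1\]: implemented as
#'   a Bernoulli carrier of an extra near-zero-SIFT site).
#' @param planted_snvs Optional tibble with columns `name`,
#'   `carrier_prob_a`, `carrier_prob_b`, `in_domain` (logical): each planted
#'   SNV lives in its own gene with class-specific carrier probabilities.
#' @param seed Mandatory integer seed; identical config and seed give an
#'   identical cohort.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples_a = 30, n_samples_b = 30,
                              n_genes = 200, background_rate = 0.2,
                              nondeleterious_rate = 0.4, sites_per_gene = 8,
                              deleterious_fraction = 0.5,
                              isoform_counts = 1:5,
                              planted_genes = NULL, planted_snvs = NULL,
                              seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("`seed` is mandatory for a simulation_config")
  }
  stopifnot(n_samples_a >= 1, n_samples_b >= 1, n_genes >= 1,
            background_rate >= 0, nondeleterious_rate >= 0,
            sites_per_gene >= 1, deleterious_fraction > 0,
            deleterious_fraction <= 1, all(isoform_counts >= 1))
  if (!is.null(planted_genes)) {
    planted_genes <- tibble::as_tibble(planted_genes)
    stopifnot(all(c("gene", "class", "burden_delta") %in% names(planted_genes)),
              all(planted_genes$class %in% c("A", "B")))
    if (any(planted_genes$burden_delta < 0 | planted_genes$burden_delta > 1)) {
      abort("`burden_delta` must lie in [0, 1] (a carrier probability)")
    }
  }
  if (!is.null(planted_snvs)) {
    planted_snvs <- tibble::as_tibble(planted_snvs)
    stopifnot(all(c("name", "carrier_prob_a", "carrier_prob_b", "in_domain") %in%
                    names(planted_snvs)))
    probs <- c(planted_snvs$carrier_prob_a, planted_snvs$carrier_prob_b)
    if (any(probs < 0 | probs > 1)) {
      abort("planted SNV carrier probabilities must lie in [0, 1]")
    }
  }
  structure(list(
    n_samples_a = as.integer(n_samples_a), n_samples_b = as.integer(n_samples_b),
    n_genes = as.integer(n_genes), background_rate = background_rate,
    nondeleterious_rate = nondeleterious_rate,
    sites_per_gene = as.integer(sites_per_gene),
    deleterious_fraction = deleterious_fraction,
    isoform_counts = as.integer(isoform_counts),
    planted_genes = planted_genes, planted_snvs = planted_snvs,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate an annotated two-class SNV cohort with known ground truth
#'
#' Generates per-isoform SIFT-annotated variant records, a two-class design
#' (dimension `class`, labels `"A"`/`"B"`, constant `population`), planted
#' protein-domain intervals, and a ground-truth record naming the planted
#' differentially mutated genes and differential SNVs. All randomness flows
#' through the config's seed; the same config yields byte-identical output.
#'
#' Background carriage: each deleterious site is carried independently with
#' probability `background_rate / n_deleterious_sites`, so a gene
#' accumulates on average `background_rate` deleterious mutations per
#' sample, identically in both classes. Planted genes add one extra
#' near-zero-SIFT site carried with probability `burden_delta` in the target
#' class only; planted SNVs live in dedicated genes with class-specific
#' carrier probabilities.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `variants` (tibble, canonical variant
#'   columns), `design`, `domains`, `truth` (list: `planted_genes`,
#'   `planted_snvs` with mutation keys, `null_genes`, `dimension`,
#'   `class_a`, `class_b`, `alpha` slot left to the analyst), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  samples_a <- sprintf("SIM_A%03d", seq_len(cfg$n_samples_a))
  samples_b <- sprintf("SIM_B%03d", seq_len(cfg$n_samples_b))
  samples <- c(samples_a, samples_b)
  design <- tibble::tibble(
    sample_id = samples,
    class = rep(c("A", "B"), c(cfg$n_samples_a, cfg$n_samples_b)),
    population = "SIM"
  )

  genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))
  n_del <- max(1L, round(cfg$sites_per_gene * cfg$deleterious_fraction))
  n_tol <- cfg$sites_per_gene - n_del

  # site catalogue: fixed per-variant properties shared by all carriers
  catalogue <- build_site_catalogue(cfg, genes, n_del, n_tol)

  # planted gene burden: one extra site per planted gene, class-specific
  planted_gene_sites <- NULL
  if (!is.null(cfg$planted_genes)) {
    pg <- cfg$planted_genes
    planted_gene_sites <- make_sites(
      gene = pg$gene, site_idx = 1L, chrom = "chrP",
      base_pos = 10000000L + seq_len(nrow(pg)) * 1000L,
      sift_base = 0.001, deleterious = TRUE,
      prob_a = ifelse(pg$class == "A", pg$burden_delta, 0),
      prob_b = ifelse(pg$class == "B", pg$burden_delta, 0),
      isoform_counts = cfg$isoform_counts
    )
  }
  planted_snv_sites <- NULL
  if (!is.null(cfg$planted_snvs)) {
    ps <- cfg$planted_snvs
    planted_snv_sites <- make_sites(
      gene = paste0("SNVGENE_", ps$name), site_idx = 1L, chrom = "chrQ",
      base_pos = 20000000L + seq_len(nrow(ps)) * 1000L,
      sift_base = 0.001, deleterious = TRUE,
      prob_a = ps$carrier_prob_a, prob_b = ps$carrier_prob_b,
      isoform_counts = cfg$isoform_counts
    )
  }
  extra_sites <- dplyr::bind_rows(planted_gene_sites$sites, planted_snv_sites$sites)
  extra_iso <- dplyr::bind_rows(planted_gene_sites$isoforms, planted_snv_sites$isoforms)

  all_sites <- dplyr::bind_rows(catalogue$sites, extra_sites)
  all_iso <- dplyr::bind_rows(catalogue$isoforms, extra_iso)

  carried <- draw_carriage(all_sites, samples,
                           setNames(design$class, design$sample_id))

  variants <- carried |>
    dplyr::inner_join(all_iso, by = "site_uid",
                      relationship = "many-to-many") |>
    dplyr::inner_join(all_sites[, c("site_uid", "gene", "chrom", "pos", "ref_allele",
                                    "alt_allele", "dbsnp_id", "aa_change")],
                      by = "site_uid") |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      gene_symbol = .data$gene,
      transcript_id = .data$transcript_id,
      chrom = .data$chrom, pos = .data$pos,
      ref_allele = .data$ref_allele, alt_allele = .data$alt_allele,
      sift_score = .data$sift_score,
      dbsnp_id = .data$dbsnp_id, aa_change = .data$aa_change
    ) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos,
                   .data$alt_allele, .data$transcript_id)

  # domains: cover every planted in-domain SNV; background transcripts get
  # one interval each over the first half of a nominal 500-aa protein
  domains <- all_iso |>
    dplyr::distinct(.data$transcript_id) |>
    dplyr::mutate(domain_db = "PfamA",
                  domain_id = sprintf("PFSIM%04d", dplyr::row_number()),
                  aa_start = 1L, aa_end = 250L)
  if (!is.null(cfg$planted_snvs)) {
    out_genes <- paste0("SNVGENE_", cfg$planted_snvs$name[!cfg$planted_snvs$in_domain])
    out_tx <- all_sites$site_uid[all_sites$gene %in% out_genes]
    out_transcripts <- all_iso$transcript_id[all_iso$site_uid %in% out_tx]
    domains <- domains[!domains$transcript_id %in% out_transcripts, , drop = FALSE]
  }

  truth <- list(
    dimension = "class", class_a = "A", class_b = "B",
    planted_genes = if (is.null(cfg$planted_genes)) {
      tibble::tibble(gene = character(), class = character(),
                     burden_delta = numeric())
    } else cfg$planted_genes,
    planted_snvs = if (is.null(cfg$planted_snvs)) {
      tibble::tibble(name = character(), gene = character(), key = character(),
                     carrier_prob_a = numeric(), carrier_prob_b = numeric(),
                     in_domain = logical())
    } else {
      dplyr::mutate(cfg$planted_snvs,
                    gene = paste0("SNVGENE_", .data$name),
                    key = mutation_key(planted_snv_sites$sites$chrom,
                                       planted_snv_sites$sites$pos,
                                       planted_snv_sites$sites$ref_allele,
                                       planted_snv_sites$sites$alt_allele))
    },
    null_genes = genes
  )
  list(variants = variants, design = design, domains = domains,
       truth = truth, config = cfg)
}

# background site catalogue for the null genes
build_site_catalogue <- function(cfg, genes, n_del, n_tol) {
  per_gene <- n_del + n_tol
  gene_rep <- rep(genes, each = per_gene)
  site_idx <- rep(seq_len(per_gene), times = length(genes))
  deleterious <- site_idx <= n_del
  prob_del <- cfg$background_rate / n_del
  prob_tol <- if (n_tol > 0) cfg$nondeleterious_rate / n_tol else 0
  if (prob_del > 1 || prob_tol > 1) {
    abort("per-site carrier probability exceeds 1; raise sites_per_gene or lower the rates")
  }
  make_sites(
    gene = gene_rep, site_idx = site_idx,
    chrom = paste0("chr", (match(gene_rep, genes) - 1) %% 22 + 1),
    base_pos = (match(gene_rep, genes)) * 100000L + site_idx * 100L,
    sift_base = NA, deleterious = deleterious,
    prob_a = ifelse(deleterious, prob_del, prob_tol),
    prob_b = ifelse(deleterious, prob_del, prob_tol),
    isoform_counts = cfg$isoform_counts
  )
}

# build site + per-isoform annotation tables; sift_base = NA draws SIFT from
# the deleterious/tolerated partition, a number fixes it (planted sites)
make_sites <- function(gene, site_idx, chrom, base_pos, sift_base,
                       deleterious, prob_a, prob_b, isoform_counts) {
  n <- length(gene)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  aa_pos <- (site_idx * 37L) %% 200L + 1L  # within the nominal 500-aa protein
  aa_from <- sample(LETTERS[1:20], n, replace = TRUE)
  aa_to <- sample(LETTERS[1:20], n, replace = TRUE)
  sites <- tibble::tibble(
    site_uid = paste0(gene, "_s", site_idx),
    gene = gene, chrom = chrom, pos = as.integer(base_pos),
    ref_allele = ref, alt_allele = unname(alt),
    deleterious = deleterious, prob_a = prob_a, prob_b = prob_b,
    dbsnp_id = paste0("rsSIM", seq_along(gene) + abs(as.integer(base_pos[1]))),
    aa_change = paste0("p.", aa_from, aa_pos, aa_to)
  )
  n_iso_gene <- tibble::tibble(gene = unique(gene)) |>
    dplyr::mutate(n_iso = sample(isoform_counts, dplyr::n(), replace = TRUE))
  isoforms <- sites |>
    dplyr::left_join(n_iso_gene, by = "gene") |>
    dplyr::select("site_uid", "gene", "deleterious", "n_iso") |>
    tidyr::uncount(.data$n_iso, .id = "iso") |>
    dplyr::mutate(
      transcript_id = sprintf("TX_%s_%02d", .data$gene, .data$iso),
      sift_score = if (is.na(sift_base)) {
        ifelse(.data$deleterious,
               round(runif(dplyr::n(), 0, 0.05), 4),
               round(runif(dplyr::n(), 0.0501, 1), 4))
      } else {
        rep(sift_base, dplyr::n())
      }
    ) |>
    dplyr::select("site_uid", "transcript_id", "sift_score")
  list(sites = sites, isoforms = isoforms)
}

# Bernoulli carriage of each site by each sample, class-specific probability
draw_carriage <- function(sites, samples, class_of) {
  if (nrow(sites) == 0 || length(samples) == 0) {
    return(tibble::tibble(sample_id = character(), site_uid = character()))
  }
  n_sites <- nrow(sites)
  n_samp <- length(samples)
  prob <- matrix(0, nrow = n_sites, ncol = n_samp)
  is_a <- if (length(class_of) > 0) class_of[samples] == "A" else rep(TRUE, n_samp)
  prob[, is_a] <- sites$prob_a
  prob[, !is_a] <- sites$prob_b
  hit <- matrix(runif(n_sites * n_samp), nrow = n_sites) < prob
  idx <- which(hit, arr.ind = TRUE)
  tibble::tibble(
    sample_id = samples[idx[, "col"]],
    site_uid = sites$site_uid[idx[, "row"]]
  )
}

#' Recovery metrics against simulated ground truth
#'
#' Scores reported gene and SNV results against the planted truth of a
#' simulated cohort: power (fraction of planted genes reported), realized
#' per-gene type-I error (fraction of tested null genes reported), realized
#' FDR among reported genes, and the fraction of planted SNVs retained.
#'
#' @param truth The `truth` element of [simulate_cohort()]'s result.
#' @param dmg A `dmg_result` from [compare_classes()] on the simulated
#'   cohort (optional).
#' @param snv A selected SNV table from [select_differential_snvs()]
#'   (optional).
#' @return A one-row tibble of confusion counts and rates (NA where the
#'   corresponding input was not given).
#' @export
truth_eval <- function(truth, dmg = NULL, snv = NULL) {
  out <- tibble::tibble(
    n_planted_genes = nrow(truth$planted_genes),
    n_null_genes = length(truth$null_genes),
    power = NA_real_, type1 = NA_real_, fdr_realized = NA_real_,
    n_null_tested = NA_integer_,
    snv_planted = nrow(truth$planted_snvs), snv_retained = NA_integer_,
    snv_recall = NA_real_
  )
  if (!is.null(dmg)) {
    tested <- tidy(dmg)$gene_symbol
    universe <- c(truth$planted_genes$gene, truth$null_genes,
                  truth$planted_snvs$gene)
    alien <- setdiff(tested, universe)
    if (length(alien) > 0) {
      abort(sprintf("reported gene(s) outside the simulated universe: %s",
                    paste(head(alien, 5), collapse = ", ")))
    }
    reported <- dmg$gene_symbol
    null_tested <- intersect(tested, truth$null_genes)
    tp <- intersect(reported, truth$planted_genes$gene)
    fp <- intersect(reported, truth$null_genes)
    out$power <- if (nrow(truth$planted_genes) > 0) {
      length(tp) / nrow(truth$planted_genes)
    } else NA_real_
    out$n_null_tested <- length(null_tested)
    out$type1 <- if (length(null_tested) > 0) length(fp) / length(null_tested) else NA_real_
    out$fdr_realized <- if (length(reported) > 0) length(fp) / length(reported) else 0
  }
  if (!is.null(snv)) {
    keys <- mutation_key(snv$chrom, snv$pos, snv$ref_allele, snv$alt_allele)
    out$snv_retained <- sum(truth$planted_snvs$key %in% keys)
    out$snv_recall <- if (nrow(truth$planted_snvs) > 0) {
      out$snv_retained / nrow(truth$planted_snvs)
    } else NA_real_
  }
  out
}
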