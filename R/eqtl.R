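# eQTL engine: per-pair-per-tissue association testing, joint BH FDR control
# and cis/trans classification.

# Closed-form simple regression of expression on additive dosage with an
# intercept; two-sided t test on the slope with n - 2 df. Equivalent to
# lm(y ~ x) (cross-checked in the test suite) but cheap enough for the
# calibration suites, which run ~1e5 fits.
ols_slope_test <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx * dx)
  beta <- sum(dx * (y - my)) / sxx
  res <- y - my - beta * dx
  n <- length(x)
  rss <- sum(res * res)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  c(beta = beta, se = se, statistic = tstat,
    p_value = max(p, .Machine$double.xmin), n = n)
}

#' Test one SNP-gene association with an additive linear model
#'
#' Ordinary least squares of expression on dosage (0/1/2) with an intercept;
#' the nominal p-value is a two-sided t test on the slope with n - 2 degrees
#' of freedom. Pairs with missing dosage or expression are dropped pairwise.
#' SNPs monomorphic after filtering, or with fewer than `min_samples`
#' complete pairs, are skipped with a reason code instead of returning a
#' spurious estimate.
#'
#' @param dosage Numeric vector of alternate-allele dosages (0/1/2, `NA`
#'   allowed).
#' @param expression Numeric expression vector, same length.
#' @param min_samples Minimum complete pairs to attempt the fit (default 70).
#'
#' @return One-row tibble `beta, se, statistic, p_value, n, status, reason`;
#'   `status` is `"ok"` or `"skipped"`.
#' @export
#' @examples
#' test_association(rep(0:2, 10), rep(0:2, 10) * 2, min_samples = 10)
test_association <- function(dosage, expression, min_samples = 70) {
  stopifnot(length(dosage) == length(expression))
  ok <- !is.na(dosage) & !is.na(expression)
  x <- as.numeric(dosage[ok]); y <- as.numeric(expression[ok])
  skip <- function(reason) {
    tibble(beta = NA_real_, se = NA_real_, statistic = NA_real_,
           p_value = NA_real_, n = length(x), status = "skipped",
           reason = reason)
  }
  if (length(x) < min_samples) return(skip("insufficient_samples"))
  if (var(x) == 0) return(skip("monomorphic"))
  fit <- ols_slope_test(x, y)
  tibble(beta = fit[["beta"]], se = fit[["se"]],
         statistic = fit[["statistic"]], p_value = fit[["p_value"]],
         n = as.integer(fit[["n"]]), status = "ok", reason = NA_character_)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{j : p_j >= p_i} (m * p_j / rank_j)`, capped at 1, where `m` is
#' the size of the test family (at least `length(p)`; tests beyond the
#' supplied vector are treated as p = 1). Thin wrapper over
#' `stats::p.adjust(method = "BH")` so every module shares one routine.
#'
#' @param p Vector of nominal p-values in (0, 1].
#' @param m Family size (default `length(p)`).
#' @return Vector of q-values, same order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p, m = length(p)) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  if (m < length(p)) abort("`m` cannot be smaller than length(p)")
  p.adjust(p, method = "BH", n = m)
}

#' Classify SNP-gene pairs as cis or trans
#'
#' A pair is cis when SNP and gene lie on the same chromosome with
#' `|TSS - SNP| < cis_distance` (default 1 Mb); everything else — a distance
#' of exactly `cis_distance` or more, or different chromosomes — is trans.
#' The signed distance is `TSS - SNP position` (positive when the TSS lies
#' downstream of the SNP in reference orientation) and is `NA` with
#' `interchromosomal = TRUE` for cross-chromosome pairs.
#'
#' @param snp_chrom,snp_pos SNP chromosome and 0-based position (vectors).
#' @param gene_chrom,tss Gene chromosome and TSS (vectors, recycled).
#' @param cis_distance Cis window in bp (default 1e6; cis is strictly less).
#'
#' @return Tibble `category` (`"cis"`/`"trans"`), `distance_bp`,
#'   `interchromosomal`.
#' @export
#' @examples
#' classify_cis_trans("chr6", 32e6, "chr6", 32.5e6)
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, tss,
                               cis_distance = 1e6) {
  n <- max(length(snp_chrom), length(snp_pos), length(gene_chrom),
           length(tss))
  snp_chrom <- rep_len(snp_chrom, n); snp_pos <- rep_len(snp_pos, n)
  gene_chrom <- rep_len(gene_chrom, n); tss <- rep_len(tss, n)
  same <- snp_chrom == gene_chrom
  dist <- ifelse(same, tss - snp_pos, NA_real_)
  tibble(
    category = ifelse(same & abs(dist) < cis_distance, "cis", "trans"),
    distance_bp = dist,
    interchromosomal = !same
  )
}

#' Run the eQTL stage over spatial pairs and expression panels
#'
#' Executes one association test per (spatial pair x tissue) that passes the
#' sample-size and polymorphism gates, applies Benjamini-Hochberg FDR over
#' the executed tests (jointly across tissues by default, or per tissue), and
#' classifies each result as cis or trans by SNP-to-TSS distance. Samples are
#' matched between the genotype panel and each tissue's expression panel by
#' sample id.
#'
#' @param pairs Spatial-pair tibble ([find_spatial_pairs()]); only `snp_id`
#'   and `gene_id` are required.
#' @param genotypes Genotype tibble ([simulate_genotypes()] layout).
#' @param expression Named list of per-tissue expression tibbles.
#' @param genes Gene tibble (for TSS / chromosome lookup).
#' @param snps SNP tibble (for position lookup).
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @param min_samples Minimum complete pairs per test (default 70).
#' @param fdr_scope `"joint"` (one BH family over all executed tests, the
#'   default) or `"per_tissue"`.
#' @param cis_distance Cis window in bp (default 1e6).
#' @param distance_anchor `"tss"` (default) or `"gene_edge"` (distance to the
#'   nearest gene-body edge, 0 inside the gene).
#'
#' @return Tibble of class `eqtl_results`: one row per executed or skipped
#'   test with `snp_id, gene_id, tissue_id, beta, se, statistic, p_nominal,
#'   q_value, n_samples, category, distance_bp, interchromosomal,
#'   significant, status, reason`. Summary counts are available via
#'   [eqtl_counts()] / [glance()].
#' @export
run_eqtl_stage <- function(pairs, genotypes, expression, genes, snps,
                           q_threshold = 0.05, min_samples = 70,
                           fdr_scope = c("joint", "per_tissue"),
                           cis_distance = 1e6,
                           distance_anchor = c("tss", "gene_edge")) {
  fdr_scope <- match.arg(fdr_scope)
  distance_anchor <- match.arg(distance_anchor)
  pairs <- distinct(pairs, .data$snp_id, .data$gene_id)
  if (nrow(pairs) == 0 || length(expression) == 0) {
    warn("no testable pairs")
    return(empty_eqtl_results(q_threshold, fdr_scope))
  }
  geno <- panel_matrix(genotypes, "snp_id")
  exprs <- lapply(expression, panel_matrix, id_col = "gene_id")
  tissues <- names(exprs)
  grid <- tidyr::crossing(pairs, tissue_id = tissues)

  smp_by_tissue <- lapply(exprs, function(E)
    intersect(colnames(E), colnames(geno)))
  ng <- nrow(grid)
  beta <- se <- stat <- pval <- rep(NA_real_, ng)
  nsmp <- integer(ng)
  status <- rep("ok", ng)
  reason <- rep(NA_character_, ng)
  for (i in seq_len(ng)) {
    s <- grid$snp_id[i]; g <- grid$gene_id[i]; t <- grid$tissue_id[i]
    E <- exprs[[t]]
    if (!s %in% rownames(geno) || !g %in% rownames(E)) {
      status[i] <- "skipped"; reason[i] <- "unknown_id"
      next
    }
    smp <- smp_by_tissue[[t]]
    x <- geno[s, smp]; y <- E[g, smp]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    nsmp[i] <- length(x)
    if (length(x) < min_samples) {
      status[i] <- "skipped"; reason[i] <- "insufficient_samples"
      next
    }
    if (var(x) == 0) {
      status[i] <- "skipped"; reason[i] <- "monomorphic"
      next
    }
    fit <- ols_slope_test(x, y)
    beta[i] <- fit[["beta"]]; se[i] <- fit[["se"]]
    stat[i] <- fit[["statistic"]]; pval[i] <- fit[["p_value"]]
  }
  out <- bind_cols(grid,
                   tibble(beta = beta, se = se, statistic = stat,
                          p_nominal = pval, n_samples = nsmp,
                          status = status, reason = reason))

  cls <- out |>
    left_join(select(snps, "snp_id", snp_chrom = "chrom", snp_pos = "pos"),
              by = "snp_id") |>
    left_join(select(genes, "gene_id", gene_chrom = "chrom", "tss",
                     g_start = "start", g_end = "end"),
              by = "gene_id")
  anchor <- if (distance_anchor == "tss") {
    classify_cis_trans(cls$snp_chrom, cls$snp_pos, cls$gene_chrom, cls$tss,
                       cis_distance = cis_distance)
  } else {
    edge_dist <- ifelse(cls$snp_pos < cls$g_start,
                        cls$g_start - cls$snp_pos,
                        ifelse(cls$snp_pos >= cls$g_end,
                               cls$g_end - 1 - cls$snp_pos, 0))
    same <- cls$snp_chrom == cls$gene_chrom
    tibble(category = ifelse(same & abs(edge_dist) < cis_distance,
                             "cis", "trans"),
           distance_bp = ifelse(same, edge_dist, NA_real_),
           interchromosomal = !same)
  }
  out <- bind_cols(out, anchor)

  out$q_value <- NA_real_
  ok <- out$status == "ok"
  if (any(ok)) {
    if (fdr_scope == "joint") {
      out$q_value[ok] <- bh_fdr(out$p_nominal[ok])
    } else {
      for (t in tissues) {
        sel <- ok & out$tissue_id == t
        if (any(sel)) out$q_value[sel] <- bh_fdr(out$p_nominal[sel])
      }
    }
  }
  out$significant <- !is.na(out$q_value) & out$q_value < q_threshold

  out <- out |>
    select("snp_id", "gene_id", "tissue_id", "beta", "se", "statistic",
           "p_nominal", "q_value", "n_samples", "category", "distance_bp",
           "interchromosomal", "significant", "status", "reason") |>
    arrange(.data$snp_id, .data$gene_id, .data$tissue_id)
  structure(out, class = c("eqtl_results", class(out)),
            q_threshold = q_threshold, fdr_scope = fdr_scope)
}

empty_eqtl_results <- function(q_threshold, fdr_scope) {
  structure(
    tibble(snp_id = character(), gene_id = character(),
           tissue_id = character(), beta = numeric(), se = numeric(),
           statistic = numeric(), p_nominal = numeric(), q_value = numeric(),
           n_samples = integer(), category = character(),
           distance_bp = numeric(), interchromosomal = logical(),
           significant = logical(), status = character(),
           reason = character()),
    class = c("eqtl_results", class(tibble())),
    q_threshold = q_threshold, fdr_scope = fdr_scope
  )
}

#' Summary counts for an eQTL run
#'
#' Reports both countings of cis/trans eQTLs — SNP-gene-tissue triples and
#' distinct SNP-gene pairs (a pair counts once however many tissues support
#' it) — plus the number of distinct eGenes and eSNPs among significant
#' results.
#'
#' @param results An `eqtl_results` tibble.
#' @return One-row tibble of counts.
#' @export
eqtl_counts <- function(results) {
  sig <- filter(as_tibble(results), .data$significant)
  pair_cat <- distinct(sig, .data$snp_id, .data$gene_id, .data$category)
  tibble(
    n_tests = sum(results$status == "ok"),
    n_skipped = sum(results$status != "ok"),
    sig_triples = nrow(sig),
    sig_triples_cis = sum(sig$category == "cis"),
    sig_triples_trans = sum(sig$category == "trans"),
    sig_pairs = nrow(pair_cat),
    sig_pairs_cis = sum(pair_cat$category == "cis"),
    sig_pairs_trans = sum(pair_cat$category == "trans"),
    n_egenes = n_distinct(sig$gene_id),
    n_esnps = n_distinct(sig$snp_id)
  )
}

#' @export
glance.eqtl_results <- function(x, ...) eqtl_counts(x)

#' Link table for circos-style plotting of significant eQTLs
#'
#' @param results An `eqtl_results` tibble.
#' @param snps,genes Catalog tibbles used for coordinates.
#' @return Tibble `chrom_a, pos_a, chrom_b, pos_b, category`, one row per
#'   significant SNP-gene pair.
#' @export
eqtl_links <- function(results, snps, genes) {
  filter(as_tibble(results), .data$significant) |>
    distinct(.data$snp_id, .data$gene_id, .data$category) |>
    left_join(select(snps, "snp_id", chrom_a = "chrom", pos_a = "pos"),
              by = "snp_id") |>
    left_join(select(genes, "gene_id", chrom_b = "chrom", pos_b = "tss"),
              by = "gene_id") |>
    select("chrom_a", "pos_a", "chrom_b", "pos_b", "category")
}
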