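# Supporting statistics: Monte Carlo SNP-set enrichment null, Fisher exact
# cis:trans contrast, regulatory-score partition, per-tissue HLA
# contribution, hypergeometric gene-set enrichment.

#' Monte Carlo SNP-set enrichment test
#'
#' Compares the number of significant SNP-gene connections found for a
#' catalog SNP set against a null distribution obtained by running the same
#' spatial + eQTL pipeline on `n_sets` equally sized SNP sets drawn at random
#' from a control universe (catalog SNPs are excluded from the draws when the
#' universe is large enough). Two p-values are reported: a one-sample t test
#' of whether the observed count is consistent with the null distribution —
#' the prediction-interval form `t = (obs - mean) / (sd * sqrt(1 + 1/n))`
#' with `n - 1` df, which accounts for the sampling spread of a single null
#' draw and is calibrated under the null — and a permutation p-value
#' `(#\{null >= obs\} + 1) / (n_sets + 1)`, robust to non-normal null counts.
#'
#' @param catalog_snps Character vector of catalog SNP ids.
#' @param snp_universe Character vector of control-universe SNP ids.
#' @param pipeline_fn Function taking a vector of SNP ids and returning the
#'   significant SNP-gene connection count for that set (it should run the
#'   spatial and eQTL stages on a fixed dataset).
#' @param n_sets Number of random control sets (default 100; must be >= 2).
#' @param seed Integer seed; each control set uses a derived substream.
#'
#' @return Object of class `mc_enrichment`: `observed`, `null_connections`,
#'   `n_sets`, `t_statistic`, `p_value`, `p_permutation`, `null_mean`,
#'   `null_sd`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
monte_carlo_enrichment <- function(catalog_snps, snp_universe, pipeline_fn,
                                   n_sets = 100, seed = 1L) {
  catalog_snps <- unique(catalog_snps)
  snp_universe <- unique(snp_universe)
  k <- length(catalog_snps)
  if (n_sets < 2) abort("`n_sets` must be >= 2 (null variance is undefined)")
  pool <- setdiff(snp_universe, catalog_snps)
  if (length(pool) < k) pool <- snp_universe
  if (length(pool) < k) {
    abort("SNP universe is smaller than the catalog set")
  }
  observed <- pipeline_fn(catalog_snps)
  null_connections <- vapply(seq_len(n_sets), function(i) {
    set <- with_seed(substream_seed(seed, paste0("mc", i)),
                     sample(pool, k))
    as.numeric(pipeline_fn(set))
  }, numeric(1))
  m <- mean(null_connections)
  s <- sd(null_connections)
  if (s == 0) {
    warn("null connection counts are constant; t-based p is degenerate")
    tstat <- if (observed == m) 0 else sign(observed - m) * Inf
    p <- if (observed == m) 1 else .Machine$double.xmin
  } else {
    tstat <- (observed - m) / (s * sqrt(1 + 1 / n_sets))
    p <- max(2 * pt(-abs(tstat), df = n_sets - 1), .Machine$double.xmin)
  }
  structure(
    list(observed = as.numeric(observed),
         null_connections = null_connections,
         n_sets = as.integer(n_sets),
         t_statistic = tstat, p_value = p,
         p_permutation = (sum(null_connections >= observed) + 1) /
           (n_sets + 1),
         null_mean = m, null_sd = s, set_size = k),
    class = "mc_enrichment"
  )
}

#' @export
print.mc_enrichment <- function(x, ...) {
  cat(sprintf(paste0(
    "Monte Carlo SNP-set enrichment\n",
    "  observed connections: %g (set size %d)\n",
    "  null: mean %.2f, sd %.2f over %d random sets\n",
    "  t = %.3f, p = %.3g (permutation p = %.3g)\n"),
    x$observed, x$set_size, x$null_mean, x$null_sd, x$n_sets,
    x$t_statistic, x$p_value, x$p_permutation))
  invisible(x)
}

#' @export
tidy.mc_enrichment <- function(x, ...) {
  tibble(set = c("catalog", paste0("null_", seq_len(x$n_sets))),
         connections = c(x$observed, x$null_connections))
}

#' @export
glance.mc_enrichment <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, n_sets = x$n_sets,
         t_statistic = x$t_statistic, p_value = x$p_value,
         p_permutation = x$p_permutation)
}

#' @export
autoplot.mc_enrichment <- function(object, ...) {
  df <- tibble(connections = object$null_connections)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$connections)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "significant SNP-gene connections (null sets)",
                  y = "random sets",
                  title = sprintf("Observed = %g, t-test p = %.2g",
                                  object$observed, object$p_value))
}

#' Fisher exact test of the cis:trans ratio between SNP classes
#'
#' Two-sided Fisher exact test on the 2x2 table of cis/trans eQTL counts for
#' regulatory versus non-regulatory SNPs. The two-sided p sums the
#' probabilities of all tables (at fixed margins) whose point probability
#' does not exceed the observed table's — the convention of mainstream exact
#' tests (`stats::fisher.test`), stated here because two-sided Fisher
#' conventions differ. Both the sample odds ratio `(a*d)/(b*c)` and the
#' conditional-MLE odds ratio are reported.
#'
#' @param reg_cis,reg_trans Cis / trans counts for regulatory SNPs.
#' @param nonreg_cis,nonreg_trans Counts for non-regulatory SNPs.
#'
#' @return One-row tibble `odds_ratio, odds_ratio_cmle, p_value` plus the
#'   four counts. A zero table margin yields `p_value = 1` with a warning.
#' @export
#' @examples
#' fisher_cis_trans(46, 25, 186, 41)
fisher_cis_trans <- function(reg_cis, reg_trans, nonreg_cis, nonreg_trans) {
  counts <- c(reg_cis, reg_trans, nonreg_cis, nonreg_trans)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("all four counts must be non-negative integers")
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(c("regulatory", "non-regulatory"),
                                c("cis", "trans")))
  base <- tibble(reg_cis = reg_cis, reg_trans = reg_trans,
                 nonreg_cis = nonreg_cis, nonreg_trans = nonreg_trans)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("a table margin is zero; the Fisher test is uninformative (p = 1)")
    return(mutate(base, odds_ratio = NA_real_, odds_ratio_cmle = NA_real_,
                  p_value = 1))
  }
  ft <- fisher.test(tab)
  mutate(base,
         odds_ratio = (reg_cis * nonreg_trans) / (reg_trans * nonreg_cis),
         odds_ratio_cmle = unname(ft$estimate),
         p_value = ft$p.value)
}

#' Split eQTL SNPs into regulatory and non-regulatory sets by score
#'
#' A SNP is called regulatory when its functional regulatory score is
#' strictly below `score_threshold` (default 0.05, matching the convention
#' that small scores flag likely regulatory variants). SNPs with a missing
#' score are non-regulatory and flagged.
#'
#' @param snps SNP tibble with `snp_id` and `regulatory_score`.
#' @param score_threshold Strict upper bound for the regulatory call.
#'
#' @return The input with `regulatory` (logical) and `score_missing` columns.
#' @export
regulatory_partition <- function(snps, score_threshold = 0.05) {
  assert_cols(snps, c("snp_id", "regulatory_score"), "snps")
  mutate(snps,
         score_missing = is.na(.data$regulatory_score),
         regulatory = !.data$score_missing &
           .data$regulatory_score < score_threshold)
}

#' Per-tissue HLA contribution to significant eQTLs
#'
#' For each tissue, counts significant eQTLs split by the SNP's locus class
#' and expresses the HLA share as a percentage (`100 * HLA / total`). Tissues
#' with zero significant eQTLs are excluded from the mean/SD (with a
#' message). Each tissue is then grouped by the +/-1 SD rule over all
#' contributing tissues: `high` when strictly above mean + SD, `low` when
#' strictly below mean - SD, otherwise `mid`.
#'
#' @param eqtl_results An `eqtl_results` tibble (or any tibble with
#'   `snp_id, tissue_id, significant`).
#' @param snps SNP tibble with `locus_class`.
#'
#' @return Tibble of class `tissue_summary`: `tissue_id, n_eqtls_total,
#'   n_eqtls_hla, contribution_pct, group`, with `attr(, "mean_pct")` and
#'   `attr(, "sd_pct")`. [glance()] returns the mean and SD.
#' @export
tissue_contribution <- function(eqtl_results, snps) {
  sig <- filter(as_tibble(eqtl_results), .data$significant) |>
    left_join(select(snps, "snp_id", "locus_class"), by = "snp_id")
  if (anyNA(sig$locus_class)) {
    abort("every significant eQTL's SNP must carry a locus_class")
  }
  all_tissues <- unique(as_tibble(eqtl_results)$tissue_id)
  out <- sig |>
    group_by(.data$tissue_id) |>
    summarise(n_eqtls_total = n(),
              n_eqtls_hla = sum(.data$locus_class == "HLA"),
              .groups = "drop") |>
    mutate(contribution_pct = 100 * .data$n_eqtls_hla / .data$n_eqtls_total)
  dropped <- setdiff(all_tissues, out$tissue_id)
  if (length(dropped)) {
    inform(sprintf("tissue(s) with zero significant eQTLs excluded: %s",
                   paste(dropped, collapse = ", ")))
  }
  m <- mean(out$contribution_pct)
  s <- if (nrow(out) > 1) sd(out$contribution_pct) else 0
  out <- out |>
    mutate(group = dplyr::case_when(
      .data$contribution_pct > m + s ~ "high",
      .data$contribution_pct < m - s ~ "low",
      TRUE ~ "mid"
    )) |>
    arrange(dplyr::desc(.data$contribution_pct))
  structure(out, class = c("tissue_summary", class(out)),
            mean_pct = m, sd_pct = s)
}

#' @export
glance.tissue_summary <- function(x, ...) {
  tibble(n_tissues = nrow(x),
         mean_pct = attr(x, "mean_pct"),
         sd_pct = attr(x, "sd_pct"))
}

#' @export
autoplot.tissue_summary <- function(object, ...) {
  m <- attr(object, "mean_pct"); s <- attr(object, "sd_pct")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$tissue_id, .data$contribution_pct),
    y = .data$contribution_pct, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(m - s, m, m + s),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "HLA : total significant eQTLs (%)",
                  fill = "group",
                  title = sprintf("Mean %.2f%% ± %.2f%%", m, s))
}

#' Per-tissue HLA contribution bar chart
#'
#' Convenience wrapper: computes [tissue_contribution()] and plots it.
#'
#' @inheritParams tissue_contribution
#' @return A ggplot object.
#' @export
plot_tissue_contribution <- function(eqtl_results, snps) {
  autoplot(tissue_contribution(eqtl_results, snps))
}

#' Hypergeometric gene-set enrichment with BH FDR
#'
#' One-sided hypergeometric upper-tail test per annotation set: the
#' probability of observing at least the seen overlap between the query genes
#' and the set, given the background size. Benjamini-Hochberg FDR is applied
#' across all tested sets (via the shared [bh_fdr()] routine) and rows are
#' sorted by q then p.
#'
#' @param query_genes Character vector of query gene ids.
#' @param annotation_sets Named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param background Either an integer background-universe size or a
#'   character vector of background gene ids (the query must be a subset;
#'   set members outside the background are ignored).
#'
#' @return Tibble `set_id, k_overlap, K_set_size, n_query, N_background,
#'   p_hyper, q_value`.
#' @export
geneset_enrichment <- function(query_genes, annotation_sets, background) {
  if (length(annotation_sets) == 0) abort("no annotation sets supplied")
  if (is.null(names(annotation_sets)) || any(!nzchar(names(annotation_sets)))) {
    abort("`annotation_sets` must be a named list")
  }
  query_genes <- unique(query_genes)
  if (is.character(background)) {
    background <- unique(background)
    if (!all(query_genes %in% background)) {
      abort("query genes must be a subset of the background")
    }
    N <- length(background)
    sets <- lapply(annotation_sets, function(s) intersect(unique(s),
                                                          background))
  } else {
    N <- as.integer(background)
    sets <- lapply(annotation_sets, unique)
  }
  n <- length(query_genes)
  if (any(lengths(sets) == 0)) abort("annotation sets must be non-empty")
  rows <- purrr::imap_dfr(sets, function(s, id) {
    K <- length(s)
    k <- length(intersect(query_genes, s))
    tibble(set_id = id, k_overlap = k, K_set_size = K, n_query = n,
           N_background = N,
           p_hyper = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows$q_value <- bh_fdr(rows$p_hyper)
  arrange(rows, .data$q_value, .data$p_hyper)
}

#' Simulate many all-null eQTL panels and record the false-discovery
#' proportion
#'
#' Calibration harness for the BH step: each replicate simulates an
#' independent genotype panel and pure-noise expression for `n_tests`
#' SNP-gene pairs in one tissue, runs the full eQTL stage, and records the
#' false-discovery proportion at the given q threshold (all discoveries are
#' false under the null; FDP = 0 when nothing is called).
#'
#' @param n_tests SNP-gene pairs per replicate (default 1000).
#' @param n_reps Replicates (default 200).
#' @param n_samples Samples per replicate (default 100).
#' @param q_threshold BH threshold (default 0.05).
#' @param seed Integer seed.
#'
#' @return Tibble `rep, n_discoveries, fdp`.
#' @export
fdr_calibration <- function(n_tests = 1000, n_reps = 200, n_samples = 100,
                            q_threshold = 0.05, seed = 1L) {
  snps <- tibble(snp_id = make_ids("N", n_tests), chrom = "chr1",
                 pos = as.numeric(seq_len(n_tests)) * 10,
                 trait_p = 1e-6, locus_class = "non-HLA",
                 regulatory_score = NA_real_)
  genes <- tibble(chrom = "chr1", start = as.numeric(seq_len(n_tests)) * 100,
                  end = as.numeric(seq_len(n_tests)) * 100 + 50,
                  gene_id = make_ids("GN", n_tests), score = ".",
                  strand = "+", tss = as.numeric(seq_len(n_tests)) * 100)
  pairs <- tibble(snp_id = snps$snp_id, gene_id = genes$gene_id)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    geno <- simulate_genotypes(snps, n_samples,
                               seed = substream_seed(seed, paste0("g", r)))
    expr <- simulate_expression(geno, genes, "t1",
                                planted = tibble(snp_id = character(),
                                                 gene_id = character(),
                                                 tissue_id = character(),
                                                 beta = numeric()),
                                min_samples = min(70, n_samples),
                                seed = substream_seed(seed, paste0("e", r)))
    res <- run_eqtl_stage(pairs, geno, expr, genes, snps,
                          q_threshold = q_threshold,
                          min_samples = min(70, n_samples))
    nd <- sum(res$significant)
    tibble(rep = r, n_discoveries = nd, fdp = nd / max(nd, 1))
  })
}
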