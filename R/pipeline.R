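# Pipeline orchestration: run every stage in order on one study with one
# config, emit stage tables and a consolidated report.

#' Pipeline configuration
#'
#' Collects every tunable threshold with the defaults the analysis is built
#' around: q < 0.05 significance on the BH q-value, a strict 1 Mb cis window
#' anchored at the TSS, a minimum contact count of 1, a 70-sample floor per
#' test, one joint FDR family, 100 Monte Carlo control sets, and a 0.05
#' regulatory-score call threshold. Nothing is hard-coded downstream: every
#' stage reads these values.
#'
#' @param q_threshold BH q-value significance threshold.
#' @param cis_distance Cis window in bp (cis is strictly less).
#' @param min_count Minimum per-cell-line Hi-C contact count.
#' @param min_samples Minimum complete genotype-expression pairs per test.
#' @param fdr_scope `"joint"` or `"per_tissue"`.
#' @param n_sets Monte Carlo control sets.
#' @param score_threshold Regulatory-score call threshold (strict `<`).
#' @param include_same_fragment Keep SNP-in-gene-fragment pairs.
#' @param distance_anchor `"tss"` or `"gene_edge"`.
#' @param seed Integer seed for every stochastic stage.
#'
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(q_threshold = 0.05, cis_distance = 1e6,
                            min_count = 1, min_samples = 70,
                            fdr_scope = c("joint", "per_tissue"),
                            n_sets = 100, score_threshold = 0.05,
                            include_same_fragment = TRUE,
                            distance_anchor = c("tss", "gene_edge"),
                            seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  distance_anchor <- match.arg(distance_anchor)
  stopifnot(q_threshold >= 0, cis_distance > 0, min_count > 0,
            min_samples > 0, n_sets >= 2, score_threshold >= 0)
  if (is.null(seed)) abort("a seed is required for stochastic stages")
  structure(list(q_threshold = q_threshold, cis_distance = cis_distance,
                 min_count = min_count, min_samples = min_samples,
                 fdr_scope = fdr_scope, n_sets = n_sets,
                 score_threshold = score_threshold,
                 include_same_fragment = include_same_fragment,
                 distance_anchor = distance_anchor,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full spatial-eQTL pipeline
#'
#' Executes the stages in order — spatial mapping, eQTL testing, enrichment
#' summaries (regulatory partition + Fisher cis:trans contrast, per-tissue
#' HLA contribution, optional gene-set enrichment), LD profiling of the
#' significant eQTL SNPs — and assembles a report of every count together
#' with the full configuration and seed for provenance. A stage failure
#' aborts with the stage name; outputs of completed stages are retained in
#' `outdir` when one is given.
#'
#' @param study Study input list ([simulate_study()] / [read_study()]).
#' @param config A [pipeline_config()].
#' @param outdir Optional directory: stage TSVs and `report.json` are
#'   written there.
#' @param gmt Optional named list of annotation gene sets; when supplied,
#'   significant eGenes are tested against them over the full gene universe.
#'
#' @return List of class `spaceqtl_run`: `spatial_pairs, eqtl, links,
#'   tissue_summary, fisher, enrichment, ld, report` (report is a plain
#'   list, serialized as `report.json`).
#' @export
run_pipeline <- function(study, config = pipeline_config(), outdir = NULL,
                         gmt = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  emit <- function(tbl, name) {
    if (!is.null(outdir)) {
      readr::write_tsv(as_tibble(tbl), file.path(outdir, name))
    }
    tbl
  }

  pairs <- tryCatch(
    find_spatial_pairs(study$snps, study$genes, study$fragments,
                       study$contacts, min_count = config$min_count,
                       include_same_fragment = config$include_same_fragment),
    error = function(e) stop_stage("map-spatial", e))
  stage_log("map-spatial", "%d SNPs x %d genes -> %d spatial pairs",
            nrow(study$snps), nrow(study$genes), nrow(pairs))
  emit(pairs, "spatial_pairs.tsv")

  eqtl <- tryCatch(
    run_eqtl_stage(pairs, study$genotypes, study$expression, study$genes,
                   study$snps, q_threshold = config$q_threshold,
                   min_samples = config$min_samples,
                   fdr_scope = config$fdr_scope,
                   cis_distance = config$cis_distance,
                   distance_anchor = config$distance_anchor),
    error = function(e) stop_stage("eqtl", e))
  counts <- eqtl_counts(eqtl)
  stage_log("eqtl", "%d tests, %d significant triples (%d cis, %d trans)",
            counts$n_tests, counts$sig_triples, counts$sig_triples_cis,
            counts$sig_triples_trans)
  emit(eqtl, "eqtl_results.tsv")
  links <- emit(eqtl_links(eqtl, study$snps, study$genes), "links.tsv")

  enrich <- tryCatch({
    sig_snps <- unique(eqtl$snp_id[eqtl$significant])
    part <- regulatory_partition(
      filter(study$snps, .data$snp_id %in% sig_snps),
      score_threshold = config$score_threshold)
    pair_cat <- filter(as_tibble(eqtl), .data$significant) |>
      distinct(.data$snp_id, .data$gene_id, .data$category) |>
      left_join(select(part, "snp_id", "regulatory"), by = "snp_id")
    fisher <- fisher_cis_trans(
      sum(pair_cat$regulatory & pair_cat$category == "cis"),
      sum(pair_cat$regulatory & pair_cat$category == "trans"),
      sum(!pair_cat$regulatory & pair_cat$category == "cis"),
      sum(!pair_cat$regulatory & pair_cat$category == "trans"))
    tissue <- if (counts$sig_triples > 0) {
      tissue_contribution(eqtl, study$snps)
    } else {
      structure(tibble(tissue_id = character(), n_eqtls_total = integer(),
                       n_eqtls_hla = integer(), contribution_pct = numeric(),
                       group = character()),
                class = c("tissue_summary", class(tibble())),
                mean_pct = NA_real_, sd_pct = NA_real_)
    }
    gse <- NULL
    if (!is.null(gmt) && counts$n_egenes > 0) {
      gse <- geneset_enrichment(unique(eqtl$gene_id[eqtl$significant]),
                                gmt, background = study$genes$gene_id)
    }
    list(fisher = fisher, tissue = tissue, gse = gse)
  }, error = function(e) stop_stage("enrich", e))
  stage_log("enrich", "fisher p = %.3g; %d tissues summarised",
            enrich$fisher$p_value, nrow(enrich$tissue))
  emit(enrich$fisher, "fisher.tsv")
  emit(enrich$tissue, "tissue_summary.tsv")
  if (!is.null(enrich$gse)) emit(enrich$gse, "enrichment.tsv")

  ld <- tryCatch({
    sig_snps <- unique(eqtl$snp_id[eqtl$significant])
    if (length(sig_snps) >= 2) ld_matrix(study$genotypes, sig_snps) else NULL
  }, error = function(e) stop_stage("ld", e))
  if (!is.null(ld)) {
    stage_log("ld", "%d pairs, max r2 = %.3f", nrow(ld), attr(ld, "max_r2"))
    emit(ld, "ld_pairs.tsv")
  }

  report <- list(
    config = unclass(config),
    seed = config$seed,
    counts = as.list(counts),
    n_spatial_pairs = nrow(pairs),
    tissue_summary = as.list(glance(enrich$tissue)),
    fisher = as.list(enrich$fisher),
    ld_max_r2 = if (is.null(ld)) NULL else attr(ld, "max_r2"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(outdir)) {
    jsonlite::write_json(report[setdiff(names(report), "elapsed_sec")],
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(spatial_pairs = pairs, eqtl = eqtl, links = links,
                 tissue_summary = enrich$tissue, fisher = enrich$fisher,
                 enrichment = enrich$gse, ld = ld, report = report),
            class = "spaceqtl_run")
}

#' @export
print.spaceqtl_run <- function(x, ...) {
  cts <- x$report$counts
  cat("spatial-eQTL pipeline run\n")
  cat(sprintf("  spatial pairs: %d\n", x$report$n_spatial_pairs))
  cat(sprintf("  tests: %d; significant: %d triples (%d cis / %d trans), %d pairs\n",
              cts$n_tests, cts$sig_triples, cts$sig_triples_cis,
              cts$sig_triples_trans, cts$sig_pairs))
  cat(sprintf("  eGenes: %d; eSNPs: %d\n", cts$n_egenes, cts$n_esnps))
  cat(sprintf("  Fisher cis:trans p = %.3g\n", x$fisher$p_value))
  invisible(x)
}
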