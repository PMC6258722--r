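test_that("the Fisher cis:trans contrast matches exhaustive enumeration", {
  got <- fisher_cis_trans(46, 25, 186, 41)
  expect_equal(got$p_value, enum_fisher_p(46, 25, 186, 41),
               tolerance = 1e-12)
  expect_equal(got$odds_ratio, (46 * 41) / (25 * 186))

  # perfectly balanced table is uninformative
  expect_equal(fisher_cis_trans(1, 1, 1, 1)$p_value, 1)
  # zero margin: warned, p = 1
  expect_warning(z <- fisher_cis_trans(0, 0, 5, 7), "margin")
  expect_equal(z$p_value, 1)
  # transposition symmetry (rows <-> columns)
  expect_equal(fisher_cis_trans(9, 3, 4, 11)$p_value,
               fisher_cis_trans(9, 4, 3, 11)$p_value)
  expect_error(fisher_cis_trans(-1, 2, 3, 4), "non-negative")

  # enumeration oracle across small tables
  for (a in 0:6) for (b in 0:4) for (cc in 0:4) for (d in 0:6) {
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    expect_equal(fisher_cis_trans(a, b, cc, d)$p_value,
                 enum_fisher_p(a, b, cc, d), tolerance = 1e-12)
  }
})

test_that("regulatory partition applies a strict score threshold", {
  snps <- tibble::tibble(snp_id = c("a", "b", "c"),
                         regulatory_score = c(0.049, 0.05, NA))
  part <- regulatory_partition(snps)
  expect_equal(part$regulatory, c(TRUE, FALSE, FALSE))
  expect_equal(part$score_missing, c(FALSE, FALSE, TRUE))

  # a 25 / 88 split arises from 25 sub-threshold scores among 113
  many <- tibble::tibble(snp_id = sprintf("s%03d", 1:113),
                         regulatory_score = c(rep(0.01, 25), rep(0.5, 88)))
  p2 <- regulatory_partition(many)
  expect_equal(sum(p2$regulatory), 25)
  expect_equal(sum(!p2$regulatory), 88)
})

test_that("tissue HLA contribution is scale-free and grouped by the SD rule", {
  fake <- function(tissue, n_hla, n_non) {
    tibble::tibble(
      snp_id = c(rep("hla_snp", n_hla), rep("oth_snp", n_non)),
      gene_id = "g", tissue_id = tissue, significant = TRUE)
  }
  snps <- tibble::tibble(snp_id = c("hla_snp", "oth_snp"),
                         locus_class = c("HLA", "non-HLA"))
  res <- dplyr::bind_rows(fake("a", 4, 6), fake("b", 1, 9), fake("c", 9, 1))
  ts <- tissue_contribution(res, snps)
  expect_equal(ts$contribution_pct[ts$tissue_id == "a"], 40)
  expect_equal(attr(ts, "mean_pct"), mean(c(40, 10, 90)))

  # doubling all counts changes nothing
  ts2 <- tissue_contribution(dplyr::bind_rows(res, res), snps)
  expect_equal(ts2$contribution_pct, ts$contribution_pct)
  expect_equal(attr(ts2, "mean_pct"), attr(ts, "mean_pct"))
  expect_equal(attr(ts2, "sd_pct"), attr(ts, "sd_pct"))
  expect_equal(ts2$group, ts$group)

  # identical percentages: SD 0 and everything mid (strict inequalities)
  same <- dplyr::bind_rows(fake("a", 2, 2), fake("b", 3, 3))
  ts3 <- tissue_contribution(same, snps)
  expect_equal(attr(ts3, "sd_pct"), 0)
  expect_true(all(ts3$group == "mid"))

  # tissues with zero significant eQTLs are excluded with a message
  with_zero <- dplyr::bind_rows(res,
    tibble::tibble(snp_id = "oth_snp", gene_id = "g", tissue_id = "d",
                   significant = FALSE))
  expect_message(ts4 <- tissue_contribution(with_zero, snps), "d")
  expect_false("d" %in% ts4$tissue_id)
})

test_that("HLA effects concentrated in two tissues put them in the high group", {
  spec <- genome_spec(chromosomes = c(chr1 = 3e6, chr2 = 2e6),
                      fragment_size_mean = 5000, n_genes = 60, n_snps = 40,
                      hla_like_interval = list("chr1", 0, 1.2e6),
                      n_hla_snps = 14)
  tissues <- paste0("t", 1:6)
  genome <- simulate_genome(spec, seed = 303)
  hla_truth <- plant_effects(genome$snps, genome$genes, tissues[1:2],
                             n_cis = 3, n_trans = 0, beta = 2.5,
                             hla_only = TRUE, seed = 303)
  non_hla_snps <- dplyr::filter(genome$snps, locus_class == "non-HLA")
  used_genes <- unique(hla_truth$gene_id)
  other_truth <- plant_effects(non_hla_snps,
                               dplyr::filter(genome$genes,
                                             !gene_id %in% used_genes),
                               tissues, n_cis = 3, n_trans = 1, beta = 2.5,
                               seed = 404)
  truth <- dplyr::bind_rows(hla_truth, other_truth)
  contacts <- simulate_contacts(genome$fragments, genome$genes, genome$snps,
                                truth, seed = 303)
  geno <- simulate_genotypes(genome$snps, 180, seed = 303)
  expr <- simulate_expression(geno, genome$genes, tissues, truth,
                              seed = 303)
  pairs <- find_spatial_pairs(genome$snps, genome$genes, genome$fragments,
                              contacts, include_same_fragment = FALSE)
  res <- run_eqtl_stage(pairs, geno, expr, genome$genes, genome$snps)
  ts <- tissue_contribution(res, genome$snps)
  expect_setequal(ts$tissue_id[ts$group == "high"], tissues[1:2])
})

test_that("hypergeometric gene-set enrichment matches direct tail summation", {
  universe <- sprintf("g%02d", 1:50)
  set10 <- universe[1:10]
  for (k in 0:10) {
    query <- c(set10[seq_len(k)],
               universe[11:(11 + (10 - k) - 1)][seq_len(10 - k)])
    got <- geneset_enrichment(query, list(S = set10), background = 50)
    direct <- sum(dhyper(k:10, 10, 40, 10))
    expect_equal(got$p_hyper, direct, tolerance = 1e-12)
  }
  # zero overlap is never significant
  none <- geneset_enrichment(universe[11:20], list(S = set10),
                             background = 50)
  expect_equal(none$p_hyper, 1)

  # perfect overlap gives the smallest p among sets
  sets <- list(exact = set10, half = universe[6:15], other = universe[30:45])
  hit <- geneset_enrichment(set10, sets, background = universe)
  expect_equal(hit$set_id[1], "exact")
  expect_identical(hit$q_value, sort(hit$q_value))
  # BH here equals the shared routine
  expect_identical(sort(hit$q_value), sort(bh_fdr(hit$p_hyper)))

  expect_error(geneset_enrichment(c("zz"), sets, background = universe),
               "subset")
})

test_that("the Monte Carlo SNP-set test is sane on a synthetic counting function", {
  values <- setNames(c(rep(1, 40), rep(0, 160)), sprintf("u%03d", 1:200))
  count_fn <- function(ids) sum(values[ids])

  expect_error(monte_carlo_enrichment(names(values)[1:10], names(values),
                                      count_fn, n_sets = 1), "n_sets")
  expect_error(monte_carlo_enrichment(sprintf("u%03d", 1:150),
                                      sprintf("u%03d", 1:100), count_fn),
               "smaller")

  # an enriched catalog (all carriers) is detected far below the null
  mc <- monte_carlo_enrichment(names(values)[1:30], names(values),
                               count_fn, n_sets = 100, seed = 4)
  expect_equal(mc$observed, 30)
  expect_lt(mc$p_value, 1e-4)
  expect_lt(mc$p_permutation, 0.02)
  expect_equal(length(mc$null_connections), 100)
  # determinism and tidier shapes
  mc2 <- monte_carlo_enrichment(names(values)[1:30], names(values),
                                count_fn, n_sets = 100, seed = 4)
  expect_identical(mc$null_connections, mc2$null_connections)
  expect_equal(nrow(tidy(mc)), 101)
  expect_equal(glance(mc)$observed, 30)

  # a catalog exchangeable with the controls rejects at about the
  # nominal rate
  rej <- vapply(1:120, function(r) {
    catalog <- spaceqtl:::with_seed(1e6 + r,
                                    sample(names(values), 30))
    m <- monte_carlo_enrichment(catalog, names(values), count_fn,
                                n_sets = 40, seed = r)
    m$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), qbinom(0.005, 120, 0.05) / 120)
  expect_lte(mean(rej), qbinom(0.995, 120, 0.05) / 120)
})
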