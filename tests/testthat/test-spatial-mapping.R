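test_that("fragment assignment respects half-open boundaries and spans gene bodies", {
  fr <- tibble::tibble(chrom = "c", start = c(0, 1000), end = c(1000, 2000),
                       fragment_id = c("F000001", "F000002"))
  # SNP exactly at a fragment boundary belongs to the downstream fragment
  hit <- assign_to_fragments(
    tibble::tibble(id = "snp", chrom = "c", start = 1000, end = 1001), fr)
  expect_equal(hit$fragment_id, "F000002")
  # a gene spanning the boundary maps to both fragments
  gene <- assign_to_fragments(
    tibble::tibble(id = "g", chrom = "c", start = 500, end = 1500), fr)
  expect_setequal(gene$fragment_id, c("F000001", "F000002"))
  # positions outside every fragment are reported, not dropped
  un <- assign_to_fragments(
    tibble::tibble(id = c("in", "out"), chrom = c("c", "c"),
                   start = c(10, 5000), end = c(11, 5001)), fr)
  expect_true(is.na(un$fragment_id[un$id == "out"]))
  expect_equal(un$fragment_id[un$id == "in"], "F000001")
})

test_that("fragment assignment matches a brute-force linear scan on random points", {
  spec <- genome_spec(c(a = 2e5, b = 1.5e5, c = 5e4),
                      fragment_size_mean = 700, n_genes = 2, n_snps = 2)
  fr <- simulate_genome(spec, seed = 8)$fragments
  set.seed(99)
  n <- 10000
  chrom <- sample(names(spec$chromosomes), n, replace = TRUE)
  pos <- floor(runif(n) * spec$chromosomes[chrom])
  got <- assign_to_fragments(
    tibble::tibble(id = sprintf("p%05d", seq_len(n)), chrom = chrom,
                   start = pos, end = pos + 1), fr)
  got <- got[order(got$id), ]
  want <- brute_assign(chrom, pos, fr)
  expect_identical(got$fragment_id, want[order(sprintf("p%05d", seq_len(n)))])
})

test_that("planted pairs are recovered exactly when background contacts are absent", {
  st <- tiny_study(seed = 21, n_cis = 3, n_trans = 1)
  pairs <- find_spatial_pairs(st$snps, st$genes, st$fragments, st$contacts,
                              include_same_fragment = FALSE)
  planted <- dplyr::distinct(st$truth, snp_id, gene_id)
  expect_setequal(paste(pairs$snp_id, pairs$gene_id),
                  paste(planted$snp_id, planted$gene_id))
  # with self-fragment pairs allowed, the planted pairs are still a subset
  pairs2 <- find_spatial_pairs(st$snps, st$genes, st$fragments, st$contacts)
  expect_true(all(paste(planted$snp_id, planted$gene_id) %in%
                    paste(pairs2$snp_id, pairs2$gene_id)))
})

test_that("contact evidence pools across cell lines and filters monotonically", {
  fr <- manual_fragments()
  snps <- tibble::tibble(snp_id = "s1", chrom = "cA", pos = 150,
                         trait_p = 1e-8, locus_class = "non-HLA",
                         regulatory_score = NA_real_)
  genes <- tibble::tibble(chrom = "cB", start = 2100, end = 2900,
                          gene_id = "g1", score = ".", strand = "+",
                          tss = 2100)
  sf <- "F000001"                      # cA:[0,1000)
  gf <- fr$fragment_id[fr$chrom == "cB" & fr$start == 2000]
  contacts <- tibble::tibble(
    frag_id_a = c(sf, gf), frag_id_b = c(gf, sf),
    count = c(3L, 4L), cell_line = c("GM12878", "IMR90"))
  got <- find_spatial_pairs(snps, genes, fr, contacts)
  expect_equal(got$supporting_contacts, 7)
  expect_equal(got$n_cell_lines, 2)
  expect_false(got$same_fragment)

  # min_count gates on the best single cell line, monotonically
  expect_equal(nrow(find_spatial_pairs(snps, genes, fr, contacts,
                                       min_count = 4)), 1)
  expect_equal(nrow(find_spatial_pairs(snps, genes, fr, contacts,
                                       min_count = 5,
                                       include_same_fragment = FALSE)), 0)

  # empty contact table warns and returns no contact-supported pairs
  expect_warning(
    empty <- find_spatial_pairs(snps, genes, fr, contacts[0, ],
                                include_same_fragment = FALSE),
    "empty")
  expect_equal(nrow(empty), 0)
})

test_that("a SNP sharing a gene's fragment pairs with it without a recorded contact", {
  fr <- manual_fragments()
  snps <- tibble::tibble(snp_id = "s1", chrom = "cA", pos = 450,
                         trait_p = 1e-8, locus_class = "non-HLA",
                         regulatory_score = NA_real_)
  genes <- tibble::tibble(chrom = "cA", start = 800, end = 1200,
                          gene_id = "g1", score = ".", strand = "+",
                          tss = 800)
  no_contacts <- tibble::tibble(frag_id_a = character(),
                                frag_id_b = character(),
                                count = integer(), cell_line = character())
  expect_warning(got <- find_spatial_pairs(snps, genes, fr, no_contacts),
                 "empty")
  expect_equal(nrow(got), 1)
  expect_true(got$same_fragment)
  expect_gte(got$supporting_contacts, 1)
  expect_warning(
    none <- find_spatial_pairs(snps, genes, fr, no_contacts,
                               include_same_fragment = FALSE),
    "empty")
  expect_equal(nrow(none), 0)
})

test_that("output is invariant to row order and fragment-pair orientation", {
  st <- tiny_study(seed = 31, background_rate = 2e-4)
  base <- find_spatial_pairs(st$snps, st$genes, st$fragments, st$contacts)
  flipped <- st$contacts |>
    dplyr::mutate(tmp = frag_id_a, frag_id_a = frag_id_b, frag_id_b = tmp) |>
    dplyr::select(-tmp)
  shuffled <- flipped[sample.int(nrow(flipped)), ]
  again <- find_spatial_pairs(st$snps[sample.int(nrow(st$snps)), ],
                              st$genes[sample.int(nrow(st$genes)), ],
                              st$fragments, shuffled)
  expect_equal(as.data.frame(base), as.data.frame(again))

  # raising min_count never adds pairs
  for (k in 1:4) {
    pk <- find_spatial_pairs(st$snps, st$genes, st$fragments, st$contacts,
                             min_count = k)
    pk1 <- find_spatial_pairs(st$snps, st$genes, st$fragments, st$contacts,
                              min_count = k + 1)
    expect_true(all(paste(pk1$snp_id, pk1$gene_id) %in%
                      paste(pk$snp_id, pk$gene_id)))
  }
})

test_that("the contact join agrees with a naive nested-loop oracle", {
  st <- tiny_study(seed = 55, n_cis = 2, n_trans = 1,
                   background_rate = 5e-4)
  got <- find_spatial_pairs(st$snps, st$genes, st$fragments, st$contacts,
                            include_same_fragment = FALSE)
  want <- brute_spatial_pairs(st$snps, st$genes, st$fragments, st$contacts)
  expect_setequal(paste(got$snp_id, got$gene_id),
                  paste(want$snp_id, want$gene_id))
  merged <- merge(as.data.frame(got), want, by = c("snp_id", "gene_id"))
  expect_equal(merged$supporting_contacts.x, merged$supporting_contacts.y)
})
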