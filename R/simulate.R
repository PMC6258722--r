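# Synthetic-data module: genomes, restriction fragments, gene models, SNP
# catalogs, Hi-C contact lists, genotype panels and multi-tissue expression
# with planted eQTL effects, all with known ground truth.

#' Describe a synthetic genome
#'
#' Bundles the parameters of a toy multi-chromosome genome: chromosome sizes,
#' the mean restriction-fragment length, how many genes and SNPs to place, and
#' an HLA-like interval whose SNPs are labelled `"HLA"` (everything else is
#' `"non-HLA"`). All coordinates are 0-based half-open internally; BED output
#' is native and 1-based positions are converted at the reader boundary.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param fragment_size_mean Mean restriction-fragment length in bp. Fragment
#'   lengths are drawn from a geometric distribution around this mean and
#'   truncated so that fragments tile each chromosome exactly, emulating a
#'   restriction digest without requiring sequence.
#' @param n_genes,n_snps Number of gene models / catalog SNPs to place.
#' @param hla_like_interval List or vector `(chrom, start, end)` (0-based
#'   half-open) designating the locus whose SNPs get `locus_class = "HLA"`.
#' @param n_hla_snps Optionally force exactly this many SNPs inside the
#'   HLA-like interval (the rest are placed outside). `NULL` places all SNPs
#'   uniformly at random, so the HLA count is whatever falls inside.
#' @param gene_length_range Length-2 vector, min/max gene length in bp.
#'
#' @return A `genome_spec` list.
#' @export
#' @examples
#' genome_spec(c(chrA = 1e5, chrB = 8e4), n_genes = 20, n_snps = 30,
#'             hla_like_interval = list("chrA", 0, 2e4))
genome_spec <- function(chromosomes,
                        fragment_size_mean = 1000,
                        n_genes = 50,
                        n_snps = 100,
                        hla_like_interval = NULL,
                        n_hla_snps = NULL,
                        gene_length_range = c(2000, 20000)) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
    abort("`chromosomes` must be a named vector of lengths")
  }
  if (any(chromosomes <= 0)) abort("all chromosome lengths must be > 0")
  if (fragment_size_mean <= 0) abort("`fragment_size_mean` must be > 0")
  if (n_genes < 0 || n_snps < 0) abort("counts must be non-negative")
  if (is.null(hla_like_interval)) {
    hla_like_interval <- list(names(chromosomes)[1], 0, 0)
  }
  hla <- list(chrom = as.character(hla_like_interval[[1]]),
              start = as.numeric(hla_like_interval[[2]]),
              end = as.numeric(hla_like_interval[[3]]))
  if (!hla$chrom %in% names(chromosomes)) {
    abort("`hla_like_interval` chromosome is not declared")
  }
  if (hla$start < 0 || hla$end > chromosomes[[hla$chrom]] || hla$start > hla$end) {
    abort("`hla_like_interval` must lie within its chromosome")
  }
  if (!is.null(n_hla_snps)) {
    if (n_hla_snps > n_snps) abort("`n_hla_snps` cannot exceed `n_snps`")
    if (n_hla_snps > 0 && hla$end <= hla$start) {
      abort("`n_hla_snps` > 0 requires a non-empty `hla_like_interval`")
    }
  }
  structure(
    list(chromosomes = chromosomes,
         fragment_size_mean = fragment_size_mean,
         n_genes = as.integer(n_genes),
         n_snps = as.integer(n_snps),
         hla_like_interval = hla,
         n_hla_snps = if (is.null(n_hla_snps)) NULL else as.integer(n_hla_snps),
         gene_length_range = as.numeric(gene_length_range)),
    class = "genome_spec"
  )
}

# Geometric-like fragment lengths truncated to tile [0, len) exactly.
tile_chromosome <- function(len, mean_size) {
  lens <- integer(0)
  total <- 0
  while (total < len) {
    k <- max(16L, ceiling((len - total) / mean_size) + 8L)
    draw <- rgeom(k, prob = 1 / mean_size) + 1L
    lens <- c(lens, draw)
    total <- sum(as.double(lens))
    if (total >= len) break
  }
  ends <- cumsum(as.double(lens))
  keep <- which(ends >= len)[1]
  lens <- lens[seq_len(keep)]
  ends <- ends[seq_len(keep)]
  ends[keep] <- len
  starts <- c(0, ends[-keep])
  tibble(start = starts, end = ends)
}

#' Simulate a genome: restriction fragments, gene models and a SNP catalog
#'
#' Fragments tile each chromosome exactly (no gaps, no overlaps, 0-based
#' half-open). Genes get a uniform random start, a length drawn from the
#' spec's range, a random strand and a strand-aware TSS. SNPs get unique
#' positions, a GWAS-scale trait p-value and a regulatory score in `[0, 1]`;
#' `locus_class` is `"HLA"` iff the SNP lies inside the spec's HLA-like
#' interval (half-open, so a SNP at exactly `end` is non-HLA).
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; identical `(spec, seed)` gives identical output.
#'
#' @return A list with tibbles `fragments` (chrom, start, end, fragment_id),
#'   `genes` (chrom, start, end, gene_id, score, strand, tss) and `snps`
#'   (snp_id, chrom, pos, trait_p, locus_class, regulatory_score).
#' @export
simulate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  capacity <- sum(as.double(spec$chromosomes))
  if (spec$n_snps > capacity) {
    abort(sprintf("cannot place %d SNPs: genome has only %.0f positions",
                  spec$n_snps, capacity))
  }
  with_seed(substream_seed(seed, "genome"), {
    chroms <- names(spec$chromosomes)

    fragments <- purrr::map_dfr(chroms, function(ch) {
      tile_chromosome(spec$chromosomes[[ch]], spec$fragment_size_mean) |>
        mutate(chrom = ch, .before = 1)
    })
    fragments$fragment_id <- make_ids("F", nrow(fragments))

    glen_lo <- spec$gene_length_range[1]
    glen_hi <- spec$gene_length_range[2]
    gene_chrom <- sample(chroms, spec$n_genes, replace = TRUE,
                         prob = spec$chromosomes)
    glen <- pmin(round(runif(spec$n_genes, glen_lo, glen_hi)),
                 spec$chromosomes[gene_chrom] - 1)
    gstart <- floor(runif(spec$n_genes) * (spec$chromosomes[gene_chrom] - glen))
    strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
    genes <- tibble(
      chrom = gene_chrom, start = as.numeric(gstart),
      end = as.numeric(gstart + glen),
      gene_id = make_ids("G", spec$n_genes, width = 4L),
      score = ".", strand = strand,
      tss = ifelse(strand == "+", as.numeric(gstart),
                   as.numeric(gstart + glen - 1))
    )

    snps <- draw_snp_positions(spec)
    n <- nrow(snps)
    hla <- spec$hla_like_interval
    snps <- snps |>
      mutate(
        snp_id = make_ids("rsS", n, width = 5L),
        trait_p = 10^(-runif(n, 5.05, 12)),
        locus_class = ifelse(.data$chrom == hla$chrom &
                               .data$pos >= hla$start & .data$pos < hla$end,
                             "HLA", "non-HLA"),
        regulatory_score = runif(n)
      ) |>
      select("snp_id", "chrom", "pos", "trait_p", "locus_class",
             "regulatory_score")

    list(fragments = fragments, genes = genes, snps = snps)
  })
}

# Unique SNP positions, optionally forcing a count inside the HLA interval.
draw_snp_positions <- function(spec) {
  hla <- spec$hla_like_interval
  sample_positions <- function(n, chrom_lens, exclude_hla = FALSE) {
    if (n == 0L) return(tibble(chrom = character(), pos = numeric()))
    out <- tibble(chrom = character(), pos = numeric())
    guard <- 0L
    while (nrow(out) < n && guard < 50L) {
      need <- (n - nrow(out)) * 2L + 10L
      ch <- sample(names(chrom_lens), need, replace = TRUE, prob = chrom_lens)
      pos <- floor(runif(need) * chrom_lens[ch])
      cand <- tibble(chrom = ch, pos = as.numeric(pos))
      if (exclude_hla) {
        cand <- filter(cand, !(.data$chrom == hla$chrom &
                                 .data$pos >= hla$start & .data$pos < hla$end))
      }
      out <- distinct(bind_rows(out, cand), .data$chrom, .data$pos)
      guard <- guard + 1L
    }
    if (nrow(out) < n) abort("could not place the requested number of SNPs")
    out[seq_len(n), ]
  }
  if (is.null(spec$n_hla_snps)) {
    sample_positions(spec$n_snps, spec$chromosomes)
  } else {
    inside <- if (spec$n_hla_snps > 0) {
      width <- hla$end - hla$start
      pos <- hla$start + sample.int(width, spec$n_hla_snps,
                                    replace = spec$n_hla_snps > width) - 1
      tibble(chrom = hla$chrom, pos = as.numeric(unique(pos)))
    } else tibble(chrom = character(), pos = numeric())
    while (nrow(inside) < spec$n_hla_snps) {
      extra <- hla$start + sample.int(hla$end - hla$start, 1) - 1
      inside <- distinct(bind_rows(inside, tibble(chrom = hla$chrom,
                                                  pos = as.numeric(extra))),
                         .data$chrom, .data$pos)
    }
    outside <- sample_positions(spec$n_snps - spec$n_hla_snps,
                                spec$chromosomes, exclude_hla = TRUE)
    bind_rows(inside, outside)
  }
}

#' Plant eQTL effects with a chosen cis/trans composition
#'
#' Picks `n_cis` SNP-gene pairs on the same chromosome within `cis_distance`
#' of the TSS and `n_trans` pairs beyond it (or on different chromosomes),
#' each with effect size `beta` (expression change per alternate allele, in
#' residual-SD units) in the given tissues. SNPs and genes are not reused
#' across pairs, so planted effects are disjoint and individually
#' recoverable.
#'
#' @param snps,genes Tibbles from [simulate_genome()].
#' @param tissues Character vector of tissue ids to plant each effect in.
#' @param n_cis,n_trans Number of cis / trans pairs to plant.
#' @param beta Planted slope (scalar, recycled).
#' @param cis_distance Cis window in bp (default 1 Mb).
#' @param hla_only If `TRUE`, cis SNPs are drawn from HLA-class SNPs only.
#' @param seed Integer seed.
#'
#' @return Long tibble, one row per (snp, gene, tissue):
#'   `snp_id, gene_id, tissue_id, beta, is_trans`.
#' @export
plant_effects <- function(snps, genes, tissues, n_cis, n_trans,
                          beta = 1, cis_distance = 1e6,
                          hla_only = FALSE, seed = 1L) {
  with_seed(substream_seed(seed, "plant"), {
    snp_pool <- if (hla_only) filter(snps, .data$locus_class == "HLA") else snps
    cand <- dplyr::cross_join(
      select(snp_pool, "snp_id", snp_chrom = "chrom", "pos"),
      select(genes, "gene_id", gene_chrom = "chrom", "tss")
    ) |>
      mutate(cis = .data$snp_chrom == .data$gene_chrom &
               abs(.data$tss - .data$pos) < cis_distance)
    pick_disjoint <- function(pool, k) {
      if (k == 0) return(pool[0, ])
      pool <- pool[sample.int(nrow(pool)), ]
      out <- pool[0, ]
      for (i in seq_len(nrow(pool))) {
        r <- pool[i, ]
        if (!r$snp_id %in% out$snp_id && !r$gene_id %in% out$gene_id) {
          out <- bind_rows(out, r)
          if (nrow(out) == k) break
        }
      }
      if (nrow(out) < k) abort("not enough disjoint SNP-gene pairs to plant")
      out
    }
    cis_pairs <- pick_disjoint(filter(cand, .data$cis), n_cis)
    used <- bind_rows(cis_pairs)
    trans_pool <- filter(cand, !.data$cis,
                         !.data$snp_id %in% used$snp_id,
                         !.data$gene_id %in% used$gene_id)
    trans_pairs <- pick_disjoint(trans_pool, n_trans)
    pairs <- bind_rows(mutate(cis_pairs, is_trans = FALSE),
                       mutate(trans_pairs, is_trans = TRUE))
    tidyr::crossing(select(pairs, "snp_id", "gene_id", "is_trans"),
                    tissue_id = tissues) |>
      mutate(beta = beta) |>
      select("snp_id", "gene_id", "tissue_id", "beta", "is_trans") |>
      arrange(.data$snp_id, .data$gene_id, .data$tissue_id)
  })
}

#' Simulate a Hi-C fragment-contact list
#'
#' Guarantees that every planted SNP-gene pair is spatially supported: the
#' SNP's fragment is paired with a fragment overlapping the gene (the one
#' containing the TSS). Background contacts between uniformly random fragment
#' pairs are added at `background_rate` expected contacts per fragment pair.
#' Pairs are stored with the lexicographically smaller fragment first, one
#' row per contact event with a count >= 1 and a source cell line.
#'
#' @param fragments,genes,snps Tibbles from [simulate_genome()].
#' @param planted Planted-effect tibble ([plant_effects()]); only the distinct
#'   `(snp_id, gene_id)` pairs are used. May be empty.
#' @param background_rate Expected background contacts per unordered fragment
#'   pair (default 0).
#' @param cell_lines Cell-line labels sampled per contact.
#' @param seed Integer seed.
#'
#' @return Tibble `frag_id_a, frag_id_b, count, cell_line`.
#' @export
simulate_contacts <- function(fragments, genes, snps, planted,
                              background_rate = 0,
                              cell_lines = c("GM12878", "IMR90", "HMEC",
                                             "NHEK", "HUVEC"),
                              seed = 1L) {
  assert_cols(fragments, c("chrom", "start", "end", "fragment_id"), "fragments")
  pairs <- distinct(planted, .data$snp_id, .data$gene_id)
  bad <- setdiff(pairs$snp_id, snps$snp_id)
  if (length(bad)) abort(paste("planted SNP(s) not in catalog:",
                               paste(bad, collapse = ", ")))
  bad <- setdiff(pairs$gene_id, genes$gene_id)
  if (length(bad)) abort(paste("planted gene(s) unknown:",
                               paste(bad, collapse = ", ")))

  with_seed(substream_seed(seed, "contacts"), {
    snp_frag <- assign_to_fragments(
      tibble(id = snps$snp_id, chrom = snps$chrom,
             start = snps$pos, end = snps$pos + 1),
      fragments
    )
    tss_frag <- assign_to_fragments(
      tibble(id = genes$gene_id, chrom = genes$chrom,
             start = genes$tss, end = genes$tss + 1),
      fragments
    )
    required <- pairs |>
      left_join(setNames(snp_frag[c("id", "fragment_id")], c("snp_id", "fa")),
                by = "snp_id") |>
      left_join(setNames(tss_frag[c("id", "fragment_id")], c("gene_id", "fb")),
                by = "gene_id")
    req <- tibble(
      frag_id_a = pmin(required$fa, required$fb),
      frag_id_b = pmax(required$fa, required$fb),
      count = 1L + rpois(nrow(required), 2),
      cell_line = if (nrow(required)) sample(cell_lines, nrow(required),
                                             replace = TRUE) else character()
    )

    n_frag <- nrow(fragments)
    n_pairs <- n_frag * (n_frag - 1) / 2
    n_bg <- rpois(1, background_rate * n_pairs)
    bg <- NULL
    if (n_bg > 0) {
      i <- sample.int(n_frag, n_bg, replace = TRUE)
      j <- sample.int(n_frag, n_bg, replace = TRUE)
      keep <- i != j
      i <- i[keep]; j <- j[keep]
      bg <- tibble(
        frag_id_a = pmin(fragments$fragment_id[i], fragments$fragment_id[j]),
        frag_id_b = pmax(fragments$fragment_id[i], fragments$fragment_id[j]),
        count = 1L + rpois(length(i), 0.5),
        cell_line = sample(cell_lines, length(i), replace = TRUE)
      )
    }
    bind_rows(req, bg) |> arrange(.data$frag_id_a, .data$frag_id_b)
  })
}

#' Simulate a biallelic genotype panel under Hardy-Weinberg equilibrium
#'
#' Dosages (0/1/2 copies of the alternate allele) are drawn as
#' `Binomial(2, maf)` per SNP and sample; optional missingness is applied
#' uniformly at random.
#'
#' @param snps SNP tibble ([simulate_genome()]).
#' @param n_samples Number of samples.
#' @param maf Per-SNP minor-allele frequency; `NULL` draws `Uniform(0.05, 0.5)`
#'   per SNP, a scalar is recycled, or supply a vector of length `nrow(snps)`.
#' @param missing_rate Probability a dosage is missing (`NA`), default 0.
#' @param seed Integer seed.
#'
#' @return Tibble with `snp_id` and one integer column per sample
#'   (`S000001`, ...). The generating allele frequencies are kept in
#'   `attr(, "maf")`.
#' @export
simulate_genotypes <- function(snps, n_samples, maf = NULL,
                               missing_rate = 0, seed = 1L) {
  n_snps <- nrow(snps)
  with_seed(substream_seed(seed, "genotypes"), {
    if (is.null(maf)) maf <- runif(n_snps, 0.05, 0.5)
    maf <- rep_len(maf, n_snps)
    dos <- matrix(rbinom(n_snps * n_samples, 2L,
                         rep(maf, times = n_samples)),
                  nrow = n_snps, ncol = n_samples)
    if (missing_rate > 0) {
      dos[runif(length(dos)) < missing_rate] <- NA_integer_
    }
    samples <- make_ids("S", n_samples)
    out <- as_tibble(as.data.frame(dos), .name_repair = ~samples)
    out <- bind_cols(tibble(snp_id = snps$snp_id), out)
    attr(out, "maf") <- setNames(maf, snps$snp_id)
    out
  })
}

#' Simulate multi-tissue expression with planted additive eQTL effects
#'
#' Each tissue's expression is an independent Gaussian noise matrix (genes x
#' samples, residual-SD scale); for every planted effect targeting a (gene,
#' tissue), `beta * dosage(snp)` is added to that gene's values. Genes with no
#' planted effect are pure noise. Missing dosages contribute the SNP's mean
#' dosage so that planted means stay unbiased.
#'
#' @param genotypes Genotype tibble ([simulate_genotypes()]).
#' @param genes Gene tibble.
#' @param tissues Character vector of tissue ids.
#' @param planted Planted-effect tibble (may be empty).
#' @param noise_sd Residual standard deviation (default 1).
#' @param samples Samples per tissue: `NULL` uses every genotyped sample in
#'   every tissue, or a named list of sample-id vectors per tissue.
#' @param min_samples Refuse tissues with fewer samples than this (default 70,
#'   mirroring the donor floor used by the expression reference the model
#'   emulates).
#' @param seed Integer seed.
#'
#' @return Named list (one per tissue) of tibbles `gene_id` + sample columns.
#' @export
simulate_expression <- function(genotypes, genes, tissues, planted,
                                noise_sd = 1, samples = NULL,
                                min_samples = 70, seed = 1L) {
  stopifnot(all(is.finite(planted$beta)))
  geno <- panel_matrix(genotypes, "snp_id")
  all_samples <- colnames(geno)
  with_seed(substream_seed(seed, "expression"), {
    out <- lapply(tissues, function(t) {
      smp <- if (is.null(samples)) all_samples else samples[[t]]
      if (length(smp) < min_samples) {
        abort(sprintf("tissue '%s' has %d samples; minimum is %d",
                      t, length(smp), min_samples))
      }
      E <- matrix(rnorm(nrow(genes) * length(smp), 0, noise_sd),
                  nrow = nrow(genes),
                  dimnames = list(genes$gene_id, smp))
      eff <- filter(planted, .data$tissue_id == t)
      for (i in seq_len(nrow(eff))) {
        d <- geno[eff$snp_id[i], smp]
        if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
        E[eff$gene_id[i], ] <- E[eff$gene_id[i], ] + eff$beta[i] * d
      }
      bind_cols(tibble(gene_id = rownames(E)),
                as_tibble(as.data.frame(E), .name_repair = ~smp))
    })
    setNames(out, tissues)
  })
}

#' Simulate a paired-SNP genotype panel with controlled haplotype LD
#'
#' Draws `2n` haplotypes for two biallelic loci with alternate-allele
#' frequencies `p` and `q` and normalized disequilibrium `dprime`, then sums
#' haplotype pairs into unphased dosages. Under D' = 1 the haplotype r-squared
#' has the closed form `pq / ((1-p)(1-q))` for `p + q <= 1`, which the
#' composite genotypic estimator should recover at large n.
#'
#' @param n Number of diploid samples.
#' @param p,q Alternate-allele frequencies at the two loci.
#' @param dprime Normalized LD coefficient D' in `[0, 1]`.
#' @param seed Integer seed.
#'
#' @return Tibble `sample_id, dosage_a, dosage_b`; `attr(, "expected_r2")`
#'   holds the analytic haplotype r-squared.
#' @export
simulate_haplotype_pair <- function(n, p, q, dprime = 1, seed = 1L) {
  stopifnot(p > 0, p < 1, q > 0, q < 1, dprime >= 0, dprime <= 1)
  d_max <- min(p * (1 - q), (1 - p) * q)
  D <- dprime * d_max
  hap <- c(ab = (1 - p) * (1 - q) + D, aB = (1 - p) * q - D,
           Ab = p * (1 - q) - D, AB = p * q + D)
  stopifnot(all(hap > -1e-12))
  hap <- pmax(hap, 0)
  alt_a <- c(ab = 0, aB = 0, Ab = 1, AB = 1)
  alt_b <- c(ab = 0, aB = 1, Ab = 0, AB = 1)
  with_seed(substream_seed(seed, "haplotypes"), {
    h1 <- sample(names(hap), n, replace = TRUE, prob = hap)
    h2 <- sample(names(hap), n, replace = TRUE, prob = hap)
    out <- tibble(
      sample_id = make_ids("S", n),
      dosage_a = alt_a[h1] + alt_a[h2],
      dosage_b = alt_b[h1] + alt_b[h2]
    )
    attr(out, "expected_r2") <- D^2 / (p * (1 - p) * q * (1 - q))
    out
  })
}

#' Simulate a complete spatial-eQTL study with known ground truth
#'
#' One call produces every pipeline input: genome (fragments, genes, SNP
#' catalog), planted effects, Hi-C contacts guaranteed to support each planted
#' pair, a genotype panel, and per-tissue expression. The returned `truth`
#' tibble is the planted ground truth used by the recovery tests.
#'
#' @param spec A [genome_spec()].
#' @param tissues Tissue ids.
#' @param n_cis,n_trans Planted cis / trans pair counts.
#' @param beta Planted effect size.
#' @param n_samples Genotyped samples.
#' @param background_rate Background Hi-C contact rate per fragment pair.
#' @param noise_sd Expression residual SD.
#' @param maf Minor-allele frequency (see [simulate_genotypes()]).
#' @param planted_tissues Tissues each effect is planted in: `"all"`
#'   (default) or an integer number of tissues sampled per effect.
#' @param hla_cis_only Plant cis effects on HLA-class SNPs only.
#' @param seed Integer seed; every stage derives its own substream from it.
#'
#' @return List: `fragments, genes, snps, truth, contacts, genotypes,
#'   expression` (named list of tissue tibbles), `tissues`, `seed`.
#' @export
simulate_study <- function(spec, tissues, n_cis, n_trans,
                           beta = 1.5, n_samples = 200,
                           background_rate = 0, noise_sd = 1,
                           maf = NULL, planted_tissues = "all",
                           hla_cis_only = FALSE, seed = 1L) {
  genome <- simulate_genome(spec, seed)
  truth <- plant_effects(genome$snps, genome$genes, tissues,
                         n_cis = n_cis, n_trans = n_trans, beta = beta,
                         hla_only = hla_cis_only, seed = seed)
  if (!identical(planted_tissues, "all")) {
    k <- as.integer(planted_tissues)
    pairs <- distinct(truth, .data$snp_id, .data$gene_id)
    keep <- with_seed(substream_seed(seed, "planted_tissues"), {
      purrr::map_dfr(seq_len(nrow(pairs)), function(i)
        tibble(snp_id = pairs$snp_id[i], gene_id = pairs$gene_id[i],
               tissue_id = sample(tissues, k)))
    })
    truth <- dplyr::semi_join(truth, keep,
                              by = c("snp_id", "gene_id", "tissue_id"))
  }
  contacts <- simulate_contacts(genome$fragments, genome$genes, genome$snps,
                                truth, background_rate = background_rate,
                                seed = seed)
  genotypes <- simulate_genotypes(genome$snps, n_samples, maf = maf,
                                  seed = seed)
  expression <- simulate_expression(genotypes, genome$genes, tissues, truth,
                                    noise_sd = noise_sd, seed = seed)
  list(fragments = genome$fragments, genes = genome$genes,
       snps = genome$snps, truth = truth, contacts = contacts,
       genotypes = genotypes, expression = expression,
       tissues = tissues, seed = as.integer(seed))
}

#' The packaged demonstration study configuration
#'
#' A fixed small study used throughout the documentation and the regression
#' tests: two chromosomes, an HLA-like locus on the first, five planted cis
#' and two planted trans effects at strong effect size in every tissue, no
#' background contacts, 200 samples, four tissues.
#'
#' @param seed Integer seed (default 20260101).
#' @return The [simulate_study()] result list.
#' @export
demo_study <- function(seed = 20260101L) {
  spec <- genome_spec(
    chromosomes = c(chr1 = 4e6, chr2 = 3e6),
    fragment_size_mean = 4000,
    n_genes = 80,
    n_snps = 60,
    hla_like_interval = list("chr1", 1e6, 1.5e6),
    n_hla_snps = 15
  )
  simulate_study(spec,
                 tissues = c("pancreas", "whole_blood", "thyroid", "lung"),
                 n_cis = 5, n_trans = 2, beta = 2, n_samples = 200,
                 background_rate = 0, noise_sd = 1, seed = seed)
}
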