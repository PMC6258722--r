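# Independent oracles and small fixture builders shared across test files.

# Brute-force Benjamini-Hochberg step-up: for each p_i, the minimum over all
# j with p_j >= p_i of (m / rank_j) * p_j, capped at 1. Quadratic loop, no
# cummin shortcut.
brute_bh <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  L <- length(p)
  q <- numeric(L)
  for (k in seq_len(L)) {
    j <- k:L
    q[k] <- min(1, min((m / j) * ps[j]))
  }
  out <- numeric(L)
  out[o] <- q
  out
}

# Exhaustive two-sided Fisher exact p: enumerate every table with the
# observed margins and sum the probabilities of tables whose point
# probability does not exceed the observed one (with the conventional
# one-part-in-1e7 tie tolerance).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  supp <- max(0, k - n):min(k, m)
  probs <- dhyper(supp, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive linear-scan point-to-fragment assignment.
brute_assign <- function(chrom, pos, fragments) {
  vapply(seq_along(pos), function(i) {
    hit <- which(fragments$chrom == chrom[i] &
                   fragments$start <= pos[i] & pos[i] < fragments$end)
    if (length(hit)) fragments$fragment_id[hit[1]] else NA_character_
  }, character(1))
}

# Naive nested-loop spatial join: for every SNP x gene, scan the whole
# contact list for a qualifying fragment pair.
brute_spatial_pairs <- function(snps, genes, fragments, contacts,
                                min_count = 1) {
  snp_frag <- brute_assign(snps$chrom, snps$pos, fragments)
  cc <- aggregate(count ~ a + b + cell_line,
                  data = transform(contacts,
                                   a = pmin(frag_id_a, frag_id_b),
                                   b = pmax(frag_id_a, frag_id_b)),
                  FUN = sum)
  out <- NULL
  for (i in seq_len(nrow(snps))) {
    sf <- snp_frag[i]
    if (is.na(sf)) next
    for (j in seq_len(nrow(genes))) {
      gfs <- fragments$fragment_id[fragments$chrom == genes$chrom[j] &
                                     fragments$start < genes$end[j] &
                                     genes$start[j] < fragments$end]
      total <- 0
      qualifies <- FALSE
      for (gf in gfs) {
        a <- min(sf, gf); b <- max(sf, gf)
        rows <- cc[cc$a == a & cc$b == b, ]
        if (nrow(rows)) {
          total <- total + sum(rows$count)
          if (any(rows$count >= min_count)) qualifies <- TRUE
        }
      }
      if (qualifies) {
        out <- rbind(out, data.frame(snp_id = snps$snp_id[i],
                                     gene_id = genes$gene_id[j],
                                     supporting_contacts = total))
      }
    }
  }
  out
}

# Fixed-layout manual fixture: two chromosomes tiled by 1 kb fragments.
manual_fragments <- function(chrom_lens = c(cA = 10000, cB = 8000),
                             size = 1000) {
  do.call(rbind, lapply(names(chrom_lens), function(ch) {
    starts <- seq(0, chrom_lens[[ch]] - size, by = size)
    data.frame(chrom = ch, start = starts, end = starts + size)
  })) |>
    (\(df) {
      df$fragment_id <- sprintf("F%06d", seq_len(nrow(df)))
      tibble::as_tibble(df)
    })()
}

# A small fast study used by several suites.
tiny_study <- function(seed = 7L, tissues = c("t1", "t2"),
                       n_cis = 3, n_trans = 1, beta = 2,
                       n_samples = 100, background_rate = 0) {
  spec <- genome_spec(chromosomes = c(chr1 = 2e6, chr2 = 1.5e6),
                      fragment_size_mean = 5000, n_genes = 40, n_snps = 30,
                      hla_like_interval = list("chr1", 5e5, 8e5),
                      n_hla_snps = 8)
  simulate_study(spec, tissues = tissues, n_cis = n_cis, n_trans = n_trans,
                 beta = beta, n_samples = n_samples,
                 background_rate = background_rate, seed = seed)
}
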