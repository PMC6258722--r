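# Spatial-mapping module: SNP/gene -> restriction-fragment assignment and the
# fragment-contact join that yields candidate SNP-gene pairs.

#' Assign genomic positions to restriction fragments
#'
#' Maps each record to the fragment(s) it overlaps under 0-based half-open
#' coordinates. Point records (width 1) map to the unique fragment containing
#' them; interval records (gene bodies) map to every overlapping fragment.
#' Records overlapping no fragment are returned explicitly with
#' `fragment_id = NA`, never dropped.
#'
#' @param positions Tibble with columns `id, chrom, start, end` (0-based
#'   half-open; for a SNP at position p use `start = p, end = p + 1`).
#' @param fragments Fragment tibble `chrom, start, end, fragment_id` tiling
#'   each chromosome.
#'
#' @return Tibble `id, fragment_id`, one row per (record, overlapping
#'   fragment), plus one `NA` row per unmapped record.
#' @export
#' @examples
#' fr <- tibble::tibble(chrom = "c", start = c(0, 1000), end = c(1000, 2000),
#'                      fragment_id = c("F1", "F2"))
#' assign_to_fragments(
#'   tibble::tibble(id = "snp", chrom = "c", start = 1000, end = 1001), fr)
assign_to_fragments <- function(positions, fragments) {
  assert_cols(positions, c("id", "chrom", "start", "end"), "positions")
  assert_cols(fragments, c("chrom", "start", "end", "fragment_id"), "fragments")
  levs <- union(unique(fragments$chrom), unique(positions$chrom))
  fr <- GenomicRanges::GRanges(
    factor(fragments$chrom, levels = levs),
    IRanges::IRanges(start = fragments$start + 1, end = fragments$end)
  )
  qr <- GenomicRanges::GRanges(
    factor(positions$chrom, levels = levs),
    IRanges::IRanges(start = positions$start + 1,
                     end = pmax(positions$end, positions$start + 1))
  )
  hits <- GenomicRanges::findOverlaps(qr, fr)
  mapped <- tibble(
    id = positions$id[S4Vectors::queryHits(hits)],
    fragment_id = fragments$fragment_id[S4Vectors::subjectHits(hits)]
  )
  unmapped <- setdiff(positions$id, mapped$id)
  bind_rows(mapped, tibble(id = unmapped, fragment_id = NA_character_)) |>
    arrange(.data$id, .data$fragment_id)
}

#' Find SNP-gene pairs supported by Hi-C fragment contacts
#'
#' A pair is emitted when the SNP's fragment and any fragment overlapping the
#' gene body appear together in the contact list with a summed count of at
#' least `min_count` in at least one cell line. Contact orientation is
#' ignored (fragment pairs are unordered) and cell lines are pooled, with
#' per-pair provenance retained. A SNP falling inside a fragment that itself
#' overlaps a gene is trivially co-located with that gene and is emitted with
#' `same_fragment = TRUE` even without a recorded contact; set
#' `include_same_fragment = FALSE` to drop such pairs.
#'
#' @param snps SNP tibble (`snp_id, chrom, pos`, ...).
#' @param genes Gene tibble (`gene_id, chrom, start, end`, ...).
#' @param fragments Fragment tibble tiling the genome.
#' @param contacts Contact tibble `frag_id_a, frag_id_b, count, cell_line`.
#' @param min_count Minimum per-cell-line summed contact count (default 1).
#' @param include_same_fragment Keep SNP-in-gene-fragment pairs (default TRUE).
#'
#' @return Tibble `snp_id, gene_id, supporting_contacts, n_cell_lines,
#'   cell_lines, snp_fragment_id, same_fragment`, one row per SNP-gene pair.
#' @export
find_spatial_pairs <- function(snps, genes, fragments, contacts,
                               min_count = 1, include_same_fragment = TRUE) {
  assert_cols(contacts, c("frag_id_a", "frag_id_b", "count", "cell_line"),
              "contacts")
  snp_map <- assign_to_fragments(
    tibble(id = snps$snp_id, chrom = snps$chrom,
           start = snps$pos, end = snps$pos + 1),
    fragments
  ) |> rename(snp_id = "id", snp_fragment_id = "fragment_id")
  if (anyNA(snp_map$snp_fragment_id)) {
    warn(sprintf("%d SNP(s) map to no fragment and are excluded",
                 sum(is.na(snp_map$snp_fragment_id))))
    snp_map <- filter(snp_map, !is.na(.data$snp_fragment_id))
  }
  gene_map <- assign_to_fragments(
    tibble(id = genes$gene_id, chrom = genes$chrom,
           start = genes$start, end = genes$end),
    fragments
  ) |> rename(gene_id = "id", gene_fragment_id = "fragment_id") |>
    filter(!is.na(.data$gene_fragment_id))

  if (nrow(contacts) == 0) {
    warn("contact table is empty")
  }
  bad <- setdiff(c(contacts$frag_id_a, contacts$frag_id_b),
                 fragments$fragment_id)
  if (length(bad)) {
    abort(paste("contacts reference unknown fragment(s):",
                paste(head(bad, 5), collapse = ", ")))
  }

  # Canonicalize and pool: per-(pair, cell line) summed counts; a pair
  # qualifies when any cell line reaches min_count.
  cc <- if (nrow(contacts) == 0) {
    tibble(a = character(), b = character(), total = numeric(),
           best_cell = numeric(), n_cell_lines = integer(),
           cell_lines = character())
  } else contacts |>
    mutate(a = pmin(.data$frag_id_a, .data$frag_id_b),
           b = pmax(.data$frag_id_a, .data$frag_id_b)) |>
    group_by(.data$a, .data$b, .data$cell_line) |>
    summarise(count = sum(.data$count), .groups = "drop_last") |>
    summarise(total = sum(.data$count),
              best_cell = max(.data$count),
              n_cell_lines = n_distinct(.data$cell_line),
              cell_lines = paste(sort(unique(.data$cell_line)),
                                 collapse = ","),
              .groups = "drop") |>
    filter(.data$best_cell >= min_count)

  both_dir <- bind_rows(
    cc |> rename(sf = "a", gf = "b"),
    cc |> filter(.data$a != .data$b) |> rename(sf = "b", gf = "a")
  )

  via_contacts <- snp_map |>
    inner_join(both_dir, by = c(snp_fragment_id = "sf"),
               relationship = "many-to-many") |>
    inner_join(gene_map, by = c(gf = "gene_fragment_id"),
               relationship = "many-to-many") |>
    group_by(.data$snp_id, .data$gene_id, .data$snp_fragment_id) |>
    summarise(supporting_contacts = sum(.data$total),
              cell_lines = paste(sort(unique(unlist(
                strsplit(.data$cell_lines, ",", fixed = TRUE)))),
                collapse = ","),
              .groups = "drop") |>
    mutate(n_cell_lines = lengths(strsplit(.data$cell_lines, ",",
                                           fixed = TRUE)),
           same_fragment = FALSE)

  out <- via_contacts
  if (include_same_fragment) {
    same <- snp_map |>
      inner_join(gene_map, by = c(snp_fragment_id = "gene_fragment_id"),
                 relationship = "many-to-many") |>
      distinct(.data$snp_id, .data$gene_id, .data$snp_fragment_id) |>
      mutate(supporting_contacts = 1L, n_cell_lines = 0L,
             cell_lines = "", same_fragment = TRUE)
    out <- bind_rows(via_contacts, anti_join(same, via_contacts,
                                             by = c("snp_id", "gene_id")))
    # a pair supported both ways keeps its contact evidence but is flagged
    flagged <- dplyr::semi_join(via_contacts, same,
                                by = c("snp_id", "gene_id"))
    if (nrow(flagged)) {
      out <- out |>
        mutate(same_fragment = .data$same_fragment |
                 paste(.data$snp_id, .data$gene_id) %in%
                 paste(flagged$snp_id, flagged$gene_id))
    }
  }
  out |>
    select("snp_id", "gene_id", "supporting_contacts", "n_cell_lines",
           "cell_lines", "snp_fragment_id", "same_fragment") |>
    arrange(.data$snp_id, .data$gene_id)
}
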