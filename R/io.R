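# Readers and writers for the pipeline's plain-text interchange formats.
# Coordinates are 0-based half-open internally; BED is written natively and
# 1-based SNP positions are converted at this boundary.

#' Write a simulated study to a directory of plain-text files
#'
#' Emits `fragments.bed` (chrom, start, end, fragment_id), `genes.bed`
#' (chrom, start, end, gene_id, score, strand), `snps.tsv` (with 1-based
#' `pos_1based`), `contacts.tsv`, `genotypes.tsv` (SNP x sample),
#' `expression.<tissue>.tsv` (gene x sample) and `truth.tsv`.
#'
#' @param study A [simulate_study()] result list.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$fragments[c("chrom", "start", "end", "fragment_id")],
                   file.path(dir, "fragments.bed"), col_names = FALSE)
  readr::write_tsv(study$genes[c("chrom", "start", "end", "gene_id",
                                 "score", "strand")],
                   file.path(dir, "genes.bed"), col_names = FALSE)
  snps_out <- study$snps |>
    mutate(pos_1based = .data$pos + 1) |>
    select("snp_id", "chrom", "pos_1based", "trait_p", "locus_class",
           "regulatory_score")
  readr::write_tsv(snps_out, file.path(dir, "snps.tsv"))
  readr::write_tsv(study$contacts, file.path(dir, "contacts.tsv"))
  readr::write_tsv(study$genotypes, file.path(dir, "genotypes.tsv"))
  for (t in names(study$expression)) {
    readr::write_tsv(study$expression[[t]],
                     file.path(dir, sprintf("expression.%s.tsv", t)))
  }
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read study inputs back from a directory
#'
#' Inverse of [write_study()]: reconstructs the input list (0-based internal
#' coordinates; gene TSS re-derived from strand).
#'
#' @param dir Directory holding the interchange files.
#' @return A study list (`fragments, genes, snps, contacts, genotypes,
#'   expression, tissues`; `truth` when `truth.tsv` is present).
#' @export
read_study <- function(dir) {
  fragments <- readr::read_tsv(
    file.path(dir, "fragments.bed"),
    col_names = c("chrom", "start", "end", "fragment_id"),
    col_types = "cddc", progress = FALSE)
  genes <- readr::read_tsv(
    file.path(dir, "genes.bed"),
    col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
    col_types = "cddccc", progress = FALSE) |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1))
  snps <- readr::read_tsv(file.path(dir, "snps.tsv"), progress = FALSE,
                          show_col_types = FALSE) |>
    mutate(pos = .data$pos_1based - 1) |>
    select("snp_id", "chrom", "pos", "trait_p", "locus_class",
           "regulatory_score")
  contacts <- readr::read_tsv(file.path(dir, "contacts.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  genotypes <- readr::read_tsv(file.path(dir, "genotypes.tsv"),
                               show_col_types = FALSE, progress = FALSE)
  expr_files <- list.files(dir, pattern = "^expression\\..+\\.tsv$")
  tissues <- sub("^expression\\.(.+)\\.tsv$", "\\1", expr_files)
  expression <- setNames(lapply(expr_files, function(f)
    readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                    progress = FALSE)), tissues)
  out <- list(fragments = fragments, genes = genes, snps = snps,
              contacts = contacts, genotypes = genotypes,
              expression = expression, tissues = tissues)
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_tsv(truth_path, show_col_types = FALSE,
                                 progress = FALSE)
  }
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description, then
#' member gene ids.
#'
#' @param path Path to the `.gmt` file.
#' @return Named list of gene-id character vectors; descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("malformed GMT line(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2),
                                         names(sets))
  sets
}
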