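# LD module: composite (genotypic) r-squared among catalog SNPs.

#' Composite genotypic r-squared between two SNPs
#'
#' Squared Pearson correlation of the 0/1/2 dosage vectors after pairwise
#' deletion of missing values — the standard unphased estimator of haplotype
#' LD, which tracks the haplotype r-squared closely under Hardy-Weinberg
#' equilibrium. Undefined (returned as `NA`) when either SNP is monomorphic
#' after filtering or fewer than 2 complete pairs remain: an undefined
#' correlation must not masquerade as absence of LD.
#'
#' @param dosage_a,dosage_b Numeric dosage vectors of equal length.
#' @return Scalar r-squared in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' pairwise_r2(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0))
pairwise_r2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b))
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  x <- dosage_a[ok]; y <- dosage_b[ok]
  if (length(x) < 2 || var(x) == 0 || var(y) == 0) return(NA_real_)
  min(cor(x, y)^2, 1)
}

#' Pairwise LD matrix with linkage-strength labels
#'
#' Computes the composite r-squared for every unordered pair among the
#' selected SNPs (`C(n, 2)` rows) and labels each pair: `robust` when
#' r-squared > 0.8 (the conventional threshold for robust linkage), `weak`
#' when <= 0.6, `intermediate` in between. The maximum off-diagonal
#' r-squared is kept as an attribute.
#'
#' @param genotypes Genotype tibble (`snp_id` + sample columns).
#' @param snp_ids SNPs to profile; `NULL` uses all (>= 2 required).
#'
#' @return Tibble of class `ld_result`: `snp_a, snp_b, r_squared, n_samples,
#'   strength`; `attr(, "max_r2")` holds the maximum pairwise value
#'   (`NA` if every pair is undefined). [glance()] and [autoplot()] methods
#'   are provided.
#' @export
ld_matrix <- function(genotypes, snp_ids = NULL) {
  geno <- panel_matrix(genotypes, "snp_id")
  if (!is.null(snp_ids)) {
    missing <- setdiff(snp_ids, rownames(geno))
    if (length(missing)) {
      abort(paste("SNP(s) not in the genotype panel:",
                  paste(head(missing, 5), collapse = ", ")))
    }
    geno <- geno[snp_ids, , drop = FALSE]
  }
  if (nrow(geno) < 2) abort("need at least 2 SNPs")
  idx <- combn(rownames(geno), 2)
  rows <- purrr::map_dfr(seq_len(ncol(idx)), function(j) {
    a <- idx[1, j]; b <- idx[2, j]
    ok <- !is.na(geno[a, ]) & !is.na(geno[b, ])
    tibble(snp_a = a, snp_b = b,
           r_squared = pairwise_r2(geno[a, ], geno[b, ]),
           n_samples = sum(ok))
  })
  rows <- mutate(rows, strength = dplyr::case_when(
    is.na(.data$r_squared) ~ NA_character_,
    .data$r_squared > 0.8 ~ "robust",
    .data$r_squared <= 0.6 ~ "weak",
    TRUE ~ "intermediate"
  ))
  max_r2 <- if (all(is.na(rows$r_squared))) NA_real_ else
    max(rows$r_squared, na.rm = TRUE)
  structure(rows, class = c("ld_result", class(rows)), max_r2 = max_r2)
}

#' @export
glance.ld_result <- function(x, ...) {
  tibble(n_pairs = nrow(x), max_r2 = attr(x, "max_r2"),
         n_robust = sum(x$strength == "robust", na.rm = TRUE),
         n_weak = sum(x$strength == "weak", na.rm = TRUE),
         n_undefined = sum(is.na(x$r_squared)))
}

#' @export
autoplot.ld_result <- function(object, ...) {
  df <- as_tibble(object)
  both <- bind_rows(df, rename(df, snp_a = "snp_b", snp_b = "snp_a"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$snp_a, y = .data$snp_b,
                                     fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(R^2)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
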