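# RNA-seq support: expression-based copy-number inference by gene-window
# moving averages, and binomial dropout-aware validation of genomic
# variants.

#' Infer relative copy-number scores from expression
#'
#' Per gene, `log2(TPM + 1)` is centered across samples; a center-aligned
#' moving average over `window` genes (truncated at chromosome ends) smooths
#' out single-gene effects; finally each gene's mean windowed value over the
#' normal samples is subtracted, so scores sit near zero in normals and
#' deviate with copy number in tumors. Chromosomes with fewer genes than the
#' window are skipped with a warning.
#'
#' @param expr Tibble with columns `gene`, `chrom`, `start`, then one column
#'   per sample of TPM values.
#' @param normals Character vector of normal-sample column names.
#' @param window Moving-average window in genes; default 101 (odd).
#' @return Long tibble (`gene`, `chrom`, `start`, `sample`, `score`).
#' @export
infer_expression_cnv <- function(expr, normals, window = 101) {
  stopifnot(all(c("gene", "chrom", "start") %in% names(expr)))
  if (length(normals) == 0) abort("need at least one normal sample")
  samples <- setdiff(names(expr), c("gene", "chrom", "start", "end"))
  if (!all(normals %in% samples)) abort("normal sample(s) missing from expression matrix")
  expr <- expr |> arrange(.data$chrom, .data$start)
  small <- expr |> dplyr::count(.data$chrom) |> filter(.data$n < window)
  if (nrow(small) > 0) {
    warn(paste0("chromosome(s) with fewer than ", window, " genes skipped: ",
                paste(small$chrom, collapse = ", ")))
    expr <- expr |> filter(!.data$chrom %in% small$chrom)
  }
  if (nrow(expr) == 0) {
    return(tibble(gene = character(), chrom = character(), start = integer(),
                  sample = character(), score = double()))
  }
  lv <- log2(as.matrix(expr[samples]) + 1)
  lv <- lv - rowMeans(lv)
  smoothed <- do.call(rbind, lapply(split(seq_len(nrow(expr)), expr$chrom), function(i) {
    apply(lv[i, , drop = FALSE], 2, function(x) {
      zoo::rollapply(x, width = window, FUN = mean, partial = TRUE,
                     align = "center")
    })
  }))
  # split() reorders chromosomes; restore genomic order
  idx <- unlist(split(seq_len(nrow(expr)), expr$chrom))
  smoothed <- smoothed[match(seq_len(nrow(expr)), idx), , drop = FALSE]
  scores <- smoothed - rowMeans(smoothed[, normals, drop = FALSE])
  tibble(gene = rep(expr$gene, times = length(samples)),
         chrom = rep(expr$chrom, times = length(samples)),
         start = rep(expr$start, times = length(samples)),
         sample = rep(samples, each = nrow(expr)),
         score = as.vector(scores))
}

#' Probability of sampling zero alternate reads
#'
#' Under binomial sampling of `rna_depth` reads at the genomic variant
#' allele fraction, the probability that no read carries the alternate
#' allele is \eqn{P_0 = (1 - VAF)^{depth}}. A variant at VAF 0.1 covered by
#' 10 RNA-seq reads has \eqn{P_0 = 0.35}.
#'
#' @param wgs_vaf Genomic variant allele fraction in \[0, 1\].
#' @param rna_depth RNA-seq read depth at the locus.
#' @return Dropout probability.
#' @export
dropout_probability <- function(wgs_vaf, rna_depth) {
  stopifnot(all(wgs_vaf >= 0), all(wgs_vaf <= 1), all(rna_depth >= 0))
  (1 - wgs_vaf)^rna_depth
}

#' Classify RNA-seq validation status of genomic variants
#'
#' Eligible observations (genomic VAF > 0.1, RNA depth >= 10) are
#' classified: any alternate RNA read makes the variant `validated`;
#' otherwise presence of the variant's RNA evidence in another sample
#' genomically carrying it makes it `validated_in_other`; otherwise a
#' dropout probability above `p0_skip` makes it `skipped_dropout`
#' (sampling alone plausibly explains the zero); remaining variants are
#' `not_expressed`.
#'
#' @param obs Tibble with columns `variant_id`, `rna_depth`, `rna_alt`,
#'   `wgs_vaf` and logical `in_other_samples`.
#' @param p0_skip Dropout-probability skip threshold; default 0.05.
#' @param min_vaf,min_depth Eligibility bounds (strict `>` on VAF, `>=` on
#'   depth); defaults 0.1 and 10.
#' @return The eligible rows with `p0` and `category` columns.
#' @export
classify_validation <- function(obs, p0_skip = 0.05, min_vaf = 0.1,
                                min_depth = 10) {
  eligible <- obs |>
    filter(.data$wgs_vaf > min_vaf, .data$rna_depth >= min_depth)
  eligible |>
    mutate(p0 = dropout_probability(.data$wgs_vaf, .data$rna_depth),
           category = dplyr::case_when(
             .data$rna_alt >= 1 ~ "validated",
             .data$in_other_samples ~ "validated_in_other",
             .data$p0 > p0_skip ~ "skipped_dropout",
             TRUE ~ "not_expressed"))
}
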