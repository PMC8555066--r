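# Joint multi-sample variant table: loading, quality filtering, somatic
# calling against matched normals.

#' Load a joint multi-sample VCF into a long variant table
#'
#' Reads a VCF 4.x file (plain or bgzipped) with per-sample depth (`DP`) and
#' allele-depth (`AD`) fields and returns one row per variant x sample with
#' the observed depth, alternate-read count and allele fraction
#' (AF = alt/depth). Sites with more than one ALT allele are split into one
#' record per alternate allele and flagged `multiallelic`; they are removed
#' later by [filter_variants()] rather than at load time. When `AD` is absent
#' the FreeBayes-style `RO`/`AO` pair is used instead; if neither is present
#' loading fails naming the offending sample.
#'
#' @param path Path to a VCF file.
#' @param normal_names Character vector of matched-normal sample names; must
#'   all be present in the VCF header.
#' @return A tibble with columns `variant_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `qual`, `multiallelic`, `sample`, `depth`, `alt_count`,
#'   `af` (`NA` where depth is 0). The normal-sample names are carried in the
#'   `"normals"` attribute.
#' @export
load_vcf <- function(path, normal_names = character()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (length(samples) == 0) abort("VCF declares no samples")
  missing_normals <- setdiff(normal_names, samples)
  if (length(missing_normals) > 0) {
    abort(paste0("normal sample(s) not in VCF: ",
                 paste(missing_normals, collapse = ", ")))
  }
  fix <- v@fix
  if (nrow(fix) == 0) {
    out <- tibble(variant_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  qual = double(), multiallelic = logical(),
                  sample = character(), depth = integer(),
                  alt_count = integer(), af = double())
    attr(out, "normals") <- normal_names
    attr(out, "samples") <- samples
    return(out)
  }

  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  use_ad <- !all(is.na(ad))
  if (!use_ad) {
    ao <- vcfR::extract.gt(v, element = "AO")
    ro <- vcfR::extract.gt(v, element = "RO")
    if (all(is.na(ao))) {
      abort(paste0("no AD (or AO/RO) allele counts for sample ", samples[1]))
    }
  }
  if (all(is.na(dp))) abort(paste0("no DP field for sample ", samples[1]))

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  site_idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))
  alt_vec <- unlist(alt_list)

  sites <- tibble(
    site = site_idx,
    chrom = fix[site_idx, "CHROM"],
    pos = as.integer(fix[site_idx, "POS"]),
    ref = fix[site_idx, "REF"],
    alt = alt_vec,
    qual = suppressWarnings(as.numeric(fix[site_idx, "QUAL"])),
    multiallelic = n_alt[site_idx] > 1L,
    alt_idx = alt_idx
  )

  per_sample <- purrr::map(samples, function(s) {
    depth <- as.integer(dp[site_idx, s])
    if (use_ad) {
      counts <- strsplit(ad[site_idx, s], ",", fixed = TRUE)
      alt_count <- as.integer(purrr::map2_chr(counts, alt_idx + 1L, function(x, i) {
        if (length(x) >= i) x[i] else NA_character_
      }))
    } else {
      ao_counts <- strsplit(ao[site_idx, s], ",", fixed = TRUE)
      alt_count <- as.integer(purrr::map2_chr(ao_counts, alt_idx, function(x, i) {
        if (length(x) >= i) x[i] else NA_character_
      }))
    }
    tibble(sample = s, row = seq_along(site_idx), depth = depth,
           alt_count = alt_count)
  })
  long <- bind_rows(per_sample)
  long <- long |> arrange(.data$row, .data$sample)
  out <- sites[long$row, ] |>
    mutate(sample = long$sample,
           depth = dplyr::coalesce(long$depth, 0L),
           alt_count = dplyr::coalesce(long$alt_count, 0L),
           af = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_),
           variant_id = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    select("variant_id", "chrom", "pos", "ref", "alt", "qual", "multiallelic",
           "sample", "depth", "alt_count", "af")
  attr(out, "normals") <- normal_names
  attr(out, "samples") <- samples
  out
}

# Sample names present in a long variant table (declared order if recorded).
variant_samples <- function(tbl) {
  attr(tbl, "samples") %||% c_sort(unique(tbl$sample))
}

variant_normals <- function(tbl, normals = NULL) {
  normals <- normals %||% attr(tbl, "normals")
  if (is.null(normals) || length(normals) == 0) {
    abort("no normal samples given (pass `normals` or load with `load_vcf`)")
  }
  missing <- setdiff(normals, unique(tbl$sample))
  if (length(missing) > 0) {
    abort(paste0("normal sample(s) absent from table: ",
                 paste(missing, collapse = ", ")))
  }
  normals
}

#' Apply site-quality, depth, mask and multi-allelic filters
#'
#' Retains variants with site quality strictly above `min_quality`, depth
#' strictly above `min_depth` in *every* sample, position inside the
#' accessibility mask (when given), outside the low-complexity mask (when
#' given), and a single alternate allele. Record order is preserved and the
#' operation is idempotent.
#'
#' @param tbl Long variant table from [load_vcf()].
#' @param min_quality Phred site-quality threshold (strict `>`); default 30.
#' @param min_depth Per-sample depth threshold (strict `>`); default 15.
#' @param accessibility Optional keep-inside region mask
#'   (see [read_region_mask()]).
#' @param lcr Optional keep-outside (low-complexity) region mask.
#' @return The filtered variant table (attributes preserved).
#' @export
filter_variants <- function(tbl, min_quality = 30, min_depth = 15,
                            accessibility = NULL, lcr = NULL) {
  stopifnot(min_quality >= 0, min_depth >= 0)
  per_variant <- tbl |>
    group_by(.data$variant_id) |>
    summarise(chrom = first(.data$chrom), pos = first(.data$pos),
              qual = first(.data$qual), multiallelic = first(.data$multiallelic),
              min_dp = min(.data$depth), .groups = "drop")
  keep <- per_variant$qual > min_quality &
    per_variant$min_dp > min_depth &
    !per_variant$multiallelic
  if (!is.null(accessibility)) {
    keep <- keep & pos_in_mask(per_variant$chrom, per_variant$pos, accessibility)
  }
  if (!is.null(lcr)) {
    keep <- keep & !pos_in_mask(per_variant$chrom, per_variant$pos, lcr)
  }
  out <- tbl |> filter(.data$variant_id %in% per_variant$variant_id[keep])
  attr(out, "normals") <- attr(tbl, "normals")
  attr(out, "samples") <- attr(tbl, "samples")
  out
}

#' Call somatic status against matched normal samples
#'
#' A variant is somatic when, in every matched normal, its allele fraction is
#' below 0.1 *or* its alternate-read count is less than five. Variants
#' failing the rule in at least one normal are `inherited`; variants with
#' zero depth in any normal are `indeterminate` (absence in the normal cannot
#' be asserted) and are excluded from the somatic set.
#'
#' @param tbl Long variant table (typically after [filter_variants()]).
#' @param normals Character vector of normal sample names; defaults to the
#'   names recorded by [load_vcf()].
#' @param max_af Normal allele-fraction clause (`af < max_af`); default 0.1.
#' @param max_alt Normal alternate-count clause (`alt_count < max_alt`);
#'   default 5.
#' @return The table with a per-variant `status` column
#'   (`"somatic"`, `"inherited"` or `"indeterminate"`).
#' @export
call_somatic <- function(tbl, normals = NULL, max_af = 0.1, max_alt = 5) {
  normals <- variant_normals(tbl, normals)
  status <- tbl |>
    filter(.data$sample %in% normals) |>
    group_by(.data$variant_id) |>
    summarise(
      any_zero = any(.data$depth == 0),
      all_clear = all(.data$depth == 0 |
                        .data$af < max_af | .data$alt_count < max_alt),
      .groups = "drop") |>
    mutate(status = dplyr::case_when(
      .data$any_zero ~ "indeterminate",
      .data$all_clear ~ "somatic",
      TRUE ~ "inherited")) |>
    select("variant_id", "status")
  n_ind <- sum(status$status == "indeterminate")
  if (n_ind > 0) {
    inform(paste0(n_ind, " variant(s) indeterminate (zero depth in a normal); ",
                  "excluded from the somatic set"))
  }
  out <- tbl |>
    select(-dplyr::any_of("status")) |>
    left_join(status, by = "variant_id")
  attr(out, "normals") <- normals
  attr(out, "samples") <- attr(tbl, "samples")
  out
}

#' Write / read the canonical wide variant table
#'
#' Round-trip tab-delimited export: one row per variant, per-sample
#' `<sample>.DP` / `<sample>.AD` / `<sample>.AF` columns, plus `status` when
#' somatic calling has been run.
#'
#' @param tbl Long variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(tbl, path) {
  wide <- tbl |>
    mutate(af_chr = ifelse(is.na(.data$af), "NA", format(.data$af, digits = 10))) |>
    tidyr::pivot_wider(
      id_cols = c("variant_id", "chrom", "pos", "ref", "alt", "qual",
                  "multiallelic", dplyr::any_of("status")),
      names_from = "sample", values_from = c("depth", "alt_count"),
      names_glue = "{sample}.{.value}")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @param normals Normal-sample names to attach to the restored table.
#' @export
read_variant_table <- function(path, normals = character()) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  samples <- unique(sub("\\.depth$", "", grep("\\.depth$", names(wide), value = TRUE)))
  long <- wide |>
    tidyr::pivot_longer(
      cols = dplyr::matches("\\.(depth|alt_count)$"),
      names_to = c("sample", ".value"), names_sep = "\\.") |>
    mutate(af = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_))
  attr(long, "normals") <- normals
  attr(long, "samples") <- samples
  long
}

#' Write a long variant table as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with `GT:DP:AD` per-sample fields, suitable for
#' round-tripping simulator output through [load_vcf()].
#'
#' @param tbl Long variant table (one alt allele per record).
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(tbl, path) {
  samples <- variant_samples(tbl)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  wide <- tbl |>
    mutate(gt = paste0("0/1:", .data$depth, ":",
                       .data$depth - .data$alt_count, ",", .data$alt_count)) |>
    tidyr::pivot_wider(
      id_cols = c("variant_id", "chrom", "pos", "ref", "alt", "qual"),
      names_from = "sample", values_from = "gt",
      values_fill = "./.:0:0,0") |>
    arrange(.data$chrom, .data$pos, .data$alt)
  gt_cols <- do.call(paste, c(wide[samples], sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.\tGT:DP:AD\t%s",
                  wide$chrom, wide$pos, wide$ref, wide$alt,
                  format(wide$qual, trim = TRUE), gt_cols)
  writeLines(c(header, body), path)
  invisible(path)
}
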