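# Shared fixtures, built in code at test time.

# Ten-record toy VCF on chr1 with samples T1 and two normals. Exactly four
# records each fail one filter rule:
#   pos 100  site quality 30 (not > 30)
#   pos 200  depth 15 in T1 (not > 15)
#   pos 3000 outside the accessibility mask (chr1:0-2500)
#   pos 400  inside the low-complexity mask (chr1:350-450)
# The six survivors (pos 500..1000) all pass; five are somatic (normals
# carry no alternate reads) and one (pos 1000) is an inherited het
# (normals at AF 0.5 with >= 5 alt reads).
write_toy_vcf <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  gt <- function(dp, ad) paste0("0/1:", dp, ":", dp - ad, ",", ad)
  rec <- function(pos, qual, t1, n1, n2, alt = "T") {
    paste("chr1", pos, ".", "A", alt, qual, "PASS", ".", "GT:DP:AD",
          t1, n1, n2, sep = "\t")
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "T1", "N1", "N2", sep = "\t"),
    rec(100, 30, gt(40, 20), gt(40, 0), gt(40, 0)),
    rec(200, 50, gt(15, 8), gt(40, 0), gt(40, 0)),
    rec(3000, 50, gt(40, 20), gt(40, 0), gt(40, 0)),
    rec(400, 50, gt(40, 20), gt(40, 0), gt(40, 0)),
    rec(500, 50, gt(40, 20), gt(40, 0), gt(40, 0)),
    rec(600, 60, gt(38, 15), gt(42, 1), gt(40, 0)),
    rec(700, 70, gt(36, 12), gt(40, 0), gt(40, 2)),
    rec(800, 80, gt(44, 22), gt(40, 3), gt(40, 0)),
    rec(900, 90, gt(50, 30), gt(40, 0), gt(40, 0)),
    rec(1000, 95, gt(40, 22), gt(40, 20), gt(44, 21))
  )
  vcf <- file.path(dir, "toy.vcf")
  writeLines(lines, vcf)
  acc <- file.path(dir, "accessible.bed")
  writeLines("chr1\t0\t2500", acc)
  lcr <- file.path(dir, "lcr.bed")
  writeLines("chr1\t350\t450", lcr)
  list(vcf = vcf, accessibility = acc, lcr = lcr)
}

# Small atlas built directly from a parent map and prevalence matrix.
toy_atlas <- function(parent, prev) {
  subclone_atlas(parent, prev)
}

# Long variant table built from an AF matrix (variants x samples), one
# somatic record per cell, constant depth.
table_from_af <- function(af, depth = 100, status = "somatic",
                          chrom = "chr14") {
  stopifnot(!is.null(colnames(af)))
  ids <- rownames(af) %||% paste0(chrom, ":", seq_len(nrow(af)) * 10, ":A:T")
  rows <- list()
  for (i in seq_len(nrow(af))) {
    for (s in colnames(af)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant_id = ids[i], chrom = chrom, pos = i * 10L,
        ref = "A", alt = "T", qual = 100, multiallelic = FALSE,
        sample = s, depth = depth,
        alt_count = as.integer(round(af[i, s] * depth)),
        af = round(af[i, s] * depth) / depth, status = status)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "samples") <- colnames(af)
  attr(out, "normals") <- character()
  out
}

`%||%` <- rlang::`%||%`
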