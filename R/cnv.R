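# Copy-number profiles: 1-Mb binning of segment log2 ratios, UPGMA sample
# clustering, and CNV-based sample grouping.

#' Bin segment log2 ratios into fixed genomic windows
#'
#' Each bin's value is the segment-length-weighted mean log2 ratio of the
#' segments overlapping it; bins with no segment coverage in a sample are
#' `NA` (missing, never zero-filled). Bin boundaries are identical across
#' samples (taken over the union of covered ranges).
#'
#' @param segments Tibble with columns `sample`, `chrom`, `start`, `end`
#'   (0-based half-open), `total_cn`, `log2_ratio` and optionally `loh`.
#' @param bin_size Window size in bp; default 1e6.
#' @return A long tibble (`sample`, `chrom`, `bin_start`, `bin_end`, `log2`)
#'   with one row per sample x bin, `NA` log2 where uncovered.
#' @export
bin_log2 <- function(segments, bin_size = 1e6) {
  stopifnot(all(c("sample", "chrom", "start", "end", "log2_ratio") %in%
                  names(segments)))
  overlaps <- segments |>
    group_by(.data$sample, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(prev_end = dplyr::lag(.data$end)) |>
    filter(!is.na(.data$prev_end) & .data$start < .data$prev_end)
  if (nrow(overlaps) > 0) {
    bad <- overlaps[1, ]
    abort(sprintf("overlapping segments in sample %s at %s:%d",
                  bad$sample, bad$chrom, bad$start))
  }
  bins <- segments |>
    group_by(.data$chrom) |>
    summarise(max_end = max(.data$end), .groups = "drop") |>
    mutate(bin = purrr::map(.data$max_end, function(e) {
      starts <- seq(0, e - 1, by = bin_size)
      tibble(bin_start = starts, bin_end = pmin(starts + bin_size, e))
    })) |>
    select("chrom", "bin") |>
    tidyr::unnest("bin")
  grid <- tidyr::expand_grid(sample = c_sort(unique(segments$sample)), bins)
  # overlap join: segment [start,end) x bin [bin_start,bin_end)
  joined <- grid |>
    left_join(segments, by = c("sample", "chrom"),
              relationship = "many-to-many") |>
    mutate(ov = pmin(.data$end, .data$bin_end) - pmax(.data$start, .data$bin_start),
           ov = ifelse(!is.na(.data$ov) & .data$ov > 0, .data$ov, NA_real_))
  joined |>
    group_by(.data$sample, .data$chrom, .data$bin_start, .data$bin_end) |>
    summarise(log2 = if (all(is.na(.data$ov))) NA_real_ else {
      sum(.data$log2_ratio[!is.na(.data$ov)] * .data$ov[!is.na(.data$ov)]) /
        sum(.data$ov[!is.na(.data$ov)])
    }, .groups = "drop") |>
    arrange(.data$sample, .data$chrom, .data$bin_start)
}

# Long profile tibble -> samples x bins matrix (bins ordered chrom, start).
profile_matrix <- function(profile) {
  wide <- profile |>
    mutate(bin = paste(.data$chrom, .data$bin_start, sep = ":")) |>
    arrange(.data$chrom, .data$bin_start) |>
    tidyr::pivot_wider(id_cols = "sample", names_from = "bin",
                       values_from = "log2") |>
    arrange(.data$sample)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample
  m
}

# Pairwise Euclidean distance over bins non-missing in both profiles.
pairwise_euclidean <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      d[i, j] <- d[j, i] <- sqrt(sum((m[i, ok] - m[j, ok])^2))
    }
  }
  as.dist(d)
}

#' UPGMA dendrogram over copy-number profiles
#'
#' Samples are compared by Euclidean distance over the bins non-missing in
#' both, then clustered by UPGMA (average linkage). Samples are ordered
#' lexicographically first so tied merges are deterministic.
#'
#' @param profile Long bin tibble from [bin_log2()].
#' @return An `hclust` object (convert with [ape::as.phylo()] for Newick
#'   export).
#' @export
cluster_profiles <- function(profile) {
  m <- profile_matrix(profile)
  if (nrow(m) < 2) abort("need at least 2 samples to cluster")
  hclust(pairwise_euclidean(m), method = "average")
}

#' Group samples by shared copy-number events
#'
#' Cuts the UPGMA dendrogram at the largest gap in merge heights, then keeps
#' a cluster as a group only if its members share at least `shared_event_min`
#' discrete CNV events: maximal runs of consecutive bins whose log2 values
#' deviate beyond `deviation` in the same direction in every member.
#' Remaining samples are `"ungrouped"`. Groups are labeled G1, G2, ... in
#' order of their first member's name.
#'
#' @param profile Long bin tibble from [bin_log2()].
#' @param shared_event_min Minimum shared discrete events; default 2.
#' @param deviation Absolute log2 deviation defining an event bin;
#'   default 0.3.
#' @return Tibble (`sample`, `group`).
#' @export
assign_groups <- function(profile, shared_event_min = 2, deviation = 0.3) {
  m <- profile_matrix(profile)
  if (nrow(m) < 2) {
    return(tibble(sample = rownames(m), group = "G1"))
  }
  hc <- cluster_profiles(profile)
  h <- sort(hc$height)
  if (max(h) - min(h) < 1e-12) {
    members <- list(rownames(m))
  } else {
    gaps <- diff(c(0, h))
    # cut below the largest inter-merge gap
    k <- nrow(m) - (which.max(gaps) - 1L)
    cl <- cutree(hc, k = k)
    members <- split(names(cl), cl)
  }
  bin_meta <- profile |>
    distinct(.data$chrom, .data$bin_start) |>
    arrange(.data$chrom, .data$bin_start)
  grouped <- purrr::map(members, function(s) {
    sub <- m[s, , drop = FALSE]
    up <- apply(sub > deviation, 2, function(x) all(!is.na(x)) && all(x))
    down <- apply(sub < -deviation, 2, function(x) all(!is.na(x)) && all(x))
    hit <- up | down
    # count maximal runs of event bins within a chromosome
    r <- rle(paste0(ifelse(hit, "1", "0"), "@", bin_meta$chrom))
    n_events <- sum(grepl("^1@", r$values))
    if (n_events >= shared_event_min) s else character()
  })
  grouped <- grouped[lengths(grouped) > 0]
  if (length(grouped) > 0) {
    grouped <- grouped[c_order(purrr::map_chr(grouped, ~ c_sort(.x)[1]))]
    names(grouped) <- paste0("G", seq_along(grouped))
  }
  assignment <- tibble(sample = rownames(m), group = "ungrouped")
  for (g in names(grouped)) {
    assignment$group[assignment$sample %in% grouped[[g]]] <- g
  }
  assignment
}

#' Plot a binned copy-number profile matrix
#'
#' @param profile Long bin tibble from [bin_log2()].
#' @param ... Unused.
#' @return A ggplot heatmap of log2 ratios (samples x bins).
#' @export
plot_cnv_profile <- function(profile, ...) {
  profile |>
    mutate(bin = paste(.data$chrom, .data$bin_start / 1e6, sep = ":")) |>
    ggplot(aes(x = factor(.data$bin, levels = unique(.data$bin)),
               y = .data$sample, fill = .data$log2)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0, name = "log2 ratio") +
    labs(x = "1-Mb bin", y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
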