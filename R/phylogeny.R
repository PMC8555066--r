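# Cross-sample perfect phylogeny from somatic variant presence/absence on
# copy-stable chromosomes.

#' Encode somatic variants as a binary presence/absence matrix
#'
#' A variant is present in a sample when its allele fraction is strictly
#' above `af_threshold` (AF exactly at the threshold encodes as absent);
#' missing AFs (zero depth) encode as absent. All-zero rows are dropped.
#'
#' @param tbl Long variant table with somatic `status` set
#'   (see [call_somatic()]).
#' @param chroms Chromosomes to use; restrict to copy-stable chromosomes.
#' @param samples Tumor samples to encode (defaults to all non-normal
#'   samples).
#' @param af_threshold Presence cutoff (strict `>`); default 0.1.
#' @return Integer matrix variants x samples in \{0, 1\}, with the threshold
#'   in attribute `"af_threshold"`.
#' @export
encode_binary <- function(tbl, chroms, samples = NULL, af_threshold = 0.1) {
  if (length(chroms) == 0) abort("empty chromosome selection")
  if (!"status" %in% names(tbl)) abort("run call_somatic() first")
  samples <- samples %||% setdiff(variant_samples(tbl), attr(tbl, "normals"))
  sub <- tbl |>
    filter(.data$status == "somatic", .data$chrom %in% chroms,
           .data$sample %in% samples)
  wide <- sub |>
    mutate(present = as.integer(!is.na(.data$af) & .data$af > af_threshold)) |>
    tidyr::pivot_wider(id_cols = "variant_id", names_from = "sample",
                       values_from = "present", values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$variant_id
  missing_cols <- setdiff(samples, colnames(m))
  if (length(missing_cols) > 0) {
    m <- cbind(m, matrix(0L, nrow(m), length(missing_cols),
                         dimnames = list(NULL, missing_cols)))
  }
  m <- m[, samples, drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  attr(m, "af_threshold") <- af_threshold
  m
}

#' Cluster variants with identical binary occurrence vectors
#'
#' Variants sharing the same presence pattern across samples are assumed to
#' have arisen in the same clone. Clusters are ordered by descending
#' sample-set size, then lexicographically by sample set, and labeled VC1,
#' VC2, ...
#'
#' @param m Binary matrix from [encode_binary()].
#' @return Tibble (`cluster_id`, `n_variants`, `sample_set` list-column,
#'   `members` list-column).
#' @export
cluster_variants <- function(m) {
  if (nrow(m) == 0) abort("empty binary matrix")
  pattern <- apply(m, 1, paste, collapse = "")
  groups <- split(rownames(m), pattern)
  sets <- purrr::map(names(groups), function(p) {
    colnames(m)[strsplit(p, "")[[1]] == "1"]
  })
  out <- tibble(
    n_variants = unname(lengths(groups)),
    sample_set = sets,
    members = unname(groups)
  ) |>
    mutate(size = lengths(.data$sample_set),
           key = purrr::map_chr(.data$sample_set, set_key)) |>
    arrange(desc(.data$size), .data$key) |>
    mutate(cluster_id = paste0("VC", row_number())) |>
    select("cluster_id", "n_variants", "sample_set", "members")
  out
}

#' Pairwise compatibility of two variant clusters
#'
#' Under the infinite sites assumption two clusters must have nested or
#' disjoint sample sets; overlap without containment violates the
#' three-gamete condition.
#'
#' @param s1,s2 Character vectors of sample names.
#' @return `"nested"`, `"disjoint"` or `"conflict"`.
#' @export
check_compatibility <- function(s1, s2) {
  inter <- length(intersect(s1, s2))
  if (inter == 0) "disjoint"
  else if (is_subset(s1, s2) || is_subset(s2, s1)) "nested"
  else "conflict"
}

# All conflicting cluster pairs (indices into the cluster tibble).
conflict_pairs <- function(clusters) {
  n <- nrow(clusters)
  if (n < 2) return(list())
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (check_compatibility(clusters$sample_set[[i]],
                              clusters$sample_set[[j]]) == "conflict") {
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  pairs
}

# Re-project clusters onto a reduced sample set, dropping emptied clusters
# and re-merging clusters whose patterns have become identical.
project_clusters <- function(clusters, samples) {
  proj <- clusters |>
    mutate(sample_set = purrr::map(.data$sample_set, intersect, samples)) |>
    filter(lengths(.data$sample_set) > 0) |>
    mutate(key = purrr::map_chr(.data$sample_set, set_key)) |>
    group_by(.data$key) |>
    summarise(n_variants = sum(.data$n_variants),
              sample_set = .data$sample_set[1],
              members = list(unlist(.data$members)),
              .groups = "drop") |>
    mutate(size = lengths(.data$sample_set)) |>
    arrange(desc(.data$size), .data$key) |>
    mutate(cluster_id = paste0("VC", row_number())) |>
    select("cluster_id", "n_variants", "sample_set", "members")
  proj
}

#' Flag mixture samples breaking the perfect phylogeny
#'
#' Samples that contain cell populations from divergent lineages make
#' cluster sample-sets overlap without containment. The sample sitting in
#' the intersection of the most conflicting cluster pairs is removed
#' (ties broken lexicographically) and clusters are re-projected; this
#' repeats until no conflicts remain.
#'
#' @param clusters Cluster tibble from [cluster_variants()].
#' @param samples All sample names under consideration.
#' @return List with `mixture_samples` (character) and `clusters` (pruned,
#'   re-projected cluster tibble).
#' @export
flag_mixture_samples <- function(clusters, samples) {
  removed <- character()
  repeat {
    pairs <- conflict_pairs(clusters)
    if (length(pairs) == 0) break
    if (length(removed) + 1 >= length(samples) / 2) {
      abort("conflict removal would exhaust half the samples; data violate infinite sites globally")
    }
    counts <- table(unlist(purrr::map(pairs, function(p) {
      intersect(clusters$sample_set[[p[1]]], clusters$sample_set[[p[2]]])
    })))
    worst <- c_sort(names(counts)[counts == max(counts)])[1]
    removed <- c(removed, worst)
    clusters <- project_clusters(clusters, setdiff(samples, removed))
  }
  list(mixture_samples = removed, clusters = clusters)
}

#' Build the perfect phylogeny over samples
#'
#' Clusters (pairwise nested or disjoint) are arranged by sample-set
#' containment; each sample attaches as a leaf under the smallest cluster
#' containing it. Branch lengths are variant counts (cluster sizes, leaves
#' 0). The root is the cluster spanning all samples (truncal variants); when
#' no cluster spans all samples an implicit zero-length root is added.
#'
#' @param clusters Conflict-free cluster tibble (see
#'   [flag_mixture_samples()]).
#' @param samples Sample names to place as leaves.
#' @return An object of class `mst_phylogeny`: list with `nodes` (tibble
#'   `node`, `parent`, `n_variants`, `sample_set`, `type`) and `samples`.
#' @export
build_perfect_phylogeny <- function(clusters, samples) {
  if (length(conflict_pairs(clusters)) > 0) {
    abort("clusters still conflict; run flag_mixture_samples() first")
  }
  full <- purrr::map_lgl(clusters$sample_set, ~ setequal(.x, samples))
  nodes <- clusters |>
    mutate(type = "cluster", node = .data$cluster_id) |>
    select("node", "n_variants", "sample_set", "type")
  if (!any(full)) {
    nodes <- bind_rows(
      tibble(node = "root", n_variants = 0L,
             sample_set = list(samples), type = "root"),
      nodes)
  }
  sizes <- lengths(nodes$sample_set)
  parent <- purrr::map_chr(seq_len(nrow(nodes)), function(i) {
    supersets <- which(purrr::map_lgl(nodes$sample_set, function(s) {
      is_subset(nodes$sample_set[[i]], s)
    }) & (sizes > sizes[i] |
            (sizes == sizes[i] & seq_len(nrow(nodes)) < i)))
    if (length(supersets) == 0) return(NA_character_)
    nodes$node[supersets[which.min(sizes[supersets])]]
  })
  nodes$parent <- parent
  leaf_parent <- purrr::map_chr(samples, function(s) {
    holding <- which(purrr::map_lgl(nodes$sample_set, ~ s %in% .x))
    nodes$node[holding[which.min(sizes[holding])]]
  })
  leaves <- tibble(node = samples, parent = leaf_parent, n_variants = 0L,
                   sample_set = purrr::map(samples, ~.x), type = "leaf")
  out <- list(nodes = bind_rows(nodes, leaves) |>
                select("node", "parent", "n_variants", "sample_set", "type"),
              samples = samples)
  class(out) <- "mst_phylogeny"
  out
}

#' @export
print.mst_phylogeny <- function(x, ...) {
  n_int <- sum(x$nodes$type != "leaf")
  cat("<mst_phylogeny> ", length(x$samples), " samples, ", n_int,
      " internal nodes\n", sep = "")
  invisible(x)
}

#' Tidy a sample phylogeny into a node tibble
#'
#' @param x An `mst_phylogeny`.
#' @param ... Unused.
#' @return Tibble of nodes with parent, branch length (variant count) and
#'   sample set.
#' @export
tidy.mst_phylogeny <- function(x, ...) {
  x$nodes |>
    mutate(sample_set = purrr::map_chr(.data$sample_set, set_key))
}

#' Convert a sample phylogeny to an `ape::phylo` tree
#'
#' Branch lengths are variant counts. Degree-one internal chains are
#' preserved as singleton nodes via `collapse.singles = FALSE` semantics
#' (ape tolerates them in Newick output).
#'
#' @param x An `mst_phylogeny`.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.mst_phylogeny <- function(x, ...) {
  nodes <- x$nodes
  nwk_for <- function(id) {
    children <- nodes$node[!is.na(nodes$parent) & nodes$parent == id]
    me <- nodes[nodes$node == id, ]
    label <- gsub("[(),:;]", "_", id)
    if (length(children) == 0) {
      paste0(label, ":", me$n_variants)
    } else {
      paste0("(", paste(purrr::map_chr(children, nwk_for), collapse = ","),
             ")", label, ":", me$n_variants)
    }
  }
  root <- nodes$node[is.na(nodes$parent)]
  txt <- paste0(nwk_for(root), ";")
  ape::read.tree(text = txt)
}

#' Write a sample phylogeny as Newick
#'
#' @param x An `mst_phylogeny`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylogeny_newick <- function(x, path) {
  ape::write.tree(as.phylo.mst_phylogeny(x), file = path)
  invisible(path)
}

#' UPGMA dendrogram on Hamming distances between samples
#'
#' Cross-check of the perfect phylogeny grouping: samples are clustered by
#' the Hamming distance between their binary occurrence columns.
#'
#' @param m Binary matrix from [encode_binary()].
#' @return An `hclust` object.
#' @export
upgma_hamming <- function(m) {
  if (ncol(m) < 2) abort("need at least 2 samples")
  m <- m[, c_sort(colnames(m)), drop = FALSE]
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[, i] != m[, j])
    }
  }
  hclust(as.dist(d), method = "average")
}

#' Per-sample truncal / shared / private variant fractions
#'
#' For each tumor sample other than the designated primary, the fraction of
#' its present somatic variants that are present in the primary
#' (`truncal_fraction`), present in at least one other non-primary sample
#' but not the primary (`shared_fraction`), or found nowhere else
#' (`private_fraction`). Fractions sum to 1.
#'
#' @param tbl Long variant table with `status` set.
#' @param primary_sample Name of the primary-tumor sample.
#' @param samples Tumor samples to report on (defaults to non-normals).
#' @param af_threshold Presence cutoff (strict `>`); default 0.1.
#' @return Tibble (`sample`, `truncal_fraction`, `shared_fraction`,
#'   `private_fraction`).
#' @export
sharing_stats <- function(tbl, primary_sample, samples = NULL,
                          af_threshold = 0.1) {
  samples <- samples %||% setdiff(variant_samples(tbl), attr(tbl, "normals"))
  if (!primary_sample %in% samples) abort("unknown primary sample")
  pres <- tbl |>
    filter(.data$status == "somatic", .data$sample %in% samples) |>
    mutate(present = !is.na(.data$af) & .data$af > af_threshold) |>
    tidyr::pivot_wider(id_cols = "variant_id", names_from = "sample",
                       values_from = "present", values_fill = FALSE)
  pm <- as.matrix(pres[, -1, drop = FALSE])
  others <- setdiff(samples, primary_sample)
  purrr::map(others, function(s) {
    mine <- pm[, s]
    if (sum(mine) == 0) {
      return(tibble(sample = s, truncal_fraction = NA_real_,
                    shared_fraction = NA_real_, private_fraction = NA_real_))
    }
    in_primary <- pm[, primary_sample]
    rest <- setdiff(others, s)
    in_rest <- if (length(rest) > 0) {
      rowSums(pm[, rest, drop = FALSE]) > 0
    } else rep(FALSE, nrow(pm))
    truncal <- sum(mine & in_primary)
    shared <- sum(mine & !in_primary & in_rest)
    private <- sum(mine & !in_primary & !in_rest)
    tibble(sample = s,
           truncal_fraction = truncal / sum(mine),
           shared_fraction = shared / sum(mine),
           private_fraction = private / sum(mine))
  }) |> bind_rows()
}
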