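# Subclone reconstruction: VAF clustering, purity-corrected cellular
# prevalence, exhaustive subclone-tree enumeration, joint assembly.

#' Cluster somatic variants by allele-fraction level across samples
#'
#' Variants are first partitioned by presence pattern (AF at or above
#' `af_positive`). Within a pattern, a conservative over-segmentation
#' (complete linkage at `merge_tol` on the per-sample maximum distance) is
#' followed by centroid agglomeration: clusters merge while their mean AFs
#' fall inside the merge band in every sample. The band is `merge_tol`
#' widened for binomial read noise (see Details in the package vignette),
#' and remaining noise-outlier groups are absorbed into the nearest major
#' cluster of their pattern. Restrict `chroms` to copy-number-neutral
#' chromosomes so AF is proportional to cellular prevalence.
#'
#' @param tbl Long variant table with `status` set.
#' @param samples Tumor samples to use (defaults to non-normals).
#' @param chroms Optional chromosome restriction.
#' @param af_positive Positive-detection AF cutoff; default 0.05.
#' @param merge_tol Per-sample AF merge tolerance; default 0.1.
#' @param absorb_frac Clusters smaller than this fraction of their
#'   presence-pattern's largest cluster are absorbed into the nearest major
#'   cluster (read-noise outliers); default 0.3.
#' @param purity Optional tibble (`sample`, `purity`). When given, AFs are
#'   capped at the founding-clone level `purity/2` for distance
#'   computations: AF above that level carries no prevalence information
#'   (the clone is fully clonal), so saturated noise cannot split a
#'   cluster. Reported mean AFs stay uncapped.
#' @return An object of class `mst_vafclusters`: tibble (`cluster_id`,
#'   `n_variants`, `members` list-column) with the clusters x samples mean-AF
#'   matrix in attribute `"mean_af"`.
#' @export
cluster_vafs <- function(tbl, samples = NULL, chroms = NULL,
                         af_positive = 0.05, merge_tol = 0.1,
                         absorb_frac = 0.3, purity = NULL) {
  samples <- samples %||% setdiff(variant_samples(tbl), attr(tbl, "normals"))
  sub <- tbl |> filter(.data$status == "somatic", .data$sample %in% samples)
  if (!is.null(chroms)) sub <- sub |> filter(.data$chrom %in% chroms)
  if (nrow(sub) == 0) {
    warn("no somatic variants in the selected region")
    out <- tibble(cluster_id = character(), n_variants = integer(),
                  members = list())
    attr(out, "mean_af") <- matrix(0, 0, length(samples),
                                   dimnames = list(NULL, samples))
    class(out) <- c("mst_vafclusters", class(out))
    return(out)
  }
  wide <- sub |>
    mutate(af0 = dplyr::coalesce(.data$af, 0)) |>
    tidyr::pivot_wider(id_cols = "variant_id", names_from = "sample",
                       values_from = "af0", values_fill = 0)
  af <- as.matrix(wide[, samples, drop = FALSE])
  rownames(af) <- wide$variant_id
  af_d <- af
  if (!is.null(purity)) {
    cap <- setNames(purity$purity, purity$sample)[samples] / 2
    if (any(is.na(cap))) abort("purity missing for some samples")
    af_d <- pmin(af, matrix(cap, nrow(af), length(samples), byrow = TRUE))
  }
  # per-sample median depth: sets the binomial noise scale used to veto
  # merges whose pooled spread read sampling cannot explain
  med_depth <- sub |>
    group_by(.data$sample) |>
    summarise(d = stats::median(.data$depth), .groups = "drop")
  med_depth <- setNames(med_depth$d, med_depth$sample)[samples]
  med_depth[is.na(med_depth) | med_depth < 1] <- 1
  pattern <- apply(af >= af_positive, 1, paste, collapse = "")
  # centroid agglomeration: repeatedly merge the closest pair of clusters
  # while, in every sample, their mean AFs differ by less than the merge
  # band. Stage-1 fragments of a single clone sit up to ~2 binomial SDs
  # apart by construction (thresholded splits of one distribution), so the
  # band is 1.3x the tolerance, widened to 3 pooled within-cluster SDs
  # (bounded at 2x) when read noise is larger.
  merge_centroid <- function(rows) {
    # stage 1: conservative over-segmentation (complete linkage at the
    # tolerance) so stage-2 centroids are noise-averaged fragment means and
    # single outlier variants cannot chain two clones together
    if (length(rows) > 2) {
      frag <- cutree(hclust(stats::dist(af_d[rows, , drop = FALSE],
                                        method = "maximum"),
                            method = "complete"),
                     h = merge_tol)
      members <- unname(split(rows, frag))
    } else {
      members <- as.list(rows)
    }
    k <- length(members)
    sizes <- lengths(members)
    means <- t(vapply(members, function(r) colMeans(af_d[r, , drop = FALSE]),
                      numeric(ncol(af_d))))
    ss <- t(vapply(members, function(r) {
      m <- af_d[r, , drop = FALSE]
      colSums(sweep(m, 2, colMeans(m), `-`)^2)
    }, numeric(ncol(af_d))))
    # merge ratio < 1 when every per-sample gap is inside the band and the
    # merged spread stays explainable by binomial read noise
    ratio <- function(i, j) {
      n <- sizes[i] + sizes[j]
      sd_pool <- if (n >= 4) sqrt((ss[i, ] + ss[j, ]) / (n - 2)) else 0
      band <- pmax(1.3 * merge_tol, pmin(3 * sd_pool, 2 * merge_tol))
      r <- max(abs(means[i, ] - means[j, ]) / band)
      if (n >= 8) {
        delta <- means[i, ] - means[j, ]
        m_pool <- (means[i, ] * sizes[i] + means[j, ] * sizes[j]) / n
        var_merged <- (ss[i, ] + ss[j, ] +
                         sizes[i] * sizes[j] / n * delta^2) / (n - 1)
        sd_binom <- sqrt(pmax(m_pool * (1 - m_pool), 1e-6) / med_depth)
        if (any(sqrt(var_merged) > 1.5 * sd_binom)) r <- Inf
      }
      r
    }
    d <- matrix(Inf, k, k)
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) d[i, j] <- d[j, i] <- ratio(i, j)
    }
    while (length(members) > 1 && min(d) < 1) {
      ij <- arrayInd(which.min(d), dim(d))
      i <- min(ij); j <- max(ij)
      delta <- means[i, ] - means[j, ]
      ss[i, ] <- ss[i, ] + ss[j, ] +
        sizes[i] * sizes[j] / (sizes[i] + sizes[j]) * delta^2
      means[i, ] <- (means[i, ] * sizes[i] + means[j, ] * sizes[j]) /
        (sizes[i] + sizes[j])
      sizes[i] <- sizes[i] + sizes[j]
      members[[i]] <- c(members[[i]], members[[j]])
      means <- means[-j, , drop = FALSE]
      ss <- ss[-j, , drop = FALSE]
      sizes <- sizes[-j]
      members[j] <- NULL
      d <- d[-j, -j, drop = FALSE]
      if (length(members) > 1) {
        for (l in setdiff(seq_along(members), i)) {
          d[l, i] <- d[i, l] <- ratio(i, l)
        }
        d[i, i] <- Inf
      }
    }
    members
  }
  clusters <- list()
  for (p in c_sort(unique(pattern))) {
    rows <- which(pattern == p)
    groups <- if (length(rows) == 1) list(rows) else merge_centroid(rows)
    # absorb minor clusters (read-noise outlier groups) into the nearest
    # major cluster of the same presence pattern
    sizes <- lengths(groups)
    majors <- which(sizes >= max(2, ceiling(absorb_frac * max(sizes))))
    if (length(majors) > 0 && length(majors) < length(groups)) {
      gmeans <- t(vapply(groups, function(r) colMeans(af_d[r, , drop = FALSE]),
                         numeric(ncol(af))))
      for (i in setdiff(seq_along(groups), majors)) {
        d <- apply(abs(sweep(gmeans[majors, , drop = FALSE], 2,
                             gmeans[i, ], `-`)), 1, max)
        tgt <- majors[which.min(d)]
        groups[[tgt]] <- c(groups[[tgt]], groups[[i]])
      }
      groups <- groups[majors]
    }
    clusters <- c(clusters, groups)
  }
  means <- t(vapply(clusters, function(rows) {
    colMeans(af[rows, , drop = FALSE])
  }, numeric(length(samples))))
  colnames(means) <- samples
  ord <- order(-rowSums(means >= af_positive), -rowMeans(means),
               purrr::map_chr(clusters, ~ c_sort(rownames(af)[.x])[1]),
               method = "radix")
  clusters <- clusters[ord]
  means <- means[ord, , drop = FALSE]
  out <- tibble(
    cluster_id = paste0("C", seq_along(clusters)),
    n_variants = lengths(clusters),
    members = purrr::map(clusters, ~ rownames(af)[.x])
  )
  rownames(means) <- out$cluster_id
  attr(out, "mean_af") <- means
  class(out) <- c("mst_vafclusters", class(out))
  out
}

#' Convert allele fraction to cellular prevalence
#'
#' Purity- and copy-state-corrected cell fraction:
#' \deqn{CP = af (p C_t + 2 (1-p)) / (p C_v)}
#' for a variant carried on `copies_variant` of `copies_total` tumor copies
#' at purity `p`, capped at 1 (with a warning). In the default heterozygous
#' copy-neutral case this is `2 af / p`; a founding-clone variant at AF ~0.5
#' in a pure sample maps to prevalence 1.
#'
#' @param af Allele fraction(s).
#' @param purity Tumor purity in (0, 1].
#' @param copies_total Total tumor copy number at the locus; default 2.
#' @param copies_variant Tumor copies carrying the variant; default 1.
#' @return Cellular prevalence in \[0, 1\].
#' @export
prevalence <- function(af, purity, copies_total = 2, copies_variant = 1) {
  if (any(purity <= 0)) abort("purity must be in (0, 1]")
  stopifnot(all(copies_variant <= copies_total), all(copies_variant > 0))
  cp <- af * (purity * copies_total + (1 - purity) * 2) / (purity * copies_variant)
  if (any(cp > 1 + 1e-9)) {
    warn(sprintf("%d prevalence value(s) above 1 capped", sum(cp > 1 + 1e-9)))
  }
  pmin(1, cp)
}

#' Cellular prevalence matrix for VAF clusters
#'
#' @param clusters `mst_vafclusters` from [cluster_vafs()].
#' @param purity Tibble (`sample`, `purity`).
#' @param copies_total,copies_variant Copy-state correction passed to
#'   [prevalence()]; defaults assume heterozygous variants on copy-neutral
#'   loci.
#' @return Numeric matrix clusters x samples of prevalences.
#' @export
cluster_prevalence <- function(clusters, purity, copies_total = 2,
                               copies_variant = 1) {
  af <- attr(clusters, "mean_af")
  p <- setNames(purity$purity, purity$sample)[colnames(af)]
  if (any(is.na(p))) abort("purity missing for some samples")
  fac <- (p * copies_total + (1 - p) * 2) / (p * copies_variant)
  prev <- sweep(af, 2, fac, `*`)
  prev[] <- pmin(1, prev)
  prev
}

# Identify the founding (root) cluster: prevalence within `tol` of 1 in at
# least one sample, maximal presence set; ties -> more variants, then id.
# Presence uses a noise floor so stray sub-percent prevalences do not count.
find_root_cluster <- function(prev, n_variants, tol, min_presence = 0.05) {
  near_one <- apply(prev, 1, function(x) any(x >= 1 - tol))
  if (!any(near_one)) {
    # fallback: accept a cluster that dominates every other cluster in
    # every sample (prevalence estimates can sit below 1 - tol when reads
    # are noisy or clusters were merged conservatively)
    dom <- purrr::map_lgl(seq_len(nrow(prev)), function(i) {
      all(purrr::map_lgl(setdiff(seq_len(nrow(prev)), i), function(j) {
        all(prev[i, ] >= prev[j, ] - tol - 1e-9)
      }))
    })
    if (!any(dom)) {
      abort("no founding cluster: no cluster reaches prevalence ~1 in any sample")
    }
    warn("no cluster reaches prevalence ~1; using the dominating cluster as the founding clone")
    near_one <- dom
  }
  presence <- prev >= min_presence
  cand <- which(near_one)
  # the founding cluster must be able to sit above every other cluster
  dominates <- purrr::map_lgl(cand, function(i) {
    all(purrr::map_lgl(setdiff(seq_len(nrow(prev)), i), function(j) {
      all(prev[i, ] >= prev[j, ] - tol - 1e-9)
    }))
  })
  if (any(dominates)) cand <- cand[dominates]
  breadth <- rowSums(presence)[cand]
  cand <- cand[breadth == max(breadth)]
  if (length(cand) > 1) cand <- cand[order(-n_variants[cand], cand)]
  cand[1]
}

# Sum-constraint violation of a parent assignment (L1 slack over
# sample x node).
tree_violation <- function(parent, prev) {
  total <- 0
  for (v in seq_len(nrow(prev))) {
    kids <- which(parent == v)
    if (length(kids) == 0) next
    slack <- colSums(prev[kids, , drop = FALSE]) - prev[v, ]
    total <- total + sum(pmax(0, slack))
  }
  total
}

# Does the assignment satisfy all constraints within tolerance?
tree_valid <- function(parent, prev, tol) {
  for (v in seq_len(nrow(prev))) {
    kids <- which(parent == v)
    if (length(kids) == 0) next
    if (any(colSums(prev[kids, , drop = FALSE]) > prev[v, ] + tol + 1e-9)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Enumerate all subclone trees consistent with cellular prevalences
#'
#' Exhaustively enumerates rooted trees over the clusters (root = founding
#' cluster) and keeps those in which, in every sample, the prevalence of a
#' parent plus `tolerance` is at least the summed prevalence of its
#' children, and every parent's prevalence is at least each child's minus
#' `tolerance` (lineage containment). The violation of a tree is the total
#' L1 slack used; the chosen solution minimizes it, ties broken by the
#' lexicographically smallest parent array.
#'
#' @param prev Clusters x samples prevalence matrix
#'   (see [cluster_prevalence()]), or an `mst_vafclusters` plus `purity`.
#' @param tolerance Prevalence slack accommodating VAF measurement error;
#'   default 0.1.
#' @param n_variants Optional per-cluster variant counts (root tie-break).
#' @return An object of class `mst_solutions`: list with `trees` (list of
#'   named parent vectors; the root maps to `NA`), `violations`, `chosen`
#'   (index of the minimal-violation tree, or `NA` when no tree is valid),
#'   `root`, `tolerance`, `prevalence`.
#' @export
enumerate_trees <- function(prev, tolerance = 0.1, n_variants = NULL) {
  if (nrow(prev) > 12) {
    abort("more than 12 clusters: enumeration is infeasible; raise merge_tol to pre-merge clusters")
  }
  ids <- rownames(prev) %||% paste0("C", seq_len(nrow(prev)))
  rownames(prev) <- ids
  n <- nrow(prev)
  n_variants <- n_variants %||% rep(1L, n)
  if (n == 1) {
    sol <- list(trees = list(setNames(NA_integer_, ids)), violations = 0,
                chosen = 1L, root = ids[1], tolerance = tolerance,
                prevalence = prev)
    class(sol) <- "mst_solutions"
    return(sol)
  }
  root <- find_root_cluster(prev, n_variants, tolerance)
  others <- setdiff(seq_len(n), root)
  # allowed parents: containment within tolerance in every sample
  allowed <- purrr::map(seq_len(n), function(child) {
    ok <- purrr::map_lgl(seq_len(n), function(p) {
      p != child && all(prev[p, ] >= prev[child, ] - tolerance - 1e-9)
    })
    which(ok)
  })
  trees <- list()
  parent <- rep(NA_integer_, n)
  # assign children in order of decreasing total prevalence; track child sums
  ord <- others[order(-rowSums(prev[others, , drop = FALSE]), others)]
  child_sum <- matrix(0, n, ncol(prev))
  recurse <- function(k) {
    if (k > length(ord)) {
      trees[[length(trees) + 1]] <<- parent
      return(invisible())
    }
    child <- ord[k]
    for (p in allowed[[child]]) {
      # cycle check: walk up from p
      anc <- p; cyc <- FALSE
      while (!is.na(anc)) {
        if (anc == child) { cyc <- TRUE; break }
        anc <- parent[anc]
      }
      if (cyc) next
      new_sum <- child_sum[p, ] + prev[child, ]
      if (any(new_sum > prev[p, ] + tolerance + 1e-9)) next
      parent[child] <<- p
      child_sum[p, ] <<- new_sum
      recurse(k + 1)
      parent[child] <<- NA_integer_
      child_sum[p, ] <<- child_sum[p, ] - prev[child, ]
    }
    invisible()
  }
  recurse(1)
  if (length(trees) == 0) {
    diag_msg <- "no valid tree under the prevalence constraints"
    warn(diag_msg)
    sol <- list(trees = list(), violations = numeric(), chosen = NA_integer_,
                root = ids[root], tolerance = tolerance, prevalence = prev)
    class(sol) <- "mst_solutions"
    return(sol)
  }
  named <- purrr::map(trees, function(p) setNames(ifelse(is.na(p), NA, ids[p]), ids))
  viol <- purrr::map_dbl(trees, tree_violation, prev = prev)
  ser <- purrr::map_chr(named, ~ paste(.x, collapse = "|"))
  # violations within half the tolerance of the minimum are
  # measurement-indistinguishable; among those, prefer the more linear
  # topology (a child at the same prevalence as its parent is a clonal
  # sweep, not a coexisting sibling)
  total_depth <- purrr::map_dbl(trees, function(p) {
    sum(purrr::map_int(seq_along(p), function(v) {
      d <- 0L; a <- p[v]
      while (!is.na(a)) { d <- d + 1L; a <- p[a] }
      d
    }))
  })
  vmin <- min(viol)
  cand <- which(viol <= vmin + tolerance / 2)
  chosen <- cand[order(-total_depth[cand], ser[cand])[1]]
  sol <- list(trees = named, violations = viol, chosen = chosen,
              root = ids[root], tolerance = tolerance, prevalence = prev)
  class(sol) <- "mst_solutions"
  sol
}

#' @export
print.mst_solutions <- function(x, ...) {
  cat("<mst_solutions> ", length(x$trees), " tree(s), root ", x$root, sep = "")
  if (!is.na(x$chosen)) {
    cat(", chosen #", x$chosen, " (violation ",
        format(x$violations[x$chosen], digits = 4), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tidy enumerated subclone trees
#'
#' @param x An `mst_solutions`.
#' @param ... Unused.
#' @return Tibble with one row per (tree, cluster): `tree`, `cluster`,
#'   `parent`, `violation`, `chosen`.
#' @export
tidy.mst_solutions <- function(x, ...) {
  purrr::imap(x$trees, function(tr, i) {
    tibble(tree = i, cluster = names(tr), parent = unname(tr),
           violation = x$violations[i], chosen = i == x$chosen)
  }) |> bind_rows()
}

#' One-row summary of a solution set
#'
#' @param x An `mst_solutions`.
#' @param ... Unused.
#' @return Tibble with `n_trees`, `n_clusters`, `chosen`,
#'   `chosen_violation`, `tolerance`.
#' @export
glance.mst_solutions <- function(x, ...) {
  tibble(n_trees = length(x$trees), n_clusters = nrow(x$prevalence),
         chosen = x$chosen,
         chosen_violation = if (is.na(x$chosen)) NA_real_ else x$violations[x$chosen],
         tolerance = x$tolerance)
}

# Chosen tree of a solution set as a named parent vector.
chosen_tree <- function(sol) {
  if (is.na(sol$chosen)) abort("solution set has no valid tree")
  sol$trees[[sol$chosen]]
}

#' Assemble per-group subclone solutions into one joint tree
#'
#' Merges the chosen trees of several solution sets (sharing truncal/group
#' clusters by cluster id) into a single parent map. When a cluster has
#' different parents in different solutions, the parent giving the smaller
#' total violation on the combined prevalence matrix is kept and the
#' conflict is reported in the `conflicts` attribute rather than silently
#' dropped.
#'
#' @param solutions Named list of `mst_solutions`.
#' @return Tibble (`cluster`, `parent`) for the joint tree, with attribute
#'   `"conflicts"` (tibble of cluster, kept parent, alternatives).
#' @export
assemble_multi_sample <- function(solutions) {
  edges <- purrr::imap(solutions, function(sol, nm) {
    tr <- chosen_tree(sol)
    tibble(cluster = names(tr), parent = unname(tr), solution = nm)
  }) |> bind_rows()
  prev_all <- purrr::map(solutions, function(sol) sol$prevalence)
  conflicts <- list()
  joint <- edges |>
    group_by(.data$cluster) |>
    summarise(parents = list(unique(.data$parent)), .groups = "drop")
  pick <- purrr::map_chr(seq_len(nrow(joint)), function(i) {
    ps <- joint$parents[[i]]
    ps_real <- ps[!is.na(ps)]
    if (length(ps_real) == 0) return(NA_character_)
    if (length(unique(ps_real)) == 1) return(ps_real[1])
    # conflict: score each candidate parent by summed violation across the
    # solutions whose prevalence matrices contain both clusters
    scores <- purrr::map_dbl(ps_real, function(p) {
      s <- 0
      for (pm in prev_all) {
        if (all(c(joint$cluster[i], p) %in% rownames(pm))) {
          s <- s + sum(pmax(0, pm[joint$cluster[i], ] - pm[p, ]))
        }
      }
      s
    })
    keep <- ps_real[order(scores, ps_real)][1]
    conflicts[[length(conflicts) + 1]] <<- tibble(
      cluster = joint$cluster[i], kept = keep,
      alternatives = paste(setdiff(ps_real, keep), collapse = ","))
    keep
  })
  out <- tibble(cluster = joint$cluster, parent = pick)
  attr(out, "conflicts") <- bind_rows(conflicts)
  out
}
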