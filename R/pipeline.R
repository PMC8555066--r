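# End-to-end convenience wrappers: variant table -> subclone atlas ->
# migration graph.

#' Reconstruct subclones and their per-site prevalences
#'
#' Runs VAF clustering on copy-neutral chromosomes, converts cluster mean
#' AFs to purity-corrected cellular prevalences, drops clusters smaller
#' than `min_cluster_variants` (read-noise strays off the presence-pattern
#' partition), enumerates candidate subclone trees and returns the
#' minimal-violation solution as an atlas.
#'
#' @param tbl Long variant table with `status` set (see [call_somatic()]).
#' @param purity Tibble (`sample`, `purity`).
#' @param chroms Copy-neutral chromosomes to use; default `"chr14"`.
#' @param samples Tumor samples (defaults to non-normals).
#' @param af_positive,merge_tol See [cluster_vafs()].
#' @param tolerance Prevalence tolerance for [enumerate_trees()];
#'   default 0.1.
#' @param min_cluster_variants Minimum variants per retained cluster;
#'   default 5.
#' @return List with `clusters`, `prev` (clusters x samples), `solutions`
#'   (`mst_solutions`) and `atlas` (`mst_atlas`, `NULL` when no valid
#'   tree).
#' @export
reconstruct_subclones <- function(tbl, purity, chroms = "chr14",
                                  samples = NULL, af_positive = 0.05,
                                  merge_tol = 0.1, tolerance = 0.1,
                                  min_cluster_variants = 5) {
  samples <- samples %||% setdiff(variant_samples(tbl), attr(tbl, "normals"))
  clusters <- cluster_vafs(tbl, samples = samples, chroms = chroms,
                           af_positive = af_positive, merge_tol = merge_tol,
                           purity = purity)
  keep <- clusters$n_variants >= min_cluster_variants
  af <- attr(clusters, "mean_af")[keep, , drop = FALSE]
  clusters_kept <- clusters[keep, ]
  attr(clusters_kept, "mean_af") <- af
  class(clusters_kept) <- class(clusters)

  try_enumerate <- function(cl) {
    prev <- cluster_prevalence(cl, purity)
    sol <- tryCatch(
      enumerate_trees(prev, tolerance = tolerance, n_variants = cl$n_variants),
      error = function(e) {
        warn(conditionMessage(e))
        NULL
      })
    list(prev = prev, sol = sol)
  }
  # an unsatisfiable constraint set indicates over-segmentation: coarsen
  # minimally by merging the closest same-presence-pattern cluster pair and
  # retry
  for (attempt in 1:4) {
    fit <- try_enumerate(clusters_kept)
    if (!is.null(fit$sol) && !is.na(fit$sol$chosen)) break
    if (nrow(clusters_kept) < 2) break
    pat <- apply(fit$prev >= af_positive, 1, paste, collapse = "")
    dup <- pat %in% pat[duplicated(pat)]
    if (sum(dup) < 2) break
    idx <- which(dup)
    best <- NULL; best_d <- Inf
    for (i in idx) for (j in idx[idx > i]) {
      if (pat[i] != pat[j]) next
      d <- max(abs(fit$prev[i, ] - fit$prev[j, ]))
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (is.null(best)) break
    inform(sprintf("no consistent tree; merging clusters %s and %s and retrying",
                   clusters_kept$cluster_id[best[1]],
                   clusters_kept$cluster_id[best[2]]))
    afm <- attr(clusters_kept, "mean_af")
    n1 <- clusters_kept$n_variants[best[1]]
    n2 <- clusters_kept$n_variants[best[2]]
    afm[best[1], ] <- (afm[best[1], ] * n1 + afm[best[2], ] * n2) / (n1 + n2)
    clusters_kept$n_variants[best[1]] <- n1 + n2
    clusters_kept$members[[best[1]]] <- c(clusters_kept$members[[best[1]]],
                                          clusters_kept$members[[best[2]]])
    cls <- class(clusters_kept)
    clusters_kept <- clusters_kept[-best[2], ]
    afm <- afm[-best[2], , drop = FALSE]
    attr(clusters_kept, "mean_af") <- afm
    class(clusters_kept) <- cls
  }
  atlas <- if (!is.null(fit$sol) && !is.na(fit$sol$chosen)) {
    subclone_atlas(chosen_tree(fit$sol), fit$prev)
  } else NULL
  list(clusters = clusters_kept, prev = fit$prev, solutions = fit$sol,
       atlas = atlas)
}

#' Classify all migration events and assemble the graph
#'
#' @param atlas An `mst_atlas`.
#' @param primary Primary-site name.
#' @param groups,precedences Optional group labels and allele-state wave
#'   precedences for [build_graph()].
#' @param ... Thresholds passed to [classify_seeding()].
#' @return An `mst_migration`.
#' @export
infer_migration <- function(atlas, primary = NULL, groups = NULL,
                            precedences = NULL, ...) {
  events <- bind_rows(
    classify_seeding(atlas, primary = primary, ...),
    detect_recolonization(atlas))
  incubators <- detect_incubators(events, atlas)
  build_graph(events, groups = groups, precedences = precedences,
              incubators = incubators, primary = primary)
}

#' Order sample groups by allele-specific copy states at a locus
#'
#' For each pair of groups, takes one representative sample per group,
#' infers the paired allele-specific state at the locus from inherited het
#' variant AFs ([infer_allele_state_pair()]) and keeps the strict
#' precedences implied by the no-resurrection rule
#' ([order_allele_states()]).
#'
#' @param tbl Long variant table with `status` set (inherited variants are
#'   used).
#' @param segments Copy-number segment tibble covering the locus.
#' @param purity Tibble (`sample`, `purity`).
#' @param groups Tibble (`sample`, `group`); `"ungrouped"` samples are
#'   ignored.
#' @param locus_chrom Chromosome of the ordering locus.
#' @return Tibble (`earlier`, `later`, `locus`) of strict group
#'   precedences.
#' @export
order_groups_by_allele_states <- function(tbl, segments, purity, groups,
                                          locus_chrom) {
  gs <- c_sort(setdiff(unique(groups$group), "ungrouped"))
  rep_of <- purrr::map_chr(gs, function(g) {
    c_sort(groups$sample[groups$group == g])[1]
  })
  p <- setNames(purity$purity, purity$sample)
  cn_of <- function(s) {
    seg <- segments |> filter(.data$sample == s, .data$chrom == locus_chrom)
    if (nrow(seg) == 0) abort(paste0("no segment at locus for ", s))
    as.integer(seg$total_cn[which.max(seg$end - seg$start)])
  }
  afs_of <- function(s) {
    tbl |>
      filter(.data$sample == s, .data$chrom == locus_chrom,
             .data$status == "inherited") |>
      select("variant_id", "af")
  }
  out <- list()
  if (length(gs) < 2) return(tibble(earlier = character(),
                                    later = character(), locus = character()))
  for (i in seq_len(length(gs) - 1)) {
    for (j in (i + 1):length(gs)) {
      s1 <- rep_of[i]; s2 <- rep_of[j]
      pair <- dplyr::inner_join(afs_of(s1), afs_of(s2), by = "variant_id",
                                suffix = c("_1", "_2"))
      res <- tryCatch(
        infer_allele_state_pair(pair, cn_of(s1), cn_of(s2),
                                p[[s1]], p[[s2]]),
        error = function(e) NULL)
      if (is.null(res) || is.na(res$concordant)) next
      rel <- order_allele_states(res$state_1, res$state_2)
      if (rel == "precedes") {
        out[[length(out) + 1]] <- tibble(earlier = gs[i], later = gs[j],
                                         locus = locus_chrom)
      } else if (rel == "follows") {
        out[[length(out) + 1]] <- tibble(earlier = gs[j], later = gs[i],
                                         locus = locus_chrom)
      }
    }
  }
  if (length(out) == 0) tibble(earlier = character(), later = character(),
                               locus = character())
  else bind_rows(out)
}
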