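# Scoring pipeline output against simulator ground truth. These helpers
# run the relevant pipeline stages on a simulated cohort and compare the
# result with the truth bundle.

# Expected binary presence (clades) implied by the truth: a clone's
# mutations are present in a site when their expected AF clears the
# encoding threshold.
truth_clades <- function(cohort, af_threshold = 0.1) {
  carry <- cohort$truth$carrying
  p <- setNames(cohort$purity$purity, cohort$purity$sample)
  pres <- sweep(carry, 2, p[colnames(carry)], `*`) / 2 > af_threshold
  keys <- apply(pres, 1, function(x) set_key(colnames(pres)[x]))
  unique(keys[keys != ""])
}

#' Check perfect-phylogeny topology recovery on a simulated cohort
#'
#' Runs somatic calling, binary encoding, variant clustering, mixture
#' flagging and perfect-phylogeny construction, then compares the
#' reconstructed clade set (cluster sample-sets) with the clades implied by
#' the planted tree and site compositions. For a perfect phylogeny the
#' clade set determines the topology, so equality is tree isomorphism.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param af_threshold Presence threshold for [encode_binary()].
#' @return `TRUE` when the reconstructed topology matches the truth.
#' @export
evaluate_phylogeny_recovery <- function(cohort, af_threshold = 0.1) {
  tbl <- call_somatic(cohort$variants)
  samples <- setdiff(variant_samples(tbl), attr(tbl, "normals"))
  m <- encode_binary(tbl, chroms = "chr14", af_threshold = af_threshold)
  cl <- cluster_variants(m)
  fx <- flag_mixture_samples(cl, samples)
  if (length(fx$mixture_samples) > 0) return(FALSE)
  rec <- purrr::map_chr(fx$clusters$sample_set, set_key)
  setequal(rec, truth_clades(cohort, af_threshold))
}

# Majority-vote mapping cluster id -> true clone over member variants.
match_clusters_to_clones <- function(clusters, variant_clone) {
  purrr::map_chr(clusters$members, function(ms) {
    hits <- variant_clone[ms]
    hits <- hits[!is.na(hits)]
    if (length(hits) == 0) return(NA_character_)
    names(sort(-table(hits)))[1]
  })
}

#' Score subclone prevalence and tree recovery on a simulated cohort
#'
#' Runs [reconstruct_subclones()], maps each recovered cluster to a planted
#' clone by majority vote over member variants, and reports the RMSE
#' between estimated and true cellular prevalences plus whether the chosen
#' tree reproduces the planted parent structure (mapping bijective and
#' every parent edge matching).
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param ... Passed to [reconstruct_subclones()].
#' @return List with `rmse`, `tree_recovered`, `n_clusters`.
#' @export
evaluate_subclone_recovery <- function(cohort, ...) {
  tbl <- call_somatic(cohort$variants)
  rec <- suppressMessages(suppressWarnings(
    reconstruct_subclones(tbl, cohort$purity, chroms = "chr14", ...)))
  if (is.null(rec$atlas)) {
    return(list(rmse = NA_real_, tree_recovered = FALSE,
                n_clusters = nrow(rec$clusters)))
  }
  map <- match_clusters_to_clones(rec$clusters, cohort$truth$variant_clone)
  truth_prev <- cohort$truth$carrying
  est <- rec$prev[, colnames(truth_prev), drop = FALSE]
  err <- purrr::map_dbl(seq_along(map), function(i) {
    if (is.na(map[i])) return(NA_real_)
    mean((est[i, ] - truth_prev[map[i], ])^2)
  })
  rmse <- sqrt(mean(err, na.rm = TRUE))
  tree_ok <- FALSE
  if (!anyNA(map) && !any(duplicated(map)) &&
      setequal(map, names(cohort$truth$parent))) {
    est_parent <- chosen_tree(rec$solutions)
    names(map) <- rec$clusters$cluster_id
    tree_ok <- all(purrr::map_lgl(names(est_parent), function(cid) {
      tp <- cohort$truth$parent[[map[[cid]]]]
      ep <- est_parent[[cid]]
      if (is.na(ep)) is.na(tp) else (!is.na(tp) && map[[ep]] == tp)
    }))
  }
  list(rmse = rmse, tree_recovered = tree_ok, n_clusters = nrow(rec$clusters))
}

#' Score seeding-event recovery on a scripted scenario cohort
#'
#' Runs the full reconstruction and migration classification and compares
#' the recovered `(source, target, kind)` event triples and incubator set
#' with the scripted truth.
#'
#' @param cohort A scenario cohort from [simulate_cohort()].
#' @param ... Passed to [reconstruct_subclones()].
#' @return List with `estimated`, `truth` (character vectors of event
#'   triples), `exact` (events and incubators both match) and
#'   `incubators_ok`.
#' @export
evaluate_seeding_recovery <- function(cohort, ...) {
  tbl <- call_somatic(cohort$variants)
  rec <- suppressMessages(suppressWarnings(
    reconstruct_subclones(tbl, cohort$purity, chroms = "chr14", ...)))
  tru <- paste(cohort$truth$events$source, cohort$truth$events$target,
               cohort$truth$events$kind)
  if (is.null(rec$atlas)) {
    return(list(estimated = character(), truth = tru, exact = FALSE,
                incubators_ok = FALSE))
  }
  mg <- infer_migration(rec$atlas, primary = cohort$truth$primary)
  est <- unique(paste(mg$edges$source, mg$edges$target, mg$edges$kind))
  inc_ok <- setequal(mg$incubators, cohort$truth$incubators)
  list(estimated = est, truth = tru,
       exact = setequal(est, tru) && length(est) == length(tru) && inc_ok,
       incubators_ok = inc_ok)
}

#' Brute-force subclone-tree enumeration via Prüfer sequences
#'
#' Independent oracle for [enumerate_trees()]: generates every labeled tree
#' on the clusters from all Prüfer sequences, roots each at the founding
#' cluster, and applies the same validity constraints directly. Intended
#' for small instances (at most ~7 clusters).
#'
#' @param prev Clusters x samples prevalence matrix.
#' @param tolerance Prevalence tolerance.
#' @return Character vector of serialized valid parent maps
#'   (`paste(parent, collapse = "|")` over clusters in row order).
#' @export
prufer_enumerate <- function(prev, tolerance = 0.1) {
  ids <- rownames(prev)
  n <- nrow(prev)
  root <- find_root_cluster(prev, rep(1L, n), tolerance)
  if (n == 1) return(paste(NA, collapse = "|"))
  if (n == 2) {
    seqs <- list(integer(0))
  } else {
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
    seqs <- split(as.matrix(grid), row(grid))
  }
  valid <- character()
  for (s in seqs) {
    edges <- prufer_to_edges(as.integer(s), n)
    parent <- orient_edges(edges, root, n)
    ok <- TRUE
    for (child in seq_len(n)) {
      pa <- parent[child]
      if (is.na(pa)) next
      if (any(prev[pa, ] < prev[child, ] - tolerance - 1e-9)) { ok <- FALSE; break }
    }
    if (ok) {
      for (v in seq_len(n)) {
        kids <- which(!is.na(parent) & parent == v)
        if (length(kids) == 0) next
        child_sum <- colSums(prev[kids, , drop = FALSE])
        if (any(child_sum > prev[v, ] + tolerance + 1e-9)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      named <- ifelse(is.na(parent), NA, ids[parent])
      valid <- c(valid, paste(named, collapse = "|"))
    }
  }
  sort(unique(valid))
}

# Decode a Prüfer sequence into an edge list on n labeled nodes.
prufer_to_edges <- function(s, n) {
  degree <- rep(1L, n)
  for (x in s) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, n - 1, 2)
  ptr <- 0L
  s2 <- s
  for (x in s) {
    leaf <- min(which(degree == 1L))
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, x)
    degree[leaf] <- 0L
    degree[x] <- degree[x] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- last
  edges
}

# Orient an undirected edge list away from the root -> parent vector.
orient_edges <- function(edges, root, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, n)
  queue <- root
  seen <- logical(n)
  seen[root] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  parent
}
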