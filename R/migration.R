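# Metastatic migration inference: seeding classification, recolonization,
# incubator detection, and the site migration graph with wave ordering.

#' Bundle a subclone tree and per-site prevalences into an atlas
#'
#' @param parent Named character vector mapping each subclone to its parent
#'   (root maps to `NA`), e.g. the chosen tree of [enumerate_trees()].
#' @param prev Subclones x sites prevalence matrix.
#' @param site_meta Optional tibble (`site`, `organ`).
#' @return An object of class `mst_atlas`.
#' @export
subclone_atlas <- function(parent, prev, site_meta = NULL) {
  stopifnot(setequal(names(parent), rownames(prev)))
  prev <- prev[names(parent), , drop = FALSE]
  root <- names(parent)[is.na(parent)]
  if (length(root) != 1) abort("parent map must have exactly one root")
  out <- list(parent = parent, prev = prev, root = root,
              site_meta = site_meta)
  class(out) <- "mst_atlas"
  out
}

#' @export
print.mst_atlas <- function(x, ...) {
  cat("<mst_atlas> ", nrow(x$prev), " subclones x ", ncol(x$prev),
      " sites, root ", x$root, "\n", sep = "")
  invisible(x)
}

# Ancestor chain of a node (excluding itself), rootwards.
node_ancestors <- function(parent, node) {
  out <- character()
  a <- parent[[node]]
  while (!is.na(a)) {
    out <- c(out, a)
    a <- parent[[a]]
  }
  out
}

# Nodes strictly between ancestor x and descendant y.
path_between <- function(parent, x, y) {
  chain <- c(y, node_ancestors(parent, y))
  i <- match(x, chain)
  if (is.na(i) || i < 3) return(character())
  chain[2:(i - 1)]
}

# Edge distance between two nodes in the subclone tree.
tree_distance <- function(parent, a, b) {
  anc_a <- c(a, node_ancestors(parent, a))
  anc_b <- c(b, node_ancestors(parent, b))
  common <- intersect(anc_a, anc_b)[1]
  (match(common, anc_a) - 1) + (match(common, anc_b) - 1)
}

# Standalone ("own") prevalence: cells whose most-derived subclone is s.
standalone_prevalence <- function(atlas) {
  prev <- atlas$prev
  own <- prev
  for (s in rownames(prev)) {
    kids <- names(atlas$parent)[!is.na(atlas$parent) & atlas$parent == s]
    if (length(kids) > 0) {
      own[s, ] <- prev[s, ] - colSums(prev[kids, , drop = FALSE])
    }
  }
  own
}

empty_events <- function() {
  tibble(source = character(), target = character(), kind = character(),
         subclones = character(), ambiguous = logical())
}

#' Classify monoclonal and polyclonal seeding events
#'
#' A subclone at partial prevalence in one site (its harbor, where it
#' emerged) and at full prevalence (at or above `full_threshold`) in another
#' site marks a monoclonal seeding of the latter by the former. Two or more
#' related subclones (siblings or ancestor/descendant) at low prevalence
#' (below `low_threshold`) in both sites of a pair mark a polyclonal seeding
#' event; its source is the site where the migrating subclones' parents are
#' more prevalent. The root (truncal) subclone designates the primary and
#' emits no events. A subclone with no harbor site inherits its parent's
#' source.
#'
#' @param atlas An `mst_atlas`.
#' @param full_threshold Prevalence taken as "100%"; default 0.9.
#' @param low_threshold "Low" prevalence bound for the polyclonal rule;
#'   default 0.5.
#' @param min_presence Prevalence below which a subclone is absent;
#'   default 0.05.
#' @param primary Optional primary-site name (tie-breaks polyclonal
#'   sources).
#' @return Tibble of events (`source`, `target`, `kind`, `subclones`
#'   comma-joined, `ambiguous`).
#' @export
classify_seeding <- function(atlas, full_threshold = 0.9, low_threshold = 0.5,
                             min_presence = 0.05, primary = NULL) {
  prev <- atlas$prev
  parent <- atlas$parent
  sites <- colnames(prev)
  subs <- setdiff(rownames(prev), atlas$root)
  harbor_of <- list()
  if (!is.null(primary)) harbor_of[[atlas$root]] <- primary
  events <- list()
  # process rootwards so a harborless subclone can inherit its parent's source
  depth <- purrr::map_int(rownames(prev), ~ length(node_ancestors(parent, .x)))
  for (s in subs[order(depth[match(subs, rownames(prev))])]) {
    founded <- sites[prev[s, ] >= full_threshold]
    harbors <- sites[prev[s, ] >= min_presence & prev[s, ] < full_threshold]
    source <- if (length(harbors) > 0) {
      if (length(harbors) == 1) harbors else {
        # tie-break by subclone-tree proximity of the harbor's resident clones
        prox <- purrr::map_dbl(harbors, function(h) {
          residents <- setdiff(rownames(prev)[prev[, h] >= min_presence], s)
          if (length(residents) == 0) return(Inf)
          min(purrr::map_dbl(residents, tree_distance, parent = parent, a = s))
        })
        c_sort(harbors[prox == min(prox)])[1]
      }
    } else {
      p <- parent[[s]]
      src <- harbor_of[[p]] %||% NA_character_
      if (is.na(src)) {
        inform(sprintf("subclone %s has no harbor site; origin inherited from parent lineage", s))
      }
      src
    }
    harbor_of[[s]] <- source
    for (t in setdiff(founded, source)) {
      if (is.na(source)) next
      events[[length(events) + 1]] <- tibble(
        source = source, target = t, kind = "monoclonal",
        subclone = s, ambiguous = FALSE)
    }
  }
  mono <- bind_rows(events)
  mono <- if (nrow(mono) == 0) empty_events() else mono |>
    group_by(.data$source, .data$target, .data$kind) |>
    summarise(subclones = paste(c_sort(unique(.data$subclone)), collapse = ","),
              ambiguous = FALSE, .groups = "drop")

  # polyclonal: related subclone sets at low prevalence in both sites
  poly <- list()
  if (length(sites) >= 2) {
    for (i in seq_len(length(sites) - 1)) {
      for (j in (i + 1):length(sites)) {
        a <- sites[i]; b <- sites[j]
        low_both <- subs[prev[subs, a] >= min_presence &
                           prev[subs, a] < low_threshold &
                           prev[subs, b] >= min_presence &
                           prev[subs, b] < low_threshold]
        if (length(low_both) < 1) next
        related <- function(x, y) {
          (!is.na(parent[[x]]) && !is.na(parent[[y]]) &&
             parent[[x]] == parent[[y]]) ||
            x %in% node_ancestors(parent, y) || y %in% node_ancestors(parent, x)
        }
        keep <- purrr::map_lgl(low_both, function(x) {
          any(purrr::map_lgl(setdiff(low_both, x), related, x = x))
        })
        # two or more related migrants, or a lone subclone at low prevalence
        # in both sites (it cannot make up either tumor alone)
        mig <- if (sum(keep) >= 2) low_both[keep] else low_both
        parents_prev <- function(site) {
          ps <- unique(stats::na.omit(unlist(parent[mig])))
          if (length(ps) == 0) 0 else sum(prev[ps, site])
        }
        pa <- parents_prev(a); pb <- parents_prev(b)
        # parent prevalences closer than 0.05 cannot order the pair reliably
        src <- if (pa > pb + 0.05) a else if (pb > pa + 0.05) b
          else if (!is.null(primary) && primary %in% c(a, b)) primary
          else if (pa > pb) a else if (pb > pa) b
          else c_sort(c(a, b))[1]
        tgt <- setdiff(c(a, b), src)
        poly[[length(poly) + 1]] <- tibble(
          source = src, target = tgt, kind = "polyclonal",
          subclones = paste(c_sort(mig), collapse = ","), ambiguous = FALSE)
      }
    }
  }
  bind_rows(mono, bind_rows(poly))
}

#' Detect recolonization of established sites
#'
#' A site A holding an ancestor X and a descendant Y, with at least one
#' intermediate on the X-to-Y path never standing alone at A but standing
#' alone exclusively at one other site B, indicates that Y evolved at B and
#' invaded (recolonized) A. "Standing alone" means cells whose most-derived
#' subclone is the intermediate (standalone prevalence at or above
#' `standalone_threshold`).
#'
#' @param atlas An `mst_atlas`.
#' @param min_presence Prevalence below which a subclone is absent;
#'   default 0.05.
#' @param standalone_threshold Standalone-prevalence cutoff; default 0.1.
#' @return Tibble of recolonization events; multiple candidate source sites
#'   are all reported with `ambiguous = TRUE`.
#' @export
detect_recolonization <- function(atlas, min_presence = 0.05,
                                  standalone_threshold = 0.1) {
  prev <- atlas$prev
  parent <- atlas$parent
  own <- standalone_prevalence(atlas)
  sites <- colnames(prev)
  events <- list()
  for (a in sites) {
    present <- rownames(prev)[prev[, a] >= min_presence]
    for (y in setdiff(present, atlas$root)) {
      # the anchor X must have an established resident population at A that
      # does not carry Y's branch (standalone X cells)
      anc_here <- intersect(node_ancestors(parent, y), present)
      anc_here <- anc_here[own[anc_here, a] >= standalone_threshold]
      for (x in anc_here) {
        mids <- path_between(parent, x, y)
        if (length(mids) == 0) next
        missing <- mids[own[mids, a] < standalone_threshold]
        if (length(missing) == 0) next
        # each missing intermediate must stand alone exclusively at one
        # other site (in-situ evolution suffices otherwise)
        origins <- purrr::map(missing, function(m) {
          setdiff(sites[own[m, ] >= standalone_threshold], a)
        })
        if (any(lengths(origins) != 1)) next
        bs <- unique(unlist(origins))
        # a recolonizer is not itself established at its origin site;
        # shared low prevalence there is co-migration, not recolonization
        bs <- bs[prev[y, bs] < min_presence]
        for (b in bs) {
          events[[length(events) + 1]] <- tibble(
            source = b, target = a, kind = "recolonization",
            subclones = y, ambiguous = length(bs) > 1)
        }
      }
    }
  }
  ev <- bind_rows(events)
  if (nrow(ev) == 0) return(empty_events())
  ev |> distinct(.data$source, .data$target, .data$kind, .data$subclones,
                 .data$ambiguous)
}

#' Flag subclonal incubator sites
#'
#' A site is an incubator when at least `min_chain` subclones forming an
#' ancestor-descendant chain each emerged there (it is their harbor) and
#' each seeded at least one other site from there.
#'
#' @param events Seeding events from [classify_seeding()].
#' @param atlas An `mst_atlas`.
#' @param min_chain Minimum chain length; default 2.
#' @param full_threshold,min_presence As in [classify_seeding()] (used to
#'   re-derive harbor sites).
#' @return Character vector of incubator sites.
#' @export
detect_incubators <- function(events, atlas, min_chain = 2,
                              full_threshold = 0.9, min_presence = 0.05) {
  if (nrow(events) == 0) return(character())
  prev <- atlas$prev
  parent <- atlas$parent
  out <- character()
  for (s in colnames(prev)) {
    ev_s <- events |> filter(.data$source == s, .data$kind == "monoclonal")
    if (nrow(ev_s) == 0) next
    seeded <- unique(unlist(strsplit(ev_s$subclones, ",")))
    # only subclones that actually emerged at s (harbor there)
    emerged <- seeded[prev[seeded, s] >= min_presence &
                        prev[seeded, s] < full_threshold]
    if (length(emerged) < min_chain) next
    # longest ancestor-descendant chain within `emerged`
    depth <- purrr::map_int(emerged, ~ length(node_ancestors(parent, .x)))
    emerged <- emerged[order(depth)]
    chain_len <- purrr::map_int(seq_along(emerged), function(i) {
      anc <- node_ancestors(parent, emerged[i])
      1L + sum(emerged[seq_len(i - 1)] %in% anc)
    })
    if (max(chain_len) >= min_chain) out <- c(out, s)
  }
  out
}

#' Assemble the migration graph with metastatic wave ordering
#'
#' Combines classified seeding events, sample groups and allele-state
#' precedences between groups into a site graph. The wave order is the
#' transitive closure of the supplied group precedences; a cycle is an
#' error naming the offending relations. Edge directions inconsistent with
#' the wave order (an edge from a later-wave group into an earlier-wave
#' founding) are reported in the `inconsistencies` attribute, not silently
#' fixed.
#'
#' @param events Event tibble ([classify_seeding()] plus
#'   [detect_recolonization()] rows).
#' @param groups Optional tibble (`sample`, `group`).
#' @param precedences Optional tibble (`earlier`, `later`, `locus`) of
#'   group-level allele-state orderings (see [order_allele_states()]).
#' @param incubators Optional character vector from [detect_incubators()].
#' @param primary Optional primary-site name.
#' @return An object of class `mst_migration`: list with `sites`, `edges`,
#'   `incubators`, `wave_order` (tibble `group`, `rank`) and `primary`.
#' @export
build_graph <- function(events, groups = NULL, precedences = NULL,
                        incubators = character(), primary = NULL) {
  sites <- c_sort(unique(c(events$source, events$target, primary)))
  wave_order <- NULL
  if (!is.null(precedences) && nrow(precedences) > 0) {
    gs <- unique(c(precedences$earlier, precedences$later))
    ord <- character()
    rem <- gs
    edges <- precedences
    while (length(rem) > 0) {
      has_pred <- unique(edges$later[edges$earlier %in% rem])
      free <- c_sort(setdiff(rem, has_pred))
      if (length(free) == 0) {
        abort(paste0("cycle in wave precedences among loci: ",
                     paste(unique(edges$locus), collapse = ", ")))
      }
      ord <- c(ord, list(free))
      rem <- setdiff(rem, free)
      edges <- edges |> filter(!.data$earlier %in% free)
    }
    wave_order <- purrr::imap(ord, function(g, i) tibble(group = g, rank = i)) |>
      bind_rows()
    if (!is.null(groups)) {
      wave_order <- wave_order |>
        bind_rows(tibble(group = setdiff(unique(groups$group),
                                         wave_order$group),
                         rank = NA_integer_))
    }
  } else if (!is.null(groups)) {
    wave_order <- tibble(group = c_sort(unique(groups$group)),
                         rank = NA_integer_)
  }
  # connectivity / founding sanity: every seeded site except the primary
  # should have an incoming edge
  unseeded <- setdiff(sites, c(events$target, primary))
  inconsistencies <- character()
  if (length(unseeded) > 0) {
    inconsistencies <- c(inconsistencies,
                         paste0("site(s) without incoming edge: ",
                                paste(unseeded, collapse = ", ")))
  }
  out <- list(sites = sites, edges = events, incubators = incubators,
              wave_order = wave_order, primary = primary,
              groups = groups, inconsistencies = inconsistencies)
  class(out) <- "mst_migration"
  out
}

#' @export
print.mst_migration <- function(x, ...) {
  cat("<mst_migration> ", length(x$sites), " sites, ", nrow(x$edges),
      " events", sep = "")
  if (length(x$incubators) > 0) {
    cat("; incubators: ", paste(x$incubators, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tidy a migration graph into its edge list
#'
#' @param x An `mst_migration`.
#' @param ... Unused.
#' @return The event tibble.
#' @export
tidy.mst_migration <- function(x, ...) as_tibble(x$edges)

#' Serialize a migration graph to DOT
#'
#' @param x An `mst_migration`.
#' @return A character scalar with the DOT source.
#' @export
migration_dot <- function(x) {
  style <- c(monoclonal = "color=blue", polyclonal = "color=green",
             recolonization = "color=red")
  nodes <- purrr::map_chr(x$sites, function(s) {
    deco <- if (s %in% x$incubators) " [shape=box,label=\"\\N (incubator)\"]" else ""
    paste0("  \"", s, "\"", deco, ";")
  })
  edges <- purrr::pmap_chr(x$edges, function(source, target, kind, subclones, ...) {
    paste0("  \"", source, "\" -> \"", target, "\" [", style[[kind]],
           ",label=\"", subclones, "\"];")
  })
  paste(c("digraph migration {", nodes, edges, "}"), collapse = "\n")
}

#' Plot a migration graph
#'
#' Sites are laid out on a circle; edges are colored by seeding kind.
#'
#' @param object An `mst_migration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mst_migration <- function(object, ...) {
  n <- length(object$sites)
  layout <- tibble(site = object$sites,
                   x = cos(2 * pi * (seq_len(n) - 1) / n),
                   y = sin(2 * pi * (seq_len(n) - 1) / n),
                   incubator = object$sites %in% object$incubators)
  ed <- object$edges |>
    left_join(layout, by = c(source = "site")) |>
    left_join(layout, by = c(target = "site"), suffix = c("", "_t"))
  ggplot(layout, aes(.data$x, .data$y)) +
    geom_segment(data = ed,
                 aes(xend = .data$x_t, yend = .data$y_t, colour = .data$kind),
                 arrow = arrow(length = unit(0.15, "inches")),
                 linewidth = 0.6) +
    geom_point(aes(shape = .data$incubator), size = 3) +
    geom_text(aes(label = .data$site), vjust = -1) +
    ggplot2::scale_colour_manual(values = c(monoclonal = "steelblue",
                                            polyclonal = "forestgreen",
                                            recolonization = "firebrick")) +
    theme_minimal() +
    labs(x = NULL, y = NULL, colour = "seeding", shape = "incubator")
}
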