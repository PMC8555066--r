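# Synthetic multi-site metastatic cohort simulator with full ground truth:
# subclone trees, per-branch mutations, site compositions encoding seeding
# scenarios, chromosome-scale CNV/LOH states, purities and binomial read
# sampling.

# Descendants (inclusive) of a clone in a parent map.
clone_descendants <- function(parent, clone) {
  out <- clone
  repeat {
    kids <- names(parent)[!is.na(parent) & parent %in% out &
                            !names(parent) %in% out]
    if (length(kids) == 0) break
    out <- c(out, kids)
  }
  out
}

# Mutation (carrying) prevalence matrix clones x sites from standalone
# ("own") cell fractions: a clone's mutations are carried by all its
# descendants' cells.
carrying_prevalence <- function(parent, own) {
  clones <- names(parent)
  t(vapply(clones, function(cl) {
    desc <- clone_descendants(parent, cl)
    colSums(t(own[, desc, drop = FALSE]))
  }, numeric(nrow(own))))
}

#' Simulate a subclone tree with per-branch mutations
#'
#' Each branch acquires `Poisson(muts_per_branch)` new variants (at least
#' one) at unique chromosome-14 positions, honoring the infinite sites
#' assumption; the truncal branch of clone `cl1` carries the founder
#' variants. Uses the current RNG state (seed it via [simulate_cohort()] or
#' `set.seed()`).
#'
#' @param n_subclones Number of subclones including the founding clone.
#' @param tree_shape `"random"` (each clone attaches to a uniformly chosen
#'   earlier clone), `"chain"`, or `"scripted"` with `parent` supplied.
#' @param parent Named character vector (`cl*` -> parent id, root `NA`) when
#'   `tree_shape = "scripted"`.
#' @param muts_per_branch Poisson mean of new variants per branch;
#'   default 33.
#' @return List with `parent` (named character vector) and `variants`
#'   (tibble `variant_id`, `clone`, `chrom`, `pos`).
#' @export
simulate_tree <- function(n_subclones, tree_shape = c("random", "chain", "scripted"),
                          parent = NULL, muts_per_branch = 33) {
  tree_shape <- match.arg(tree_shape)
  if (tree_shape == "scripted") {
    stopifnot(!is.null(parent))
    clones <- names(parent)
  } else {
    stopifnot(n_subclones >= 1)
    clones <- paste0("cl", seq_len(n_subclones))
    parent <- setNames(rep(NA_character_, n_subclones), clones)
    if (n_subclones > 1) {
      for (k in 2:n_subclones) {
        parent[k] <- if (tree_shape == "chain") clones[k - 1]
                     else clones[sample.int(k - 1, 1)]
      }
    }
  }
  counts <- pmax(1L, rpois(length(clones), muts_per_branch))
  pos <- 1000L * seq_len(sum(counts))
  variants <- tibble(
    clone = rep(clones, counts),
    chrom = "chr14",
    pos = pos,
    ref = "A", alt = "T"
  ) |>
    mutate(variant_id = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  list(parent = parent, variants = variants)
}

# Compositions where every site is a pure expansion of one subclone.
sim_composition_single <- function(parent, n_sites) {
  clones <- names(parent)
  resident <- clones[sample.int(length(clones), n_sites, replace = TRUE)]
  sites <- sprintf("S%02d", seq_len(n_sites))
  own <- matrix(0, n_sites, length(clones), dimnames = list(sites, clones))
  own[cbind(seq_len(n_sites), match(resident, clones))] <- 1
  own
}

# Compositions with a primary site plus one "home" site per non-root clone:
# the clone dominates its home with its parent lineage in the background.
# Designed so the planted tree is the (essentially unique) minimal-violation
# solution.
sim_composition_home <- function(parent) {
  clones <- names(parent)
  root <- clones[is.na(parent)]
  others <- setdiff(clones, root)
  sites <- c("P", paste0("H_", others))
  own <- matrix(0, length(sites), length(clones),
                dimnames = list(sites, clones))
  own["P", root] <- 1
  for (cl in others) {
    a <- runif(1, 0.45, 0.6)
    b <- runif(1, 0.2, 0.3)
    s <- paste0("H_", cl)
    own[s, cl] <- a
    p <- parent[[cl]]
    if (p == root) {
      own[s, root] <- 1 - a
    } else {
      own[s, p] <- b
      own[s, root] <- 1 - a - b
    }
  }
  own
}

#' Script a named seeding scenario with exact ground truth
#'
#' Emits a subclone tree, site compositions (standalone cell fractions that
#' satisfy the tree sum constraints with zero slack), the seeding events the
#' composition realizes, and — for `"four_waves"` — copy-number segments,
#' group labels and the planted allele-state wave ordering.
#'
#' Scenarios: `"jumping_board"` (a harbor site whose resident subclones
#' found all downstream sites), `"incubator"` (an ancestor-descendant chain
#' evolving at one site, each link founding another site),
#' `"recolonization"` (a descendant returning to an established site while
#' its intermediates stand alone only at the origin site), `"polyclonal"`
#' (two sibling subclones co-seeding a site at low prevalence) and
#' `"four_waves"` (four CNV-defined groups with a chromosome-3-style allele
#' ordering placing wave 1 first).
#'
#' @param name Scenario name.
#' @return List with `parent`, `own` (sites x clones standalone fractions),
#'   `events` (truth tibble `source`, `target`, `kind`, `subclones`),
#'   `incubators`, `primary`, and for `"four_waves"` also `segments`,
#'   `groups`, `allele_states`, `precedences`, `locus_chrom`.
#' @export
script_scenario <- function(name) {
  scenarios <- c("jumping_board", "incubator", "recolonization",
                 "polyclonal", "four_waves")
  if (!name %in% scenarios) {
    abort(paste0("unknown scenario '", name, "'; options: ",
                 paste(scenarios, collapse = ", ")))
  }
  own_matrix <- function(sites, clones, entries) {
    own <- matrix(0, length(sites), length(clones),
                  dimnames = list(sites, clones))
    for (e in entries) own[e[[1]], e[[2]]] <- as.numeric(e[[3]])
    own
  }
  ev <- function(...) {
    rows <- list(...)
    purrr::map(rows, function(r) {
      tibble(source = r[[1]], target = r[[2]], kind = r[[3]],
             subclones = r[[4]])
    }) |> bind_rows()
  }
  if (name == "jumping_board") {
    parent <- c(cl1 = NA, cl2 = "cl1", cl3 = "cl2", cl4 = "cl2")
    own <- own_matrix(c("P", "M1", "M2"), names(parent), list(
      list("P", "cl1", 0.4), list("P", "cl2", 0.6),
      list("M1", "cl3", 1), list("M2", "cl4", 1)))
    truth <- ev(list("P", "M1", "monoclonal", "cl2,cl3"),
                list("P", "M2", "monoclonal", "cl2,cl4"))
    list(parent = parent, own = own, events = truth,
         incubators = character(), primary = "P",
         purity_range = c(0.75, 0.95))
  } else if (name == "incubator") {
    parent <- c(cl1 = NA, cl2 = "cl1", cl3 = "cl2", cl4 = "cl3", cl5 = "cl4")
    own <- own_matrix(c("P", "I", "M3", "M4", "M5"), names(parent), list(
      list("P", "cl1", 1),
      list("I", "cl1", 0.20), list("I", "cl2", 0.20), list("I", "cl3", 0.22),
      list("I", "cl4", 0.20), list("I", "cl5", 0.18),
      list("M3", "cl3", 1), list("M4", "cl4", 1), list("M5", "cl5", 1)))
    truth <- ev(list("I", "M3", "monoclonal", "cl2,cl3"),
                list("I", "M4", "monoclonal", "cl2,cl3,cl4"),
                list("I", "M5", "monoclonal", "cl2,cl3,cl4,cl5"))
    list(parent = parent, own = own, events = truth,
         incubators = "I", primary = "P", purity_range = c(0.75, 0.95))
  } else if (name == "recolonization") {
    parent <- c(cl1 = NA, cl2 = "cl1", cl3 = "cl2", cl4 = "cl3")
    own <- own_matrix(c("P", "A", "B"), names(parent), list(
      list("P", "cl1", 0.55), list("P", "cl2", 0.45),
      list("A", "cl2", 0.5), list("A", "cl4", 0.5),
      list("B", "cl2", 0.2), list("B", "cl3", 0.8)))
    truth <- ev(list("P", "A", "monoclonal", "cl2"),
                list("P", "B", "monoclonal", "cl2"),
                list("B", "A", "recolonization", "cl4"))
    list(parent = parent, own = own, events = truth,
         incubators = character(), primary = "P",
         purity_range = c(0.75, 0.95))
  } else if (name == "polyclonal") {
    parent <- c(cl1 = NA, cl4 = "cl1", cl2 = "cl4", cl3 = "cl4")
    own <- own_matrix(c("S", "T"), names(parent), list(
      list("S", "cl1", 0.35), list("S", "cl4", 0.15),
      list("S", "cl2", 0.3), list("S", "cl3", 0.2),
      list("T", "cl1", 0.45), list("T", "cl2", 0.32), list("T", "cl3", 0.23)))
    truth <- ev(list("S", "T", "polyclonal", "cl2,cl3"))
    list(parent = parent, own = own, events = truth,
         incubators = character(), primary = "S",
         purity_range = c(0.75, 0.95))
  } else { # four_waves
    parent <- c(cl1 = NA, cl2 = "cl1", cl3 = "cl1", cl4 = "cl3", cl5 = "cl3")
    sites <- c("P", "g1a", "g1b", "g2a", "g2b", "g3a", "g3b", "g4a", "g4b")
    own <- own_matrix(sites, names(parent), c(
      list(list("P", "cl1", 0.2), list("P", "cl2", 0.3), list("P", "cl3", 0.5)),
      purrr::map(c("g1a", "g1b"), ~ list(.x, "cl2", 1)),
      purrr::map(c("g2a", "g2b"), ~ list(.x, "cl3", 1)),
      purrr::map(c("g3a", "g3b"), ~ list(.x, "cl4", 1)),
      purrr::map(c("g4a", "g4b"), ~ list(.x, "cl5", 1))))
    truth <- ev(list("P", "g1a", "monoclonal", "cl2"),
                list("P", "g1b", "monoclonal", "cl2"),
                list("P", "g2a", "monoclonal", "cl3"),
                list("P", "g2b", "monoclonal", "cl3"),
                list("P", "g3a", "monoclonal", "cl3,cl4"),
                list("P", "g3b", "monoclonal", "cl3,cl4"),
                list("P", "g4a", "monoclonal", "cl3,cl5"),
                list("P", "g4b", "monoclonal", "cl3,cl5"))
    groups <- tibble(
      sample = sites,
      group = c("ungrouped", "G1", "G1", "G2", "G2", "G3", "G3", "G4", "G4"))
    # per-group CNV chromosome (a gain and a loss -> two shared events), plus
    # the chromosome-3 analog whose allele states order wave 1 first
    group_chrom <- c(G1 = "chr5", G2 = "chr6", G3 = "chr7", G4 = "chr8")
    segs <- purrr::map(sites, function(s) {
      g <- groups$group[groups$sample == s]
      base <- tibble(sample = s, chrom = c("chr1", "chr1"),
                     start = c(0, 6e7), end = c(6e7, 1.2e8),
                     total_cn = 2L, log2_ratio = 0, loh = FALSE)
      chr3 <- if (g == "G1") {
        tibble(sample = s, chrom = "chr3", start = 0, end = 1e8,
               total_cn = 3L, log2_ratio = 0.58, loh = FALSE)
      } else if (g == "ungrouped") {
        tibble(sample = s, chrom = "chr3", start = 0, end = 1e8,
               total_cn = 2L, log2_ratio = 0, loh = FALSE)
      } else {
        tibble(sample = s, chrom = "chr3", start = 0, end = 1e8,
               total_cn = 2L, log2_ratio = 0, loh = TRUE)
      }
      extra <- if (g == "ungrouped") NULL else {
        gc <- group_chrom[[g]]
        tibble(sample = s, chrom = gc,
               start = c(0, 3e7, 6e7), end = c(3e7, 6e7, 9e7),
               total_cn = c(3L, 2L, 1L), log2_ratio = c(0.58, 0, -1),
               loh = c(FALSE, FALSE, TRUE))
      }
      neutral <- purrr::map(setdiff(unname(group_chrom), if (g == "ungrouped") character() else group_chrom[[g]]),
                            function(ch) tibble(sample = s, chrom = ch, start = 0, end = 9e7,
                                                total_cn = 2L, log2_ratio = 0, loh = FALSE)) |>
        bind_rows()
      bind_rows(base, chr3, extra, neutral)
    }) |> bind_rows()
    allele_states <- purrr::map(sites, function(s) {
      g <- groups$group[groups$sample == s]
      if (g == "G1") c(count_A = 2, count_B = 1)
      else if (g == "ungrouped") c(count_A = 1, count_B = 1)
      else c(count_A = 2, count_B = 0)
    })
    names(allele_states) <- sites
    precedences <- tibble(earlier = "G1", later = c("G2", "G3", "G4"),
                          locus = "chr3")
    list(parent = parent, own = own, events = truth,
         incubators = character(), primary = "P",
         purity_range = c(0.75, 0.95),
         segments = segs, groups = groups, allele_states = allele_states,
         precedences = precedences, locus_chrom = "chr3")
  }
}

#' Simulate read counts for a cohort
#'
#' Per tumor site and variant, the expected allele fraction follows the
#' purity mixture model: for a somatic variant on a copy-neutral locus,
#' \eqn{AF = p \cdot CP / 2} with `CP` the clone's mutation prevalence; for
#' inherited het variants at a CNV/LOH locus the allele-specific copy state
#' sets the expectation (see [expected_het_af()]). Depths are Poisson around
#' `depth_mean` and alternate counts binomial; sequencing-error alternate
#' reads appear at `error_rate`. Matched normals carry germline hets at AF
#' 0.5 and error reads only. With `noiseless = TRUE`, allele fractions are
#' (up to rounding at depth 10000) exactly their expectations.
#'
#' @param tree List from [simulate_tree()] (or a scripted scenario).
#' @param own Sites x clones standalone cell-fraction matrix.
#' @param purity Named numeric vector of per-site purities.
#' @param depth_mean Mean sequencing depth; default 60.
#' @param n_normals Number of matched normal samples; default 2.
#' @param error_rate Per-base sequencing error alternate-read rate;
#'   default 1e-3.
#' @param noiseless Replace sampling by expectations; default FALSE.
#' @param germline Optional tibble of inherited het variants (`variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `hap` in `"A"`/`"B"`).
#' @param allele_states Optional named list site -> `c(count_A, count_B)`
#'   for the germline locus.
#' @return Long variant table (see [load_vcf()]) covering tumor sites and
#'   normals, with `"normals"`/`"samples"` attributes set.
#' @export
simulate_reads <- function(tree, own, purity, depth_mean = 60, n_normals = 2,
                           error_rate = 1e-3, noiseless = FALSE,
                           germline = NULL, allele_states = NULL) {
  sites <- rownames(own)
  normals <- if (n_normals > 0) paste0("N", seq_len(n_normals)) else character()
  carrying <- carrying_prevalence(tree$parent, own)
  variants <- tree$variants
  qual <- runif(nrow(variants) + if (is.null(germline)) 0 else nrow(germline),
                200, 1000)
  exp_af <- function(sample, tab) {
    if (sample %in% normals) {
      ifelse(tab$somatic, 0, 0.5)
    } else {
      p <- purity[[sample]]
      af <- numeric(nrow(tab))
      som <- tab$somatic
      af[som] <- p * carrying[tab$clone[som], sample] / 2
      if (any(!som)) {
        st <- if (!is.null(allele_states)) allele_states[[sample]] else c(1, 1)
        cn <- sum(st)
        m <- ifelse(tab$hap[!som] == "A", st[[1]], st[[2]])
        af[!som] <- expected_het_af(m, cn, p)
      }
      af
    }
  }
  tab <- variants |> mutate(somatic = TRUE, hap = NA_character_)
  if (!is.null(germline)) {
    tab <- bind_rows(tab, germline |> mutate(somatic = FALSE, clone = NA_character_))
  }
  tab$qual <- qual
  all_samples <- c(sites, normals)
  rows <- purrr::map(all_samples, function(s) {
    af0 <- exp_af(s, tab)
    af_eff <- af0 + (1 - af0) * error_rate
    if (noiseless) {
      depth <- rep(10000L, nrow(tab))
      af_eff <- af0  # expectations, no error reads
      alt_reads <- as.integer(round(af_eff * depth))
    } else {
      depth <- rpois(nrow(tab), depth_mean)
      alt_reads <- rbinom(nrow(tab), depth, af_eff)
    }
    tibble(variant_id = tab$variant_id, chrom = tab$chrom, pos = tab$pos,
           ref = tab$ref, alt = tab$alt, qual = tab$qual,
           multiallelic = FALSE, sample = s, depth = depth,
           alt_count = alt_reads,
           af = ifelse(depth > 0, alt_reads / depth, NA_real_))
  })
  out <- bind_rows(rows) |> arrange(.data$chrom, .data$pos, .data$sample)
  attr(out, "normals") <- normals
  attr(out, "samples") <- all_samples
  out
}

#' Simulate a complete multi-site cohort with ground truth
#'
#' Draws a subclone tree (or a scripted scenario), site compositions,
#' per-site purities and read counts, returning both the pipeline inputs
#' and a truth bundle sufficient to score every downstream inference. All
#' randomness flows through a single stream keyed by `seed`, so identical
#' configurations are bit-reproducible.
#'
#' @param seed Integer RNG seed.
#' @param n_subclones,tree_shape,muts_per_branch Tree parameters
#'   (see [simulate_tree()]); ignored when `scenario` is given.
#' @param n_sites Number of tumor sites for `composition = "single_clone"`.
#' @param composition `"single_clone"` (each site a pure subclone
#'   expansion), `"home_sites"` (a primary plus one mixed home site per
#'   subclone) or `"scripted"` (via `scenario`).
#' @param scenario Optional scenario name (see [script_scenario()]).
#' @param purity_range Per-site purity range; default `c(0.6, 1)`, or the
#'   scenario's own range (scripted scenarios use `c(0.75, 0.95)`,
#'   reflecting the high-purity samples such analyses are restricted to).
#' @param depth_mean,n_normals,error_rate,noiseless Passed to
#'   [simulate_reads()].
#' @param germline_n Number of inherited het variants at the CNV locus in
#'   `"four_waves"`; default 30.
#' @return List with `variants` (long table), `purity` (tibble `sample`,
#'   `purity`) and `truth` (list: `parent`, `variant_clone` map, `own`,
#'   `carrying`, `events`, `incubators`, `groups`, `segments`,
#'   `precedences`, `primary`, `config`).
#' @export
simulate_cohort <- function(seed, n_subclones = 8, n_sites = 12,
                            tree_shape = "random", muts_per_branch = 33,
                            composition = c("single_clone", "home_sites",
                                            "scripted"),
                            scenario = NULL, purity_range = NULL,
                            depth_mean = 60, n_normals = 2, error_rate = 1e-3,
                            noiseless = FALSE, germline_n = 30) {
  composition <- if (!is.null(scenario)) "scripted" else match.arg(composition)
  set.seed(seed)
  sc <- NULL
  if (composition == "scripted") {
    sc <- script_scenario(scenario)
    tree <- simulate_tree(tree_shape = "scripted", parent = sc$parent,
                          muts_per_branch = muts_per_branch)
    own <- sc$own
  } else {
    tree <- simulate_tree(n_subclones, tree_shape,
                          muts_per_branch = muts_per_branch)
    own <- if (composition == "single_clone") {
      sim_composition_single(tree$parent, n_sites)
    } else {
      sim_composition_home(tree$parent)
    }
  }
  purity_range <- purity_range %||% sc$purity_range %||% c(0.6, 1)
  sites <- rownames(own)
  purity <- setNames(runif(length(sites), purity_range[1], purity_range[2]),
                     sites)
  germline <- NULL
  if (!is.null(sc$locus_chrom)) {
    germline <- tibble(
      chrom = sc$locus_chrom,
      pos = 2000L * seq_len(germline_n),
      ref = "C", alt = "G",
      hap = sample(c("A", "B"), germline_n, replace = TRUE)
    ) |>
      mutate(variant_id = variant_key(.data$chrom, .data$pos, .data$ref,
                                      .data$alt))
  }
  variants <- simulate_reads(tree, own, purity, depth_mean = depth_mean,
                             n_normals = n_normals, error_rate = error_rate,
                             noiseless = noiseless, germline = germline,
                             allele_states = sc$allele_states)
  list(
    variants = variants,
    purity = tibble(sample = sites, purity = unname(purity)),
    truth = list(
      parent = tree$parent,
      variant_clone = setNames(tree$variants$clone, tree$variants$variant_id),
      own = own,
      carrying = carrying_prevalence(tree$parent, own),
      events = sc$events %||% NULL,
      incubators = sc$incubators %||% character(),
      groups = sc$groups %||% NULL,
      segments = sc$segments %||% NULL,
      precedences = sc$precedences %||% NULL,
      allele_states = sc$allele_states %||% NULL,
      locus_chrom = sc$locus_chrom %||% NULL,
      primary = sc$primary %||% "P",
      seed = seed
    )
  )
}
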