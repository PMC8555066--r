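binmat <- function(rows, samples) {
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  rownames(m) <- paste0("v", seq_len(nrow(m)))
  m
}

clusters_from_sets <- function(sets, n = NULL) {
  n <- n %||% rep(1L, length(sets))
  tibble::tibble(cluster_id = paste0("VC", seq_along(sets)),
                 n_variants = as.integer(n),
                 sample_set = sets,
                 members = purrr::map2(seq_along(sets), n,
                                       ~ paste0("v", .x, "_", seq_len(.y))))
}

test_that("binary encoding thresholds AF strictly and drops empty rows", {
  af <- matrix(c(0.11, 0.10, 0, 0.3, 0.05, 0), 3, 2, byrow = TRUE,
               dimnames = list(c("chr14:10:A:T", "chr14:20:A:T",
                                 "chr14:30:A:T"), c("S1", "S2")))
  tbl <- table_from_af(af)
  m <- encode_binary(tbl, chroms = "chr14", samples = c("S1", "S2"))
  expect_equal(m["chr14:10:A:T", ], c(S1 = 1L, S2 = 0L))  # 0.11 > 0.1; 0.10 is absent
  expect_equal(m["chr14:20:A:T", ], c(S1 = 0L, S2 = 1L))
  expect_false("chr14:30:A:T" %in% rownames(m))           # all-absent row dropped
  expect_error(encode_binary(tbl, chroms = character()), "empty")
})

test_that("variants with identical occurrence vectors cluster together", {
  m <- binmat(list(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1)), c("S1", "S2", "S3"))
  cl <- cluster_variants(m)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$n_variants), c(1L, 2L))

  m1 <- binmat(list(c(1, 0), c(1, 0)), c("S1", "S2"))
  expect_equal(nrow(cluster_variants(m1)), 1)

  # brute-force check on a 6-row matrix
  set.seed(11)
  m6 <- binmat(purrr::map(1:6, ~ rbinom(3, 1, 0.5) + c(1, 0, 0) * 0), c("A", "B", "C"))
  m6 <- m6[rowSums(m6) > 0, , drop = FALSE]
  cl6 <- cluster_variants(m6)
  brute <- unname(split(rownames(m6), apply(m6, 1, paste, collapse = "")))
  expect_setequal(purrr::map_chr(cl6$members, ~ paste(sort(.x), collapse = ",")),
                  purrr::map_chr(brute, ~ paste(sort(.x), collapse = ",")))
})

test_that("cluster compatibility follows nested/disjoint/conflict trichotomy", {
  expect_equal(check_compatibility(c("S1", "S2"), "S1"), "nested")
  expect_equal(check_compatibility("S1", "S2"), "disjoint")
  expect_equal(check_compatibility(c("S1", "S2"), c("S2", "S3")), "conflict")
})

test_that("mixture samples are flagged greedily and conflicts resolve", {
  samples <- c("S1", "S2", "S3")
  # conflict-free
  cl_ok <- clusters_from_sets(list(c("S1", "S2", "S3"), c("S1", "S2"), "S3"))
  expect_length(flag_mixture_samples(cl_ok, samples)$mixture_samples, 0)

  # single conflicting pair: the shared sample resolves it (validated by
  # exhaustive search over single removals)
  cl_bad <- clusters_from_sets(list(c("S1", "S2"), c("S2", "S3")))
  fx <- flag_mixture_samples(cl_bad, samples)
  expect_equal(fx$mixture_samples, "S2")
  resolves <- purrr::map_lgl(samples, function(s) {
    proj <- metastrack:::project_clusters(cl_bad, setdiff(samples, s))
    length(metastrack:::conflict_pairs(proj)) == 0
  })
  expect_true(resolves[samples == "S2"])
  expect_length(metastrack:::conflict_pairs(fx$clusters), 0)

  # planted mixture site: a sample carrying two divergent lineages
  sets <- list(c("A", "B", "C", "MIX"), c("A", "MIX"), c("B", "MIX"), "C")
  fx2 <- flag_mixture_samples(clusters_from_sets(sets), c("A", "B", "C", "MIX"))
  expect_equal(fx2$mixture_samples, "MIX")
})

test_that("after mixture flagging no conflicts remain (random matrices)", {
  set.seed(13)
  for (i in 1:20) {
    m <- binmat(purrr::map(1:12, ~ rbinom(5, 1, 0.4)), paste0("S", 1:5))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0) next
    cl <- cluster_variants(m)
    fx <- tryCatch(flag_mixture_samples(cl, paste0("S", 1:5)),
                   error = function(e) NULL)  # degenerate-matrix guard
    if (is.null(fx)) next
    expect_length(metastrack:::conflict_pairs(fx$clusters), 0)
  }
})

test_that("perfect phylogeny arranges clusters by containment", {
  samples <- c("S1", "S2", "S3")
  cl <- clusters_from_sets(list(c("S1", "S2", "S3"), c("S1", "S2"), "S3"),
                           n = c(5, 3, 2))
  ph <- build_perfect_phylogeny(cl, samples)
  nodes <- tidy(ph)
  expect_equal(nodes$parent[nodes$node == "VC2"], "VC1")
  expect_equal(nodes$parent[nodes$node == "VC3"], "VC1")
  expect_equal(nodes$parent[nodes$node == "S3"], "VC3")
  expect_equal(nodes$n_variants[nodes$node == "VC1"], 5L)

  # every cluster's sample set equals the leaf set of its subtree
  leafset <- function(node) {
    kids <- nodes$node[!is.na(nodes$parent) & nodes$parent == node]
    if (length(kids) == 0) return(node)
    unlist(purrr::map(kids, leafset))
  }
  for (i in which(nodes$type == "cluster")) {
    expect_setequal(leafset(nodes$node[i]),
                    strsplit(nodes$sample_set[i], ",")[[1]])
  }

  # single sample: single-leaf tree with the truncal branch
  ph1 <- build_perfect_phylogeny(clusters_from_sets(list("S1"), n = 7), "S1")
  expect_equal(sum(tidy(ph1)$n_variants), 7L)

  # conflicting clusters are rejected
  expect_error(build_perfect_phylogeny(
    clusters_from_sets(list(c("S1", "S2"), c("S2", "S3"))), samples),
    "conflict")
})

test_that("noiseless simulated cohorts are reconstructed exactly", {
  for (s in c(301, 302, 303)) {
    co <- simulate_cohort(seed = s, n_subclones = 10, n_sites = 12,
                          composition = "single_clone", noiseless = TRUE)
    expect_true(evaluate_phylogeny_recovery(co))
  }
})

test_that("presence regenerated from the tree matches the input matrix", {
  co <- simulate_cohort(seed = 44, n_subclones = 7, n_sites = 9,
                        composition = "single_clone", noiseless = TRUE)
  tbl <- call_somatic(co$variants)
  samples <- setdiff(unique(tbl$sample), attr(tbl, "normals"))
  m <- encode_binary(tbl, chroms = "chr14")
  cl <- cluster_variants(m)
  # each variant's row equals its cluster's sample-set indicator
  for (i in seq_len(nrow(cl))) {
    ind <- as.integer(colnames(m) %in% cl$sample_set[[i]])
    for (v in cl$members[[i]]) expect_equal(unname(m[v, ]), ind)
  }
})

test_that("hamming UPGMA cross-check behaves like the profile version", {
  m <- binmat(list(c(1, 1, 0, 0), c(0, 1, 1, 1), c(0, 0, 1, 1)),
              c("A", "B", "C", "D"))
  # identical columns merge at height 0
  expect_equal(upgma_hamming(m)$height[1], 0)  # C and D identical
  # hand-computed: d(A,B)=1, d(C,D)=0, then mean(3,3,2,2) = 2.5
  hc <- upgma_hamming(m)
  expect_equal(sort(hc$height), c(0, 1, 2.5))
  expect_error(upgma_hamming(m[, 1, drop = FALSE]), "2 samples")
})

test_that("sharing fractions decompose into truncal/shared/private", {
  af <- matrix(c(0.4, 0.4, 0.0,   # in primary and M1 -> truncal for M1
                 0.0, 0.3, 0.3,   # shared between M1 and M2
                 0.0, 0.4, 0.0,   # private to M1
                 0.3, 0.0, 0.0),  # primary-only
               4, 3, byrow = TRUE,
               dimnames = list(paste0("chr14:", 1:4 * 10, ":A:T"),
                               c("P", "M1", "M2")))
  tbl <- table_from_af(af)
  st <- sharing_stats(tbl, "P", samples = c("P", "M1", "M2"))
  m1 <- st[st$sample == "M1", ]
  expect_equal(unlist(m1[-1], use.names = FALSE), c(1 / 3, 1 / 3, 1 / 3))
  m2 <- st[st$sample == "M2", ]
  expect_equal(unlist(m2[-1], use.names = FALSE), c(0, 1, 0))
  expect_error(sharing_stats(tbl, "nope"), "primary")

  # identical to primary -> all truncal; fully private -> all private
  af2 <- matrix(c(0.4, 0.4, 0, 0.3, 0.3, 0, 0, 0, 0.5), 3, 3, byrow = TRUE,
                dimnames = list(paste0("chr14:", 1:3 * 10, ":A:T"),
                                c("P", "Twin", "Lone")))
  st2 <- sharing_stats(table_from_af(af2), "P")
  expect_equal(st2$truncal_fraction[st2$sample == "Twin"], 1)
  expect_equal(st2$private_fraction[st2$sample == "Lone"], 1)
})

test_that("variants land in the correct cluster under read noise", {
  # two clones with true AFs at least 0.15 from the 0.1 threshold
  set.seed(99)
  n <- 200; depth <- 60
  truth <- rbind(c(0.45, 0.45, 0.0), c(0.45, 0.25, 0.30))
  assign <- sample(1:2, n, replace = TRUE)
  af <- t(vapply(assign, function(k) rbinom(3, depth, truth[k, ]) / depth,
                 numeric(3)))
  dimnames(af) <- list(paste0("chr14:", 1:n * 10, ":A:T"), c("S1", "S2", "S3"))
  m <- encode_binary(table_from_af(af, depth = depth), chroms = "chr14",
                     samples = c("S1", "S2", "S3"))
  expected_pattern <- apply((truth > 0.1) * 1L, 1, paste, collapse = "")
  got <- apply(m[rownames(af), ], 1, paste, collapse = "")
  expect_gte(mean(got == expected_pattern[assign]), 0.95)
})
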