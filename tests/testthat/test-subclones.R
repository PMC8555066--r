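test_that("VAF clustering groups by presence pattern then AF level", {
  # two variants within tolerance everywhere form one cluster
  af <- matrix(c(0.48, 0.25, 0.50, 0.27), 2, 2, byrow = TRUE,
               dimnames = list(c("chr14:10:A:T", "chr14:20:A:T"),
                               c("S1", "S2")))
  cl <- cluster_vafs(table_from_af(af))
  expect_equal(nrow(cl), 1)
  expect_equal(unname(attr(cl, "mean_af")[1, ]), c(0.49, 0.26))

  # different presence patterns never merge
  af2 <- matrix(c(0.5, 0, 0, 0.5), 2, 2, byrow = TRUE,
                dimnames = list(c("chr14:10:A:T", "chr14:20:A:T"),
                                c("S1", "S2")))
  expect_equal(nrow(cluster_vafs(table_from_af(af2))), 2)

  # empty region warns and returns an empty cluster set
  empty <- table_from_af(af)[0, ]
  attr(empty, "samples") <- c("S1", "S2")
  attr(empty, "normals") <- character()
  expect_warning(cl0 <- cluster_vafs(empty), "no somatic")
  expect_equal(nrow(cl0), 0)

  # simulated cohort: cluster count equals planted clone count
  co <- simulate_cohort(seed = 77, n_subclones = 5, composition = "home_sites",
                        depth_mean = 60)
  tbl <- call_somatic(co$variants)
  cl_sim <- cluster_vafs(tbl, chroms = "chr14", purity = co$purity)
  big <- sum(cl_sim$n_variants >= 5)
  expect_equal(big, 5)
})

test_that("prevalence applies the purity and copy-state correction", {
  expect_equal(prevalence(0.5, 1), 1)          # founding clone in a pure sample
  expect_equal(prevalence(0.2, 0.8), 0.5)      # 2*af/purity
  expect_warning(p <- prevalence(0.4, 0.5), "capped")
  expect_equal(p, 1)
  # single-copy regions (group-shared deletion): CP = af at purity 1
  expect_equal(prevalence(0.7, 1, copies_total = 1, copies_variant = 1), 0.7)
  expect_error(prevalence(0.2, 0), "purity")

  # monotone increasing in AF, decreasing in purity
  afs <- seq(0.01, 0.45, by = 0.02)
  expect_true(all(diff(prevalence(afs, 0.95)) > 0))
  ps <- seq(0.5, 1, by = 0.05)
  expect_true(all(diff(prevalence(0.2, ps)) < 0))
})

test_that("tree enumeration matches hand-enumerated solutions", {
  # one sample, prevalences 1.0/0.6/0.3: chain and star are both valid
  prev1 <- matrix(c(1, 0.6, 0.3), 3, 1,
                  dimnames = list(c("A", "B", "C"), "S1"))
  sol1 <- enumerate_trees(prev1, tolerance = 0.1)
  sers <- sort(vapply(sol1$trees, paste, "", collapse = "|"))
  expect_equal(sers, sort(c("NA|A|B", "NA|A|A")))

  # a second sample disambiguates: only the star remains
  prev2 <- cbind(prev1, c(1, 0.0, 1))
  colnames(prev2) <- c("S1", "S2")
  sol2 <- enumerate_trees(prev2, tolerance = 0.1)
  expect_length(sol2$trees, 1)
  expect_equal(unname(sol2$trees[[1]]), c(NA, "A", "A"))

  # single cluster: trivial tree with zero violation
  sol0 <- enumerate_trees(matrix(1, 1, 1, dimnames = list("A", "S1")))
  expect_equal(sol0$violations, 0)
  expect_equal(sol0$chosen, 1L)

  # combinatorial guard
  big <- matrix(runif(13 * 2), 13, 2)
  expect_error(enumerate_trees(big), "12")
})

test_that("enumeration agrees with the Prüfer brute-force oracle", {
  set.seed(31)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    s <- sample(1:3, 1)
    prev <- rbind(matrix(runif(s, 0.92, 1), 1),
                  matrix(runif((k - 1) * s, 0, 0.9), k - 1))
    rownames(prev) <- paste0("C", seq_len(k))
    sol <- suppressWarnings(enumerate_trees(prev, tolerance = 0.1))
    mine <- if (length(sol$trees) > 0) {
      sort(vapply(sol$trees, paste, "", collapse = "|"))
    } else character()
    expect_identical(unname(mine), prufer_enumerate(prev, tolerance = 0.1))
  }
})

test_that("every reported tree satisfies the child-sum constraint", {
  set.seed(17)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    prev <- rbind(rep(1, 2), matrix(runif((k - 1) * 2, 0, 0.9), k - 1))
    rownames(prev) <- paste0("C", seq_len(k))
    sol <- suppressWarnings(enumerate_trees(prev, tolerance = 0.1))
    for (tr in sol$trees) {
      idx <- setNames(seq_len(k), rownames(prev))
      parent <- unname(idx[tr])
      expect_true(metastrack:::tree_valid(parent, prev, 0.1))
    }
  }
})

test_that("solution sets tidy and glance into tabular summaries", {
  prev <- matrix(c(1, 0.6, 0.3), 3, 1,
                 dimnames = list(c("A", "B", "C"), "S1"))
  sol <- enumerate_trees(prev, tolerance = 0.1)
  td <- tidy(sol)
  expect_equal(nrow(td), 3 * length(sol$trees))
  expect_equal(sum(td$chosen), 3)
  gl <- glance(sol)
  expect_equal(gl$n_trees, length(sol$trees))
  expect_equal(gl$n_clusters, 3)
})

test_that("multi-sample assembly merges shared clusters and reports conflicts", {
  prev_a <- matrix(c(1, 0.6, 0.3), 3, 1,
                   dimnames = list(c("F", "X", "Y"), "S1"))
  sol_a <- enumerate_trees(cbind(prev_a, c(1, 0, 1)), tolerance = 0.1)
  # identical solutions join to the same tree
  joint <- assemble_multi_sample(list(g1 = sol_a, g2 = sol_a))
  tr <- metastrack:::chosen_tree(sol_a)
  expect_equal(setNames(joint$parent, joint$cluster)[names(tr)], tr)
  expect_equal(nrow(attr(joint, "conflicts")), 0)

  # disjoint cluster sets sharing only the founder star-join at the founder
  prev_b <- matrix(c(1, 0.5), 2, 1, dimnames = list(c("F", "Z"), "S3"))
  sol_b <- enumerate_trees(prev_b, tolerance = 0.1)
  joint2 <- assemble_multi_sample(list(g1 = sol_a, g2 = sol_b))
  expect_setequal(joint2$cluster, c("F", "X", "Y", "Z"))
  expect_equal(joint2$parent[joint2$cluster == "Z"], "F")

  # conflicting parentage is resolved by violation and reported
  sol_c <- sol_a
  sol_c$trees <- list(c(F = NA, X = "F", Y = "X"))
  sol_c$violations <- 0
  sol_c$chosen <- 1L
  joint3 <- assemble_multi_sample(list(g1 = sol_a, g2 = sol_c))
  expect_equal(nrow(attr(joint3, "conflicts")), 1)
  expect_equal(attr(joint3, "conflicts")$cluster, "Y")
})
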