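seg <- function(sample, chrom, start, end, cn, log2, loh = FALSE) {
  tibble::tibble(sample = sample, chrom = chrom, start = start, end = end,
                 total_cn = cn, log2_ratio = log2, loh = loh)
}

test_that("bin_log2 computes length-weighted window means and flags gaps", {
  # one segment spanning three full bins
  b <- bin_log2(seg("S1", "chr1", 0, 3e6, 3, 0.58))
  expect_equal(nrow(b), 3)
  expect_equal(b$log2, rep(0.58, 3))

  # two segments half-covering one bin: weighted mean
  segs <- dplyr::bind_rows(seg("S1", "chr1", 0, 5e5, 2, 0),
                           seg("S1", "chr1", 5e5, 1e6, 3, 1))
  expect_equal(bin_log2(segs)$log2, 0.5)

  # a sample without coverage of a bin gets NA there, not zero
  segs2 <- dplyr::bind_rows(seg("S1", "chr1", 0, 2e6, 2, 0.2),
                            seg("S2", "chr1", 0, 1e6, 2, 0.1))
  b2 <- bin_log2(segs2)
  expect_true(is.na(b2$log2[b2$sample == "S2" & b2$bin_start == 1e6]))

  # overlapping segments are a data error naming the interval
  expect_error(bin_log2(dplyr::bind_rows(seg("S1", "chr1", 0, 1e6, 2, 0),
                                         seg("S1", "chr1", 5e5, 2e6, 2, 1))),
               "overlapping")
})

test_that("cluster_profiles reproduces hand-computed UPGMA", {
  # 1-D profiles 0, 1, 10, 12 -> distances AB=1, CD=2, (AB)(CD)=10.5
  segs <- dplyr::bind_rows(seg("A", "chr1", 0, 1e6, 2, 0),
                           seg("B", "chr1", 0, 1e6, 2, 1),
                           seg("C", "chr1", 0, 1e6, 2, 10),
                           seg("D", "chr1", 0, 1e6, 2, 12))
  hc <- cluster_profiles(bin_log2(segs))
  expect_equal(sort(hc$height), c(1, 2, 10.5))

  # identical profiles merge at height 0
  segs_id <- dplyr::bind_rows(seg("A", "chr1", 0, 1e6, 2, 0.3),
                              seg("B", "chr1", 0, 1e6, 2, 0.3))
  expect_equal(cluster_profiles(bin_log2(segs_id))$height, 0)

  # two identical + one distant: the identical pair merges first
  segs3 <- dplyr::bind_rows(seg("A", "chr1", 0, 1e6, 2, 0),
                            seg("B", "chr1", 0, 1e6, 2, 0),
                            seg("C", "chr1", 0, 1e6, 2, 5))
  hc3 <- cluster_profiles(bin_log2(segs3))
  expect_equal(hc3$height[1], 0)
  expect_error(cluster_profiles(bin_log2(seg("A", "chr1", 0, 1e6, 2, 0))),
               "2 samples")
})

test_that("assign_groups recovers planted CNV groups and leaves the rest ungrouped", {
  co <- simulate_cohort(seed = 3, scenario = "four_waves", depth_mean = 200)
  grp <- assign_groups(bin_log2(co$truth$segments))
  merged <- dplyr::left_join(grp, co$truth$groups, by = "sample",
                             suffix = c("_est", "_truth"))
  # same partition (labels may permute)
  tab <- table(merged$group_est, merged$group_truth)
  expect_equal(sum(tab > 0), length(unique(merged$group_truth)))
  expect_equal(merged$group_est[merged$group_truth == "ungrouped"], "ungrouped")

  # all-identical profiles (sharing two discrete events) form a single group
  segs_id <- dplyr::bind_rows(seg("A", "chr1", 0, 5e6, 3, 0.58),
                              seg("A", "chr2", 0, 5e6, 1, -1),
                              seg("B", "chr1", 0, 5e6, 3, 0.58),
                              seg("B", "chr2", 0, 5e6, 1, -1))
  expect_true(all(assign_groups(bin_log2(segs_id))$group == "G1"))

  # flat profiles share no events: all ungrouped
  segs_flat <- dplyr::bind_rows(seg("A", "chr1", 0, 5e6, 2, 0),
                                seg("B", "chr1", 0, 5e6, 2, 0.01))
  expect_true(all(assign_groups(bin_log2(segs_flat))$group == "ungrouped"))
})

test_that("expected het AF follows the purity mixture model", {
  # pure tumor, total CN 3: the two alleles sit at 1/3 and 2/3
  expect_equal(round(expected_het_af(c(1, 2), 3, 1), 2), c(0.33, 0.67))
  # pure tumor, copy-neutral LOH: AF collapses to 0 or 1
  expect_equal(expected_het_af(c(0, 2), 2, 1), c(0, 1))
  # half-pure tumor, copy-neutral LOH, variant on the retained allele
  expect_equal(expected_het_af(2, 2, 0.5), 0.75)
  # reductions: m/c at purity 1; 0.5 for a balanced het at any purity
  m <- sample(0:3, 20, replace = TRUE)
  c_tot <- m + sample(1:3, 20, replace = TRUE)
  expect_equal(expected_het_af(m, c_tot, 1), m / c_tot)
  expect_equal(expected_het_af(1, 2, runif(10, 0.01, 1)), rep(0.5, 10))
})

test_that("paired allele states are recovered from inherited variant AFs", {
  set.seed(42)
  sim_pair <- function(n, st1, st2, p1, p2, depth = 60) {
    hap <- sample(c("A", "B"), n, replace = TRUE)
    m1 <- ifelse(hap == "A", st1[1], st1[2])
    m2 <- ifelse(hap == "A", st2[1], st2[2])
    e1 <- expected_het_af(m1, sum(st1), p1)
    e2 <- expected_het_af(m2, sum(st2), p2)
    tibble::tibble(af_1 = rbinom(n, depth, e1) / depth,
                   af_2 = rbinom(n, depth, e2) / depth)
  }
  # amplified-allele-retained pattern (concordant)
  res <- infer_allele_state_pair(sim_pair(30, c(2, 1), c(2, 0), 1, 1), 3, 2)
  expect_equal(unname(res$state_1), c(2, 1))
  expect_equal(unname(res$state_2), c(2, 0))
  expect_true(res$concordant)
  expect_gte(res$vote_fraction, 0.9)

  # discordant: the allele amplified in sample 1 is lost in sample 2
  res2 <- infer_allele_state_pair(sim_pair(30, c(2, 1), c(0, 2), 1, 1), 3, 2)
  expect_false(res2$concordant)
  expect_equal(unname(res2$state_2), c(0, 2))

  # balanced state: haplotype identity unresolvable
  res3 <- infer_allele_state_pair(sim_pair(30, c(1, 1), c(2, 0), 1, 1), 2, 2)
  expect_true(is.na(res3$concordant))

  expect_error(infer_allele_state_pair(sim_pair(5, c(2, 1), c(2, 0), 1, 1), 3, 2),
               "10")

  # planted-state recovery across loci at depth 60 with purity in [0.6, 1]
  ok <- replicate(80, {
    p1 <- runif(1, 0.6, 1); p2 <- runif(1, 0.6, 1)
    r <- tryCatch(
      infer_allele_state_pair(sim_pair(25, c(2, 1), c(2, 0), p1, p2), 3, 2,
                              p1, p2),
      error = function(e) NULL)
    !is.null(r) && identical(unname(r$state_1), c(2, 1)) &&
      identical(unname(r$state_2), c(2, 0)) && isTRUE(r$concordant)
  })
  expect_gte(mean(ok), 0.99)
})

test_that("allele-state ordering enforces the no-resurrection rule", {
  # amplification then loss of the second allele
  expect_equal(order_allele_states(c(A = 2, B = 1), c(A = 2, B = 0)), "precedes")
  # a lost allele cannot return
  expect_equal(order_allele_states(c(A = 1, B = 0), c(A = 1, B = 1)), "follows")
  # equal states are mutually reachable
  expect_equal(order_allele_states(c(A = 2, B = 0), c(A = 2, B = 0)), "equivalent")
  # losses of different alleles are incomparable
  expect_equal(order_allele_states(c(A = 2, B = 0), c(A = 0, B = 2)), "incomparable")

  # the "precedes-or-equivalent" relation is reflexive and transitive
  set.seed(7)
  states <- replicate(40, sample(0:3, 2), simplify = FALSE)
  can_precede <- function(x, y) {
    order_allele_states(x, y) %in% c("precedes", "equivalent")
  }
  for (x in states) expect_true(can_precede(x, x))
  for (i in 1:40) {
    x <- states[[sample(40, 1)]]; y <- states[[sample(40, 1)]]
    z <- states[[sample(40, 1)]]
    if (can_precede(x, y) && can_precede(y, z)) {
      expect_true(can_precede(x, z))
    }
  }
})
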