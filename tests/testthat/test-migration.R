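test_that("monoclonal seeding is read off harbor/founded prevalence patterns", {
  parent <- c(root = NA, s = "root")
  prev <- rbind(root = c(S = 1, T = 1), s = c(S = 0.4, T = 1))
  ev <- classify_seeding(toy_atlas(parent, prev), primary = "S")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$source, "S")
  expect_equal(ev$target, "T")
  expect_equal(ev$kind, "monoclonal")
  expect_equal(ev$subclones, "s")

  # single-site cohort: no events
  prev1 <- rbind(root = c(S = 1), s = c(S = 0.4))
  expect_equal(nrow(classify_seeding(toy_atlas(parent, prev1))), 0)
})

test_that("related subclones at low prevalence in two sites are polyclonal", {
  parent <- c(root = NA, anc = "root", a = "anc", b = "anc")
  prev <- rbind(root = c(S = 1, T = 1),
                anc = c(S = 0.85, T = 0.65),
                a = c(S = 0.4, T = 0.35),
                b = c(S = 0.3, T = 0.3))
  ev <- classify_seeding(toy_atlas(parent, prev), primary = "S")
  poly <- ev[ev$kind == "polyclonal", ]
  expect_equal(nrow(poly), 1)
  expect_equal(poly$source, "S")   # ancestors more prevalent at S
  expect_equal(poly$target, "T")
  expect_equal(poly$subclones, "a,b")
})

test_that("recolonization requires exclusive standalone intermediates elsewhere", {
  parent <- c(root = NA, x = "root", mid = "x", y = "mid")
  # established site A holds x and y but no standalone mid; B holds mid alone
  prev <- rbind(root = c(P = 1, A = 1, B = 1),
                x = c(P = 0.7, A = 1, B = 1),
                mid = c(P = 0, A = 0.5, B = 0.8),
                y = c(P = 0, A = 0.5, B = 0))
  ev <- detect_recolonization(toy_atlas(parent, prev))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$source, "B")
  expect_equal(ev$target, "A")
  expect_equal(ev$subclones, "y")
  expect_false(ev$ambiguous)

  # intermediate standing alone at A: in-situ evolution, no event
  prev2 <- prev
  prev2["mid", "A"] <- 0.8
  expect_equal(nrow(detect_recolonization(toy_atlas(parent, prev2))), 0)

  # intermediate standing alone at two other sites: not exclusive, no event
  prev3 <- prev
  prev3["mid", "P"] <- 0.6
  expect_equal(nrow(detect_recolonization(toy_atlas(parent, prev3))), 0)
})

test_that("incubators require an ancestor-descendant chain of local seeders", {
  parent <- c(root = NA, a = "root", b = "a", c = "b")
  prev <- rbind(root = c(I = 1, M1 = 1, M2 = 1),
                a = c(I = 0.8, M1 = 1, M2 = 1),
                b = c(I = 0.5, M1 = 0, M2 = 1),
                c = c(I = 0.2, M1 = 0, M2 = 0))
  atlas <- toy_atlas(parent, prev)
  ev <- classify_seeding(atlas, primary = "P")
  expect_equal(detect_incubators(ev, atlas), "I")

  # one subclone seeding many targets is not a chain
  parent2 <- c(root = NA, a = "root")
  prev2 <- rbind(root = c(I = 1, M1 = 1, M2 = 1),
                 a = c(I = 0.6, M1 = 1, M2 = 1))
  atlas2 <- toy_atlas(parent2, prev2)
  ev2 <- classify_seeding(atlas2, primary = "P")
  expect_length(detect_incubators(ev2, atlas2), 0)

  expect_length(detect_incubators(metastrack:::empty_events(), atlas), 0)
})

test_that("wave order is the transitive closure of allele-state precedences", {
  ev <- tibble::tibble(source = "P", target = c("a1", "b1"),
                       kind = "monoclonal", subclones = "s", ambiguous = FALSE)
  prec <- tibble::tibble(earlier = c("G1", "G2"), later = c("G2", "G3"),
                         locus = "chr3")
  g <- build_graph(ev, precedences = prec, primary = "P")
  wo <- setNames(g$wave_order$rank, g$wave_order$group)
  expect_true(wo[["G1"]] < wo[["G2"]] && wo[["G2"]] < wo[["G3"]])

  # single group: trivial order
  g1 <- build_graph(ev, groups = tibble::tibble(sample = "a1", group = "G1"),
                    primary = "P")
  expect_equal(g1$wave_order$group, "G1")

  # conflicting loci orderings are a hard error naming the loci
  bad <- tibble::tibble(earlier = c("G1", "G2"), later = c("G2", "G1"),
                        locus = c("chr3", "chr6"))
  expect_error(build_graph(ev, precedences = bad), "chr3.*chr6")
})

test_that("scripted scenarios are recovered end-to-end at depth 200", {
  for (scen in c("jumping_board", "incubator", "recolonization",
                 "polyclonal", "four_waves")) {
    co <- simulate_cohort(seed = 8, scenario = scen, depth_mean = 200)
    r <- evaluate_seeding_recovery(co)
    expect_true(r$exact, label = paste(scen, "event recovery"))
  }
})

test_that("four-wave cohorts recover group structure and wave order", {
  co <- simulate_cohort(seed = 6, scenario = "four_waves", depth_mean = 200)
  tbl <- call_somatic(co$variants)
  groups <- assign_groups(bin_log2(co$truth$segments))
  prec <- order_groups_by_allele_states(tbl, co$truth$segments, co$purity,
                                        groups, "chr3")
  expect_setequal(paste(prec$earlier, prec$later),
                  paste(co$truth$precedences$earlier,
                        co$truth$precedences$later))
  rec <- reconstruct_subclones(tbl, co$purity, chroms = "chr14")
  mg <- infer_migration(rec$atlas, primary = "P", groups = groups,
                        precedences = prec)
  expect_equal(mg$wave_order$rank[mg$wave_order$group == "G1"], 1L)
  expect_true(all(mg$wave_order$rank[mg$wave_order$group %in%
                                       c("G2", "G3", "G4")] == 2L))
  # DOT serialization covers every edge
  dot <- migration_dot(mg)
  expect_true(all(grepl("digraph", dot)))
  expect_equal(length(gregexpr("->", dot)[[1]]), nrow(mg$edges))
})
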