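test_that("clustering expectation matches exhaustive enumeration", {
  # two singleton groups, one gene: exactly one group hit
  ex <- clustering_expectation(c(1, 1), 1)
  expect_equal(ex$eta, 1)
  expect_equal(ex$sigma, 0)

  # frozen enumeration over all C(4,2) = 6 draws of sizes {2,2}
  ex2 <- clustering_expectation(c(2, 2), 2)
  expect_equal(ex2$eta, 5 / 3)
  expect_equal(ex2$sigma, sqrt(2 / 9))

  # saturation: every group hit, zero variance
  ex3 <- clustering_expectation(c(3, 2, 4), 9)
  expect_equal(ex3$eta, 3)
  expect_equal(ex3$sigma, 0)

  set.seed(13)
  for (b in 1:8) {
    sizes <- sample(1:4, sample(2:4, 1), replace = TRUE)
    n <- sample.int(sum(sizes), 1)
    e <- enum_clustering(sizes, n)
    ex <- clustering_expectation(sizes, n)
    expect_equal(ex$eta, unname(e["eta"]), tolerance = 1e-12)
    expect_equal(ex$sigma, unname(e["sigma"]), tolerance = 1e-7)
  }

  expect_error(clustering_expectation(c(2, 2), 5), "exceeds")
  expect_error(clustering_expectation(c(0, 2), 1), "sizes")

  # with-replacement variant: p_g = 1 - (1 - N_g/M)^n
  exr <- clustering_expectation(c(1, 1), 1, replace = TRUE)
  expect_equal(exr$eta, 1)
  expect_equal(clustering_expectation(c(2, 2), 2, replace = TRUE)$eta,
               2 * (1 - 0.25))
})

test_that("clustering bounds delimit the attainable range", {
  b <- clustering_bounds(c(3, 2), 4)
  expect_equal(b$n_min, 2)
  expect_equal(b$n_max, 2)
  expect_equal(clustering_bounds(c(5, 5), 5)$n_min, 1)
  expect_equal(clustering_bounds(c(2, 2), 1), list(n_min = 1L, n_max = 1L))

  # observed n always within bounds for random draws
  set.seed(17)
  sizes <- c(4, 3, 3, 2, 1, 1)
  groups <- make_groups(split(sprintf("g%02d", 1:14),
                              rep(seq_along(sizes), sizes)))
  for (b in 1:20) {
    n_map <- sample.int(14, 1)
    cs <- clustering_z(groups, sample(sprintf("g%02d", 1:14), n_map))
    bounds <- clustering_bounds(groups$sizes, n_map)
    expect_gte(cs$n, bounds$n_min)
    expect_lte(cs$n, bounds$n_max)
  }
})

test_that("clustering Z flags saturation and signs extremes correctly", {
  members <- list(c("a1", "a2", "a3", "a4"), c("b1", "b2", "b3", "b4"),
                  c("c1", "c2", "c3", "c4"), c("d1", "d2", "d3", "d4"))
  groups <- make_groups(members)

  # all genes of one group: maximal clustering, Z < 0
  cs <- clustering_z(groups, members[[1]])
  expect_equal(cs$n, 1)
  expect_lt(cs$Z, 0)

  # one gene per group: maximal dispersion, Z > 0
  cs2 <- clustering_z(groups, c("a1", "b1", "c1", "d1"))
  expect_equal(cs2$n, 4)
  expect_gt(cs2$Z, 0)

  # genes outside the MRS are dropped and counted
  cs3 <- clustering_z(groups, c("a1", "a2", "zz1", "zz2"))
  expect_equal(cs3$n_mapped, 2)
  expect_equal(cs3$n_unmapped, 2)
  expect_error(clustering_z(groups, c("zz1", "zz2")), "none of the")

  # full saturation: sigma = 0, Z flagged
  cs4 <- clustering_z(groups, unlist(members))
  expect_equal(cs4$sigma, 0)
  expect_true(is.na(cs4$Z))
  expect_match(cs4$note, "sigma")
})

test_that("functional coherence computes f_c^g per group", {
  groups <- make_groups(list(c("g1", "g2", "g3"), c("g4", "g5"), c("g6")))
  ann <- annotation_map(c(g1 = "c1", g2 = "c1", g3 = "c2",
                          g6 = "c1", g6 = "c2"))
  fc <- functional_coherence(groups, ann)
  tab <- fc$table
  g1row <- tab[tab$group_id == 1 & tab$category == "c1", ]
  expect_equal(g1row$f, 2 / 3)
  expect_equal(tab[tab$group_id == 1 & tab$category == "c2", "f"], 1 / 3)

  # group of g4,g5 is entirely unannotated: absent from the table
  expect_false(2 %in% tab$group_id[tab$group_id == 2])
  # multi-label singleton: f = 1 for both categories
  expect_equal(tab[tab$group_id == 3, "f"], c(1, 1))

  # only the 3-gene group is eligible (Ntilde > 1) and it is incoherent
  expect_equal(fc$n_eligible, 1)
  expect_equal(fc$summary, 0)

  # a coherent eligible group
  ann2 <- annotation_map(c(g1 = "c1", g2 = "c1", g3 = "c1"))
  expect_equal(functional_coherence(groups, ann2)$summary, 1)
})

test_that("coherence permutation null behaves at its fixed points", {
  groups <- make_groups(list(c("g1", "g2"), c("g3", "g4"), c("g5", "g6")))
  # identical annotations: observed equals every permutation, Z = 0
  ann <- annotation_map(setNames(rep("c1", 6), paste0("g", 1:6)))
  z <- coherence_null_z(groups, ann, n_perm = 100, seed = 7)
  expect_equal(z$Z, 0)
  expect_match(z$note, "degenerate")

  expect_error(coherence_null_z(groups, ann, n_perm = 10), "n_perm")

  # planted one-category-per-module annotations: fraction 1, large Z
  model <- planted_model(n_species = 300, n_modules = 8,
                         genes_per_module = 4, fp_rate = 0.05,
                         fn_rate = 0.05, seed = 23)
  gp <- generate_profiles(model)
  assoc <- association_pipeline(gp$profile, x_th = 20)
  groups2 <- correlog_groups(build_mrs(assoc$w))
  ann2 <- generate_annotations(model, purity = 1)
  fc <- functional_coherence(groups2, ann2)
  expect_equal(fc$summary, 1)
  z2 <- coherence_null_z(groups2, ann2, n_perm = 200, seed = 7)
  expect_gt(z2$Z, 2)
})

test_that("category overlap ratio counts co-occupied groups", {
  groups <- make_groups(list(c("g1", "g2"), c("g3", "g4"), c("g5", "g6")))
  ann <- annotation_map(c(g1 = "c1", g2 = "c2",   # both in group 1
                          g3 = "c1",              # only c1 in group 2
                          g5 = "c2"))             # only c2 in group 3
  expect_equal(category_overlap(groups, ann, "c1", "c2"), 1 / 3)

  ann2 <- annotation_map(c(g1 = "c1", g3 = "c2"))
  expect_equal(category_overlap(groups, ann2, "c1", "c2"), 0)

  expect_equal(category_overlap(groups, ann, "c1", "c1"), 1)
  y <- category_overlap(groups, ann, "zz", "zz")
  expect_true(is.na(y))
  expect_match(attr(y, "note"), "neither")
})

test_that("category overlap P uses the add-one convention", {
  groups <- make_groups(split(sprintf("g%02d", 1:24), rep(1:8, each = 3)))
  # c1 and c2 never share a group: observed Y = 0, P is maximal
  labs <- setNames(rep("c3", 24), sprintf("g%02d", 1:24))
  labs["g01"] <- "c1"; labs["g04"] <- "c2"
  ann <- annotation_map(labs)
  op <- category_overlap_p(groups, ann, "c1", "c2", n_perm = 100, seed = 3)
  expect_equal(op$observed, 0)
  expect_gt(op$P, 0.5)
  expect_lte(op$P, 1)

  # strongly co-segregating categories: small P, add-one lower bound
  labs2 <- setNames(rep(c("c1", "c2", "c3"), 8), sprintf("g%02d", 1:24))
  labs2[7:24] <- sprintf("c%02d", 4 + seq_len(18))  # unique elsewhere
  ann2 <- annotation_map(labs2)
  op2 <- category_overlap_p(groups, ann2, "c1", "c2", n_perm = 200,
                            seed = 3)
  expect_equal(op2$observed, 1)
  expect_lt(op2$P, 0.1)
  expect_gte(op2$P, 1 / 201)
})

test_that("shortest-path strata match a naive all-pairs oracle", {
  edges <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"))
  ps <- shortest_path_strata(edges, c("a", "b", "c"))
  expect_equal(ps$distance[ps$gene_a %in% c("a", "c") &
                           ps$gene_b %in% c("a", "c")], 2)

  # two components: cross pairs unreachable
  edges2 <- data.frame(gene_a = c("a", "c"), gene_b = c("b", "d"))
  ps2 <- shortest_path_strata(edges2, letters[1:4])
  unr <- ps2[ps2$stratum == "unreachable", ]
  expect_equal(nrow(unr), 4)
  expect_true(all(is.infinite(unr$distance)))

  expect_error(shortest_path_strata(edges, c("x", "y")), "no overlap")

  # Floyd-Warshall oracle on a random graph
  set.seed(29)
  n <- 15
  ids <- sprintf("n%02d", 1:n)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(ut)) < 0.15
  edges3 <- data.frame(gene_a = ids[ut[keep, 1]], gene_b = ids[ut[keep, 2]])
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (k in seq_len(nrow(edges3)))
    d[edges3$gene_a[k], edges3$gene_b[k]] <-
      d[edges3$gene_b[k], edges3$gene_a[k]] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  ps3 <- shortest_path_strata(edges3, ids)
  present <- unique(c(edges3$gene_a, edges3$gene_b))
  for (r in seq_len(nrow(ps3)))
    expect_equal(ps3$distance[r], d[ps3$gene_a[r], ps3$gene_b[r]])
  expect_true(all(ps3$gene_a %in% present))
})

test_that("pair-set comparison standardizes against a matched null", {
  set.seed(37)
  model <- planted_model(n_species = 300, n_modules = 6,
                         genes_per_module = 4, anti_pairs = NULL,
                         fp_rate = 0.05, fn_rate = 0.05, seed = 5)
  gp <- generate_profiles(model)
  assoc <- association_pipeline(gp$profile, x_th = 20)
  mod <- gp$modules[assoc$gene_ids]
  ut <- which(upper.tri(assoc$w), arr.ind = TRUE)
  same <- mod[ut[, 1]] == mod[ut[, 2]]
  within <- pair_set(assoc$gene_ids[ut[same, 1]], assoc$gene_ids[ut[same, 2]])

  cmp <- pairset_w_comparison(assoc, within, n_draws = 500, seed = 11)
  expect_gt(cmp$Z, 3)
  expect_lt(cmp$P, 0.01)
  expect_equal(cmp$per_stratum$n_pairs, nrow(within))

  # pair set = entire population: every null draw reproduces the set
  all_pairs <- pair_set(assoc$gene_ids[ut[, 1]], assoc$gene_ids[ut[, 2]])
  cmp2 <- pairset_w_comparison(assoc, all_pairs, n_draws = 200, seed = 11)
  expect_equal(cmp2$Z, 0)
  expect_match(cmp2$note, "degenerate")

  # constant matrix: flagged degenerate null
  wc <- matrix(1, 4, 4); diag(wc) <- 0
  dimnames(wc) <- list(paste0("g", 1:4), paste0("g", 1:4))
  cmp3 <- pairset_w_comparison(wc, pair_set("g1", "g2"), n_draws = 200,
                               seed = 1)
  expect_match(cmp3$note, "degenerate")

  # r and I matrices work through the same interface
  cmpr <- pairset_w_comparison(assoc, within, n_draws = 200, seed = 2,
                               statistic = "r")
  expect_gt(cmpr$Z, 3)

  expect_error(pairset_w_comparison(assoc, pair_set("nope", "g1")),
               "absent")
  expect_error(pair_set("g1", "g1"), "self-pairs")
})

test_that("stratified nulls draw within strata and flag missing ones", {
  set.seed(41)
  w <- random_w(12)
  ids <- rownames(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  strat <- sample(c("1", "2"), nrow(ut), replace = TRUE)
  pop <- pair_set(ids[ut[, 1]], ids[ut[, 2]], stratum = strat)
  obs <- pop[pop$stratum == "1", ][1:5, ]
  cmp <- pairset_w_comparison(w, obs, null_pairs = pop, n_draws = 300,
                              seed = 9)
  expect_true(is.finite(cmp$Z))
  # resampling kicks in (with a message) when a stratum is too small
  tiny_pop <- pop[pop$stratum == "1", ][1:3, ]
  expect_message(
    pairset_w_comparison(w, obs, null_pairs = tiny_pop, n_draws = 100,
                         seed = 9),
    "resampled")
  pop2 <- pop[pop$stratum == "2", ]
  expect_error(pairset_w_comparison(w, obs, null_pairs = pop2,
                                    n_draws = 100, seed = 9),
               "stratum")
})

test_that("phylum dispersion regression recovers a planted trend", {
  fx <- phylum_fixture(seed = 11)
  pd <- phylum_dispersion_z(fx$gp$profile, fx$taxonomy, x_th = 10,
                            n_phyla_max = 9, n_perm = 100, seed = 5)
  expect_gt(pd$slope_norm, 0)
  expect_gt(pd$Z, 2)
  expect_equal(pd$n_genes_used, 48)

  # uniform spread: every gene inhabits all phyla, too few distinct
  # n_phyla values to regress
  model <- planted_model(n_species = 240, n_modules = 4,
                         genes_per_module = 3, seed = 2)
  gp <- generate_profiles(model)
  tax <- synthetic_taxonomy(240, n_phyla = 4)
  expect_error(phylum_dispersion_z(gp$profile, tax, x_th = 20,
                                   n_phyla_max = 9, n_perm = 100),
               "distinct n_phyla")
  expect_error(phylum_dispersion_z(gp$profile, tax[1:10], x_th = 20),
               "cover")
})
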