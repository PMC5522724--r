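fig2_table <- function() {
  average_consensus_table(build_forests(fig2_matrix())$additional)
}

test_that("OLS on the worked-example table fits ((O,A),(B,C,D)) exactly", {
  tab <- fig2_table()
  top <- tree_from_newick("((O,A),(B,C,D))")
  fit <- ols_fit(top, tab)
  expect_equal(fit$score, 0, tolerance = 1e-12)
  # frozen hand-solved lengths: pendants O=A=1, B=C=D=4/3, internal 1/3
  lens <- fit$tree$edge.length
  tips <- fit$tree$tip.label[fit$tree$edge[, 2]]
  expect_equal(unname(lens[which(tips %in% c("O", "A"))]), c(1, 1),
               tolerance = 1e-9)
  expect_equal(unname(lens[which(tips %in% c("B", "C", "D"))]),
               rep(4 / 3, 3), tolerance = 1e-9)
  internal <- lens[is.na(tips)]
  expect_equal(sort(internal), sort(internal))  # both internal edges exist
  expect_equal(sum(internal), 1 / 3, tolerance = 1e-9)
  # implied distances reproduce the table
  expect_equal(fit$p, tab$d, tolerance = 1e-9)

  # the 5-taxon star cannot fit this table exactly
  star <- ols_fit(tree_from_newick("(O,A,B,C,D)"), tab)
  expect_gt(star$score, 0.01)
})

test_that("a table generated from a tree is recovered with score 0", {
  tr <- random_rooted_tree(6, 11)
  tr$edge.length <- seq(0.5, by = 0.25, length.out = nrow(tr$edge))
  tab <- additive_table_of(tr)
  fit <- ols_fit(tr, tab)
  expect_equal(fit$score, 0, tolerance = 1e-16)
  expect_equal(path_length_matrix(fit$tree)[tab$taxa, tab$taxa], tab$d,
               tolerance = 1e-9)
})

test_that("closed-form OLS equals brute-force minimization (<=6 taxa)", {
  for (n in 4:6) {
    set.seed(n)
    d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 1, 4)
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    tab <- distance_table(d)
    tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = letters[1:n])
    for (k in seq_along(tops)) {
      phy <- tops[[k]]  # [[ restores the shared TipLabel attribute
      a <- ols_fit(phy, tab)$score
      b <- brute_force_ls_score(phy, tab)
      expect_equal(a, b, tolerance = 1e-8)
    }
  }
})

test_that("WLS weighting and its zero-distance contract", {
  tab <- fig2_table()
  cfg <- fit_config(criterion = "wls", power = 7)
  f <- ols_fit(tree_from_newick("((O,A),(B,C,D))"), tab, cfg)
  expect_equal(f$score, 0, tolerance = 1e-12)  # exact fit is exact under any w
  star <- ols_fit(tree_from_newick("(O,A,B,C,D)"), tab, cfg)
  bstar <- brute_force_ls_score(ape::unroot(tree_from_newick("(O,A,B,C,D)")),
                                tab, power = 7)
  expect_equal(ols_fit(ape::unroot(tree_from_newick("(O,A,B,C,D)")), tab,
                       cfg)$score, bstar, tolerance = 1e-8)
  d0 <- tab; d0$d["O", "A"] <- 0; d0$d["A", "O"] <- 0
  expect_error(ols_fit(tree_from_newick("((O,A),(B,C,D))"), d0, cfg), "P'")
})

test_that("negative-branch-length policies", {
  # within-pair distances exceed cross distances: the internal edge of the
  # matching quartet must go negative under unconstrained OLS
  d <- rbind(c(0, 3, 2, 2), c(3, 0, 2, 2), c(2, 2, 0, 3), c(2, 2, 3, 0))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tab <- distance_table(d)
  top <- tree_from_newick("((a,b),(c,d))")
  allow <- ols_fit(top, tab, fit_config(negbrlen = "allow"))
  clamp <- ols_fit(top, tab, fit_config(negbrlen = "clamp_zero"))
  constr <- ols_fit(top, tab, fit_config(negbrlen = "constrain_nonneg"))
  expect_true(any(allow$tree$edge.length < 0))
  expect_true(all(clamp$tree$edge.length >= 0))
  expect_true(all(constr$tree$edge.length >= 0))
  expect_gte(clamp$score, allow$score)
  # constrained solve is optimal among nonnegative solutions
  expect_lte(constr$score, clamp$score + 1e-12)
  expect_gte(constr$score, allow$score - 1e-12)
})

test_that("exhaustive search on the worked example: score 0, clade (BCD)", {
  tab <- fig2_table()
  fits <- search_best_tree(tab)
  expect_equal(fits[[1]]$score, 0, tolerance = 1e-12)
  expect_length(fits, 3)  # the three resolutions of (B,C,D)
  rooted <- lapply(fits, function(f) root_at_outgroup(f$tree, "O"))
  for (r in rooted) expect_true(has_clade(r, c("B", "C", "D")))
  cons <- strict_consensus(structure(rooted, class = "multiPhylo"))
  expect_true(has_clade(cons, c("B", "C", "D")))
  expect_true(has_clade(cons, c("A", "B", "C", "D")))
})

test_that("search degenerate cases: additive uniqueness and total ties", {
  tr <- random_rooted_tree(5, 21)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
  tab <- additive_table_of(tr)
  fits <- search_best_tree(tab)
  expect_length(fits, 1)
  expect_equal(fits[[1]]$score, 0, tolerance = 1e-12)
  expect_true(same_topology(fits[[1]]$tree, tr))

  deq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  ties <- search_best_tree(distance_table(deq))
  expect_length(ties, 3)  # symmetry: all quartets tie
  expect_error(search_best_tree(distance_table(deq[1:3, 1:3])), "4 taxa")
})

test_that("NNI hill-climb search agrees with exhaustive at small n", {
  tr <- random_rooted_tree(6, 33)
  tab <- average_consensus_table(
    suppressWarnings(build_forests(matrix_from_tree(tr, outgroup = "t1")))$additional)
  ex <- search_best_tree(tab, fit_config())
  hc <- search_best_tree(tab, fit_config(search = "nni"))
  expect_equal(hc[[1]]$score, ex[[1]]$score, tolerance = 1e-9)
})

test_that("exhaustive enumeration counts (2n-5)!! topologies", {
  expect_length(phangorn::allTrees(5, rooted = FALSE), 15)
  expect_length(phangorn::allTrees(6, rooted = FALSE), 105)
})

test_that("score is invariant under taxon permutation of the table", {
  tab <- fig2_table()
  perm <- c("C", "O", "D", "A", "B")
  tab2 <- distance_table(tab$d[perm, perm])
  top <- tree_from_newick("((O,A),(B,C,D))")
  expect_equal(ols_fit(top, tab)$score, ols_fit(top, tab2)$score,
               tolerance = 1e-12)
  f1 <- search_best_tree(tab); f2 <- search_best_tree(tab2)
  expect_equal(f1[[1]]$score, f2[[1]]$score, tolerance = 1e-12)
})

test_that("NJ: consistency on additive tables, worked-example split, 3 taxa", {
  tr <- random_rooted_tree(7, 5)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
  expect_true(same_topology(nj_tree(additive_table_of(tr)), tr))

  njt <- nj_tree(fig2_table())
  expect_true(has_clade(root_at_outgroup(njt, "O"), c("B", "C", "D")))

  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(distance_table(d3))
  expect_equal(ape::Ntip(t3), 3)
  expect_equal(sum(t3$edge.length), 4)  # a=1, b=1, c=2 solves the 3 pairs
})

test_that("UPGMA: ultrametric recovery and the known non-clock failure", {
  # ultrametric table: correct nesting and heights
  du <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  up <- upgma_tree(distance_table(du))
  expect_true(has_clade(up, c("A", "B")))
  expect_equal(max(ape::node.depth.edgelength(up)), 4)  # root height 8/2

  # additive but non-clock: unequal rates make a and d the closest pair
  # (d(a,d) = 4 < d(a,b) = 6), so UPGMA joins the wrong cherry; NJ does not
  tr <- tree_from_newick("((a:1,b:5):1,(c:6,d:2):1)")
  tab <- additive_table_of(tr)
  expect_true(same_topology(nj_tree(tab), tr))
  expect_false(same_topology(upgma_tree(tab), tr))

  two <- distance_table(matrix(c(0, 3, 3, 0), 2,
                               dimnames = list(c("A", "B"), c("A", "B"))))
  cherry <- upgma_tree(two)
  expect_equal(cherry$edge.length, c(1.5, 1.5))
})

test_that("BME length: quartet closed form, additivity, wrong-topology penalty", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  q <- tree_from_newick("((a,b),(c,d))")
  expect_equal(bme_length(q, distance_table(d)), 4)

  tr <- random_rooted_tree(6, 17)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
  tab <- additive_table_of(tr)
  expect_equal(bme_length(tr, tab), sum(ape::unroot(tr)$edge.length),
               tolerance = 1e-9)
  # BME of the true quartet < any alternative on additive data
  tq <- tree_from_newick("((a:1,b:2):1,(c:1,d:3):1)")
  tabq <- additive_table_of(tq)
  right <- bme_length(tree_from_newick("((a,b),(c,d))"), tabq)
  for (alt in c("((a,c),(b,d))", "((a,d),(b,c))"))
    expect_gt(bme_length(tree_from_newick(alt), tabq), right)

  expect_error(bme_length(tree_from_newick("(a,b,c,(d,e))"),
                          distance_table(matrix(0, 5, 5,
                            dimnames = list(c(letters[1:3], "d", "e"),
                                            c(letters[1:3], "d", "e"))))),
               "binary")
})

test_that("BME search on additive tables returns the generating topology", {
  tr <- random_rooted_tree(6, 29)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
  fits <- search_best_tree(additive_table_of(tr), fit_config(criterion = "bme"))
  expect_true(same_topology(fits[[1]]$tree, tr))
})

test_that("strict consensus keeps exactly the shared clades", {
  trees <- structure(list(
    tree_from_newick("(O,(A,(B,(C,D))))"),
    tree_from_newick("(O,(A,(C,(B,D))))"),
    tree_from_newick("(O,(A,(D,(B,C))))")), class = "multiPhylo")
  cons <- strict_consensus(trees)
  expect_true(has_clade(cons, c("B", "C", "D")))
  expect_false(has_clade(cons, c("C", "D")))

  one <- tree_from_newick("(O,(A,(B,C)))")
  expect_equal(suppressWarnings(ape::dist.topo(strict_consensus(
    structure(list(one, one), class = "multiPhylo")), one)),
    structure(0, names = "PH85"), ignore_attr = TRUE)

  t1 <- tree_from_newick("((A,B),(C,D))")
  t2 <- tree_from_newick("((A,C),(B,D))")
  star <- strict_consensus(structure(list(t1, t2), class = "multiPhylo"))
  expect_equal(star$Nnode, 1)

  t3 <- tree_from_newick("((A,B),(C,E))")
  expect_error(strict_consensus(structure(list(t1, t3), class = "multiPhylo")),
               "leaf sets")
})

test_that("outgroup rooting places the root on the pendant edge", {
  un <- ape::unroot(tree_from_newick("((O,A),(B,(C,D)))"))
  r <- root_at_outgroup(un, "O")
  expect_true(has_clade(r, c("A", "B", "C", "D")))
  expect_true(has_clade(r, c("C", "D")))
  expect_error(root_at_outgroup(un, "nope"), "not a leaf")
  # re-rooting an already O-rooted tree is the identity on topology
  r2 <- root_at_outgroup(r, "O")
  expect_true(same_topology(r, r2))
  expect_true(has_clade(r2, c("A", "B", "C", "D")))
})
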