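test_that("combined distance is the Euclidean norm of the two components", {
  expect_equal(combined_distance(0, 0), 0)
  expect_equal(combined_distance(0.3, 0.4), 0.5)
  expect_error(combined_distance(-0.1, 0.2), "non-negative")
  set.seed(12)
  for (i in 1:30) {
    dm <- runif(1, 0, 0.5); ds <- runif(1)
    expect_equal(combined_distance(dm, ds), sqrt(sum(c(dm, ds)^2)), tolerance = 1e-14)
    # monotone in each argument; collapses to the other component at zero
    expect_gte(combined_distance(dm + 0.01, ds), combined_distance(dm, ds))
    expect_equal(combined_distance(0, ds), ds)
  }
  expect_equal(combined_distance(0.3, 0.4, normalize = TRUE), sqrt(0.36 + 0.16))
})

test_that("distance matrices satisfy their invariants and match elementwise recomputation", {
  set.seed(13)
  cats <- rbind(a = random_catalog(), b = random_catalog(), c = random_catalog())
  fga <- c(a = 0.1, b = 0.5, c = 0.3)
  for (mode in c("mutational", "scna", "combined")) {
    m <- build_distance_matrix(cats, fga, mode = mode)
    expect_equal(diag(m), c(a = 0, b = 0, c = 0))
    expect_equal(m, t(m), ignore_attr = TRUE)
    expect_true(all(m >= 0))
  }
  m <- build_distance_matrix(cats, fga, mode = "combined")
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j],
                 combined_distance(spectrum_distance(cats[i, ], cats[j, ]),
                                   scna_distance(fga[[i]], fga[[j]])),
                 tolerance = 1e-12)
  }
  # identical samples sit at distance zero
  m0 <- build_distance_matrix(rbind(a = cats[1, ], b = cats[1, ]),
                              c(a = 0.2, b = 0.2))
  expect_equal(m0["a", "b"], 0)
  # scna-only mode ignores the catalogs entirely
  ms <- build_distance_matrix(cats, fga, mode = "scna")
  expect_equal(ms["a", "b"], abs(fga["a"] - fga["b"]), ignore_attr = TRUE)
  expect_error(build_distance_matrix(cats, fga[1:2], mode = "combined"),
               "sample sets differ")
})

test_that("hierarchical clustering merges tight pairs first and heights are monotone", {
  ids <- c("a1", "a2", "b1", "b2")
  m <- matrix(1, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 0
  m["a1", "a2"] <- m["a2", "a1"] <- 0.05
  m["b1", "b2"] <- m["b2", "b1"] <- 0.08
  hc <- hierarchical_cluster(m)
  expect_equal(sort(hc$height[1:2]), c(0.05, 0.08))
  expect_equal(sort(stats::cutree(hc, 2)), sort(c(a1 = 1, a2 = 1, b1 = 2, b2 = 2)))
  # equidistant chain under single linkage: all merge heights equal
  chain <- as.matrix(stats::dist(matrix(1:5, ncol = 1)))
  dimnames(chain) <- list(letters[1:5], letters[1:5])
  hs <- hierarchical_cluster(chain, "single")
  expect_true(all(hs$height == 1))
  # complete/average linkage heights are non-decreasing on random matrices
  set.seed(14)
  for (link in c("complete", "average")) {
    x <- matrix(runif(60), ncol = 6)
    r <- as.matrix(stats::dist(x))
    expect_true(all(diff(hierarchical_cluster(r, link)$height) >= -1e-12))
  }
  expect_error(hierarchical_cluster(m[1, 1, drop = FALSE]), "two samples")
})

test_that("dendrograms export as Newick readable by ape", {
  set.seed(15)
  x <- matrix(runif(40), ncol = 4)
  rownames(x) <- paste0("s", 1:10)
  hc <- hierarchical_cluster(as.matrix(stats::dist(x)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(x))
})

test_that("queries are assigned to reference groups by cluster majority", {
  # two tight reference groups; queries constructed next to group A
  ids <- c("A1", "A2", "A3", "B1", "B2", "B3", "q1", "q2")
  m <- matrix(1, 8, 8, dimnames = list(ids, ids))
  diag(m) <- 0
  near <- function(i, j, d) m[i, j] <<- m[j, i] <<- d
  for (i in c("A1", "A2", "A3", "q1", "q2")) for (j in c("A1", "A2", "A3", "q1", "q2"))
    if (i != j) near(i, j, 0.05)
  for (i in c("B1", "B2", "B3")) for (j in c("B1", "B2", "B3")) if (i != j) near(i, j, 0.05)
  labels <- stats::setNames(c("A", "A", "A", "B", "B", "B"), ids[1:6])
  asg <- assign_groups(m, labels, c("q1", "q2"))
  expect_equal(asg$assigned_group, c("A", "A"))
  expect_equal(asg$rule, c("majority", "majority"))
  expect_equal(asg$support, c(3L, 3L))

  # a query identical to a reference gets that reference's group
  m2 <- m
  m2["q1", "B1"] <- m2["B1", "q1"] <- 0
  for (j in c("B2", "B3")) { m2["q1", j] <- m2[j, "q1"] <- 0.05 }
  for (j in c("A1", "A2", "A3", "q2")) { m2["q1", j] <- m2[j, "q1"] <- 1 }
  asg2 <- assign_groups(m2, labels, "q1")
  expect_equal(asg2$assigned_group, "B")

  # permutation invariance to sample ordering
  perm <- sample(ids)
  asg3 <- assign_groups(m[perm, perm], labels, c("q1", "q2"))
  expect_equal(asg3[order(asg3$sample_id), "assigned_group"],
               asg[order(asg$sample_id), "assigned_group"])
  expect_error(assign_groups(m, character(0), "q1"), "no reference")
})

test_that("ties and label-free clusters fall back as documented", {
  # cluster holding one A and one B reference: tie broken by mean distance
  ids <- c("A1", "B1", "A2", "B2", "q")
  m <- matrix(1, 5, 5, dimnames = list(ids, ids))
  diag(m) <- 0
  m["A1", "B1"] <- m["B1", "A1"] <- 0.05
  m["q", "A1"] <- m["A1", "q"] <- 0.06
  m["q", "B1"] <- m["B1", "q"] <- 0.2
  labels <- stats::setNames(c("A", "B", "A", "B"), ids[1:4])
  asg <- assign_groups(m, labels, "q", k = 3)
  expect_equal(asg$assigned_group, "A")
  expect_equal(asg$rule, "majority_tie_mean_distance")

  # no labelled member in the query's cluster: nearest labelled neighbour
  m2 <- matrix(1, 5, 5, dimnames = list(ids, ids))
  diag(m2) <- 0
  m2["A1", "A2"] <- m2["A2", "A1"] <- 0.05
  m2["B1", "B2"] <- m2["B2", "B1"] <- 0.05
  m2["q", "B1"] <- m2["B1", "q"] <- 0.9
  asg2 <- assign_groups(m2, labels, "q", k = 3)
  expect_equal(asg2$rule, "nearest_neighbour")
  expect_equal(asg2$assigned_group, "B")
})

test_that("association test switches between Fisher and chi-squared correctly", {
  strong <- matrix(c(10, 0, 0, 10), 2)
  res <- association_test(strong)
  expect_equal(res$method, "fisher_exact")
  expect_equal(res$p_value, oracle_fisher_2x2(strong), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)

  balanced <- matrix(c(5, 5, 5, 5), 2)
  resb <- association_test(balanced, force = "fisher")
  expect_equal(resb$p_value, 1)

  big <- matrix(c(30, 10, 12, 28), 2)
  resc <- association_test(big)
  expect_equal(resc$method, "chi_squared")
  uniform <- matrix(rep(20, 6), 2)
  expect_equal(association_test(uniform)$statistic, 0)
  expect_equal(association_test(uniform)$p_value, 1)
  expect_error(association_test(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})
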