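test_that("MAD matches the hand-computed unscaled definition", {
  m <- matrix(c(0, 2, 4, 10,          # median 3, |dev| = 3,1,1,7 -> MAD 2
                5, 5, 5, 5),          # constant -> MAD 0
              2, 4, byrow = TRUE,
              dimnames = list(c("var", "flat"), paste0("s", 1:4)))
  expect_equal(unname(gene_mad(m)), c(2, 0))

  em <- expr_matrix(m, log_transformed = TRUE)
  hv <- select_hvgs(em, cutoff = 1)
  expect_identical(hv$gene_ids, "var")
  expect_identical(select_hvgs(em, cutoff = -1)$gene_ids, c("var", "flat"))
  expect_warning(select_hvgs(em, cutoff = 99), "no genes")
  expect_error(select_hvgs(expr_matrix(m, log_transformed = FALSE)),
               "log-transformed")
})

test_that("select_hvgs is monotone in the cutoff", {
  m <- toy_internode_matrix(100, seed = 3)
  cuts <- c(-1, 0, 0.5, 1, 1.5, 2)
  sets <- lapply(cuts, function(ct)
    suppressWarnings(select_hvgs(m, ct)$gene_ids))
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("assign_zones recovers planted zones and orders labels by stage", {
  cfg <- sim_config(n_genes = 600, noise_sd = 0.1, seed = 31)
  sim <- simulate_expression(cfg)
  logm <- log_transform(collapse_replicates(sim$expr, sim$meta), 1)
  hm <- logm[select_hvgs(logm, 1)$gene_ids, ]
  za <- assign_zones(hm, k = 4)
  expect_identical(za$zones, sim$truth$zone)
  expect_equal(ari(za$zones, sim$truth$zone), 1)

  # invariant to column order
  perm <- sample(ncol(hm))
  za2 <- assign_zones(hm[, perm], k = 4)
  expect_identical(za2$zones[names(za$zones)], za$zones)

  # variance fractions behave like variance fractions
  ve <- za$pca_variance_explained
  expect_true(all(ve >= 0 & ve <= 1))
  expect_true(all(diff(ve) <= 1e-8))
  expect_lte(sum(ve), 1 + 1e-8)
  expect_error(assign_zones(hm, k = 20), "exceeds")
})

test_that("zone assignment of a noiseless rank-2 matrix is clean", {
  des <- study_design()
  p1 <- rep(c(1, 0), length.out = 19)
  p2 <- seq(-1, 1, length.out = 19)
  m <- rbind(a = 2 * p1, b = -p1, c = p2, d = 3 * p2 + p1)
  colnames(m) <- des$internode
  za <- assign_zones(expr_matrix(m, log_transformed = TRUE), k = 4)
  expect_equal(sum(za$pca_variance_explained[1:2]), 1, tolerance = 1e-10)
  # k = number of columns gives singletons
  za19 <- assign_zones(toy_internode_matrix(20), k = 19)
  expect_equal(length(unique(za19$zones)), 19)
})

test_that("fuzzy c-means memberships are well-formed and converge", {
  set.seed(9)
  x <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:8)))
  fc <- fuzzy_cmeans(x, c = 3, seed = 5, nstart = 2)
  expect_equal(unname(rowSums(fc$membership)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(fc$membership >= 0 & fc$membership <= 1))
  expect_identical(unname(fc$hard_labels),
                   colnames(fc$membership)[max.col(fc$membership,
                                                   ties.method = "first")])
  # objective is non-increasing across iterations
  expect_true(all(diff(fc$objective) <= 1e-8))
  # deterministic given the seed
  fc2 <- fuzzy_cmeans(x, c = 3, seed = 5, nstart = 2)
  expect_identical(fc$membership, fc2$membership)
  # c = 1 puts every gene in the single cluster
  fc1 <- fuzzy_cmeans(x, c = 1, seed = 5)
  expect_true(all(fc1$membership == 1))
})

test_that("fuzzy c-means recovers two separated groups like the reference fit", {
  set.seed(11)
  centers <- rbind(c(3, 3, 0, 0, -3), c(-3, 0, 3, -3, 3))
  x <- centers[rep(1:2, each = 25), ] + matrix(rnorm(250, 0, 0.3), 50, 5)
  rownames(x) <- sprintf("g%02d", 1:50)
  fc <- fuzzy_cmeans(x, c = 2, fuzzifier = 1.5, seed = 3, standardize = FALSE)
  expect_true(all(apply(fc$membership, 1, max) > 0.9))
  # centroids sit on the group means
  grp_means <- rbind(colMeans(x[1:25, ]), colMeans(x[26:50, ]))
  ord <- if (sum((fc$centroids[1, ] - grp_means[1, ])^2) <
             sum((fc$centroids[1, ] - grp_means[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(fc$centroids[ord, ]), unname(grp_means), tolerance = 0.05)
  # independent reference implementation agrees on the partition
  skip_if_not_installed("e1071")
  ref <- e1071::cmeans(x, centers = 2, m = 1.5)
  expect_equal(ari(fc$hard_labels, ref$cluster), 1)
})

test_that("duplicated genes share memberships and degenerate fits stay finite", {
  x <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 5, 5), d = c(0, 5, 5.5))
  fc <- fuzzy_cmeans(x, c = 2, fuzzifier = 2, seed = 1, nstart = 1,
                     standardize = FALSE)
  expect_false(anyNA(fc$membership))
  expect_equal(fc$membership["a", ], fc$membership["b", ], tolerance = 1e-6)
  expect_identical(unname(fc$hard_labels["a"]), unname(fc$hard_labels["b"]))
  # the pair is cleanly separated from the far pair
  expect_gt(max(fc$membership["a", ]), 0.95)
})

test_that("cluster_mean_profiles reduces to the obvious special cases", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1))
  colnames(x) <- paste0("s", 1:4)
  fc <- list(membership = matrix(c(1, 0, 0, 1), 2, 2,
                                 dimnames = list(rownames(x), c("C1", "C2"))))
  prof <- cluster_mean_profiles(fc, x)
  zs <- standardize_genes(x)
  expect_equal(prof["C1", ], zs["g1", ])
  expect_equal(prof["C2", ], zs["g2", ])

  # opposite profiles with equal membership cancel
  fc2 <- list(membership = matrix(0.5, 2, 1,
                                  dimnames = list(rownames(x), "C1")))
  expect_equal(unname(cluster_mean_profiles(fc2, x)["C1", ]), rep(0, 4))
})

test_that("planted 12-cluster simulation is recovered by fuzzy c-means", {
  cfg <- sim_config(n_genes = 1800, seed = 13)
  sim <- simulate_expression(cfg)
  logm <- log_transform(collapse_replicates(sim$expr, sim$meta), 1)
  hm <- logm[select_hvgs(logm, 1)$gene_ids, ]
  fc <- fuzzy_cmeans(hm, c = 12, seed = 8)
  truth <- sim$truth$cluster[rownames(fc$membership)]
  planted <- truth != "background"
  expect_gt(ari(fc$hard_labels[planted], truth[planted]), 0.8)
  # every cluster's weighted mean profile matches a planted archetype
  prof <- cluster_mean_profiles(fc, hm)
  best <- apply(cor(t(prof), sim$truth$archetypes), 1, max)
  expect_true(all(best > 0.9))
})
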