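test_that("connectivity and adjacency behave on a printed toy matrix", {
  a <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.5,
                0.2, 0.5, 1), 3, 3)
  expect_equal(connectivity(a), c(0.7, 1.0, 0.7))

  # adjacency from data: |cor|^beta with unit diagonal, constant gene -> 0
  set.seed(2)
  x <- rbind(a = rnorm(10), b = rnorm(10), c = rep(1, 10))
  expect_warning(adj <- adjacency_matrix(x, beta = 6), "constant")
  expect_equal(diag(adj), c(a = 1, b = 1, c = 1))
  expect_equal(adj["a", "b"], abs(cor(x["a", ], x["b", ]))^6)
  expect_equal(adj["a", "c"], 0)
  expect_true(isSymmetric(adj))
})

test_that("mean connectivity decreases in beta and scale-free fit detects a power law", {
  set.seed(4)
  x <- matrix(rnorm(60 * 12), 60, 12)
  rownames(x) <- sprintf("g%02d", 1:60)
  ps <- power_scan(x, betas = 1:8, k_max = 10)
  expect_true(all(diff(ps$table$mean_k) < 0))

  # planted power-law degree sequence fits with R^2 near 1
  k <- sort(1000 * (1:500)^-1.6)
  sf <- scale_free_fit(k)
  expect_gt(sf$r_squared, 0.95)
  expect_lt(sf$slope, 0)
  expect_error(power_scan(x[, 1:3], betas = 1:3), "at least 4 samples")
})

test_that("TOM matches hand arithmetic and the brute-force oracle", {
  # 3 nodes, all off-diagonals a: TOM_ij = (a^2 + a) / (2a + 1 - a)
  for (a_val in c(0.2, 0.5, 0.9)) {
    a <- matrix(a_val, 3, 3); diag(a) <- 1
    tom <- compute_tom(a)
    expect_equal(tom[1, 2], (a_val^2 + a_val) / (2 * a_val + 1 - a_val))
  }
  # identity adjacency -> identity TOM
  expect_equal(compute_tom(diag(4)), diag(4))

  # random adjacencies against the triple-loop oracle, to 1e-12
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    r <- matrix(runif(n * n), n, n)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- compute_tom(a)
    expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("detect_modules finds planted blocks and pools small branches", {
  set.seed(5)
  block <- function(n, f, noise = 0.05) {
    t(sapply(seq_len(n), function(i) f + rnorm(length(f), 0, noise)))
  }
  f1 <- rnorm(12); f2 <- rnorm(12)
  x <- rbind(block(60, f1), block(55, f2))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  truth <- rep(c("A", "B"), c(60, 55))
  tom <- compute_tom(adjacency_matrix(x, beta = 6))
  lab <- detect_modules(tom, min_module_size = 50)
  expect_equal(ari(lab, truth), 1)
  expect_equal(length(setdiff(unique(lab), "grey")), 2)

  # permuting gene order leaves the partition unchanged
  perm <- sample(nrow(x))
  lab2 <- detect_modules(compute_tom(adjacency_matrix(x[perm, ], beta = 6)),
                         min_module_size = 50)
  expect_equal(ari(lab2[rownames(x)], lab), 1)

  # a block below min_module_size joins the unassigned pool
  x3 <- rbind(block(60, f1), block(20, f2))
  rownames(x3) <- sprintf("g%03d", seq_len(nrow(x3)))
  lab3 <- detect_modules(compute_tom(adjacency_matrix(x3, beta = 6)),
                         min_module_size = 50)
  expect_true(all(lab3[61:80] == "grey"))
  expect_true(all(lab3[1:60] != "grey"))
})

test_that("module eigengene is the leading PC with the documented sign", {
  # identical genes: eigengene equals the shared standardized profile
  p <- c(0.5, 2, -1, 3, 1, -2, 0, 1.5)
  x <- rbind(g1 = p, g2 = p, g3 = p)
  colnames(x) <- paste0("s", 1:8)
  me <- module_eigengene(x, rownames(x))
  expect_equal(cor(me, as.numeric(scale(p))), 1, tolerance = 1e-9)
  expect_gt(sum(me * scale(p)), 0)       # aligned with the mean profile

  # +p / -p in equal numbers: tie broken toward the first gene
  x2 <- rbind(g1 = p, g2 = -p)
  colnames(x2) <- paste0("s", 1:8)
  me2 <- module_eigengene(x2, rownames(x2))
  expect_gt(cor(me2, as.numeric(scale(p))), 0.99)

  # planted one-factor module: eigengene tracks the factor
  set.seed(10)
  f <- rnorm(19)
  lam <- runif(100, 0.5, 2)
  xf <- outer(lam, f) + matrix(rnorm(100 * 19, 0, 0.3), 100, 19)
  rownames(xf) <- sprintf("g%03d", 1:100)
  colnames(xf) <- study_design()$internode
  mef <- module_eigengene(xf, rownames(xf))
  expect_gt(abs(cor(mef, f)), 0.95)

  # eigengene explains the most variance among unit sample-space vectors
  zs <- standardize_genes(xf)
  ev <- eigen(crossprod(zs) / nrow(zs))
  expect_equal(attr(mef, "var_explained"),
               ev$values[1] / sum(ev$values), tolerance = 1e-8)
  expect_equal(abs(cor(mef, ev$vectors[, 1])), 1, tolerance = 1e-8)
})

test_that("module-trait statistics use the Student t transform", {
  set.seed(12)
  mes <- matrix(rnorm(2 * 19), 2, 19,
                dimnames = list(c("pink", "blue"), study_design()$internode))
  traits <- data.frame(internode = study_design()$internode,
                       length = mes["pink", ] * 3 + 10,
                       diameter = runif(19, 5, 9))
  x <- matrix(rnorm(5 * 19), 5, 19,
              dimnames = list(sprintf("g%d", 1:5), study_design()$internode))
  labels <- setNames(rep(c("pink", "blue"), c(3, 2)), rownames(x))
  mt <- module_trait(x, mes, traits, labels)
  # trait identical (affine) to an eigengene: r = 1
  r_len <- mt$stats$r[mt$stats$module == "pink" & mt$stats$trait == "length"]
  expect_equal(r_len, 1, tolerance = 1e-12)
  # p follows t = r sqrt((n-2)/(1-r^2)) with n - 2 df
  row <- mt$stats[mt$stats$module == "blue" & mt$stats$trait == "diameter", ]
  t_stat <- row$r * sqrt(17 / (1 - row$r^2))
  expect_equal(row$p, 2 * pt(-abs(t_stat), 17))
  # MM is the correlation with the own module eigengene
  expect_equal(mt$mm$mm[1], cor(x["g1", ], mes["pink", ]))
  expect_error(module_trait(x[, 1:2], mes[, 1:2], traits[1:2, ], labels),
               "at least 3")
})

test_that("hub networks rank the planted hub first", {
  set.seed(14)
  n <- 30
  tom <- matrix(0.02, n, n)
  hub <- 7
  tom[hub, ] <- tom[, hub] <- 0.6      # star topology around one hub
  diag(tom) <- 1
  genes <- sprintf("g%02d", 1:n)
  dimnames(tom) <- list(genes, genes)
  labels <- setNames(rep("pink", n), genes)
  hn <- hub_network(tom, labels, "pink", top_n = 10,
                    flagged_genes = c("g01", "g07"))
  expect_identical(hn$nodes$gene[which.max(hn$nodes$connectivity)], "g07")
  expect_identical(hn$top_flagged, "g07")
  expect_true(all(c("g01", "g07") %in% hn$nodes$gene))
  # top_n equal to module size takes the whole module
  expect_warning(hn_all <- hub_network(tom, labels, "pink", top_n = 50),
                 "whole module")
  expect_setequal(hn_all$nodes$gene, genes)
  expect_error(hub_network(tom, labels, "salmon"), "not found")
})

test_that("gene-gene correlation covers the trivial and planted cases", {
  set.seed(15)
  f <- rnorm(19)
  x <- rbind(tf = f + rnorm(19, 0, 0.1),
             target = f * 1.4 + rnorm(19, 0, 0.1),
             noise = rnorm(19),
             anti = -f + rnorm(19, 0, 0.01))
  colnames(x) <- study_design()$internode
  gg <- gene_gene_correlation(x, "tf", rownames(x))
  expect_equal(gg$r[gg$gene_b == "tf"], 1)
  expect_gt(gg$r[gg$gene_b == "target"], 0.9)
  expect_lt(gg$r[gg$gene_b == "anti"], -0.9)
  expect_error(gene_gene_correlation(x, "tf", "absent"), "absent")
})
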