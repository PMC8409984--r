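block_profile <- function(n_per_block = 10, n_regions = 12, seed = 1,
                          noise = 0.05, k = 3) {
  set.seed(seed)
  centers <- matrix(rnorm(k * n_regions, sd = 2), nrow = k)
  vals <- do.call(rbind, lapply(seq_len(k), function(b) {
    matrix(rep(centers[b, ], each = n_per_block), nrow = n_per_block) +
      matrix(rnorm(n_per_block * n_regions, sd = noise),
             nrow = n_per_block)
  }))
  dimnames(vals) <- list(sprintf("g%03d", seq_len(k * n_per_block)),
                         sprintf("R%02d", seq_len(n_regions)))
  list(scaled = scale_per_gene(vals),
       truth = rep(seq_len(k), each = n_per_block))
}

test_that("sample clustering merges identical samples first", {
  set.seed(2)
  vals <- matrix(rexp(50 * 4), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 c("A_r1", "A_r2", "B_r1", "C_r1")))
  vals[, "A_r2"] <- vals[, "A_r1"]
  em <- expr_matrix(vals, data.frame(
    sample_id = colnames(vals), region = c("A", "A", "B", "C"),
    group = "g", replicate = c(1L, 2L, 1L, 1L)))
  h <- cluster_samples(em)
  first <- sort(h$labels[-h$merge[1, ]])
  expect_identical(first, c("A_r1", "A_r2"))
  expect_equal(h$height[1], 0, tolerance = 1e-12)
  expect_true(all(diff(h$height) >= -1e-12))  # monotone merge heights

  vals[, "B_r1"] <- 3
  em2 <- expr_matrix(vals, em$samples)
  expect_error(cluster_samples(em2), "constant sample column.*B_r1")
})

test_that("soft threshold: adjacency shrinks with beta; errors on tiny input", {
  bp <- block_profile()
  ac <- abs(cor(t(bp$scaled)))
  expect_true(all(ac^3 <= ac + 1e-15))
  st <- pick_soft_threshold(bp$scaled, betas = c(1, 2, 4, 6))
  expect_true(st$beta %in% c(1, 2, 4, 6))
  expect_identical(nrow(st$fit), 4L)
  expect_error(pick_soft_threshold(bp$scaled[, 1:3]), ">= 4 regions")
})

test_that("TOM matches the formula and a double-loop oracle", {
  # no edges: off-diagonal all zero
  a0 <- diag(5)
  dimnames(a0) <- list(paste0("g", 1:5), paste0("g", 1:5))
  t0 <- tom_similarity(a0)
  expect_true(all(t0[upper.tri(t0)] == 0))

  # two nodes joined by a unit edge
  a2 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(tom_similarity(a2)["a", "b"], 1)

  set.seed(8)
  a <- random_adjacency(20)
  tom <- tom_similarity(a)
  expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
  expect_true(isSymmetric(unname(tom)))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))

  a_bad <- a
  a_bad[1, 2] <- a_bad[1, 2] + 0.2
  expect_error(tom_similarity(a_bad), "symmetric")
})

test_that("module detection separates blocks and respects min size", {
  bp <- block_profile(k = 2, n_per_block = 8, noise = 0.01)
  a <- abs(cor(t(bp$scaled)))^6
  diag(a) <- 1
  tom <- tom_similarity(a)
  asg <- detect_modules(tom, min_module_size = 3)
  expect_identical(sort(unique(unname(asg$modules))), c(1L, 2L))
  expect_equal(module_agreement(asg$modules,
                                setNames(bp$truth, rownames(bp$scaled))), 1)

  asg0 <- detect_modules(tom, min_module_size = 100)
  expect_true(all(asg0$modules == 0))
})

test_that("hierarchical and k-means modules handle edge cases", {
  bp <- block_profile(k = 3, n_per_block = 6)
  n <- nrow(bp$scaled)
  singletons <- hierarchical_modules(bp$scaled, k = n)
  expect_identical(length(unique(singletons$modules)), n)
  expect_error(hierarchical_modules(bp$scaled, k = n + 1), "exceeds")

  dup <- bp$scaled
  dup["g002", ] <- dup["g001", ]
  hm <- hierarchical_modules(dup, k = 3)
  expect_equal(hm$modules[["g001"]], hm$modules[["g002"]])
  km <- kmeans_modules(dup, k = 3, seed = 2)
  expect_equal(km$modules[["g001"]], km$modules[["g002"]])

  # labels are 1..M by decreasing size
  sizes <- table(hm$modules)
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("planted atlas modules are recovered by all three methods", {
  a <- generate_atlas(test_config(seed = 33, noise_sd = 0.05))
  uni <- names(a$truth$module_of)
  prof <- average_replicates(
    expr_matrix(a$matrix$values[uni, , drop = FALSE], a$matrix$samples))
  truth <- a$truth$module_of[uni]
  w <- wgcna_modules(prof)
  expect_gte(module_agreement(w$modules, truth), 0.95)
  sc <- scale_per_gene(prof)
  expect_gte(module_agreement(hierarchical_modules(sc, 6)$modules, truth),
             0.95)
  expect_gte(module_agreement(kmeans_modules(sc, 6, seed = 1)$modules,
                              truth), 0.95)
})

test_that("elbow selection finds k on separated blobs and flags weak ones", {
  bp <- block_profile(k = 3, n_per_block = 12, noise = 0.05)
  ke <- choose_k_elbow(bp$scaled, 2:8, restarts = 10, seed = 3)
  expect_identical(ke$k, 3L)
  expect_false(ke$weak_elbow)
  ke2 <- choose_k_elbow(bp$scaled, 2:8, restarts = 10, seed = 3)
  expect_identical(ke$wss, ke2$wss)  # deterministic under fixed seed

  set.seed(11)
  cloud <- matrix(rnorm(60 * 10), nrow = 60,
                  dimnames = list(sprintf("g%03d", 1:60), paste0("R", 1:10)))
  kc <- choose_k_elbow(cloud, 2:8, restarts = 10, seed = 5)
  expect_true(kc$weak_elbow)
  expect_error(choose_k_elbow(cloud, 2:3), "at least 3")
})

test_that("ARI is 1 on identical/relabelled partitions and ~0 on random", {
  g <- paste0("g", 1:40)
  lab <- setNames(sample(1:4, 40, replace = TRUE), g)
  expect_equal(module_agreement(lab, lab), 1)
  perm <- setNames(c(3L, 4L, 1L, 2L)[lab], g)
  expect_equal(module_agreement(lab, perm), 1)
  expect_error(module_agreement(lab, setNames(lab, paste0("x", 1:40))),
               "different gene universes")

  set.seed(19)
  aris <- vapply(1:1000, function(i) {
    a <- setNames(sample(1:4, 40, replace = TRUE), g)
    b <- setNames(sample(1:4, 40, replace = TRUE), g)
    module_agreement(a, b)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("heatmap order groups by module then dendrogram position", {
  bp <- block_profile(k = 2, n_per_block = 5, noise = 0.02)
  asg <- hierarchical_modules(bp$scaled, k = 2)
  ord <- heatmap_gene_order(asg, bp$scaled)
  mods <- asg$modules[ord]
  expect_true(all(diff(match(mods, unique(mods))) >= 0))  # module 1 block first
  expect_setequal(ord, rownames(bp$scaled))
})
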