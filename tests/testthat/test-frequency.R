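make_profile <- function(vals, groups = NULL) {
  if (is.null(groups))
    groups <- stats::setNames(rep("homeostatic", ncol(vals)),
                              colnames(vals))
  em <- expr_matrix(vals, data.frame(sample_id = colnames(vals),
                                     region = colnames(vals),
                                     group = unname(groups[colnames(vals)]),
                                     replicate = 1L))
  average_replicates(em)
}

test_that("frequency rows are percentages of the per-gene total", {
  vals <- matrix(c(10, 30, 60,
                   0, 0, 7,
                   4, 4, 4,
                   0, 0, 0), nrow = 4, byrow = TRUE,
                 dimnames = list(c("a", "b", "c", "zero"),
                                 c("ARH", "PVH", "DMH")))
  ft <- frequency_table(make_profile(vals))
  expect_equal(unname(ft$values["a", ]), c(10, 30, 60))
  expect_equal(unname(ft$values["b", ]), c(0, 0, 100))
  expect_equal(unname(ft$values["c", ]), rep(100 / 3, 3))
  expect_false("zero" %in% rownames(ft$values))
  expect_identical(ft$dropped, "zero")
  expect_true(all(abs(rowSums(ft$values) - 100) < 1e-9))
  expect_error(frequency_table(make_profile(vals), include = character(0)),
               "empty")
  # region restriction renormalizes over the included denominator
  ft2 <- frequency_table(make_profile(vals), include = c("ARH", "PVH"))
  expect_equal(unname(ft2$values["a", ]), c(25, 75))
})

test_that("frequency table is invariant to a global rescaling of samples", {
  a <- generate_atlas(test_config(seed = 21))
  prof <- average_replicates(a$matrix)
  f1 <- frequency_table(prof)
  prof2 <- prof
  prof2$values <- prof2$values * 3.7
  f2 <- frequency_table(prof2)
  expect_equal(f1$values, f2$values)
})

test_that("list summaries report mean and SEM per region", {
  vals <- matrix(c(10, 90, 30, 70), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("ARH", "PVH")))
  ft <- frequency_table(make_profile(vals))
  s <- list_summary(ft, gene_list("two", c("a", "b")))
  expect_equal(s$mean[s$region == "ARH"], 20)
  expect_equal(s$sem[s$region == "ARH"], 10)   # sd(10,30)/sqrt(2)
  expect_equal(s$n, c(2L, 2L))

  s1 <- list_summary(ft, gene_list("one", "a"))
  expect_equal(s1$sem, c(0, 0))
  expect_true(attr(s1, "sem_degenerate"))
  expect_error(list_summary(ft, gene_list("none", "q")), "no genes")
})

test_that("planted lists peak in their target group (40 seeds)", {
  hits <- vapply(1:40, function(s) {
    a <- generate_atlas(test_config(seed = s, noise_sd = 0.1))
    prof <- average_replicates(a$matrix)
    ft <- frequency_table(prof)
    gl <- generate_gene_lists(a$truth,
                              list(list(name = "l", size = 25,
                                        target_group = "reward",
                                        strength = 1.0)),
                              rownames(a$matrix$values), seed = s)
    s_l <- list_summary(ft, gl$lists$l)
    s_l$group[which.max(s_l$mean)] == "reward"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("top contributors are ordered, clamped and conservative", {
  vals <- matrix(c(50, 1, 30, 1, 20, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("x", "y", "z"), c("ARH", "PVH")))
  ft <- frequency_table(make_profile(vals))
  top <- top_contributors(ft, gene_list("l", c("x", "y", "z")), "ARH", k = 3)
  expect_identical(top$gene, c("x", "y", "z", "other"))
  expect_equal(top$percentage[4], 0)
  # k larger than the list is clamped
  top2 <- top_contributors(ft, gene_list("l", c("x", "y")), "ARH", k = 10)
  expect_identical(top2$gene, c("x", "y", "other"))
  expect_error(top_contributors(ft, gene_list("l", "x"), "NOPE", 1),
               "not in frequency table")

  # conservation on random fixtures: top-k + other == list total
  set.seed(31)
  for (i in 1:20) {
    rv <- matrix(rexp(40), nrow = 8,
                 dimnames = list(paste0("g", 1:8), paste0("R", 1:5)))
    ftr <- frequency_table(make_profile(rv))
    gl <- gene_list("r", sample(rownames(rv), 5))
    tk <- top_contributors(ftr, gl, "R3", k = 2)
    expect_equal(sum(tk$percentage), sum(ftr$values[gl$genes, "R3"]))
  }
})

test_that("peak_region handles ties and degenerate genes", {
  vals <- matrix(c(5, 5, 1,
                   0, 2, 9), nrow = 2, byrow = TRUE,
                 dimnames = list(c("tie", "top"), c("PVH", "ARH", "DMH")))
  prof <- make_profile(vals)
  expect_identical(peak_region(prof, "tie"), "ARH")  # lexicographic tie-break
  expect_identical(peak_region(prof, "top"), "DMH")
  vals0 <- rbind(vals, zero = c(0, 0, 0))
  expect_error(peak_region(make_profile(vals0), "zero"), "zero expression")
  expect_error(peak_region(prof, "nope"), "not in profile")
})

test_that("markers are recovered at default noise across seeds", {
  rec <- vapply(1:5, function(s) {
    a <- generate_atlas(test_config(seed = s))
    prof <- average_replicates(a$matrix)
    mk <- a$truth$marker_of
    mean(vapply(names(mk), function(g) peak_region(prof, g) == mk[[g]],
                logical(1)))
  }, numeric(1))
  expect_true(all(rec >= 0.9))
})

test_that("pairwise region tests behave on degenerate and planted input", {
  # identical per-gene values in every region -> F = 0, flagged degenerate
  vals <- matrix(rep(c(3, 7), each = 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("R1", "R2", "R3")))
  ft <- frequency_table(make_profile(vals))
  tt <- pairwise_region_tests(ft, gene_list("l", c("a", "b")))
  expect_true(attr(tt, "degenerate"))
  expect_true(all(is.na(tt$p)))
  expect_equal(nrow(tt), 3)  # R*(R-1)/2

  # planted single-group enrichment: significant pairs involve the target
  a <- generate_atlas(test_config(seed = 17, noise_sd = 0.1))
  prof <- average_replicates(a$matrix)
  ftr <- frequency_table(prof)
  gl <- generate_gene_lists(a$truth,
                            list(list(name = "l", size = 25,
                                      target_group = "reward",
                                      strength = 1.0)),
                            rownames(a$matrix$values), seed = 17)
  res <- pairwise_region_tests(ftr, gl$lists$l, q = 0.05)
  expect_equal(nrow(res), choose(length(ftr$regions), 2))
  sig <- res[res$significant, ]
  expect_gt(nrow(sig), 0)
  target_regions <- names(prof$groups)[prof$groups == "reward"]
  frac_target <- mean(sig$region1 %in% target_regions |
                        sig$region2 %in% target_regions)
  expect_gt(frac_target, 0.5)
})

test_that("BKY two-stage flags match hand cases and stay monotone", {
  expect_true(all(bky_adjust(rep(1e-6, 10), 0.05)$reject))
  expect_false(any(bky_adjust(rep(0.9, 10), 0.05)$reject))
  expect_identical(bky_adjust(numeric(0), 0.05)$reject, logical(0))
  expect_error(bky_adjust(c(0.1, 1.2), 0.05), "in \\[0, 1\\]")

  set.seed(77)
  p <- c(runif(15, 0, 0.02), runif(10))
  expect_identical(bky_adjust(p, 0.05)$reject, oracle_bky(p, 0.05))

  # monotonicity: lowering any p never removes a rejection elsewhere
  for (i in 1:20) {
    p0 <- runif(12)
    r0 <- bky_adjust(p0, 0.05)$reject
    j <- sample(12, 1)
    p1 <- p0
    p1[j] <- p0[j] * runif(1)
    r1 <- bky_adjust(p1, 0.05)$reject
    expect_true(all(r1[-j] >= r0[-j]))
  }
})
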