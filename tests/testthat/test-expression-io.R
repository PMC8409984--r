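test_that("matrix reader parses fixtures and enforces the contract", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.tsv")
  sp <- file.path(dir, "s.tsv")
  writeLines(c("gene\ts1\ts2", "Pomc\t1.5\t2", "Agrp\t0\t4",
               "Lepr\t3\t0.25"), mp)
  writeLines(c("sample_id\tregion\tgroup\treplicate",
               "s1\tARH\thomeostatic\t1", "s2\tPVH\thomeostatic\t1"), sp)
  em <- read_expression_matrix(mp, sp)
  expect_identical(dim(em), c(3L, 2L))
  expect_equal(em$values["Lepr", "s2"], 0.25)

  writeLines(c("gene\ts1\ts2", "Pomc\t1\t2", "Agrp\t-3\t4"), mp)
  expect_error(read_expression_matrix(mp, sp), "Agrp.*s1")
  writeLines(c("gene\ts1\ts2", "Pomc\t1\t2", "Pomc\t3\t4"), mp)
  expect_error(read_expression_matrix(mp, sp), "duplicate gene ids: Pomc")
  writeLines(c("gene\ts1\ts3", "Pomc\t1\t2"), mp)
  expect_error(read_expression_matrix(mp, sp), "absent from metadata: s3")
})

test_that("write -> read round-trips a generated atlas bitwise", {
  dir <- withr::local_tempdir()
  a <- generate_atlas(test_config(seed = 7))
  write_expression_matrix(a$matrix, file.path(dir, "m.tsv"),
                          file.path(dir, "s.tsv"))
  back <- read_expression_matrix(file.path(dir, "m.tsv"),
                                 file.path(dir, "s.tsv"))
  expect_identical(back$values, a$matrix$values)
  expect_identical(back$samples$region, a$matrix$samples$region)
})

test_that("transcript aggregation sums TPM and conserves column totals", {
  tv <- matrix(c(3, 1, 7, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("tx1", "tx2"), c("s1", "s2")))
  map <- data.frame(transcript = c("tx1", "tx2"), gene = c("g", "g"))
  out <- aggregate_transcripts_to_genes(tv, map)
  expect_equal(out["g", ], c(s1 = 10, s2 = 3))

  # identity map: output equals input
  map_id <- data.frame(transcript = c("tx1", "tx2"),
                       gene = c("tx1", "tx2"))
  expect_equal(aggregate_transcripts_to_genes(tv, map_id), tv)

  # conservation on a random 50-transcript fixture
  set.seed(42)
  tv2 <- matrix(rexp(50 * 4), nrow = 50,
                dimnames = list(sprintf("t%02d", 1:50), paste0("s", 1:4)))
  map2 <- data.frame(transcript = rownames(tv2),
                     gene = paste0("g", sample(1:12, 50, replace = TRUE)))
  out2 <- aggregate_transcripts_to_genes(tv2, map2)
  expect_equal(colSums(out2), colSums(tv2))

  expect_error(
    aggregate_transcripts_to_genes(tv, map[1, , drop = FALSE]),
    "unmapped transcripts: tx2")
})

test_that("replicate averaging is the arithmetic mean per region", {
  em <- toy_matrix()
  prof <- average_replicates(em)
  expect_equal(unname(prof$values["Pomc", ]), c(5, 5))      # (10, 0) -> 5
  expect_equal(unname(prof$values["Agrp", "PVH"]), 5)       # single replicate
  set.seed(1)
  vals <- matrix(rexp(12), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("ARH_r", 1:3)))
  em3 <- expr_matrix(vals, data.frame(sample_id = colnames(vals),
                                      region = "ARH", group = "homeostatic",
                                      replicate = 1:3))
  expect_equal(average_replicates(em3)$values[, "ARH"],
               (vals[, 1] + vals[, 2] + vals[, 3]) / 3)
  expect_error(average_replicates(em, regions = c("ARH", "NTS")),
               "no samples: NTS")
})

test_that("per-gene scaling is a population z-score with zero-safe rows", {
  m <- matrix(c(0, 10, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("r1", "r2")))
  sc <- scale_per_gene(m)
  expect_equal(unname(sc[1, ]), c(-1, 1))
  expect_equal(unname(sc[2, ]), c(0, 0))
  set.seed(9)
  rm <- matrix(rnorm(200), nrow = 10,
               dimnames = list(paste0("g", 1:10), paste0("r", 1:20)))
  sc2 <- scale_per_gene(rm)
  expect_true(all(abs(rowMeans(sc2)) < 1e-12))
  expect_true(all(abs(sqrt(rowMeans(sc2^2)) - 1) < 1e-12))
})

test_that("averaging then scaling is invariant to replicate order", {
  a <- generate_atlas(test_config(seed = 13, n_genes = 600))
  em <- a$matrix
  perm <- sample(ncol(em$values))
  em2 <- expr_matrix(em$values[, perm], em$samples[perm, ])
  s1 <- scale_per_gene(average_replicates(em))
  s2 <- scale_per_gene(average_replicates(em2))
  expect_equal(s1, s2[, colnames(s1)])
})

test_that("gene lists round-trip and symbols map with case normalization", {
  dir <- withr::local_tempdir()
  lists <- list(a = gene_list("a", c("Pomc", "Lepr")),
                b = gene_list("b", c("Agrp")),
                c = gene_list("c", c("Sim1", "Mc4r", "Pomc")),
                d = gene_list("d", "Bdnf"),
                e = gene_list("e", c("Tub", "Gipr")))
  p <- file.path(dir, "lists.tsv")
  write_gene_lists(lists, p)
  back <- read_gene_lists(p)
  expect_identical(names(back), names(lists))
  for (nm in names(lists))
    expect_identical(back[[nm]]$genes, lists[[nm]]$genes)

  ids <- c("Pomc", "Lepr", "Agrp")
  human <- gene_list("obesity", c("POMC", "LEPR"))
  mapped <- map_symbols(human, ids, mode = "case-normalize")
  expect_identical(mapped$genes, c("Pomc", "Lepr"))
  expect_identical(attr(mapped, "n_dropped"), 0L)

  partial <- gene_list("x", c("Pomc", "Nosuchgene"))
  m2 <- map_symbols(partial, ids)
  expect_identical(m2$genes, "Pomc")
  expect_identical(attr(m2, "dropped"), "Nosuchgene")
  expect_error(map_symbols(gene_list("y", "ZZZ"), ids), "empty after mapping")
})
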