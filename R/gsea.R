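#' Rank genes by a target-vs-rest differential statistic
#'
#' Default metric is signal-to-noise: (mean_target - mean_other) /
#' (sd_target + sd_other), with each group's SD floored at
#' `max(0.2 * |group mean|, 1e-8)` so single-replicate groups and
#' zero-variance genes never produce NaN. Genes are sorted by the
#' statistic, descending, with ties broken lexicographically by gene id.
#'
#' @param em an [expr_matrix].
#' @param target_samples,other_samples sample ids (>= 1 target, >= 2 other).
#' @param metric `"s2n"` (signal-to-noise) or `"diff"` (mean difference).
#' @return data.frame of class `ranked_list`: `gene`, `stat` in rank order;
#'   attribute `target`.
#' @export
rank_genes <- function(em, target_samples, other_samples,
                       metric = c("s2n", "diff")) {
  metric <- match.arg(metric)
  stopifnot(inherits(em, "expr_matrix"))
  ids <- colnames(em$values)
  if (!all(c(target_samples, other_samples) %in% ids))
    stop("unknown sample ids", call. = FALSE)
  if (length(target_samples) < 1 || length(other_samples) < 2)
    stop("need >= 1 target and >= 2 other samples", call. = FALSE)
  tv <- em$values[, target_samples, drop = FALSE]
  ov <- em$values[, other_samples, drop = FALSE]
  mt <- rowMeans(tv)
  mo <- rowMeans(ov)
  if (metric == "s2n") {
    st <- if (ncol(tv) > 1) apply(tv, 1, stats::sd) else rep(0, nrow(tv))
    so <- apply(ov, 1, stats::sd)
    st <- pmax(st, 0.2 * abs(mt), 1e-8)
    so <- pmax(so, 0.2 * abs(mo), 1e-8)
    stat <- (mt - mo) / (st + so)
  } else {
    stat <- mt - mo
  }
  genes <- rownames(em$values)
  ord <- order(-stat, genes)
  out <- data.frame(gene = genes[ord], stat = unname(stat[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, hits increment the running sum by
#' `|stat|^p` normalized over the set's hits and misses decrement it by
#' `1/(N - N_hits)`; the enrichment score is the signed maximum deviation
#' from zero. With `p = 0` this is the classical Kolmogorov-Smirnov
#' statistic between hit and miss position distributions.
#'
#' @param ranked a `ranked_list` (or data.frame with `gene`, `stat`).
#' @param gene_set character vector; at least one member must be in the
#'   ranked list.
#' @param p weighting exponent (default 1).
#' @return list with `es`, `running` (length-N running sum) and `peak`
#'   (index of the extremum).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no genes in the ranked list",
                    call. = FALSE)
  if (nh == N) stop("gene set covers the whole ranked list", call. = FALSE)
  w <- abs(ranked$stat)^p
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / nh, N)   # all-zero stats: fall back to p = 0 weights
  dec <- 1 / (N - nh)
  step <- ifelse(hit, inc, -dec)
  running <- cumsum(step)
  # signed maximum deviation; an exact magnitude tie (possible with p = 0,
  # where deviations are rational) resolves to the positive extremum
  run_max <- max(running)
  run_min <- min(running)
  if (run_max >= -run_min - 1e-12) {
    peak <- which.max(running)
  } else {
    peak <- which.min(running)
  }
  list(es = running[peak], running = running, peak = peak)
}

#' Gene-set permutation null for the enrichment score
#'
#' ES of `n_perm` uniformly random gene sets of the same size drawn from
#' the ranked list. Gene-set permutation is used (not phenotype
#' permutation) because regions can have as few as one replicate.
#'
#' @param ranked a `ranked_list`.
#' @param set_size size of the random sets.
#' @param p weighting exponent.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return numeric vector of null ES values.
#' @export
permutation_null <- function(ranked, set_size, p = 1, n_perm = 1000,
                             seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  set.seed(as.integer(seed))
  N <- nrow(ranked)
  vapply(seq_len(n_perm), function(i) {
    enrichment_score(ranked, sample(ranked$gene, set_size), p)$es
  }, numeric(1))
}

#' Normalize an ES against its permutation null
#'
#' NES = ES divided by the mean of the same-sign null values;
#' `p_perm = (1 + #same-sign null at least as extreme) / (n_perm + 1)`.
#' If no null value shares the sign of the ES, the NES is undefined and
#' flagged (`nes = NA`, `defined = FALSE`).
#'
#' @param es observed enrichment score.
#' @param null numeric vector of null ES values.
#' @return list with `nes`, `p_perm`, `defined`.
#' @export
normalize_and_test <- function(es, null) {
  n <- length(null)
  if (es == 0)
    return(list(nes = 0, p_perm = 1, defined = TRUE))
  same <- if (es > 0) null[null > 0] else null[null < 0]
  if (length(same) == 0)
    return(list(nes = NA_real_, p_perm = 1 / (n + 1), defined = FALSE))
  nes <- es / mean(abs(same))
  p_perm <- (1 + sum(abs(same) >= abs(es))) / (n + 1)
  list(nes = nes, p_perm = p_perm, defined = TRUE)
}

#' Run GSEA for every (target, list) combination
#'
#' Targets are either the region groups (samples of all the group's
#' regions aggregated) or the individual regions; each target's samples
#' are compared against all other samples. The ranked universe is the
#' union of all list genes present in the matrix (`universe = "lists"`,
#' mirroring an analysis run on the input gene lists only) or all matrix
#' genes (`universe = "all"`). A target/list result is flagged significant
#' when the ES is positive and the within-list Benjamini-Hochberg FDR of
#' the permutation p values is below `q`.
#'
#' @param em an [expr_matrix].
#' @param lists named list of [gene_list] objects.
#' @param level `"group"` or `"region"`.
#' @param n_perm permutations per (target, list).
#' @param seed integer seed.
#' @param q FDR level for the significance flag.
#' @param p weighting exponent.
#' @param universe `"lists"` or `"all"`.
#' @return data.frame: `target`, `list`, `n_genes`, `es`, `nes`, `p_perm`,
#'   `fdr`, `significant`, `n_perm`, `seed`. Lists with no genes in the
#'   matrix are skipped and reported in attribute `skipped`.
#' @export
gsea_all <- function(em, lists, level = c("group", "region"),
                     n_perm = 1000, seed = 1L, q = 0.05, p = 1,
                     universe = c("lists", "all")) {
  level <- match.arg(level)
  universe <- match.arg(universe)
  stopifnot(inherits(em, "expr_matrix"))
  meta <- em$samples
  fac <- if (level == "group") meta$group else meta$region
  targets <- unique(fac)
  matrix_genes <- rownames(em$values)
  sets <- lapply(lists, function(l) intersect(l$genes, matrix_genes))
  names(sets) <- vapply(lists, `[[`, character(1), "name")
  skipped <- names(sets)[vapply(sets, length, integer(1)) == 0]
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  if (length(sets) == 0) stop("no list genes present in the matrix",
                              call. = FALSE)
  uni <- if (universe == "lists") unique(unlist(sets)) else matrix_genes
  if (universe == "lists" && length(sets) == 1 &&
      length(uni) == length(sets[[1]])) {
    warning("single list covers the whole universe; using all matrix genes")
    uni <- matrix_genes
  }
  sub <- expr_matrix(em$values[uni, , drop = FALSE], meta)
  rows <- list()
  seed_i <- as.integer(seed)
  for (tg in targets) {
    t_ids <- meta$sample_id[fac == tg]
    o_ids <- meta$sample_id[fac != tg]
    ranked <- rank_genes(sub, t_ids, o_ids)
    for (nm in names(sets)) {
      gs <- sets[[nm]]
      gs_in <- intersect(gs, uni)
      es <- enrichment_score(ranked, gs_in, p)$es
      null <- permutation_null(ranked, length(gs_in), p, n_perm, seed_i)
      seed_i <- seed_i + 1L
      nt <- normalize_and_test(es, null)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, list = nm, n_genes = length(gs_in), es = es,
        nes = nt$nes, p_perm = nt$p_perm, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  for (nm in unique(out$list)) {
    i <- out$list == nm
    out$fdr[i] <- stats::p.adjust(out$p_perm[i], "BH")
  }
  out$significant <- out$es > 0 & out$fdr < q
  out$n_perm <- n_perm
  out$seed <- as.integer(seed)
  attr(out, "skipped") <- skipped
  out
}
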