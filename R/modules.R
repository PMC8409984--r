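#' Hierarchical clustering of samples
#'
#' Distance is 1 - Pearson correlation between sample columns over all
#' genes; merging uses average linkage. Constant sample columns have no
#' defined correlation and are an error.
#'
#' @param em an [expr_matrix].
#' @return an [stats::hclust] tree with sample ids as labels.
#' @export
cluster_samples <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(em$values, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample column(s): ",
         paste(colnames(em$values)[sds == 0], collapse = ", "),
         call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(em$values))
  stats::hclust(d, method = "average")
}

#' Module assignment container
#' @param modules named integer vector, gene -> module id (0 = unassigned).
#' @param method one of `"wgcna"`, `"hierarchical"`, `"kmeans"`.
#' @param params list of parameters used.
#' @return object of class `module_assignment`.
#' @export
module_assignment <- function(modules, method, params = list()) {
  stopifnot(is.numeric(modules), !is.null(names(modules)))
  structure(list(modules = stats::setNames(as.integer(modules),
                                           names(modules)),
                 method = method, params = params),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  m <- x$modules
  cat(sprintf("<module_assignment> %s: %d genes, %d modules (%d unassigned)\n",
              x$method, length(m), length(unique(m[m > 0])), sum(m == 0)))
  invisible(x)
}

# relabel clusters 1..M by decreasing size; ties by smallest original
# label; label 0 (unassigned) is preserved
relabel_by_size <- function(labels) {
  labels <- as.integer(labels)
  pos <- labels[labels > 0]
  if (length(pos) == 0) return(labels)
  tab <- table(pos)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  map <- stats::setNames(seq_along(ord), names(tab)[ord])
  out <- labels
  out[labels > 0] <- map[as.character(pos)]
  as.integer(out)
}

#' Choose the soft-threshold power for a correlation network
#'
#' For each candidate power, adjacency is `|cor|^beta` between gene rows of
#' the scaled profile. The primary criterion is the scale-free topology
#' fit: regress log10 frequency on log10 mean connectivity over 10
#' connectivity bins and take the R-squared (counted only when the slope
#' is negative); the smallest power reaching `r2_cutoff` wins. When no
#' power qualifies (typical for strong planted block structure, which is
#' not scale free), the power maximizing the mean silhouette width of a
#' trial TOM clustering is chosen instead.
#'
#' @param scaled genes x regions matrix (rows z-scored), >= 4 regions.
#' @param betas candidate integer powers.
#' @param r2_cutoff scale-free fit threshold (default 0.8).
#' @param min_size,cut_fraction trial clustering parameters for the
#'   silhouette fallback.
#' @return list with `beta`, `criterion` (`"scale_free"` or
#'   `"silhouette"`), and `fit` (per-power data.frame: `beta`, `r2`,
#'   `slope`, `mean_connectivity`, `silhouette`).
#' @export
pick_soft_threshold <- function(scaled, betas = c(1:10, 12, 14, 16),
                                r2_cutoff = 0.8, min_size = 3,
                                cut_fraction = 0.99) {
  stopifnot(is.matrix(scaled))
  if (ncol(scaled) < 4)
    stop("need >= 4 regions for stable correlations", call. = FALSE)
  ac <- abs(stats::cor(t(scaled)))
  sil <- r2 <- slope <- meank <- rep(NA_real_, length(betas))
  for (i in seq_along(betas)) {
    a <- ac^betas[i]
    k <- rowSums(a) - 1
    meank[i] <- mean(k)
    sf <- scale_free_fit(k)
    r2[i] <- sf$r2
    slope[i] <- sf$slope
    tomd <- 1 - tom_similarity(a)
    mod <- detect_modules_dist(tomd, min_size, cut_fraction)
    sil[i] <- mean_silhouette(tomd, mod)
  }
  fit <- data.frame(beta = betas, r2 = r2, slope = slope,
                    mean_connectivity = meank, silhouette = sil)
  ok <- which(r2 >= r2_cutoff & slope < 0)
  if (length(ok)) {
    list(beta = betas[min(ok)], criterion = "scale_free", fit = fit)
  } else {
    list(beta = betas[which.max(sil)], criterion = "silhouette", fit = fit)
  }
}

# scale-free topology fit of a connectivity vector: R^2 and slope of
# log10(p(k)) ~ log10(k) over 10 connectivity bins
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r2 = 0, slope = 0))
  br <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- as.numeric(table(bin)) / length(k)
  keep <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

# mean silhouette width of assigned genes on a distance matrix; NA-safe
mean_silhouette <- function(d, labels) {
  keep <- labels > 0
  if (sum(keep) < 3 || length(unique(labels[keep])) < 2) return(-1)
  d <- d[keep, keep, drop = FALSE]
  lab <- labels[keep]
  n <- length(lab)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab == lab[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
      mean(d[i, lab == cl]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, where the sum runs over `u != i, j` and `k` is the row sum of
#' the adjacency excluding the diagonal; the diagonal is 1.
#'
#' @param adjacency symmetric matrix, values in `[0, 1]`, unit diagonal.
#' @return TOM matrix of the same shape.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  if (!isSymmetric(unname(a), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(a < 0 | a > 1)) stop("adjacency values must be in [0, 1]",
                               call. = FALSE)
  if (any(abs(diag(a) - 1) > 1e-10))
    stop("adjacency must have unit diagonal", call. = FALSE)
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a          # sum_{u != i,j} a_iu a_uj for i != j
  num <- l + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# static tree cut on a distance matrix; returns raw labels with 0 for
# clusters below min_size
detect_modules_dist <- function(dmat, min_size, cut_fraction) {
  h <- stats::hclust(stats::as.dist(dmat), method = "average")
  cuth <- cut_fraction * max(h$height)
  lab <- stats::cutree(h, h = cuth)
  tab <- table(lab)
  small <- as.integer(names(tab)[tab < min_size])
  lab[lab %in% small] <- 0L
  relabel_by_size(lab)
}

#' Detect modules from a topological overlap matrix
#'
#' Average-linkage tree on `1 - TOM`, cut statically at
#' `cut_fraction * max(merge height)`; clusters smaller than
#' `min_module_size` become module 0 (unassigned); surviving modules are
#' relabeled 1..M by decreasing size.
#'
#' @param tom TOM matrix with gene dimnames.
#' @param min_module_size minimum genes per module (default 3).
#' @param cut_fraction fraction of the maximum merge height at which the
#'   tree is cut (default 0.99).
#' @return a [module_assignment] (method `"wgcna"`).
#' @export
detect_modules <- function(tom, min_module_size = 3, cut_fraction = 0.99) {
  stopifnot(is.matrix(tom), !is.null(rownames(tom)))
  lab <- detect_modules_dist(1 - tom, min_module_size, cut_fraction)
  names(lab) <- rownames(tom)
  if (all(lab == lab[1]) && lab[1] != 0)
    warning("all genes fell in a single module at the chosen cut")
  module_assignment(lab, "wgcna",
                    list(min_module_size = min_module_size,
                         cut_fraction = cut_fraction))
}

#' One-call WGCNA-style module detection
#'
#' Scales the profile per gene, picks the soft threshold, forms the
#' unsigned adjacency and TOM, and cuts the TOM tree.
#'
#' @param profile a `region_profile` (or genes x regions matrix).
#' @param betas,r2_cutoff see [pick_soft_threshold].
#' @param min_module_size,cut_fraction see [detect_modules].
#' @param signed use signed adjacency `((1 + cor)/2)^beta` instead of
#'   `|cor|^beta`.
#' @return a [module_assignment]; the soft-threshold scan is attached as
#'   attribute `soft_threshold`.
#' @export
wgcna_modules <- function(profile, betas = c(1:10, 12, 14, 16),
                          r2_cutoff = 0.8, min_module_size = 3,
                          cut_fraction = 0.99, signed = FALSE) {
  scaled <- scale_per_gene(profile)
  st <- pick_soft_threshold(scaled, betas, r2_cutoff,
                            min_module_size, cut_fraction)
  cc <- stats::cor(t(scaled))
  a <- if (signed) ((1 + cc) / 2)^st$beta else abs(cc)^st$beta
  diag(a) <- 1
  tom <- tom_similarity(a)
  out <- detect_modules(tom, min_module_size, cut_fraction)
  out$params$beta <- st$beta
  out$params$criterion <- st$criterion
  out$params$signed <- signed
  attr(out, "soft_threshold") <- st
  out
}

#' Hierarchical-clustering modules
#'
#' Correlation distance (1 - Pearson over regions), average linkage, cut
#' into `k` groups; labels relabeled by decreasing size.
#'
#' @param scaled genes x regions matrix (rows z-scored).
#' @param k number of modules (2 <= k <= n genes).
#' @return a [module_assignment] (method `"hierarchical"`).
#' @export
hierarchical_modules <- function(scaled, k) {
  stopifnot(is.matrix(scaled), !is.null(rownames(scaled)))
  n <- nrow(scaled)
  if (k > n) stop("k exceeds the number of genes", call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(scaled)))
  h <- stats::hclust(d, method = "average")
  lab <- relabel_by_size(stats::cutree(h, k = k))
  names(lab) <- rownames(scaled)
  out <- module_assignment(lab, "hierarchical", list(k = k))
  attr(out, "tree") <- h
  out
}

# best-of-restarts Lloyd k-means; restarts yielding empty clusters or
# non-distinct initial centers count as failed fits and are discarded
.kmeans_restarts <- function(x, k, restarts, iter.max = 200) {
  best <- NULL
  failed <- 0L
  for (r in seq_len(restarts)) {
    init <- x[sample(nrow(x), k), , drop = FALSE]
    fit <- withCallingHandlers(
      tryCatch(stats::kmeans(x, centers = init, iter.max = iter.max,
                             algorithm = "Lloyd"),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(fit) || length(unique(fit$cluster)) < k) {
      failed <- failed + 1L
      next
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means failed in all ", restarts, " restarts for k = ", k,
         call. = FALSE)
  if (failed > 0)
    attr(best, "failed_restarts") <- failed
  best
}

#' K-means modules
#'
#' Lloyd's algorithm on the scaled rows (Euclidean), best of `restarts`
#' random initializations by total within-cluster sum of squares, under a
#' fixed seed; labels relabeled by decreasing size.
#'
#' @param scaled genes x regions matrix (rows z-scored).
#' @param k number of modules.
#' @param restarts random restarts (default 25).
#' @param seed integer seed.
#' @return a [module_assignment] (method `"kmeans"`); attribute `wss` is
#'   the total within-cluster sum of squares.
#' @export
kmeans_modules <- function(scaled, k, restarts = 25, seed = 1L) {
  stopifnot(is.matrix(scaled), !is.null(rownames(scaled)))
  if (k > nrow(scaled)) stop("k exceeds the number of genes", call. = FALSE)
  set.seed(as.integer(seed))
  km <- .kmeans_restarts(scaled, k, restarts)
  lab <- relabel_by_size(km$cluster)
  names(lab) <- rownames(scaled)
  out <- module_assignment(lab, "kmeans",
                           list(k = k, restarts = restarts, seed = seed))
  attr(out, "wss") <- km$tot.withinss
  out
}

#' Choose k by the elbow of the within-cluster sum of squares
#'
#' Runs k-means for every k in the range and returns the k maximizing the
#' discrete second difference `WSS(k-1) - 2 WSS(k) + WSS(k+1)` (ties go to
#' the smallest k). When the maximal second difference is below
#' `weak_threshold` times the total WSS drop over the range, the elbow is
#' flagged weak. The default 0.3 sits between the two empirical regimes: a
#' genuine elbow concentrates nearly the whole drop in one second
#' difference (ratio near 1), while a structureless cloud spreads it
#' (ratio below about 0.2).
#'
#' @param scaled genes x regions matrix.
#' @param k_range integer vector of at least 3 consecutive candidate k.
#' @param restarts,seed passed to [kmeans_modules].
#' @param weak_threshold weak-elbow threshold (default 0.05).
#' @return list with `k`, `wss` (named vector), `weak_elbow` (logical),
#'   `second_diff`.
#' @export
choose_k_elbow <- function(scaled, k_range, restarts = 25, seed = 1L,
                           weak_threshold = 0.3) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3)
    stop("k_range must contain at least 3 values", call. = FALSE)
  n_failed <- 0L
  wss <- vapply(seq_along(k_range), function(i) {
    set.seed(as.integer(seed) + i)
    fit <- .kmeans_restarts(scaled, k_range[i], restarts)
    n_failed <<- n_failed + (attr(fit, "failed_restarts") %||% 0L)
    fit$tot.withinss
  }, numeric(1))
  names(wss) <- k_range
  if (any(diff(wss) > 0))
    warning("within-cluster SS not monotone over k_range; ",
            "using best-of-restarts values")
  d2 <- wss[-c(1, length(wss))] * -2 + wss[-c(length(wss) - 1, length(wss))] +
    wss[-c(1, 2)]
  best <- which.max(d2)            # which.max returns the first (smallest k) tie
  drop_total <- max(wss) - min(wss)
  weak <- drop_total <= 0 || max(d2) < weak_threshold * drop_total
  list(k = k_range[best + 1L], wss = wss, weak_elbow = weak,
       second_diff = d2)
}

#' Adjusted Rand index between two module assignments
#'
#' Chance-corrected agreement of the two partitions over the same gene
#' universe; label permutations do not change the value.
#'
#' @param a,b [module_assignment] objects (or named label vectors) over
#'   identical gene sets.
#' @return ARI in `[-1, 1]`.
#' @export
module_agreement <- function(a, b) {
  la <- if (inherits(a, "module_assignment")) a$modules else a
  lb <- if (inherits(b, "module_assignment")) b$modules else b
  if (!setequal(names(la), names(lb)))
    stop("assignments cover different gene universes", call. = FALSE)
  lb <- lb[names(la)]
  tab <- table(la, lb)
  n <- sum(tab)
  sum_cells <- sum(choose(tab, 2))
  sum_rows <- sum(choose(rowSums(tab), 2))
  sum_cols <- sum(choose(colSums(tab), 2))
  expected <- sum_rows * sum_cols / choose(n, 2)
  maxi <- (sum_rows + sum_cols) / 2
  if (abs(maxi - expected) < .Machine$double.eps * n^2) return(1)
  (sum_cells - expected) / (maxi - expected)
}

#' Heatmap gene ordering: module number, then dendrogram order
#'
#' Genes are ordered by module id (unassigned genes last), and within the
#' ordering by the position at which each gene appears in the global
#' hierarchical clustering of the scaled profile (correlation distance,
#' average linkage).
#'
#' @param assignment a [module_assignment].
#' @param scaled genes x regions matrix covering the assignment's genes.
#' @return character vector of gene ids in display order.
#' @export
heatmap_gene_order <- function(assignment, scaled) {
  genes <- names(assignment$modules)
  stopifnot(all(genes %in% rownames(scaled)))
  scaled <- scaled[genes, , drop = FALSE]
  h <- stats::hclust(stats::as.dist(1 - stats::cor(t(scaled))),
                     method = "average")
  pos <- match(seq_along(genes), h$order)   # leaf position of each gene
  mod <- assignment$modules
  mod_key <- ifelse(mod == 0, .Machine$integer.max, mod)
  genes[order(mod_key, pos)]
}
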