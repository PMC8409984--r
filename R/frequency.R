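#' Per-gene regional frequency distribution
#'
#' For each gene, the replicate-averaged TPM of every region (brain regions
#' and, by default, the mESC columns) is expressed as a percentage of the
#' gene's total across the included regions, so each row sums to 100. Genes
#' with zero total TPM have no defined frequency and are excluded; their
#' ids are attached as attribute `dropped`.
#'
#' @param profile a `region_profile` from [average_replicates].
#' @param include optional character vector of regions to include in the
#'   denominator (default: all regions of the profile).
#' @return a `freq_table`: list with `values` (gene x region percentages),
#'   `regions`, `groups`.
#' @export
frequency_table <- function(profile, include = NULL) {
  stopifnot(inherits(profile, "region_profile"))
  if (is.null(include)) include <- profile$regions
  if (length(include) == 0) stop("empty region set", call. = FALSE)
  bad <- setdiff(include, profile$regions)
  if (length(bad))
    stop("regions not in profile: ", paste(bad, collapse = ", "),
         call. = FALSE)
  v <- profile$values[, include, drop = FALSE]
  tot <- rowSums(v)
  dropped <- rownames(v)[tot == 0]
  keep <- tot > 0
  vals <- 100 * v[keep, , drop = FALSE] / tot[keep]
  structure(list(values = vals, regions = include,
                 groups = profile$groups[include], dropped = dropped),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d genes x %d regions\n", nrow(x$values),
              length(x$regions)))
  invisible(x)
}

#' Per-list frequency summary (mean +/- SEM per region)
#'
#' Compiles the frequency percentages of all genes of a list and reports,
#' per region, their mean and standard error (sample SD / sqrt(n)). With a
#' single retained gene the SEM is reported as 0 and flagged.
#'
#' @param freq a `freq_table`.
#' @param list a [gene_list].
#' @return data.frame with columns `list`, `region`, `group`, `mean`,
#'   `sem`, `n`; attribute `sem_degenerate` is TRUE when n = 1.
#' @export
list_summary <- function(freq, list) {
  stopifnot(inherits(freq, "freq_table"), inherits(list, "gene_list"))
  genes <- intersect(list$genes, rownames(freq$values))
  if (length(genes) == 0)
    stop("no genes of list '", list$name, "' in frequency table",
         call. = FALSE)
  v <- freq$values[genes, , drop = FALSE]
  n <- length(genes)
  m <- colMeans(v)
  sem <- if (n > 1) apply(v, 2, stats::sd) / sqrt(n) else rep(0, ncol(v))
  out <- data.frame(list = list$name, region = freq$regions,
                    group = unname(freq$groups),
                    mean = unname(m), sem = unname(sem), n = n,
                    stringsAsFactors = FALSE)
  attr(out, "sem_degenerate") <- n == 1
  out
}

#' Top contributing genes of a list in one region
#'
#' The list's genes are ordered by their frequency percentage in the
#' region (descending, ties broken lexicographically by gene id); the top
#' `k` are returned and the remainder is aggregated as `"other"`.
#'
#' @param freq a `freq_table`.
#' @param list a [gene_list].
#' @param region region id.
#' @param k number of genes to report (clamped to the list size).
#' @return data.frame with columns `gene`, `percentage`; last row is
#'   `"other"`.
#' @export
top_contributors <- function(freq, list, region, k = 3) {
  stopifnot(inherits(freq, "freq_table"), k >= 1)
  if (!region %in% freq$regions)
    stop("region '", region, "' not in frequency table", call. = FALSE)
  genes <- intersect(list$genes, rownames(freq$values))
  if (length(genes) == 0)
    stop("no genes of list '", list$name, "' in frequency table",
         call. = FALSE)
  p <- freq$values[genes, region]
  ord <- order(-p, genes)
  k <- min(k, length(genes))
  top <- ord[seq_len(k)]
  data.frame(gene = c(genes[top], "other"),
             percentage = c(p[top], sum(p[-top])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Region of peak expression for one gene
#'
#' Region with the maximal replicate-averaged TPM; exact ties are broken
#' by lexicographic region id.
#'
#' @param profile a `region_profile`.
#' @param gene gene id.
#' @return region id (character).
#' @export
peak_region <- function(profile, gene) {
  stopifnot(inherits(profile, "region_profile"))
  if (!gene %in% rownames(profile$values))
    stop("gene '", gene, "' not in profile", call. = FALSE)
  v <- profile$values[gene, ]
  if (all(v == 0)) stop("gene '", gene, "' has zero expression everywhere",
                        call. = FALSE)
  tied <- profile$regions[v == max(v)]
  sort(tied)[1]
}

#' Pairwise region comparisons of a list's frequency profile
#'
#' One-way ANOVA across regions with the list's genes as the unit of
#' observation, followed by all pairwise contrasts as pooled-variance t
#' tests (Fisher-LSD form, df = N - R), adjusted jointly by the
#' Benjamini-Krieger-Yekutieli two-stage step-up at level `q`.
#'
#' @param freq a `freq_table`.
#' @param list a [gene_list] with at least two retained genes.
#' @param q FDR level (default 0.05).
#' @return data.frame with one row per region pair: `region1`, `region2`,
#'   `t`, `p`, `p_adj`, `significant`; attributes `F`, `p_anova`,
#'   `degenerate`.
#' @export
pairwise_region_tests <- function(freq, list, q = 0.05) {
  stopifnot(inherits(freq, "freq_table"))
  genes <- intersect(list$genes, rownames(freq$values))
  if (length(genes) < 2)
    stop("need at least 2 list genes for region tests", call. = FALSE)
  regions <- freq$regions
  if (length(regions) < 2) stop("need at least 2 regions", call. = FALSE)
  v <- freq$values[genes, regions, drop = FALSE]
  n <- nrow(v)                       # genes per region (balanced)
  R <- length(regions)
  N <- n * R
  gm <- mean(v)
  cm <- colMeans(v)
  ssb <- n * sum((cm - gm)^2)
  ssw <- sum(sweep(v, 2, cm)^2)
  df_w <- N - R
  mse <- ssw / df_w
  degenerate <- mse <= 0
  Fstat <- if (degenerate) {
    if (ssb > 0) Inf else 0
  } else (ssb / (R - 1)) / mse
  p_anova <- if (degenerate) NA_real_ else
    stats::pf(Fstat, R - 1, df_w, lower.tail = FALSE)
  pairs <- utils::combn(regions, 2)
  d <- cm[pairs[1, ]] - cm[pairs[2, ]]
  if (degenerate) {
    tval <- rep(NA_real_, ncol(pairs))
    p <- rep(NA_real_, ncol(pairs))
    sig <- rep(NA, ncol(pairs))
    p_adj <- rep(NA_real_, ncol(pairs))
  } else {
    tval <- d / sqrt(mse * (2 / n))
    p <- 2 * stats::pt(-abs(tval), df_w)
    adj <- bky_adjust(p, q)
    sig <- adj$reject
    p_adj <- adj$adj
  }
  out <- data.frame(region1 = pairs[1, ], region2 = pairs[2, ],
                    t = unname(tval), p = unname(p), p_adj = p_adj,
                    significant = sig, stringsAsFactors = FALSE)
  attr(out, "F") <- Fstat
  attr(out, "p_anova") <- p_anova
  attr(out, "degenerate") <- degenerate
  out
}

# Benjamini-Hochberg step-up at level `level`: logical rejection flags
.bh_reject <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * level)
  r <- if (length(k)) max(k) else 0L
  rej <- logical(m)
  if (r > 0) rej[o[seq_len(r)]] <- TRUE
  rej
}

#' Benjamini-Krieger-Yekutieli two-stage adaptive FDR
#'
#' Two-stage step-up: stage 1 is Benjamini-Hochberg at level
#' `q' = q/(1+q)`, giving `r1` rejections and the estimate `m0 = m - r1`
#' of the number of true nulls; if `r1 = 0` nothing is rejected, if
#' `r1 = m` everything is; otherwise stage 2 is Benjamini-Hochberg at
#' level `q' * m / m0`. The returned `adj` values are the BH-adjusted p
#' values rescaled by `m0 / m`; comparing `adj <= q'` reproduces the
#' stage-2 flags.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param q target FDR level.
#' @return list with `reject` (logical), `adj` (numeric), `r1`, `m0`.
#' @export
bky_adjust <- function(p, q = 0.05) {
  if (length(p) == 0)
    return(list(reject = logical(0), adj = numeric(0), r1 = 0L, m0 = 0L))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p values must be in [0, 1]", call. = FALSE)
  m <- length(p)
  qp <- q / (1 + q)
  r1 <- sum(.bh_reject(p, qp))
  if (r1 == 0) {
    reject <- logical(m)
    m0 <- m
  } else if (r1 == m) {
    reject <- rep(TRUE, m)
    m0 <- 0L
  } else {
    m0 <- m - r1
    reject <- .bh_reject(p, qp * m / m0)
  }
  adj <- stats::p.adjust(p, "BH") * (if (r1 == m) 0 else (m - r1) / m)
  list(reject = reject, adj = pmin(adj, 1), r1 = as.integer(r1),
       m0 = as.integer(max(m0, 0)))
}
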