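#' Expression matrix with sample metadata
#'
#' Bundles a gene x sample matrix of TPM values with a sample metadata
#' table. Columns of `values` and rows of `samples` are kept in the same
#' order; both are validated on construction.
#'
#' @param values numeric matrix, genes as rows (unique rownames), samples as
#'   columns (colnames = sample ids). All values must be finite and
#'   non-negative.
#' @param samples data.frame with columns `sample_id`, `region`, `group`,
#'   `replicate` and optionally `batch`; one row per column of `values`, in
#'   column order. `(region, replicate)` pairs must be unique.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || anyNA(rownames(values)))
    stop("`values` must have gene ids as rownames", call. = FALSE)
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "region", "group", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"batch" %in% names(samples)) samples$batch <- NA_character_
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (is.null(colnames(values)))
    stop("`values` must have sample ids as colnames", call. = FALSE)
  if (!identical(colnames(values), samples$sample_id))
    stop("matrix columns and metadata sample_id must match in order",
         call. = FALSE)
  key <- paste(samples$region, samples$replicate)
  if (anyDuplicated(key))
    stop("(region, replicate) pairs must be unique", call. = FALSE)
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, %d regions, %d groups\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$region)),
              length(unique(x$samples$group))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

new_region_profile <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (any(values < 0)) stop("region profile must be non-negative")
  if (!all(colnames(values) %in% names(groups)))
    stop("every region needs a group label")
  structure(list(values = values,
                 regions = colnames(values),
                 groups = groups[colnames(values)]),
            class = "region_profile")
}

#' @export
print.region_profile <- function(x, ...) {
  cat(sprintf("<region_profile> %d genes x %d regions\n",
              nrow(x$values), length(x$regions)))
  invisible(x)
}

#' A named gene list
#'
#' @param name list name (also used as the genetic category / disease label
#'   unless `category` is given).
#' @param genes character vector of gene symbols; must be non-empty and
#'   duplicate-free.
#' @param category optional category label.
#' @return an object of class `gene_list`.
#' @export
gene_list <- function(name, genes, category = name) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene list '", name, "' is empty",
                               call. = FALSE)
  if (anyDuplicated(genes))
    stop("gene list '", name, "' has duplicate symbols", call. = FALSE)
  structure(list(name = name, category = category, genes = genes),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> '%s' (%s): %d genes\n", x$name, x$category,
              length(x$genes)))
  invisible(x)
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file is tab-separated with a `gene` column followed by one
#' column per sample; the metadata file has columns
#' `sample_id, region, group, replicate[, batch]`. Samples present in the
#' matrix header but absent from the metadata are an error.
#'
#' @param path path of the matrix TSV.
#' @param metadata_path path of the sample metadata TSV.
#' @return an [expr_matrix].
#' @export
read_expression_matrix <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("matrix file needs a gene column plus samples",
                          call. = FALSE)
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path,
                              call. = FALSE)
  rownames(vals) <- genes
  meta <- read_sample_metadata(metadata_path)
  missing <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing))
    stop("samples in matrix header absent from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  expr_matrix(vals, meta)
}

#' Read sample metadata
#' @param path TSV with columns `sample_id, region, group, replicate[, batch]`.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  req <- c("sample_id", "region", "group", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta$replicate <- as.integer(meta$replicate)
  meta
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' @param em an [expr_matrix].
#' @param path output path for the matrix TSV.
#' @param metadata_path optional output path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, metadata_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  chr <- matrix(sprintf("%.17g", em$values), nrow = nrow(em$values),
                dimnames = dimnames(em$values))  # full precision: lossless round trip
  tab <- data.frame(gene = rownames(em$values), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(em$samples, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Sum transcript-level TPM to gene level
#'
#' Gene-level abundance is the per-sample sum of the TPM of its
#' transcripts; per-sample totals are conserved exactly.
#'
#' @param transcript_values numeric matrix, transcripts x samples.
#' @param tx2gene data.frame with columns `transcript`, `gene`; every
#'   transcript in the matrix must be mapped exactly once.
#' @return numeric matrix, genes x samples.
#' @export
aggregate_transcripts_to_genes <- function(transcript_values, tx2gene) {
  stopifnot(is.matrix(transcript_values))
  tx2gene <- as.data.frame(tx2gene, stringsAsFactors = FALSE)
  if (!all(c("transcript", "gene") %in% names(tx2gene)))
    stop("tx2gene needs columns `transcript` and `gene`", call. = FALSE)
  if (anyDuplicated(tx2gene$transcript))
    stop("transcripts mapped to more than one gene", call. = FALSE)
  idx <- match(rownames(transcript_values), tx2gene$transcript)
  if (anyNA(idx))
    stop("unmapped transcripts: ",
         paste(rownames(transcript_values)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  g <- tx2gene$gene[idx]
  out <- rowsum(transcript_values, group = g, reorder = TRUE)
  as.matrix(out)
}

#' Average replicate samples within each region
#'
#' Each region column of the result is the unweighted arithmetic mean of
#' that region's replicate columns (TPM scale, not log). Regions appear in
#' order of first appearance in the metadata.
#'
#' @param em an [expr_matrix].
#' @param regions optional subset of regions to keep (error if any has no
#'   samples).
#' @return a `region_profile`: genes x regions matrix plus region->group map.
#' @export
average_replicates <- function(em, regions = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  meta <- em$samples
  all_regions <- unique(meta$region)
  if (is.null(regions)) regions <- all_regions
  absent <- setdiff(regions, all_regions)
  if (length(absent))
    stop("regions with no samples: ", paste(absent, collapse = ", "),
         call. = FALSE)
  cols <- vapply(regions, function(r) {
    j <- which(meta$region == r)
    rowMeans(em$values[, j, drop = FALSE])
  }, numeric(nrow(em$values)))
  colnames(cols) <- regions
  groups <- vapply(regions, function(r) meta$group[meta$region == r][1],
                   character(1))
  new_region_profile(cols, groups)
}

#' Z-score each gene across regions
#'
#' Rows are centred and divided by the population standard deviation
#' (divisor n, the heatmap convention); constant rows map to all zeros.
#'
#' @param profile a `region_profile` or a plain numeric matrix.
#' @return numeric matrix of the same shape.
#' @export
scale_per_gene <- function(profile) {
  v <- if (inherits(profile, "region_profile")) profile$values else profile
  stopifnot(is.matrix(v))
  n <- ncol(v)
  mu <- rowMeans(v)
  cv <- v - mu
  sd_pop <- sqrt(rowMeans(cv^2))
  out <- cv / ifelse(sd_pop > 0, sd_pop, 1)
  out[sd_pop == 0, ] <- 0
  out
}

#' Read gene lists from a two-column TSV
#'
#' @param path TSV with columns `gene`, `list_name` (one row per
#'   membership; a gene may appear in several lists).
#' @return named list of [gene_list] objects, in order of first appearance.
#' @export
read_gene_lists <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("gene", "list_name") %in% names(tab)))
    stop("gene-list file needs columns `gene` and `list_name`", call. = FALSE)
  nm <- unique(tab$list_name)
  out <- lapply(nm, function(n) gene_list(n, unique(tab$gene[tab$list_name == n])))
  names(out) <- nm
  out
}

#' Write gene lists to a two-column TSV
#' @param lists list of [gene_list] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_lists <- function(lists, path) {
  tab <- do.call(rbind, lapply(lists, function(l)
    data.frame(gene = l$genes, list_name = l$name,
               stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map gene-list symbols onto the ids of an expression matrix
#'
#' Symbols absent from `gene_ids` are dropped; the dropped symbols and
#' their count are attached as attributes. Mode `"case-normalize"` converts
#' all-uppercase human-style symbols to mouse-style title case
#' (`POMC -> Pomc`) before matching.
#'
#' @param list a [gene_list].
#' @param gene_ids character vector of matrix gene ids.
#' @param mode `"exact"` or `"case-normalize"`.
#' @return the mapped [gene_list], with attributes `dropped` (character)
#'   and `n_dropped`.
#' @export
map_symbols <- function(list, gene_ids, mode = c("exact", "case-normalize")) {
  mode <- match.arg(mode)
  stopifnot(inherits(list, "gene_list"))
  sym <- list$genes
  if (mode == "case-normalize") {
    sym <- vapply(sym, function(s) {
      paste0(toupper(substring(s, 1, 1)), tolower(substring(s, 2)))
    }, character(1), USE.NAMES = FALSE)
  }
  keep <- sym %in% gene_ids
  if (!any(keep))
    stop("gene list '", list$name, "' empty after mapping", call. = FALSE)
  out <- gene_list(list$name, unique(sym[keep]), list$category)
  attr(out, "dropped") <- list$genes[!keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
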