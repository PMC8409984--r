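#' @keywords internal
stage_error <- function(stage, msg) {
  stop(structure(class = c("regatlas_stage_error", "error", "condition"),
                 list(message = sprintf("stage '%s': %s", stage, msg),
                      call = NULL, stage = stage)))
}

check_files <- function(stage, paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stage_error(stage, paste("missing input file(s):",
                             paste(missing, collapse = ", ")))
  invisible(TRUE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

default_params <- function() {
  list(q = 0.05, n_perm = 200, gsea_level = "group",
       gsea_universe = "lists", module_method = "wgcna", k = NULL,
       k_range = 2:10, min_module_size = 3, cut_fraction = 0.99,
       beta_grid = c(1:10, 12, 14, 16), include_mesc = TRUE,
       overrep_formula = "ratio")
}

stage_frequency <- function(em, lists, q, include_mesc, out_dir) {
  prof <- average_replicates(em)
  include <- prof$regions
  if (!include_mesc) include <- include[prof$groups != "stemcell"]
  ft <- frequency_table(prof, include)
  write_tsv(data.frame(gene = rownames(ft$values), ft$values,
                       check.names = FALSE),
            file.path(out_dir, "frequency_table.tsv"))
  summ <- do.call(rbind, lapply(lists, function(l) list_summary(ft, l)))
  write_tsv(summ, file.path(out_dir, "list_summary.tsv"))
  tests <- do.call(rbind, lapply(lists, function(l) {
    tt <- pairwise_region_tests(ft, l, q)
    cbind(list = l$name, tt)
  }))
  write_tsv(tests, file.path(out_dir, "pairwise_tests.tsv"))
  invisible(ft)
}

stage_gsea <- function(em, lists, params, seed, out_dir) {
  res <- gsea_all(em, lists, level = params$gsea_level,
                  n_perm = params$n_perm, seed = seed, q = params$q,
                  universe = params$gsea_universe)
  write_tsv(res, file.path(out_dir, "gsea.tsv"))
  invisible(res)
}

stage_modules <- function(em, lists, params, seed, out_dir) {
  # sample dendrogram over all genes
  h <- cluster_samples(em)
  ape::write.tree(ape::as.phylo(h),
                  file.path(out_dir, "sample_dendrogram.nwk"))
  # module detection on the union of list genes
  uni <- intersect(unique(unlist(lapply(lists, `[[`, "genes"))),
                   rownames(em$values))
  if (length(uni) < 4)
    stage_error("modules", "fewer than 4 list genes present in the matrix")
  prof <- average_replicates(expr_matrix(em$values[uni, , drop = FALSE],
                                         em$samples))
  scaled <- scale_per_gene(prof)
  methods <- params$module_method
  if (identical(methods, "all"))
    methods <- c("wgcna", "hierarchical", "kmeans")
  k <- params$k
  if (is.null(k) && any(methods %in% c("hierarchical", "kmeans"))) {
    k <- choose_k_elbow(scaled, params$k_range, seed = seed)$k
  }
  assignments <- list()
  for (m in methods) {
    asg <- switch(m,
      wgcna = wgcna_modules(prof, betas = params$beta_grid,
                            min_module_size = params$min_module_size,
                            cut_fraction = params$cut_fraction),
      hierarchical = hierarchical_modules(scaled, k),
      kmeans = kmeans_modules(scaled, k, seed = seed),
      stage_error("modules", paste("unknown method", m)))
    assignments[[m]] <- asg
    write_tsv(data.frame(gene = names(asg$modules),
                         module = unname(asg$modules), method = m),
              file.path(out_dir, paste0("modules_", m, ".tsv")))
  }
  if (length(assignments) > 1) {
    cmb <- utils::combn(names(assignments), 2)
    agree <- data.frame(method1 = cmb[1, ], method2 = cmb[2, ],
                        ari = apply(cmb, 2, function(pp)
                          module_agreement(assignments[[pp[1]]],
                                           assignments[[pp[2]]])))
    write_tsv(agree, file.path(out_dir, "module_agreement.tsv"))
  }
  invisible(list(assignments = assignments, scaled = scaled))
}

stage_overrep <- function(assignments, lists, params, out_dir) {
  for (m in names(assignments)) {
    tab <- overrepresentation_table(assignments[[m]], lists,
                                    formula = params$overrep_formula)
    write_tsv(tab, file.path(out_dir, paste0("overrep_", m, ".tsv")))
  }
  invisible(TRUE)
}

#' Run the full atlas pipeline from a configuration
#'
#' Stages: simulate (or load inputs), frequency, gsea, modules, overrep,
#' report. Each stage writes TSV outputs into the run directory; a
#' manifest records input checksums, parameters, seed and package version.
#' The run is deterministic given the configuration and seed.
#'
#' @param config a list or the path of a JSON config file with fields
#'   `seed`, `out_dir`, either `simulate` (an [atlas_config] spec plus a
#'   `lists` array of list specs) or `inputs` (paths `matrix`, `metadata`,
#'   `lists`), and optional `params` overriding [default_params()] values
#'   (`q`, `n_perm`, `gsea_level`, `module_method`, `k`, `k_range`,
#'   `min_module_size`, `cut_fraction`, `beta_grid`, `include_mesc`,
#'   `overrep_formula`).
#' @param out_dir overrides `config$out_dir`.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    check_files("config", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- utils::modifyList(default_params(),
                              as.list(config$params %||% list()))

  # stage: inputs (simulate or load)
  data_dir <- file.path(out_dir, "data")
  dir.create(data_dir, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    sim <- as.list(config$simulate)
    list_specs <- sim$lists
    sim$lists <- NULL
    sim$seed <- seed
    cfg <- do.call(atlas_config, sim)
    atlas <- generate_atlas(cfg)
    lists <- NULL
    if (!is.null(list_specs)) {
      if (is.data.frame(list_specs))
        list_specs <- lapply(seq_len(nrow(list_specs)), function(i)
          as.list(list_specs[i, , drop = FALSE]))
      gl <- generate_gene_lists(atlas$truth, list_specs,
                                rownames(atlas$matrix$values),
                                seed = seed + 1L)
      atlas$truth <- gl$truth
      lists <- gl$lists
    }
    write_atlas(atlas, lists, data_dir)
    matrix_path <- file.path(data_dir, "matrix.tsv")
    metadata_path <- file.path(data_dir, "metadata.tsv")
    lists_path <- file.path(data_dir, "lists.tsv")
  } else if (!is.null(config$inputs)) {
    matrix_path <- config$inputs$matrix
    metadata_path <- config$inputs$metadata
    lists_path <- config$inputs$lists
  } else {
    stage_error("inputs", "config needs either `simulate` or `inputs`")
  }
  check_files("frequency", c(matrix_path, metadata_path))
  if (is.null(lists_path) || !file.exists(lists_path))
    stage_error("frequency",
                paste("missing gene-list file:",
                      if (is.null(lists_path)) "<unset>" else lists_path))

  em <- read_expression_matrix(matrix_path, metadata_path)
  lists <- read_gene_lists(lists_path)
  lists <- lapply(lists, function(l)
    tryCatch(map_symbols(l, rownames(em$values)),
             error = function(e) stage_error("frequency",
                                             conditionMessage(e))))

  stage_frequency(em, lists, params$q, params$include_mesc, out_dir)
  stage_gsea(em, lists, params, seed, out_dir)
  mods <- stage_modules(em, lists, params, seed, out_dir)
  stage_overrep(mods$assignments, lists, params, out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("regatlas")),
    seed = seed, params = params,
    inputs = list(matrix = unname(tools::md5sum(matrix_path)),
                  metadata = unname(tools::md5sum(metadata_path)),
                  lists = unname(tools::md5sum(lists_path))),
    input_paths = list(matrix = matrix_path, metadata = metadata_path,
                       lists = lists_path),
    outputs = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.(tsv|nwk)$", full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the report tables of a completed run
#'
#' Reads the stage TSVs of a run directory and emits, under
#' `<run>/report/`: the heatmap gene order (module number first, then the
#' order in which the gene appears in the hierarchical clustering of the
#' scaled profile), the target x list enrichment matrix, and a wide
#' overrepresentation table. Numbers are taken verbatim from the stage
#' outputs. Missing stages are skipped and flagged in the returned value.
#'
#' @param run_dir a directory produced by [run_pipeline].
#' @return invisibly, a list with `report_dir` and `stages_missing`.
#' @export
report_run <- function(run_dir) {
  rep_dir <- file.path(run_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  missing <- character(0)

  mod_files <- list.files(run_dir, pattern = "^modules_.*\\.tsv$",
                          full.names = TRUE)
  manifest_path <- file.path(run_dir, "manifest.json")
  matrix_path <- metadata_path <- NULL
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    matrix_path <- man$input_paths$matrix
    metadata_path <- man$input_paths$metadata
  }
  if (length(mod_files) && !is.null(matrix_path) &&
      file.exists(matrix_path)) {
    em <- read_expression_matrix(matrix_path, metadata_path)
    for (f in mod_files) {
      tab <- utils::read.delim(f, stringsAsFactors = FALSE)
      asg <- module_assignment(stats::setNames(tab$module, tab$gene),
                               tab$method[1])
      prof <- average_replicates(
        expr_matrix(em$values[tab$gene, , drop = FALSE], em$samples))
      ord <- heatmap_gene_order(asg, scale_per_gene(prof))
      write_tsv(data.frame(position = seq_along(ord), gene = ord,
                           module = asg$modules[ord]),
                file.path(rep_dir, paste0("gene_order_", tab$method[1],
                                          ".tsv")))
    }
  } else missing <- c(missing, "modules")

  gsea_path <- file.path(run_dir, "gsea.tsv")
  if (file.exists(gsea_path)) {
    g <- utils::read.delim(gsea_path, stringsAsFactors = FALSE)
    wide <- stats::reshape(g[, c("target", "list", "es")],
                           idvar = "target", timevar = "list",
                           direction = "wide")
    names(wide) <- sub("^es\\.", "", names(wide))
    write_tsv(wide, file.path(rep_dir, "enrichment_matrix.tsv"))
  } else missing <- c(missing, "gsea")

  ov_files <- list.files(run_dir, pattern = "^overrep_.*\\.tsv$",
                         full.names = TRUE)
  if (length(ov_files)) {
    for (f in ov_files) {
      o <- utils::read.delim(f, stringsAsFactors = FALSE)
      wide <- stats::reshape(o[, c("module", "list", "score")],
                             idvar = "module", timevar = "list",
                             direction = "wide")
      names(wide) <- sub("^score\\.", "", names(wide))
      write_tsv(wide, file.path(rep_dir,
                                sub("^overrep_", "overrep_wide_",
                                    basename(f))))
    }
  } else missing <- c(missing, "overrep")

  if (length(missing))
    warning("report built from a partial run; missing stage(s): ",
            paste(missing, collapse = ", "))
  invisible(list(report_dir = rep_dir, stages_missing = missing))
}
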