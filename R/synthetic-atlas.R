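#' Configuration for the synthetic regional expression atlas
#'
#' The defaults emulate the design of a bulk RNA-seq atlas of energy-balance
#' brain regions: 22 brain regions (adult homeostatic / executive / reward /
#' cerebellar regions plus four embryonic regions) and two embryonic stem
#' cell lines, with replicate punches per region, region-specific
#' neuropeptide-like marker genes, and blocks of co-expressed genes tied to
#' region groups.
#'
#' All gene-level baselines are deterministic functions of the
#' configuration (log-normal quantiles), so with `noise_sd = 0` the
#' generated matrix is identical across seeds; the seed only drives noise
#' and list sampling.
#'
#' @param region_groups named character vector mapping region acronym to
#'   group label (`homeostatic`, `executive`, `reward`, `cerebellum`,
#'   `embryonic`, `stemcell`). Default mirrors the 22-region + 2-line atlas.
#' @param replicates_per_region integer scalar or named vector (1--4
#'   replicates per region); default 3 for adult regions, 2 for embryonic
#'   and stem-cell samples.
#' @param n_genes total genes in the atlas.
#' @param n_modules_planted number of planted co-expression modules;
#'   modules are assigned to region groups cyclically in the order above.
#' @param module_size genes per planted module.
#' @param marker_genes_per_region region-specific marker genes per region.
#' @param marker_fold_change multiplicative elevation (> 1) of a marker in
#'   its region and of a module block in its target group's regions.
#' @param stage_signature_genes genes elevated in all adult regions and,
#'   separately, in all embryonic + stem-cell samples (the developmental
#'   axis that dominates sample clustering); elevation is
#'   `marker_fold_change`.
#' @param baseline_log_mean,baseline_log_sd log10 TPM baseline mean and SD
#'   across genes.
#' @param noise_sd log10-scale SD of replicate noise; module-internal gene
#'   noise and module region jitter scale with it.
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `atlas_config`.
#' @export
atlas_config <- function(region_groups = default_region_groups(),
                         replicates_per_region = NULL,
                         n_genes = 1000,
                         n_modules_planted = 6,
                         module_size = 40,
                         marker_genes_per_region = 5,
                         marker_fold_change = 10,
                         stage_signature_genes = 100,
                         baseline_log_mean = 1,
                         baseline_log_sd = 1,
                         noise_sd = 0.2,
                         seed = 1L) {
  regions <- names(region_groups)
  if (is.null(regions) || anyDuplicated(regions))
    stop("region_groups must be a named vector with unique region names",
         call. = FALSE)
  if (is.null(replicates_per_region)) {
    replicates_per_region <- ifelse(
      region_groups %in% c("embryonic", "stemcell"), 2L, 3L)
    names(replicates_per_region) <- regions
  } else if (length(replicates_per_region) == 1) {
    replicates_per_region <- stats::setNames(
      rep(as.integer(replicates_per_region), length(regions)), regions)
  } else {
    if (!all(regions %in% names(replicates_per_region)))
      stop("replicates_per_region must cover every region", call. = FALSE)
    replicates_per_region <-
      as.integer(replicates_per_region[regions])
    names(replicates_per_region) <- regions
  }
  counts <- c(n_genes = n_genes, n_modules_planted = n_modules_planted,
              module_size = module_size,
              marker_genes_per_region = marker_genes_per_region)
  if (any(counts < 1) || any(replicates_per_region < 1))
    stop("all counts must be >= 1", call. = FALSE)
  if (any(replicates_per_region > 4))
    stop("replicates_per_region must be between 1 and 4", call. = FALSE)
  if (marker_fold_change <= 1)
    stop("marker_fold_change must be > 1", call. = FALSE)
  need <- n_modules_planted * module_size +
    length(regions) * marker_genes_per_region
  if (n_genes < need)
    stop(sprintf(paste0("n_genes (%d) too small: %d planted module genes + ",
                        "%d markers require at least %d genes"),
                 n_genes, n_modules_planted * module_size,
                 length(regions) * marker_genes_per_region, need),
         call. = FALSE)
  structure(list(region_groups = region_groups,
                 regions = regions,
                 replicates_per_region = replicates_per_region,
                 n_genes = as.integer(n_genes),
                 n_modules_planted = as.integer(n_modules_planted),
                 module_size = as.integer(module_size),
                 marker_genes_per_region = as.integer(marker_genes_per_region),
                 marker_fold_change = marker_fold_change,
                 stage_signature_genes = as.integer(stage_signature_genes),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "atlas_config")
}

#' Default region roster: 22 brain regions plus two mESC lines
#'
#' Acronyms follow Allen Brain Atlas naming for the adult regions;
#' embryonic punches are forebrain, terminal/peduncular hypothalamus,
#' midbrain and hindbrain.
#' @return named character vector, region -> group.
#' @export
default_region_groups <- function() {
  c(ARH = "homeostatic", PVH = "homeostatic", DMH = "homeostatic",
    VMH = "homeostatic", LHA = "homeostatic", PB = "homeostatic",
    NTS = "homeostatic", DVC = "homeostatic",
    ACA = "executive", FRP = "executive", ENT = "executive",
    ACB = "reward", VTA = "reward",
    CENT2 = "cerebellum", CUL45 = "cerebellum", UVU = "cerebellum",
    CBN = "cerebellum", FL = "cerebellum",
    EF = "embryonic", EHY = "embryonic", EM = "embryonic",
    EH = "embryonic",
    B6.1 = "stemcell", B6.2 = "stemcell")
}

group_order <- c("homeostatic", "executive", "reward", "embryonic",
                 "cerebellum", "stemcell")

# deterministic pseudo-shuffle: spreads sorted baseline quantiles across
# gene indices without consuming RNG state
.det_shuffle <- function(n) order(sin(seq_len(n) * 12.9898))

#' Generate a synthetic atlas with planted ground truth
#'
#' Baseline expression is log-normal per gene (deterministic quantiles of
#' `N(baseline_log_mean, baseline_log_sd)` on the log10 scale). Markers are
#' multiplicative bumps of `marker_fold_change` in their region; each
#' planted module shares a latent region profile elevated in its target
#' group's regions (embryonic and stem-cell module profiles are partially
#' coupled, emulating the shared developmental program), plus independent
#' per-gene noise. Replicate columns add i.i.d. log10-normal noise with SD
#' `noise_sd`, then every sample column is renormalized to 1e6 TPM.
#'
#' @param config an [atlas_config].
#' @return list with elements `matrix` (an [expr_matrix]) and `truth`, a
#'   list with `marker_of` (gene -> region), `module_of` (gene -> planted
#'   module id), `module_target_group` (module id -> group),
#'   `peak_group_of` (gene -> expected peak group, planted genes only) and
#'   `list_target_group` (filled by [generate_gene_lists]).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_config"))
  cfg <- config
  regions <- cfg$regions
  groups <- cfg$region_groups
  R <- length(regions)
  G <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(G))

  # deterministic baselines (identical across seeds)
  q <- stats::qnorm(stats::ppoints(G), cfg$baseline_log_mean,
                    cfg$baseline_log_sd)
  baseline <- 10^q[.det_shuffle(G)]

  n_mark <- R * cfg$marker_genes_per_region
  n_mod <- cfg$n_modules_planted * cfg$module_size
  marker_idx <- seq_len(n_mark)
  module_idx <- n_mark + seq_len(n_mod)
  rest_idx <- setdiff(seq_len(G), c(marker_idx, module_idx))

  marker_of <- stats::setNames(rep(regions, each = cfg$marker_genes_per_region),
                               genes[marker_idx])
  module_of <- stats::setNames(rep(seq_len(cfg$n_modules_planted),
                                   each = cfg$module_size),
                               genes[module_idx])
  avail_groups <- group_order[group_order %in% unique(groups)]
  module_target_group <- avail_groups[
    (seq_len(cfg$n_modules_planted) - 1L) %% length(avail_groups) + 1L]

  set.seed(cfg$seed)
  profile <- matrix(baseline, nrow = G, ncol = R,
                    dimnames = list(genes, regions))

  # markers: multiplicative bump in the planted region
  for (i in marker_idx) {
    profile[i, marker_of[genes[i]]] <-
      profile[i, marker_of[genes[i]]] * cfg$marker_fold_change
  }

  # developmental stage signature: adult vs embryonic+stemcell programs
  # carry the full marker-level fold (stage dominates sample clustering)
  n_sig <- min(cfg$stage_signature_genes, floor(length(rest_idx) / 2))
  adult <- !(groups %in% c("embryonic", "stemcell"))
  sig_fold <- sqrt(cfg$marker_fold_change)
  adult_sig <- rest_idx[seq_len(n_sig)]
  dev_sig <- rest_idx[n_sig + seq_len(n_sig)]
  profile[adult_sig, adult] <- profile[adult_sig, adult] *
    cfg$marker_fold_change
  profile[dev_sig, !adult] <- profile[dev_sig, !adult] *
    cfg$marker_fold_change

  # planted modules: shared latent region profile + per-gene noise
  for (m in seq_len(cfg$n_modules_planted)) {
    tg <- module_target_group[m]
    latent <- rep(1, R)
    latent[groups == tg] <- cfg$marker_fold_change
    # embryonic and stem-cell programs are partially shared
    if (tg == "embryonic") latent[groups == "stemcell"] <- sig_fold
    if (tg == "stemcell") latent[groups == "embryonic"] <- sig_fold
    latent <- latent * 10^stats::rnorm(R, 0, 0.3 * cfg$noise_sd)
    rows <- module_idx[module_of == m]
    noise <- 10^matrix(stats::rnorm(length(rows) * R, 0, 0.5 * cfg$noise_sd),
                       nrow = length(rows))
    profile[rows, ] <- profile[rows, ] * rep(latent, each = length(rows)) *
      noise
  }

  # expand to replicate sample columns with log-normal replicate noise
  reps <- cfg$replicates_per_region
  sample_region <- rep(regions, times = reps[regions])
  sample_rep <- unlist(lapply(reps[regions], seq_len), use.names = FALSE)
  sample_id <- paste0(sample_region, "_r", sample_rep)
  S <- length(sample_id)
  vals <- profile[, sample_region, drop = FALSE] *
    10^matrix(stats::rnorm(G * S, 0, cfg$noise_sd), nrow = G)
  colnames(vals) <- sample_id
  # TPM renormalization: each sample sums to 1e6
  vals <- sweep(vals, 2, colSums(vals), "/") * 1e6

  samples <- data.frame(sample_id = sample_id,
                        region = sample_region,
                        group = unname(groups[sample_region]),
                        replicate = sample_rep,
                        batch = NA_character_,
                        stringsAsFactors = FALSE)

  peak_group_of <- c(stats::setNames(unname(groups[marker_of]),
                                     names(marker_of)),
                     stats::setNames(module_target_group[module_of],
                                     names(module_of)))
  truth <- list(marker_of = marker_of,
                module_of = module_of,
                module_target_group = module_target_group,
                peak_group_of = peak_group_of,
                list_target_group = character(0))
  list(matrix = expr_matrix(vals, samples), truth = truth)
}

#' Generate gene lists with planted region-group enrichment
#'
#' Each list draws `round(strength * size)` genes from the pool of genes
#' whose planted expression peaks in the target group (markers of the
#' group's regions plus module genes targeting the group); the remainder
#' is drawn uniformly from the other genes. With `strength = 0` the whole
#' list is a uniform draw. A list may request an exact overlap with a
#' previously generated list; genes outside that overlap are then drawn
#' from genes not in the other list, so the intersection size is exact.
#'
#' @param truth the `truth` component returned by [generate_atlas].
#' @param specs list of per-list specs: `list(name=, size=, target_group=
#'   NULL, strength = 0, overlap_with = NULL, overlap = 0)`.
#' @param genes character vector of all atlas gene ids.
#' @param seed integer seed.
#' @return list with `lists` (named list of [gene_list]) and `truth`
#'   (input truth with `list_target_group` filled in).
#' @export
generate_gene_lists <- function(truth, specs, genes, seed = 1L) {
  set.seed(as.integer(seed))
  out <- list()
  tg_map <- character(0)
  for (sp in specs) {
    nm <- sp$name
    size <- sp$size
    strength <- sp$strength
    if (is.null(strength) || is.na(strength)) strength <- 0
    tg <- sp$target_group
    if (!is.null(tg) && is.na(tg)) tg <- NULL
    if (!is.null(sp$overlap_with) && is.na(sp$overlap_with))
      sp$overlap_with <- NULL
    chosen <- character(0)
    excluded <- character(0)
    if (!is.null(sp$overlap_with) && !is.null(sp$overlap) &&
        !is.na(sp$overlap) && sp$overlap > 0) {
      other <- out[[sp$overlap_with]]
      if (is.null(other))
        stop("overlap_with refers to unknown list '", sp$overlap_with, "'",
             call. = FALSE)
      chosen <- sample(other$genes, min(sp$overlap, length(other$genes)))
      excluded <- setdiff(other$genes, chosen)
    }
    if (!is.null(tg)) {
      pool <- names(truth$peak_group_of)[truth$peak_group_of == tg]
      if (length(pool) == 0)
        stop("target group '", tg, "' not present in truth", call. = FALSE)
      pool <- setdiff(pool, c(chosen, excluded))
      n_target <- min(round(strength * (size - length(chosen))), length(pool))
      chosen <- c(chosen, sample(pool, n_target))
    }
    remainder <- size - length(chosen)
    if (remainder > 0) {
      pool2 <- setdiff(genes, c(chosen, excluded))
      if (!is.null(tg) && strength >= 1) {
        # strength 1: fill only from target-peaking genes
        pool2 <- intersect(pool2,
                           names(truth$peak_group_of)[
                             truth$peak_group_of == tg])
      }
      if (length(pool2) < remainder)
        stop("requested size exceeds available genes for list '", nm, "'",
             call. = FALSE)
      chosen <- c(chosen, sample(pool2, remainder))
    }
    out[[nm]] <- gene_list(nm, chosen)
    tg_map[nm] <- if (is.null(tg)) NA_character_ else tg
  }
  truth$list_target_group <- tg_map
  list(lists = out, truth = truth)
}

#' Write a generated atlas to disk
#'
#' Emits the expression matrix TSV, sample metadata TSV, gene-list TSV and
#' a JSON file with the planted truth.
#'
#' @param atlas result of [generate_atlas].
#' @param lists named list of [gene_list] (optional).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, lists = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(atlas$matrix, file.path(dir, "matrix.tsv"),
                          file.path(dir, "metadata.tsv"))
  if (!is.null(lists) && length(lists))
    write_gene_lists(lists, file.path(dir, "lists.tsv"))
  truth <- atlas$truth
  jsonlite::write_json(
    list(marker_of = as.list(truth$marker_of),
         module_of = as.list(truth$module_of),
         module_target_group = truth$module_target_group,
         list_target_group = as.list(truth$list_target_group)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
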