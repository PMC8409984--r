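#' Module composition of gene lists
#'
#' For every (module, list) pair, counts `w`, the list's genes assigned to
#' the module, and the composition percentage `100 * w / z` where `z` is
#' the module size. A gene belonging to several lists contributes to each
#' of its lists (membership counted with multiplicity). Unassigned genes
#' (module 0) are excluded unless `include_unassigned` is set, in which
#' case module 0 appears as its own row block.
#'
#' @param assignment a [module_assignment].
#' @param lists named list of [gene_list] objects; symbols outside the
#'   assignment's gene universe are ignored.
#' @param include_unassigned include module 0 as a module.
#' @return data.frame: `module`, `list`, `w`, `z`, `percentage`.
#' @export
module_composition <- function(assignment, lists,
                               include_unassigned = FALSE) {
  stopifnot(inherits(assignment, "module_assignment"))
  mod <- assignment$modules
  if (!include_unassigned) mod <- mod[mod > 0]
  if (length(mod) == 0) stop("no assigned genes", call. = FALSE)
  mods <- sort(unique(mod))
  z <- table(factor(mod, levels = mods))
  rows <- list()
  for (nm in names(lists)) {
    genes <- intersect(lists[[nm]]$genes, names(mod))
    w <- table(factor(mod[genes], levels = mods))
    rows[[nm]] <- data.frame(module = as.integer(mods), list = nm,
                             w = as.integer(w), z = as.integer(z),
                             percentage = 100 * as.integer(w) /
                               as.integer(z),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overrepresentation score of a list in a module
#'
#' The score is observed over expected minus one, where the expectation
#' allocates the list's `x` genes to modules proportionally to module
#' size: `expected = z * x / y` with `y` the total list-membership count
#' over the clustered universe. A score of 0 means exact proportional
#' allocation; the floor -1 is reached at `w = 0`. The `"literal"` formula
#' is the left-to-right reading `(w / (x / y)) * z - 1`, retained for
#' audit; it is not 0 under proportional allocation and is not the
#' default.
#'
#' @param w genes of the list in the module.
#' @param x genes in the list (within the clustered universe).
#' @param y total list-membership count over the clustered universe.
#' @param z genes in the module.
#' @param formula `"ratio"` (default) or `"literal"`.
#' @return numeric score (>= -1 for the ratio formula).
#' @export
overrepresentation_score <- function(w, x, y, z,
                                     formula = c("ratio", "literal")) {
  formula <- match.arg(formula)
  if (any(x < 1) || any(y < 1) || any(z < 1))
    stop("x, y, z must be >= 1", call. = FALSE)
  if (any(w < 0) || any(w > pmin(x, z)))
    stop("w must satisfy 0 <= w <= min(x, z)", call. = FALSE)
  if (any(x > y)) stop("x cannot exceed y", call. = FALSE)
  if (formula == "ratio") w / ((x / y) * z) - 1 else (w / (x / y)) * z - 1
}

#' Overrepresentation table over all (module, list) pairs
#'
#' `x` is each list's assigned-gene count, `y` the sum of `x` over lists
#' (membership with multiplicity), `z` the module sizes; one score per
#' (module, list) in long format. The conservation identity
#' `sum_modules z * (score + 1) * (x / y) = x` holds per list.
#'
#' @inheritParams module_composition
#' @param formula see [overrepresentation_score].
#' @return data.frame: `module`, `list`, `w`, `z`, `x`, `y`,
#'   `percentage`, `score`.
#' @export
overrepresentation_table <- function(assignment, lists,
                                     formula = c("ratio", "literal"),
                                     include_unassigned = FALSE) {
  formula <- match.arg(formula)
  comp <- module_composition(assignment, lists, include_unassigned)
  if (length(unique(comp$module)) < 2)
    stop("need at least 2 modules", call. = FALSE)
  x_by_list <- tapply(comp$w, comp$list, sum)
  if (any(x_by_list == 0))
    stop("list(s) with no assigned genes: ",
         paste(names(x_by_list)[x_by_list == 0], collapse = ", "),
         call. = FALSE)
  y <- sum(x_by_list)
  comp$x <- as.integer(x_by_list[comp$list])
  comp$y <- as.integer(y)
  comp$score <- overrepresentation_score(comp$w, comp$x, comp$y, comp$z,
                                         formula)
  comp
}
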