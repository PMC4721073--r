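#' Assign populations and ecosystem variants to seed-zone groups
#'
#' Routes every population through a fitted regression tree and maps each
#' ecosystem variant to a group by majority vote of its populations (ties to
#' the larger group, then the lower group number). Variants whose populations
#' land in more than one leaf are resolved by majority and reported as
#' conflicts.
#'
#' @param tree an [mrt()] tree.
#' @param populations origin table with `seedlot_id` and (for the variant
#'   map) `ecosystem_variant`, plus the predictor columns the tree uses.
#' @return object of class `"group_assignment"`: list with `populations`
#'   (seedlot_id, group), `variants` (ecosystem_variant, group, n, conflict),
#'   `profiles` (leaf trait profiles), `n_groups`, `conflicts`.
#' @export
assign_groups <- function(tree, populations) {
  stopifnot(inherits(tree, "mrt"), "seedlot_id" %in% names(populations))
  grp <- predict(tree, populations, unseen = "majority")
  pops <- data.frame(seedlot_id = populations$seedlot_id, group = grp,
                     stringsAsFactors = FALSE)
  prof <- leaf_profiles(tree)
  group_sizes <- tabulate(grp, nbins = max(grp))
  variants <- NULL; conflicts <- character(0)
  if ("ecosystem_variant" %in% names(populations)) {
    tab <- table(populations$ecosystem_variant, grp)
    win <- apply(tab, 1, function(cnt) {
      cand <- which(cnt == max(cnt))
      if (length(cand) > 1) cand <- cand[order(-group_sizes[cand], cand)]
      cand[1]
    })
    conflict <- apply(tab, 1, function(cnt) sum(cnt > 0) > 1)
    variants <- data.frame(ecosystem_variant = rownames(tab),
                           group = as.integer(colnames(tab))[win],
                           n = as.integer(rowSums(tab)),
                           conflict = as.logical(conflict),
                           stringsAsFactors = FALSE)
    conflicts <- variants$ecosystem_variant[variants$conflict]
    if (length(conflicts))
      message("variant(s) split across leaves, resolved by majority: ",
              paste(conflicts, collapse = ", "))
  }
  structure(list(populations = pops, variants = variants, profiles = prof,
                 n_groups = length(unique(grp)), conflicts = conflicts),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment: %d populations in %d groups",
              nrow(x$populations), x$n_groups))
  if (!is.null(x$variants))
    cat(sprintf("; %d ecosystem variants (%d conflicts)",
                nrow(x$variants), length(x$conflicts)))
  cat("\n")
  invisible(x)
}

#' Agreement between two partitions of the same populations
#'
#' Chance-adjusted Rand index in \[-1, 1\]: 1 for identical partitions (up to
#' relabeling), approximately 0 for independent random labelings.
#'
#' @param a,b `"group_assignment"` objects or label vectors (named, or
#'   aligned) over the same populations.
#' @return adjusted Rand index.
#' @export
compare_partitions <- function(a, b) {
  lab <- function(x) {
    if (inherits(x, "group_assignment"))
      setNames(x$populations$group, x$populations$seedlot_id)
    else x
  }
  la <- lab(a); lb <- lab(b)
  if (!is.null(names(la)) && !is.null(names(lb))) {
    if (!setequal(names(la), names(lb)))
      stop("partitions cover different population sets")
    lb <- lb[names(la)]
  } else if (length(la) != length(lb)) {
    stop("partitions cover different population sets")
  }
  mclust::adjustedRandIndex(la, lb)
}

#' Write the analysis report bundle
#'
#' Emits the tables and figure data of a full genecology run: per-trait
#' variance components with V_pop (CSV), the tree as indented text and JSON,
#' population group assignments and the variant-to-group table (CSV), leaf
#' trait profiles for bar charts (CSV), and a JSON run log with the
#' configuration. Output is deterministic: regenerating from the same inputs
#' is byte-identical.
#'
#' @param dir output directory (created if absent).
#' @param assignment a `"group_assignment"`.
#' @param decomps list of `"variance_decomposition"` objects (possibly
#'   empty, in which case the variance table is omitted with a warning).
#' @param tree the fitted `"mrt"` tree.
#' @param config optional named list recorded in the run log (seeds,
#'   parameters).
#' @return invisibly, the paths written.
#' @export
render_report <- function(dir, assignment, decomps, tree, config = list()) {
  stopifnot(inherits(assignment, "group_assignment"), inherits(tree, "mrt"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    write.csv(x, p, row.names = FALSE, na = "")
    written <<- c(written, p)
  }
  if (length(decomps)) {
    vtab <- do.call(rbind, lapply(decomps, function(d) {
      comp <- d$components
      data.frame(trait = d$trait, term = comp$term,
                 sigma2 = comp$sigma2, se = comp$se,
                 percent = comp$percent, percent_se = comp$percent_se,
                 vpop = d$vpop, vpop_se = d$vpop_se,
                 stringsAsFactors = FALSE)
    }))
    wr(vtab, "variance_components.csv")
  } else {
    warning("no variance decompositions supplied; variance table omitted")
  }
  wr(assignment$populations, "group_assignments.csv")
  if (!is.null(assignment$variants)) wr(assignment$variants, "variant_groups.csv")
  prof <- assignment$profiles
  attr(prof, "members") <- NULL
  wr(prof, "leaf_profiles.csv")

  txt <- file.path(dir, "tree.txt")
  writeLines(format_mrt(tree), txt)
  written <- c(written, txt)

  node_json <- lapply(tree$nodes, function(nd) {
    if (is.null(nd)) return(NULL)
    out <- list(id = nd$id, n = length(nd$rows), ss = nd$ss)
    if (!is.null(nd$split)) {
      sp <- nd$split
      out$split <- list(predictor = sp$predictor, kind = sp$kind,
                        ss_reduction = sp$ss_reduction,
                        ss_fraction = sp$ss_fraction)
      if (sp$kind == "numeric") out$split$threshold <- sp$threshold
      else out$split$left_levels <- sp$left_levels
      out$children <- nd$children
    }
    out
  })
  node_json <- node_json[!vapply(node_json, is.null, logical(1))]
  tj <- file.path(dir, "tree.json")
  jsonlite::write_json(
    list(total_ss = tree$total_ss, r_squared = tree$r_squared,
         n_leaves = length(mrt_leaf_ids(tree)), nodes = node_json),
    tj, auto_unbox = TRUE, digits = NA)
  written <- c(written, tj)

  lg <- file.path(dir, "run_log.json")
  jsonlite::write_json(
    list(package = "genecol",
         version = as.character(utils::packageVersion("genecol")),
         n_populations = nrow(assignment$populations),
         n_groups = assignment$n_groups,
         conflicts = assignment$conflicts,
         config = config),
    lg, auto_unbox = TRUE, digits = NA)
  written <- c(written, lg)
  invisible(written)
}
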