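#' Multivariate sum of squares about the centroid
#'
#' Total squared Euclidean distance of the rows to their multivariate mean,
#' the node impurity minimized by the multivariate regression tree. Equals
#' the sum over columns of \eqn{\sum_i (x_{ij} - \bar x_j)^2}.
#'
#' @param Y numeric matrix (rows = populations), data frame, or
#'   `"trait_matrix"`.
#' @return scalar sum of squares.
#' @export
total_ss <- function(Y) {
  Y <- response_matrix(Y)
  if (nrow(Y) == 0) return(0)
  sum(sweep(Y, 2, colMeans(Y))^2)
}

response_matrix <- function(Y) {
  if (inherits(Y, "trait_matrix")) Y <- Y$values
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyNA(Y)) stop("response matrix must be complete; impute first")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  Y
}

split_reduction <- function(nL, sL, nR, sR) {
  # parent SS - (left SS + right SS) for a binary split, via group means
  mL <- sL / nL; mR <- sR / nR
  (nL * nR / (nL + nR)) * sum((mL - mR)^2)
}

#' Best binary split on a numeric predictor
#'
#' Evaluates every midpoint between consecutive distinct sorted predictor
#' values and returns the split (rule: `value < threshold` goes left) that
#' maximizes the reduction in multivariate sum of squares, subject to both
#' children holding at least `min_leaf` rows. Ties go to the smaller
#' threshold.
#'
#' @param x numeric predictor vector, aligned with the rows of `Y`.
#' @param Y response matrix.
#' @param min_leaf minimum rows per child.
#' @return list (`kind`, `threshold`, `ss_reduction`, `n_left`) or `NULL`
#'   when no admissible split exists.
#' @export
best_numeric_split <- function(x, Y, min_leaf = 2) {
  Y <- response_matrix(Y)
  n <- length(x)
  if (n < 2 * min_leaf) return(NULL)
  ord <- order(x)
  xs <- x[ord]
  cs <- apply(Y[ord, , drop = FALSE], 2, cumsum)
  if (n == 1) cs <- matrix(cs, 1)
  tot <- cs[n, ]
  best <- NULL
  for (i in seq_len(n - 1)) {
    if (i < min_leaf || (n - i) < min_leaf) next
    if (xs[i] >= xs[i + 1]) next
    red <- split_reduction(i, cs[i, ], n - i, tot - cs[i, ])
    if (is.null(best) || red > best$ss_reduction + 1e-12) {
      best <- list(kind = "numeric", threshold = (xs[i] + xs[i + 1]) / 2,
                   ss_reduction = red, n_left = i)
    }
  }
  best
}

#' Best binary split on a categorical predictor
#'
#' With at most `max_exhaustive` distinct levels, all \eqn{2^{m-1}-1} binary
#' partitions of the levels are evaluated. Above that, levels are ordered by
#' the projection of their mean response onto the first principal axis of the
#' level means and only contiguous partitions in that order are evaluated
#' (the classic ordered-levels heuristic). Ties go to the lexicographically
#' smallest left level set; the left set is canonicalized to contain the
#' alphabetically first level.
#'
#' @param f factor (or character) predictor aligned with rows of `Y`.
#' @param Y response matrix.
#' @param min_leaf minimum rows per child.
#' @param max_exhaustive level count up to which enumeration is exhaustive.
#' @return list (`kind`, `left_levels`, `ss_reduction`, `n_left`) or `NULL`.
#' @export
best_categorical_split <- function(f, Y, min_leaf = 2, max_exhaustive = 12) {
  Y <- response_matrix(Y)
  f <- factor(f)
  f <- droplevels(f)
  m <- nlevels(f)
  if (m < 2) return(NULL)
  lv <- levels(f)
  cnt <- as.vector(table(f))
  sums <- rowsum(Y, f)          # m x p, level order
  n <- length(f)
  tot <- colSums(Y)

  eval_subset <- function(in_left) {
    nL <- sum(cnt[in_left])
    nR <- n - nL
    if (nL < min_leaf || nR < min_leaf) return(NULL)
    sL <- colSums(sums[in_left, , drop = FALSE])
    red <- split_reduction(nL, sL, nR, tot - sL)
    left <- lv[in_left]
    if (!(lv[1] %in% left)) left <- setdiff(lv, left)  # canonical side
    list(kind = "categorical", left_levels = sort(left),
         ss_reduction = red, n_left = sum(cnt[match(left, lv)]))
  }

  candidates <- list()
  if (m <= max_exhaustive) {
    for (mask in seq_len(2^(m - 1) - 1)) {
      in_left <- c(as.logical(bitwAnd(mask, 2^(seq_len(m - 1) - 1))), FALSE)
      cand <- eval_subset(in_left)
      if (!is.null(cand)) candidates[[length(candidates) + 1]] <- cand
    }
  } else {
    means <- sums / cnt
    ctr <- sweep(means, 2, colMeans(means))
    pc1 <- svd(ctr, nu = 0, nv = 1)$v[, 1]
    sc <- as.vector(ctr %*% pc1)
    ord <- order(sc, lv)
    for (j in seq_len(m - 1)) {
      in_left <- seq_len(m) %in% ord[seq_len(j)]
      cand <- eval_subset(in_left)
      if (!is.null(cand)) candidates[[length(candidates) + 1]] <- cand
    }
  }
  if (!length(candidates)) return(NULL)
  best <- candidates[[1]]
  if (length(candidates) > 1) for (cand in candidates[-1]) {
    if (cand$ss_reduction > best$ss_reduction + 1e-12) best <- cand
    else if (abs(cand$ss_reduction - best$ss_reduction) <= 1e-12) {
      a <- paste(cand$left_levels, collapse = "\r")
      b <- paste(best$left_levels, collapse = "\r")
      if (a < b) best <- cand
    }
  }
  best
}

#' Control parameters for tree growing
#'
#' @param min_leaf minimum populations per leaf (default 2: ecosystems are
#'   typically represented by a handful of seedlots).
#' @param min_improvement_fraction smallest admissible split improvement as a
#'   fraction of the total sum of squares.
#' @param max_leaves stop after this many leaves.
#' @param max_exhaustive exhaustive-enumeration limit for categorical levels.
#' @return list of class `"mrt_control"`.
#' @export
mrt_control <- function(min_leaf = 2, min_improvement_fraction = 0.01,
                        max_leaves = 16, max_exhaustive = 12) {
  structure(list(min_leaf = min_leaf,
                 min_improvement_fraction = min_improvement_fraction,
                 max_leaves = max_leaves, max_exhaustive = max_exhaustive),
            class = "mrt_control")
}

best_split_node <- function(Y, preds, rows, control, is_cat) {
  best <- NULL; best_pred <- NULL
  for (pn in names(preds)) {
    x <- preds[[pn]][rows]
    cand <- if (is_cat[[pn]])
      best_categorical_split(x, Y[rows, , drop = FALSE],
                             control$min_leaf, control$max_exhaustive)
    else
      best_numeric_split(x, Y[rows, , drop = FALSE], control$min_leaf)
    if (!is.null(cand) &&
        (is.null(best) || cand$ss_reduction > best$ss_reduction + 1e-12)) {
      best <- cand; best_pred <- pn
    }
  }
  if (is.null(best)) return(NULL)
  best$predictor <- best_pred
  best
}

#' Grow a multivariate regression tree
#'
#' Greedy best-first binary partitioning of a multivariate response by
#' numeric (climate) or categorical (ecosystem) predictors, maximizing the
#' reduction in within-node multivariate sum of squares at each step: a
#' constrained clustering of populations. At every step the frontier leaf
#' whose best admissible split yields the largest reduction is expanded, so
#' trees of every intermediate size are nested and [prune_to_leaves()] is
#' well defined.
#'
#' @param response `"trait_matrix"` (typically the pooled normalized matrix)
#'   or numeric matrix, rows = populations.
#' @param predictors data frame aligned with the response rows; factor or
#'   character columns (or those named in `categorical`) split by level
#'   subsets, numeric columns by thresholds. Missing values are not allowed.
#' @param control a [mrt_control()] list.
#' @param categorical column names to force categorical.
#' @return object of class `"mrt"`: node list, growth order, total SS,
#'   `r_squared`, and per-split `ss_fraction`.
#' @export
mrt <- function(response, predictors, control = mrt_control(),
                categorical = NULL) {
  Y <- response_matrix(response)
  predictors <- as.data.frame(predictors, stringsAsFactors = FALSE)
  if (nrow(predictors) != nrow(Y))
    stop("predictor rows do not align with response rows")
  if (anyNA(predictors))
    stop("missing predictor values are not supported")
  is_cat <- vapply(names(predictors), function(pn) {
    pn %in% categorical || is.factor(predictors[[pn]]) ||
      is.character(predictors[[pn]])
  }, logical(1))
  for (pn in names(predictors)[is_cat])
    predictors[[pn]] <- factor(predictors[[pn]])

  n <- nrow(Y)
  tot <- total_ss(Y)
  nodes <- list(list(id = 1L, parent = NA_integer_, rows = seq_len(n),
                     ss = tot, split = NULL, children = NULL))
  frontier <- list()   # node id -> candidate split
  if (tot > 0)
    frontier[["1"]] <- best_split_node(Y, predictors, seq_len(n), control, is_cat)
  split_order <- integer(0)
  floor_red <- control$min_improvement_fraction * tot

  repeat {
    n_leaves <- sum(vapply(nodes, function(nd) is.null(nd$children), logical(1)))
    if (n_leaves >= control$max_leaves) break
    cand_ids <- names(frontier)[!vapply(frontier, is.null, logical(1))]
    if (length(cand_ids)) {
      reds <- vapply(frontier[cand_ids], `[[`, numeric(1), "ss_reduction")
      cand_ids <- cand_ids[reds >= floor_red - 1e-12]
      reds <- reds[reds >= floor_red - 1e-12]
    }
    if (!length(cand_ids)) break
    pick <- cand_ids[order(-reds, as.integer(cand_ids))][1]
    id <- as.integer(pick)
    sp <- frontier[[pick]]
    frontier[[pick]] <- NULL
    rows <- nodes[[id]]$rows
    x <- predictors[[sp$predictor]][rows]
    if (sp$kind == "categorical") {
      sp$right_levels <- sort(setdiff(unique(as.character(x)), sp$left_levels))
      go_left <- as.character(x) %in% sp$left_levels
    } else {
      go_left <- x < sp$threshold
    }
    lid <- length(nodes) + 1L; rid <- lid + 1L
    nodes[[lid]] <- list(id = lid, parent = id, rows = rows[go_left],
                         ss = total_ss(Y[rows[go_left], , drop = FALSE]),
                         split = NULL, children = NULL)
    nodes[[rid]] <- list(id = rid, parent = id, rows = rows[!go_left],
                         ss = total_ss(Y[rows[!go_left], , drop = FALSE]),
                         split = NULL, children = NULL)
    sp$ss_fraction <- sp$ss_reduction / tot
    nodes[[id]]$split <- sp
    nodes[[id]]$children <- c(lid, rid)
    split_order <- c(split_order, id)
    for (cid in c(lid, rid)) {
      if (length(nodes[[cid]]$rows) >= 2 * control$min_leaf &&
          nodes[[cid]]$ss > 0)
        frontier[[as.character(cid)]] <-
          best_split_node(Y, predictors, nodes[[cid]]$rows, control, is_cat)
    }
  }

  tree <- structure(list(
    nodes = nodes, split_order = split_order, total_ss = tot,
    n = n, response = Y, predictors = predictors, control = control,
    predictor_names = names(predictors), is_cat = is_cat,
    row_names = rownames(Y)
  ), class = "mrt")
  tree$r_squared <- sum(vapply(split_order, function(id)
    nodes[[id]]$split$ss_fraction, numeric(1)))
  tree
}

mrt_leaf_ids <- function(tree) {
  # leaves in left-to-right order (depth-first traversal from the root)
  ordered <- integer(0)
  walk <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$children)) ordered <<- c(ordered, id)
    else { walk(nd$children[1]); walk(nd$children[2]) }
  }
  walk(1L)
  ordered
}

#' @export
print.mrt <- function(x, ...) {
  cat(sprintf("Multivariate regression tree: %d populations, %d leaves, R^2 = %.3f\n",
              x$n, length(mrt_leaf_ids(x)), x$r_squared))
  cat(format_mrt(x), sep = "\n")
  invisible(x)
}

#' Indented text rendering of a tree
#' @param tree an `"mrt"` object.
#' @return character vector of lines.
#' @export
format_mrt <- function(tree) {
  lines <- character(0)
  leaf_no <- 0L
  walk <- function(id, depth, label) {
    nd <- tree$nodes[[id]]
    pad <- strrep("  ", depth)
    if (is.null(nd$children)) {
      leaf_no <<- leaf_no + 1L
      lines <<- c(lines, sprintf("%s%s leaf %d: n=%d", pad, label, leaf_no,
                                 length(nd$rows)))
    } else {
      sp <- nd$split
      rule <- if (sp$kind == "numeric")
        sprintf("%s < %.4g", sp$predictor, sp$threshold)
      else
        sprintf("%s in {%s}", sp$predictor,
                paste(sp$left_levels, collapse = ","))
      lines <<- c(lines, sprintf("%s%s node %d: %s (explains %.1f%%)", pad,
                                 label, id, rule, 100 * sp$ss_fraction))
      walk(nd$children[1], depth + 1, "<")
      walk(nd$children[2], depth + 1, ">=")
    }
  }
  walk(1L, 0, "*")
  lines
}

route_rows <- function(tree, newdata, unseen = c("error", "majority")) {
  unseen <- match.arg(unseen)
  missing_cols <- setdiff(used_predictors(tree), names(newdata))
  if (length(missing_cols))
    stop("predictor column(s) absent: ", paste(missing_cols, collapse = ", "))
  vapply(seq_len(nrow(newdata)), function(i) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[id]]
      if (is.null(nd$children)) return(nd$id)
      sp <- nd$split
      x <- newdata[[sp$predictor]][i]
      if (is.na(x)) stop("missing predictor value while routing")
      if (sp$kind == "numeric") {
        id <- if (x < sp$threshold) nd$children[1] else nd$children[2]
      } else {
        x <- as.character(x)
        if (x %in% sp$left_levels) id <- nd$children[1]
        else if (x %in% sp$right_levels) id <- nd$children[2]
        else if (unseen == "majority") {
          sizes <- c(length(tree$nodes[[nd$children[1]]]$rows),
                     length(tree$nodes[[nd$children[2]]]$rows))
          id <- nd$children[which.max(sizes)]
        } else stop("unseen level '", x, "' for predictor ", sp$predictor)
      }
    }
  }, integer(1))
}

#' Route populations through a fitted tree
#'
#' @param object an `"mrt"` tree.
#' @param newdata data frame of predictor values (defaults to the training
#'   predictors if they were stored).
#' @param unseen `"error"` or `"majority"`: how to route a categorical level
#'   not observed at a node during training (majority = the child holding
#'   more training rows).
#' @param ... unused.
#' @return integer vector of leaf group numbers (left-to-right numbering).
#' @export
predict.mrt <- function(object, newdata = object$predictors,
                        unseen = c("error", "majority"), ...) {
  unseen <- match.arg(unseen)
  leaf_node <- route_rows(object, newdata, unseen)
  leaves <- mrt_leaf_ids(object)
  match(leaf_node, leaves)
}

used_predictors <- function(tree) {
  unique(vapply(tree$split_order, function(id)
    tree$nodes[[id]]$split$predictor, character(1)))
}

#' Prune a tree to a fixed number of leaves
#'
#' Keeps the first `n_leaves - 1` splits in growth order (best-first growth
#' makes this the nested subtree of largest reductions) and turns the
#' remaining internal nodes back into leaves.
#'
#' @param tree an `"mrt"` object.
#' @param n_leaves target leaf count, between 1 and the current count.
#' @return pruned `"mrt"` object.
#' @export
prune_to_leaves <- function(tree, n_leaves) {
  n_now <- length(mrt_leaf_ids(tree))
  if (n_leaves < 1 || n_leaves > n_now)
    stop(sprintf("n_leaves must be in [1, %d]", n_now))
  keep <- tree$split_order[seq_len(n_leaves - 1)]
  nodes <- tree$nodes
  drop_desc <- function(id) {
    ch <- nodes[[id]]$children
    if (is.null(ch)) return(invisible())
    for (c2 in ch) drop_desc(c2)
    nodes[[id]]$children <<- NULL
    nodes[[id]]$split <<- NULL
  }
  for (id in setdiff(tree$split_order, keep)) {
    if (!is.null(nodes[[id]]$children)) {
      for (c2 in nodes[[id]]$children) drop_desc(c2)
      nodes[[id]]$children <- NULL
      nodes[[id]]$split <- NULL
    }
  }
  reachable <- logical(length(nodes))
  mark <- function(id) {
    reachable[id] <<- TRUE
    ch <- nodes[[id]]$children
    if (!is.null(ch)) for (c2 in ch) mark(c2)
  }
  mark(1L)
  for (i in which(!reachable)) nodes[i] <- list(NULL)
  out <- tree
  out$nodes <- nodes
  out$split_order <- keep
  out$r_squared <- sum(vapply(keep, function(id)
    nodes[[id]]$split$ss_fraction, numeric(1)))
  out
}

#' Leaf trait profiles
#'
#' Mean multivariate response per leaf (in the SD units of the normalized
#' input) with leaf sizes and member populations. With a column-centered
#' response, the size-weighted mean of the profiles is the zero vector.
#'
#' @param tree an `"mrt"` object.
#' @return data frame: `group`, `node_id`, `n`, one column per response
#'   variable; member row names in `attr(,"members")`.
#' @export
leaf_profiles <- function(tree) {
  leaves <- mrt_leaf_ids(tree)
  prof <- t(vapply(leaves, function(id)
    colMeans(tree$response[tree$nodes[[id]]$rows, , drop = FALSE]),
    numeric(ncol(tree$response))))
  colnames(prof) <- colnames(tree$response)
  out <- data.frame(group = seq_along(leaves), node_id = leaves,
                    n = vapply(leaves, function(id)
                      length(tree$nodes[[id]]$rows), integer(1)))
  out <- cbind(out, as.data.frame(prof))
  members <- lapply(leaves, function(id) {
    r <- tree$nodes[[id]]$rows
    if (!is.null(tree$row_names)) tree$row_names[r] else r
  })
  attr(out, "members") <- members
  out
}

#' Cross-validated tree size selection
#'
#' K-fold cross-validation of the relative error (held-out multivariate SS to
#' the assigned training leaf mean, divided by the total SS of the data) for
#' a set of candidate tree sizes, repeated over fold reshuffles. Reports the
#' minimum-error size and the 1-SE size (smallest size within one standard
#' error of the minimum).
#'
#' @param response,predictors,control as in [mrt()].
#' @param sizes candidate leaf counts.
#' @param folds number of folds (>= 2).
#' @param reps number of repeated shufflings.
#' @param seed RNG seed.
#' @param categorical column names to force categorical.
#' @return data frame `size`, `cv_error`, `se`, with attributes `size_min`
#'   and `size_1se`.
#' @export
mrt_cv <- function(response, predictors, sizes = 1:8, folds = 10, reps = 5,
                   seed = 1, control = mrt_control(), categorical = NULL) {
  if (folds < 2) stop("folds must be >= 2")
  Y <- response_matrix(response)
  n <- nrow(Y)
  folds <- min(folds, n)
  tot <- total_ss(Y)
  control$max_leaves <- max(sizes)
  full <- mrt(Y, predictors, control = control, categorical = categorical)
  achievable <- length(mrt_leaf_ids(full))
  skipped <- sizes[sizes > achievable]
  if (length(skipped))
    warning("size(s) beyond achievable leaf count skipped: ",
            paste(skipped, collapse = ", "))
  sizes <- sizes[sizes <= achievable]
  set.seed(seed)
  errs <- matrix(NA_real_, reps, length(sizes))
  for (r in seq_len(reps)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    sse <- numeric(length(sizes))
    for (k in seq_len(folds)) {
      tr <- which(fold_id != k); te <- which(fold_id == k)
      fit <- mrt(Y[tr, , drop = FALSE], predictors[tr, , drop = FALSE],
                 control = control, categorical = categorical)
      for (si in seq_along(sizes)) {
        s <- min(sizes[si], length(mrt_leaf_ids(fit)))
        pf <- prune_to_leaves(fit, s)
        grp <- predict(pf, predictors[te, , drop = FALSE], unseen = "majority")
        prof <- leaf_profiles(pf)
        mu <- as.matrix(prof[, colnames(Y), drop = FALSE])
        sse[si] <- sse[si] + sum((Y[te, , drop = FALSE] -
                                    mu[grp, , drop = FALSE])^2)
      }
    }
    errs[r, ] <- sse / tot
  }
  cv <- colMeans(errs)
  se <- if (reps > 1) apply(errs, 2, sd) / sqrt(reps)
        else rep(NA_real_, length(sizes))    # SE undefined from one rep
  out <- data.frame(size = sizes, cv_error = cv, se = se)
  imin <- which.min(cv)
  attr(out, "size_min") <- sizes[imin]
  attr(out, "size_1se") <- if (is.finite(se[imin]))
    sizes[min(which(cv <= cv[imin] + se[imin]))] else sizes[imin]
  out
}
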