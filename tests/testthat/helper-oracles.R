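# Independent oracles used across tests. These deliberately avoid the
# package's own split/SS code paths: everything is computed by direct
# enumeration or textbook linear algebra.

# Sum of squared distances to the centroid, computed naively.
oracle_ss <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) == 0) return(0)
  m <- colMeans(Y)
  sum(apply(Y, 1, function(r) sum((r - m)^2)))
}

# Brute-force best numeric split: try every midpoint, recompute both child
# SS from scratch.
oracle_numeric_split <- function(x, Y, min_leaf = 2) {
  Y <- as.matrix(Y)
  xs <- sort(unique(x))
  best <- NULL
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    left <- x < thr
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    red <- oracle_ss(Y) - oracle_ss(Y[left, , drop = FALSE]) -
      oracle_ss(Y[!left, , drop = FALSE])
    if (is.null(best) || red > best$ss_reduction + 1e-12)
      best <- list(threshold = thr, ss_reduction = red)
  }
  best
}

# Brute-force best categorical split over all binary level partitions.
oracle_categorical_split <- function(f, Y, min_leaf = 2) {
  Y <- as.matrix(Y)
  f <- as.character(f)
  lv <- sort(unique(f))
  m <- length(lv)
  best <- NULL
  for (mask in seq_len(2^(m - 1) - 1)) {
    in_left <- c(as.logical(bitwAnd(mask, 2^(seq_len(m - 1) - 1))), FALSE)
    left <- f %in% lv[in_left]
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    red <- oracle_ss(Y) - oracle_ss(Y[left, , drop = FALSE]) -
      oracle_ss(Y[!left, , drop = FALSE])
    if (is.null(best) || red > best$ss_reduction + 1e-12)
      best <- list(left_levels = lv[in_left], ss_reduction = red)
  }
  best
}

# Greedy best-first single-output SS regression tree, grown with the same
# admissibility rules but coded independently. Returns the ordered list of
# (node rows, predictor, threshold, reduction) and the final leaf membership.
oracle_uni_tree <- function(y, X, min_leaf = 2, min_frac = 0.01,
                            max_leaves = 16) {
  X <- as.data.frame(X)
  n <- length(y)
  tot <- oracle_ss(matrix(y))
  leaves <- list(seq_len(n))
  splits <- list()
  best_for <- function(rows) {
    bb <- NULL
    for (pn in names(X)) {
      cand <- oracle_numeric_split(X[[pn]][rows], matrix(y[rows]), min_leaf)
      if (!is.null(cand) &&
          (is.null(bb) || cand$ss_reduction > bb$ss_reduction + 1e-12))
        bb <- c(cand, predictor = pn)
    }
    bb
  }
  repeat {
    if (length(leaves) >= max_leaves) break
    cands <- lapply(leaves, best_for)
    ok <- which(!vapply(cands, is.null, logical(1)))
    ok <- ok[vapply(cands[ok], `[[`, numeric(1), "ss_reduction") >=
               min_frac * tot - 1e-12]
    if (!length(ok)) break
    reds <- vapply(cands[ok], `[[`, numeric(1), "ss_reduction")
    pick <- ok[which.max(reds)]
    sp <- cands[[pick]]
    rows <- leaves[[pick]]
    left <- rows[X[[sp$predictor]][rows] < sp$threshold]
    right <- setdiff(rows, left)
    splits[[length(splits) + 1]] <- sp
    leaves <- c(leaves[-pick], list(left), list(right))
  }
  list(splits = splits, leaves = leaves)
}

# Least-squares means for an additive two-way model, solved directly from
# the normal equations of the full dummy design (generalized inverse).
oracle_ls_means <- function(injury, population, treatment) {
  P <- factor(population); Tt <- factor(treatment)
  Xm <- cbind(1, stats::model.matrix(~ P - 1), stats::model.matrix(~ Tt - 1))
  b <- MASS::ginv(crossprod(Xm)) %*% crossprod(Xm, injury)
  np <- nlevels(P); nt <- nlevels(Tt)
  mu <- b[1]; alpha <- b[1 + seq_len(np)]; tau <- b[1 + np + seq_len(nt)]
  setNames(as.numeric(mu + alpha + mean(tau)), levels(P))
}

# Simple Rand-index-free agreement helper: fraction of populations whose
# planted group matches the modal tree group within the planted group,
# after best greedy matching of groups.
oracle_recovery_rate <- function(planted, assigned) {
  tab <- table(planted, assigned)
  matched <- 0
  used <- integer(0)
  for (g in order(-rowSums(tab))) {
    cand <- setdiff(order(-tab[g, ]), used)
    if (!length(cand)) next
    matched <- matched + tab[g, cand[1]]
    used <- c(used, cand[1])
  }
  matched / length(planted)
}
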