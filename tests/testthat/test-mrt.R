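test_that("total SS matches naive computation and its algebraic identity", {
  expect_equal(total_ss(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)), 2)
  expect_equal(total_ss(matrix(5, 4, 3)), 0)
  set.seed(1)
  Y <- matrix(rnorm(60), 12, 5)
  expect_equal(total_ss(Y), oracle_ss(Y), tolerance = 1e-12)
  expect_equal(total_ss(Y), sum(apply(Y, 2, function(x) sum((x - mean(x))^2))),
               tolerance = 1e-12)
})

test_that("numeric split search equals exhaustive enumeration on small fixtures", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(4:12, 1)
    Y <- matrix(rnorm(n * 3), n, 3)
    x <- round(rnorm(n), 1)          # duplicates likely
    got <- best_numeric_split(x, Y, min_leaf = 1)
    want <- oracle_numeric_split(x, Y, min_leaf = 1)
    if (is.null(want)) { expect_null(got); next }
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$ss_reduction, want$ss_reduction, tolerance = 1e-9)
  }
  # perfectly separated response: threshold between sign groups, reduction =
  # between-group SS
  Y <- rbind(matrix(0, 3, 2), matrix(4, 3, 2))
  x <- c(-3, -2, -1, 1, 2, 3)
  sp <- best_numeric_split(x, Y, min_leaf = 1)
  expect_equal(sp$threshold, 0)
  expect_equal(sp$ss_reduction, total_ss(Y))
  # constant response, single distinct value
  expect_equal(best_numeric_split(x, matrix(1, 6, 2), 1)$ss_reduction, 0)
  expect_null(best_numeric_split(rep(2, 6), Y, 1))
})

test_that("categorical split search equals exhaustive enumeration up to 6 levels", {
  for (s in 1:30) {
    set.seed(100 + s)
    m <- sample(2:6, 1)
    n <- m * 3
    f <- sample(letters[1:m], n, replace = TRUE)
    while (length(unique(f)) < m) f <- sample(letters[1:m], n, replace = TRUE)
    Y <- matrix(rnorm(n * 2), n, 2)
    got <- best_categorical_split(f, Y, min_leaf = 1)
    want <- oracle_categorical_split(f, Y, min_leaf = 1)
    expect_equal(got$ss_reduction, want$ss_reduction, tolerance = 1e-9)
  }
  # an outlying level is singled out
  f <- c("a", "a", "b", "b", "c", "c")
  Y <- rbind(matrix(0, 4, 2), matrix(5, 2, 2))
  sp <- best_categorical_split(f, Y, min_leaf = 1)
  expect_true(identical(sp$left_levels, c("a", "b")) ||
                identical(sp$left_levels, "c"))
  expect_equal(sp$ss_reduction, total_ss(Y))
  # two levels leave a single possible partition
  sp2 <- best_categorical_split(c("x", "x", "y"), matrix(1:6, 3, 2), 1)
  expect_equal(sp2$ss_reduction,
               oracle_categorical_split(c("x", "x", "y"),
                                        matrix(1:6, 3, 2), 1)$ss_reduction)
})

test_that("the ordered-levels heuristic usually finds the exhaustive optimum", {
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    m <- 8
    f <- rep(letters[1:m], each = 3)
    mu <- matrix(rnorm(m * 2, sd = 1.5), m, 2)
    Y <- mu[match(f, letters[1:m]), ] + matrix(rnorm(length(f) * 2, sd = 0.5),
                                               length(f), 2)
    heur <- best_categorical_split(f, Y, min_leaf = 1, max_exhaustive = 2)
    exact <- best_categorical_split(f, Y, min_leaf = 1, max_exhaustive = 12)
    if (abs(heur$ss_reduction - exact$ss_reduction) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("grown trees conserve SS at every split and accumulate R^2", {
  set.seed(7)
  n <- 40
  preds <- data.frame(MAT = rnorm(n), MAP = rnorm(n),
                      zone = sample(c("a", "b", "c"), n, replace = TRUE))
  Y <- matrix(rnorm(n * 5), n, 5)
  Y[preds$MAT > 0, ] <- Y[preds$MAT > 0, ] + 1.5
  tree <- mrt(Y, preds, control = mrt_control(max_leaves = 6,
                                              min_improvement_fraction = 0))
  for (id in tree$split_order) {
    nd <- tree$nodes[[id]]
    l <- tree$nodes[[nd$children[1]]]; r <- tree$nodes[[nd$children[2]]]
    expect_equal(nd$ss, l$ss + r$ss + nd$split$ss_reduction, tolerance = 1e-9)
    expect_gte(length(l$rows), tree$control$min_leaf)
    expect_gte(length(r$rows), tree$control$min_leaf)
  }
  # leaves partition the rows
  leaves <- genecol:::mrt_leaf_ids(tree)
  allrows <- sort(unlist(lapply(leaves, function(id) tree$nodes[[id]]$rows)))
  expect_equal(allrows, seq_len(n))
  # R^2 equals the summed split fractions and the SS bookkeeping closes
  leaf_ss <- sum(vapply(leaves, function(id) tree$nodes[[id]]$ss, numeric(1)))
  reds <- sum(vapply(tree$split_order, function(id)
    tree$nodes[[id]]$split$ss_reduction, numeric(1)))
  expect_equal(leaf_ss + reds, tree$total_ss, tolerance = 1e-9)
  expect_equal(tree$r_squared, reds / tree$total_ss, tolerance = 1e-12)
})

test_that("a univariate response reproduces the greedy single-output oracle tree", {
  for (s in 1:5) {
    set.seed(20 + s)
    n <- 30
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- 2 * (X$a > 0.3) - 1.5 * (X$b > 0) + rnorm(n, sd = 0.4)
    ctl <- mrt_control(min_leaf = 2, min_improvement_fraction = 0.01,
                       max_leaves = 5)
    tree <- mrt(matrix(y, n, 1), X, control = ctl)
    orc <- oracle_uni_tree(y, X, min_leaf = 2, min_frac = 0.01, max_leaves = 5)
    got <- lapply(tree$split_order, function(id) {
      sp <- tree$nodes[[id]]$split
      list(predictor = sp$predictor, threshold = sp$threshold,
           red = sp$ss_reduction)
    })
    expect_equal(length(got), length(orc$splits))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$predictor, orc$splits[[i]]$predictor)
      expect_equal(got[[i]]$threshold, orc$splits[[i]]$threshold)
      expect_equal(got[[i]]$red, orc$splits[[i]]$ss_reduction,
                   tolerance = 1e-9)
    }
  }
})

test_that("a planted two-group signal is recovered by a depth-1 tree", {
  set.seed(5)
  n <- 30
  grp <- rep(1:2, each = n / 2)
  Y <- matrix(rnorm(n * 5, sd = 0.3), n, 5) + outer(grp == 2, rep(2, 5))
  preds <- data.frame(MAT = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
                      junk = rnorm(n))
  tree <- mrt(Y, preds, control = mrt_control(max_leaves = 2))
  expect_equal(length(tree$split_order), 1)
  expect_equal(tree$nodes[[1]]$split$predictor, "MAT")
  expect_equal(predict(tree), grp)

  # max_leaves = 1 gives the trivial tree
  t1 <- mrt(Y, preds, control = mrt_control(max_leaves = 1))
  expect_equal(t1$r_squared, 0)
  expect_equal(length(genecol:::mrt_leaf_ids(t1)), 1)
})

test_that("pruning keeps the growth-order prefix and regrowing reproduces the tree", {
  set.seed(9)
  n <- 48
  preds <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  Y <- matrix(rnorm(n * 3), n, 3) + outer(preds$x1 > 0, c(2, 0, 1)) +
    outer(preds$x2 > 0.5, c(0, 1.5, 0))
  full <- mrt(Y, preds, control = mrt_control(max_leaves = 8,
                                              min_improvement_fraction = 0.001))
  k <- length(genecol:::mrt_leaf_ids(full))
  expect_identical(prune_to_leaves(full, k)$split_order, full$split_order)
  root <- prune_to_leaves(full, 1)
  expect_equal(root$r_squared, 0)
  expect_error(prune_to_leaves(full, k + 1), "n_leaves")

  p4 <- prune_to_leaves(full, 4)
  regrown <- mrt(Y, preds, control = mrt_control(max_leaves = 4,
                                                 min_improvement_fraction = 0.001))
  expect_equal(p4$split_order, regrown$split_order)
  expect_equal(p4$r_squared, regrown$r_squared, tolerance = 1e-12)
  # leaf membership identical
  lp <- leaf_profiles(p4); lr <- leaf_profiles(regrown)
  expect_equal(attr(lp, "members"), attr(lr, "members"))
})

test_that("leaf profiles average to zero under a centered response", {
  set.seed(11)
  n <- 36
  Y <- scale(matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("t", 1:4))),
             scale = FALSE)
  preds <- data.frame(x = rnorm(n))
  tree <- mrt(Y, preds, control = mrt_control(max_leaves = 4,
                                              min_improvement_fraction = 0))
  prof <- leaf_profiles(tree)
  w <- prof$n / sum(prof$n)
  pm <- as.matrix(prof[, colnames(Y)])
  expect_equal(unname(colSums(pm * w)), rep(0, 4), tolerance = 1e-9)
  # two equal halves give mirrored profiles
  Y2 <- rbind(matrix(1, 4, 2), matrix(-1, 4, 2))
  Y2 <- Y2 + matrix(rnorm(16, sd = 0.01), 8, 2)
  Y2 <- scale(Y2, scale = FALSE)
  colnames(Y2) <- c("t1", "t2")
  t2 <- mrt(Y2, data.frame(g = rep(c(0, 1), each = 4)),
            control = mrt_control(max_leaves = 2, min_leaf = 2))
  p2 <- leaf_profiles(t2)
  expect_equal(as.numeric(p2[1, colnames(Y2)]), -as.numeric(p2[2, colnames(Y2)]),
               tolerance = 1e-9)
})

test_that("five planted adaptation groups are recovered from synthetic trials", {
  hits <- numeric(20)
  for (s in 1:20) {
    g <- generate_origins(254, 5, seed = 300 + s, group_separation = 1)
    lay <- generate_design(g$origins, 4, 8, 90, seed = s)
    obs <- simulate_observations(lay, g$origins, g$truth, seed = 400 + s)
    nz <- impute_missing(normalize_trait_matrix(population_chamber_means(obs)))
    pooled <- pool_across_chambers(nz)
    preds <- g$origins[match(rownames(pooled$values), g$origins$seedlot_id),
                       c("MAT", "MWMT", "MCMT", "TD", "DD5", "DD0",
                         "MAP", "MSP")]
    tree <- mrt(pooled, preds, control = mrt_control(max_leaves = 5))
    assigned <- predict(tree)
    planted <- g$truth$group[rownames(pooled$values)]
    hits[s] <- oracle_recovery_rate(planted, assigned)
  }
  expect_gte(mean(hits), 0.9)
})

test_that("cross-validation flags pure noise and finds planted structure", {
  set.seed(13)
  n <- 60
  preds <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  Ynoise <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("t", 1:3)))
  cv <- mrt_cv(Ynoise, preds, sizes = 1:5, folds = 5, reps = 3, seed = 2,
               control = mrt_control(min_improvement_fraction = 0))
  above <- cv$cv_error[cv$size > 1] + 2 * cv$se[cv$size > 1]
  expect_true(all(above >= 1))

  # strong 4-group structure: the CV minimum lands at size 4 in >= 90% of seeds
  grp <- rep(1:4, each = n / 4)
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(n, c(-3, -1, 1, 3)[grp], 0.3)
    Ysig <- matrix(rnorm(n * 3, sd = 0.4), n, 3,
                   dimnames = list(NULL, paste0("t", 1:3))) +
      cbind(grp, -grp, grp %% 2) * 1.5
    cv2 <- mrt_cv(Ysig, data.frame(x = x), sizes = 1:6, folds = 5, reps = 3,
                  seed = s, control = mrt_control(min_improvement_fraction = 0))
    if (attr(cv2, "size_min") == 4) hits <- hits + 1
    if (s == 1) expect_lt(cv2$cv_error[cv2$size == 4], 0.3)
  }
  expect_gte(hits, 9)

  # leave-one-out runs and prefers structure over the root as well
  set.seed(4)
  x <- rnorm(n, c(-3, -1, 1, 3)[grp], 0.3)
  Ysig <- matrix(rnorm(n * 3, sd = 0.4), n, 3,
                 dimnames = list(NULL, paste0("t", 1:3))) +
    cbind(grp, -grp, grp %% 2) * 1.5
  cv3 <- mrt_cv(Ysig[1:20, ], data.frame(x = x[1:20]), sizes = c(1, 4),
                folds = 20, reps = 1, seed = 4,
                control = mrt_control(min_improvement_fraction = 0))
  expect_lt(cv3$cv_error[cv3$size == 4], cv3$cv_error[cv3$size == 1])
})
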