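#' @importFrom Matrix sparseMatrix crossprod Diagonal determinant solve t
NULL

TERM_LABELS <- c(P = "population", E = "environment", PE = "pop_x_env",
                 B = "block_in_env", L = "loc_in_block", e = "residual")

## Sparse indicator matrix for a factor (n x nlevels).
fac2ind <- function(f) {
  f <- droplevels(factor(f))
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)))
}

## Closures over the data for the REML deviance (-2 restricted
## log-likelihood, including constants) and its analytic gradient, as
## functions of the variance vector c(sigma2_terms..., sigma2_e). Uses the
## Woodbury identity V^{-1}x = (x - Z M^{-1} Z'x / s2e)/s2e with
## M = Z'Z/s2e + D^{-1}, so each evaluation costs one sparse Cholesky of the
## q x q random-effect cross-product. The gradient uses the standard trace
## identities d(-2lR)/d sigma2_k = tr(P Z_k Z_k') - y'P Z_k Z_k' P y with
## P the REML projection; it is exact, which matters because the criterion
## is extremely flat near the optimum.
reml_machinery <- function(y, Zlist) {
  n <- length(y)
  Z <- do.call(cbind, Zlist)
  qs <- vapply(Zlist, ncol, integer(1))
  blk <- rep(seq_along(Zlist), qs)
  ZtZ <- Matrix::crossprod(Z)
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  Zt1 <- as.numeric(Matrix::crossprod(Z, rep(1, n)))
  yty <- sum(y^2); ysum <- sum(y)
  scale_tol <- 1e-10 * (var(y) + 1e-300)

  decompose <- function(v) {
    v <- pmax(as.numeric(v), 0)
    K <- length(v) - 1
    s2e <- v[K + 1]
    if (s2e <= 0) return(NULL)
    keep <- which(v[seq_len(K)] > scale_tol)
    cols <- which(blk %in% keep)
    ch <- NULL; d <- numeric(0)
    if (length(cols)) {
      d <- rep(v[seq_len(K)], qs)[cols]
      M <- ZtZ[cols, cols, drop = FALSE] / s2e + Matrix::Diagonal(x = 1 / d)
      ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE),
                     error = function(e) NULL)
      if (is.null(ch)) return(NULL)
    }
    list(v = v, K = K, s2e = s2e, cols = cols, d = d, ch = ch)
  }

  ## inner products <a' V^{-1} b> from the Z-space images of a and b
  vinner <- function(st, ab, za, zb, Mzb) {
    if (!length(st$cols)) return(ab / st$s2e)
    (ab - sum(za * Mzb) / st$s2e) / st$s2e
  }

  dev <- function(v) {
    st <- decompose(v)
    if (is.null(st)) return(Inf)
    s2e <- st$s2e
    if (!length(st$cols)) {
      ldV <- n * log(s2e)
      My <- NULL; M1 <- NULL
    } else {
      ldM <- 2 * Matrix::determinant(st$ch, sqrt = TRUE)$modulus
      ldV <- n * log(s2e) + as.numeric(ldM) + sum(log(st$d))
      My <- as.numeric(Matrix::solve(st$ch, Zty[st$cols], system = "A"))
      M1 <- as.numeric(Matrix::solve(st$ch, Zt1[st$cols], system = "A"))
    }
    zy <- Zty[st$cols]; z1 <- Zt1[st$cols]
    XtWX <- vinner(st, n, z1, z1, M1)
    XtWy <- vinner(st, ysum, z1, zy, My)
    yWy <- vinner(st, yty, zy, zy, My)
    beta <- XtWy / XtWX
    quad <- yWy - 2 * beta * XtWy + beta^2 * XtWX
    as.numeric(ldV + log(XtWX) + quad + (n - 1) * log(2 * pi))
  }

  grad <- function(v) {
    st <- decompose(v)
    if (is.null(st)) return(rep(NA_real_, length(v)))
    s2e <- st$s2e; cols <- st$cols
    solveM <- function(b) {
      if (!length(cols)) return(b[integer(0)])
      as.numeric(Matrix::solve(st$ch, b, system = "A"))
    }
    My <- solveM(Zty[cols]); M1 <- solveM(Zt1[cols])
    zy <- Zty[cols]; z1 <- Zt1[cols]
    alpha <- vinner(st, n, z1, z1, M1)          # 1' V^{-1} 1
    betaN <- vinner(st, ysum, z1, zy, My)       # 1' V^{-1} y
    bhat <- betaN / alpha
    # Z-space images of V^{-1}y and V^{-1}1, then of Py
    zVy <- (Zty - if (length(cols)) as.numeric(ZtZ[, cols] %*% My) / s2e
            else 0) / s2e
    zV1 <- (Zt1 - if (length(cols)) as.numeric(ZtZ[, cols] %*% M1) / s2e
            else 0) / s2e
    zPy <- zVy - bhat * zV1
    # n-space inner products of V^{-1}a with V^{-1}b
    nsp <- function(ab, za, zb, Mza, Mzb) {
      if (!length(cols)) return(ab / s2e^2)
      (ab - sum(za * Mzb) / s2e - sum(zb * Mza) / s2e +
         sum(Mza * as.numeric(ZtZ[cols, cols] %*% Mzb)) / s2e^2) / s2e^2
    }
    Vy_Vy <- nsp(yty, zy, zy, My, My)
    Vy_V1 <- nsp(ysum, zy, z1, My, M1)
    V1_V1 <- nsp(n, z1, z1, M1, M1)
    Py_Py <- Vy_Vy - 2 * bhat * Vy_V1 + bhat^2 * V1_V1

    g <- numeric(st$K + 1)
    for (k in seq_len(st$K)) {
      kr <- which(blk == k)
      # tr(Z_k' V^{-1} Z_k) = (n - tr(S' M^{-1} S)/s2e)/s2e, S = Z'Z_k
      if (length(cols)) {
        S <- ZtZ[cols, kr, drop = FALSE]
        trMS <- sum(S * Matrix::solve(st$ch, S, system = "A"))
        trV <- (n - trMS / s2e) / s2e
      } else trV <- n / s2e
      trP <- trV - sum(zV1[kr]^2) / alpha
      g[k] <- trP - sum(zPy[kr]^2)
    }
    # residual direction: Q = I
    if (length(cols)) {
      A <- ZtZ[cols, cols, drop = FALSE]
      trMA <- sum(Matrix::diag(Matrix::solve(st$ch, A, system = "A")))
      trVinv <- (n - trMA / s2e) / s2e
    } else trVinv <- n / s2e
    trPee <- trVinv - V1_V1 / alpha
    g[st$K + 1] <- trPee - Py_Py
    g
  }

  list(dev = dev, grad = grad)
}

reml_deviance_function <- function(y, Zlist) reml_machinery(y, Zlist)$dev

## Central-difference Hessian with scale-aware steps. The REML deviance is
## nearly quadratic but each evaluation carries sparse-Cholesky rounding
## noise, so steps must be large enough that the deviance change dominates
## the noise; steps are kept inside the nonnegativity boundary.
num_hessian <- function(f, x, rel = 0.05) {
  p <- length(x)
  h <- pmax(rel * abs(x), 1e-4 * (sum(abs(x)) + 1e-300))
  x <- pmax(x, h)                      # keep x - h inside the boundary
  f0 <- f(x)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' REML variance decomposition of a common-garden trait
#'
#' Fits the all-random nested model
#' \deqn{Y = \mu + P_i + E_j + (P \times E)_{ij} + B(E)_{jk} + L(B)_{kl} + e}
#' by REML (via \pkg{lme4}, followed by a bounded quasi-Newton polish of the
#' restricted likelihood) and reports each component with a standard error
#' from the inverse curvature (observed information) of the profiled REML
#' likelihood, the asymptotic Wald convention. The among-population
#' differentiation \eqn{V_{pop} = \sigma^2_P/(\sigma^2_P+\sigma^2_e)} and its
#' propagated standard error are attached.
#'
#' Terms with fewer than two levels are dropped with a warning. The
#' location-in-block term is dropped (with a warning) when no location has
#' replicate observations, since it is then confounded with the residual.
#' Components estimated at the zero boundary are flagged `pinned`; their
#' standard errors are still computed from the information matrix, evaluated
#' just inside the boundary.
#'
#' @param data observation data frame.
#' @param trait name of the trait column to analyse.
#' @param population,environment,block,location names of the design columns;
#'   defaults match [simulate_observations()] output. Set `location = NULL`
#'   to omit the term.
#' @param se compute standard errors (numerical Hessian; skip to speed up
#'   simulation loops).
#' @param polish run the quasi-Newton refinement after the \pkg{lme4} fit.
#' @return object of class `"variance_decomposition"`: list with `trait`,
#'   `components` (term, sigma2, se, percent, percent_se, pinned, dropped),
#'   `vpop`, `vpop_se`, `n_obs`, `reml_criterion`.
#' @export
fit_reml <- function(data, trait,
                     population = "seedlot_id", environment = "chamber_id",
                     block = "block_id", location = "position",
                     se = TRUE, polish = TRUE) {
  stopifnot(trait %in% names(data), population %in% names(data))
  y <- data[[trait]]
  if (anyNA(y)) { data <- data[!is.na(y), , drop = FALSE]; y <- data[[trait]] }
  n <- length(y)
  if (n < 2) stop("need at least 2 observations")

  pop <- factor(data[[population]])
  env <- if (!is.null(environment) && environment %in% names(data))
    factor(data[[environment]]) else factor(rep("E1", n))
  blk <- if (!is.null(block) && block %in% names(data))
    factor(paste(env, data[[block]], sep = ":")) else NULL
  loc <- if (!is.null(location) && location %in% names(data) && !is.null(blk))
    factor(paste(blk, data[[location]], sep = ":")) else NULL

  has_env <- !is.null(environment) && environment %in% names(data)
  has_blk <- has_env && !is.null(blk)
  has_loc <- has_blk && !is.null(loc)
  terms <- list()
  dropped <- character(0)
  add_term <- function(code, f, ok, why, requested = TRUE) {
    if (ok) terms[[code]] <<- f
    else if (requested) dropped <<- c(dropped, setNames(why, code))
  }
  add_term("P", pop, nlevels(pop) >= 2, "fewer than 2 population levels")
  add_term("E", env, nlevels(env) >= 2, "fewer than 2 environment levels",
           has_env)
  pe <- factor(paste(pop, env, sep = ":"))
  add_term("PE", pe, nlevels(pop) >= 2 && nlevels(env) >= 2,
           "requires 2+ populations and environments", has_env)
  add_term("B", blk, !is.null(blk) && nlevels(blk) > nlevels(env),
           "no block structure within environments", has_blk)
  loc_ok <- !is.null(loc) && nlevels(loc) >= 2 && nlevels(loc) < n &&
    max(table(loc)) >= 2
  add_term("L", loc, loc_ok,
           "no replicate observations per location (confounded with residual)",
           has_loc)
  for (code in names(dropped))
    warning(sprintf("dropping %s term: %s", TERM_LABELS[[code]],
                    dropped[[code]]), call. = FALSE)

  all_zero <- var(y) < 1e-12
  K <- length(terms)
  if (all_zero || K == 0) {
    est <- setNames(rep(0, K + 1), c(names(terms), "e"))
    if (!all_zero) est[["e"]] <- var(y)
    sevec <- setNames(rep(NA_real_, K + 1), names(est))
    pinned <- est[seq_len(K)] <= 0
    crit <- NA_real_
  } else {
    df <- data.frame(y = y)
    for (code in names(terms)) df[[code]] <- terms[[code]]
    form <- as.formula(paste(
      "y ~ 1 +", paste(sprintf("(1 | %s)", names(terms)), collapse = " + ")))
    fit <- lme4::lmer(form, data = df, REML = TRUE,
                      control = lme4::lmerControl(
                        calc.derivs = FALSE,
                        check.conv.singular = "ignore",
                        optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-12,
                                       maxeval = 5000)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    est <- setNames(numeric(K + 1), c(names(terms), "e"))
    for (code in names(terms))
      est[[code]] <- vc$vcov[match(code, vc$grp)]
    est[["e"]] <- vc$vcov[vc$grp == "Residual"]

    mach <- reml_machinery(y, lapply(terms, fac2ind))
    dev <- mach$dev
    if (polish) {
      lower <- c(rep(0, K), 1e-8 * var(y))
      sc <- pmax(est, sum(est) / 20)
      op <- tryCatch(
        optim(est, dev, gr = mach$grad, method = "L-BFGS-B", lower = lower,
              control = list(maxit = 200, parscale = sc, factr = 1e2)),
        error = function(e) NULL)
      # accept the polished point only if it does not worsen the criterion
      # and has the smaller projected gradient norm: the surface is extremely
      # flat near the optimum, so the gradient is the sharper yardstick
      if (!is.null(op) && is.finite(op$value) && op$value <= dev(est) + 1e-9) {
        pgn <- function(v) {
          g <- mach$grad(v)
          g[v <= 0 & g > 0] <- 0
          sqrt(sum(g^2))
        }
        if (isTRUE(pgn(pmax(op$par, 0)) < pgn(est))) est <- pmax(op$par, 0)
      }
    }
    crit <- dev(est)
    total <- sum(est)
    pinned <- est[seq_len(K)] < 1e-8 * total
    sevec <- setNames(rep(NA_real_, K + 1), names(est))
    if (se) {
      at <- pmax(est, 1e-6 * total)
      H <- num_hessian(dev, at)
      V <- tryCatch(2 * solve(H), error = function(e) 2 * MASS::ginv(H))
      dg <- diag(V)
      sevec[] <- sqrt(pmax(dg, 0))
      sevec[dg < 0] <- NA_real_
    }
  }

  codes <- names(GENECOL_VARIANCE_DEFAULTS$spruce$height)  # P E PE B L e order
  comp <- data.frame(
    term = unname(TERM_LABELS[codes]),
    sigma2 = NA_real_, se = NA_real_,
    pinned = FALSE, dropped = !codes %in% c(names(est), "e"),
    stringsAsFactors = FALSE
  )
  rownames(comp) <- codes
  for (code in names(est)) {
    comp[code, "sigma2"] <- est[[code]]
    comp[code, "se"] <- sevec[[code]]
    if (code != "e") comp[code, "pinned"] <- isTRUE(pinned[[code]])
  }
  tot <- sum(comp$sigma2, na.rm = TRUE)
  comp$percent <- if (tot > 0) 100 * comp$sigma2 / tot else NA_real_
  comp$percent_se <- if (tot > 0) 100 * comp$se / tot else NA_real_

  s2p <- comp["P", "sigma2"]; s2e <- comp["e", "sigma2"]
  vp <- if (!is.na(s2p) && !is.na(s2e) && (s2p + s2e) > 0) vpop(s2p, s2e)
        else NA_real_
  vp_se <- if (!is.na(vp) && vp > 0 &&
               !is.na(comp["P", "se"]) && !is.na(comp["e", "se"]))
    vpop_se(s2p, comp["P", "se"], s2e, comp["e", "se"]) else NA_real_

  structure(list(trait = trait, components = comp, vpop = vp, vpop_se = vp_se,
                 n_obs = n, reml_criterion = crit),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Variance decomposition for '%s' (n = %d)\n", x$trait, x$n_obs))
  comp <- x$components
  comp$sigma2 <- round(comp$sigma2, 3)
  comp$se <- round(comp$se, 3)
  comp$percent <- round(comp$percent, 1)
  comp$percent_se <- round(comp$percent_se, 1)
  print(comp, row.names = FALSE)
  if (!is.na(x$vpop))
    cat(sprintf("V_pop = %.3f (SE %.3f)\n", x$vpop,
                ifelse(is.na(x$vpop_se), NA, x$vpop_se)))
  invisible(x)
}

#' Express variance components as percentages of the total
#'
#' Each component is rescaled to `100 * sigma2 / sum(sigma2)`; standard
#' errors are divided by the same total (the total is treated as fixed, the
#' convention used when variance tables are printed on the percent scale).
#'
#' @param decomp a `"variance_decomposition"` object, or a non-negative
#'   numeric vector of components.
#' @return the same object with `percent` / `percent_se` filled, or the
#'   percent vector.
#' @export
percent_components <- function(decomp) {
  if (is.numeric(decomp)) {
    if (any(decomp < 0)) stop("components must be >= 0")
    tot <- sum(decomp)
    if (tot <= 0) stop("all components are zero")
    return(100 * decomp / tot)
  }
  stopifnot(inherits(decomp, "variance_decomposition"))
  tot <- sum(decomp$components$sigma2, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) stop("all components are zero")
  decomp$components$percent <- 100 * decomp$components$sigma2 / tot
  decomp$components$percent_se <- 100 * decomp$components$se / tot
  decomp
}

#' Among-population differentiation V_pop
#'
#' \eqn{V_{pop} = \sigma^2_P / (\sigma^2_P + \sigma^2_e)}: the proportion of
#' phenotypic variance among populations, a downward-biased proxy for
#' \eqn{Q_{ST}} (the denominator uses the residual variance rather than twice
#' the additive variance).
#'
#' @param sigma_P2 among-population variance component (>= 0).
#' @param sigma_e2 residual variance component (>= 0).
#' @return proportion in \[0, 1\].
#' @export
vpop <- function(sigma_P2, sigma_e2) {
  if (any(sigma_P2 < 0) || any(sigma_e2 < 0))
    stop("variance components must be >= 0")
  if (any(sigma_P2 + sigma_e2 == 0))
    stop("sigma_P2 and sigma_e2 cannot both be zero")
  sigma_P2 / (sigma_P2 + sigma_e2)
}

#' Propagated standard error of V_pop
#'
#' Applies the standard error-propagation rules for a sum (denominator) and a
#' ratio:
#' \deqn{SE_{P+e} = \sqrt{SE_P^2 + SE_e^2}}
#' \deqn{SE_{V_{pop}} = V_{pop} \sqrt{ (SE_P/\sigma^2_P)^2 +
#'   (SE_{P+e}/(\sigma^2_P+\sigma^2_e))^2 }}
#'
#' @param sigma_P2,sigma_e2 variance components.
#' @param SE_P standard error of the population component.
#' @param SE_E standard error of the residual component.
#' @return standard error of \eqn{V_{pop}} (proportion scale).
#' @export
vpop_se <- function(sigma_P2, SE_P, sigma_e2, SE_E) {
  if (any(c(sigma_P2, SE_P, sigma_e2, SE_E) < 0))
    stop("all inputs must be >= 0")
  if (any(sigma_P2 == 0))
    stop("sigma_P2 must be positive for the ratio propagation")
  v <- vpop(sigma_P2, sigma_e2)
  se_sum <- sqrt(SE_P^2 + SE_E^2)
  v * sqrt((SE_P / sigma_P2)^2 + (se_sum / (sigma_P2 + sigma_e2))^2)
}

#' Method-of-moments variance components for balanced layouts
#'
#' Expected-mean-squares estimator for a balanced one-way layout
#' (population + residual) or a balanced crossed two-way layout
#' (population, environment, interaction, residual). Serves as an independent
#' closed-form cross-check of [fit_reml()] on balanced data.
#'
#' @param data observation data frame.
#' @param trait trait column name.
#' @param population,environment design column names (`environment` ignored
#'   when absent or single-level).
#' @return named vector of components (`P`, `e`, and for the two-way layout
#'   `E` and `PE`), negative solutions pinned at 0.
#' @export
anova_components <- function(data, trait,
                             population = "seedlot_id",
                             environment = "chamber_id") {
  y <- data[[trait]]
  pop <- factor(data[[population]])
  env <- if (environment %in% names(data)) factor(data[[environment]])
         else factor(rep("E1", length(y)))
  if (nlevels(env) < 2) {
    cnt <- table(pop)
    if (length(unique(cnt)) != 1)
      stop("unbalanced data: equal replication per population required")
    r <- unname(cnt[1]); a <- nlevels(pop)
    ms <- summary(aov(y ~ pop))[[1]][, "Mean Sq"]
    s2e <- ms[2]
    c(P = max(0, (ms[1] - ms[2]) / r), e = s2e)
  } else {
    cnt <- table(pop, env)
    if (length(unique(as.vector(cnt))) != 1)
      stop("unbalanced data: equal replication per cell required")
    r <- unname(cnt[1, 1]); a <- nlevels(pop); b <- nlevels(env)
    if (r < 2) stop("need replicate observations within cells")
    sm <- summary(aov(y ~ pop * env))[[1]]
    ms <- setNames(sm[, "Mean Sq"], trimws(rownames(sm)))
    mse <- ms[["Residuals"]]
    mspe <- ms[["pop:env"]]
    c(P = max(0, (ms[["pop"]] - mspe) / (b * r)),
      E = max(0, (ms[["env"]] - mspe) / (a * r)),
      PE = max(0, (mspe - mse) / r),
      e = mse)
  }
}
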