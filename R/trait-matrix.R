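#' Population-by-chamber trait means
#'
#' Arithmetic mean of each trait per population and chamber, with cell
#' counts. Cells with no observations are absent from the long table and
#' become missing entries in the matrix representation.
#'
#' @param observations seedling observation data frame (e.g. from
#'   [simulate_observations()], possibly with `cold_injury` replaced by the
#'   LS-mean summary of [cold_hardiness_summary()]).
#' @param traits trait column names to summarize.
#' @return long data frame: `seedlot_id`, `chamber_id`, `trait`, `mean`, `n`.
#' @export
population_chamber_means <- function(observations, traits = GENECOL_TRAITS) {
  traits <- intersect(traits, names(observations))
  if (!length(traits)) stop("none of the requested traits are present")
  out <- lapply(traits, function(tr) {
    d <- observations[!is.na(observations[[tr]]), c("seedlot_id", "chamber_id", tr)]
    if (!nrow(d)) return(NULL)
    ag <- aggregate(d[[tr]], list(seedlot_id = d$seedlot_id,
                                  chamber_id = d$chamber_id), mean)
    cn <- aggregate(d[[tr]], list(seedlot_id = d$seedlot_id,
                                  chamber_id = d$chamber_id), length)
    data.frame(seedlot_id = ag$seedlot_id, chamber_id = ag$chamber_id,
               trait = tr, mean = ag$x, n = cn$x, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$trait, traits), res$chamber_id, res$seedlot_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble a population x (trait, chamber) matrix
#'
#' @param means long table from [population_chamber_means()], or a numeric
#'   matrix with populations in rows (taken as-is).
#' @return object of class `"trait_matrix"`: list with `values` (matrix,
#'   rows = populations, columns named `trait.chamber`), `missing` and
#'   `imputed` logical masks, and the `traits` / `chambers` involved.
#' @export
trait_matrix <- function(means) {
  if (is.matrix(means)) {
    vals <- means
    if (is.null(rownames(vals))) rownames(vals) <- seq_len(nrow(vals))
    tm <- list(values = vals, missing = is.na(vals),
               imputed = array(FALSE, dim(vals), dimnames(vals)),
               traits = colnames(vals), chambers = NULL)
    class(tm) <- "trait_matrix"
    return(tm)
  }
  stopifnot(all(c("seedlot_id", "chamber_id", "trait", "mean") %in% names(means)))
  pops <- sort(unique(means$seedlot_id))
  traits <- unique(means$trait)
  chambers <- sort(unique(means$chamber_id))
  cols <- as.vector(t(outer(traits, chambers, paste, sep = ".")))
  vals <- matrix(NA_real_, length(pops), length(cols),
                 dimnames = list(pops, cols))
  idx <- cbind(match(means$seedlot_id, pops),
               match(paste(means$trait, means$chamber_id, sep = "."), cols))
  vals[idx] <- means$mean
  tm <- list(values = vals, missing = is.na(vals),
             imputed = array(FALSE, dim(vals), dimnames(vals)),
             traits = traits, chambers = chambers)
  class(tm) <- "trait_matrix"
  tm
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d populations x %d columns (%d missing, %d imputed)\n",
              nrow(x$values), ncol(x$values), sum(x$missing & !x$imputed),
              sum(x$imputed)))
  invisible(x)
}

#' Normalize trait means to standard-deviation units per chamber
#'
#' Each trait-by-chamber column is expressed in units of standard deviations
#' from the overall chamber mean, computed over the non-missing population
#' means with the sample (n-1) convention. Idempotent: normalizing an
#' already-standardized matrix leaves it unchanged.
#'
#' @param x a `"trait_matrix"` (or a long means table, which is assembled
#'   first).
#' @return normalized `"trait_matrix"`.
#' @export
normalize_trait_matrix <- function(x) {
  if (!inherits(x, "trait_matrix")) x <- trait_matrix(x)
  v <- x$values
  for (j in seq_len(ncol(v))) {
    obs <- !is.na(v[, j])
    if (sum(obs) < 2)
      stop("column '", colnames(v)[j], "' has fewer than 2 observed values")
    s <- sd(v[obs, j])
    if (s <= 0)
      stop("column '", colnames(v)[j], "' has zero standard deviation")
    v[, j] <- (v[, j] - mean(v[obs, j])) / s
  }
  x$values <- v
  x
}

#' Impute missing cells by k nearest rows
#'
#' Fills each missing cell with the mean of that column over the `k` nearest
#' populations, where distance is the root mean squared difference over the
#' columns both rows have observed, and only neighbours with the target
#' column observed are used. Observed cells are never changed.
#'
#' @param x a `"trait_matrix"`, typically normalized.
#' @param k number of neighbours (default 5).
#' @param method `"knn"` or `"column_mean"` (fallback: fill with the column
#'   mean of observed entries).
#' @return `"trait_matrix"` with no missing entries and `imputed` mask set.
#' @export
impute_missing <- function(x, k = 5, method = c("knn", "column_mean")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "trait_matrix"), k >= 1)
  v <- x$values
  miss <- is.na(v)
  if (!any(miss)) return(x)
  empty <- rownames(v)[rowSums(!miss) == 0]
  if (length(empty))
    stop("row(s) with no observed values: ", paste(empty, collapse = ", "))
  if (method == "column_mean") {
    for (j in which(colSums(miss) > 0))
      v[miss[, j], j] <- mean(v[!miss[, j], j])
  } else {
    obs <- !miss
    for (i in which(rowSums(miss) > 0)) {
      shared <- obs & rep(obs[i, ], each = nrow(v))
      dim(shared) <- dim(v)
      diff2 <- sweep(v, 2, v[i, ], "-")^2
      diff2[!shared] <- NA
      nshared <- rowSums(shared)
      d <- sqrt(rowMeans(diff2, na.rm = TRUE))
      d[i] <- Inf
      d[nshared == 0] <- Inf
      for (j in which(miss[i, ])) {
        cand <- which(obs[, j] & is.finite(d))
        if (!length(cand)) { v[i, j] <- mean(v[obs[, j], j]); next }
        nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
        v[i, j] <- mean(v[nb, j])
      }
    }
  }
  x$values <- v
  x$imputed <- x$imputed | miss
  x
}

#' Pool chamber-specific normalized means across chambers
#'
#' For every population and trait, averages the chamber-specific normalized
#' values, then re-standardizes each pooled trait column. Used when
#' population-by-environment interaction is weak, giving the default
#' 5-column response for the regression tree.
#'
#' @param x a complete (imputed) `"trait_matrix"` with `trait.chamber`
#'   columns.
#' @return `"trait_matrix"` with one column per trait.
#' @export
pool_across_chambers <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  if (any(is.na(x$values))) stop("matrix must be complete; impute first")
  if (is.null(x$chambers)) return(x)
  pooled <- sapply(x$traits, function(tr) {
    cols <- paste(tr, x$chambers, sep = ".")
    cols <- intersect(cols, colnames(x$values))
    rowMeans(x$values[, cols, drop = FALSE])
  })
  dimnames(pooled) <- list(rownames(x$values), x$traits)
  out <- trait_matrix(pooled)
  out$chambers <- NULL
  normalize_trait_matrix(out)
}
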