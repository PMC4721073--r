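#' Index of injury from electrolyte-leakage conductances
#'
#' Computes the freeze-injury index
#' \deqn{I_t = 100 (R_t - R_0) / (1 - R_0), \quad R_t = L_t/L_k,\; R_0 = L_0/L_d}
#' where \eqn{L_t} is the conductance of leachate from a sample after
#' freezing, \eqn{L_k} after heat kill of that sample, and \eqn{L_0},
#' \eqn{L_d} the same pair for the unfrozen control of the measurement batch.
#'
#' @param samples data frame with columns `Lt`, `Lk`, a `batch_id` linking to
#'   the control table, and optionally `sample_id` and grouping columns
#'   (`seedlot_id`, `chamber_id`, `test_temperature`) which are carried
#'   through.
#' @param controls data frame with columns `batch_id`, `L0`, `Ld` (one row
#'   per batch).
#' @param clamp if `TRUE` (default), the injury index is limited to
#'   \[0, 100\]; the raw value is always retained in `injury_raw`. Negative
#'   raw values can arise from noisy controls.
#' @return the `samples` data frame with columns `Rt`, `R0`, `injury_raw`
#'   and `injury` appended.
#' @export
injury_index <- function(samples, controls, clamp = TRUE) {
  stopifnot(all(c("Lt", "Lk", "batch_id") %in% names(samples)),
            all(c("batch_id", "L0", "Ld") %in% names(controls)))
  if (anyDuplicated(controls$batch_id))
    stop("duplicate control rows for batch(es): ",
         paste(unique(controls$batch_id[duplicated(controls$batch_id)]),
               collapse = ", "))
  m <- match(samples$batch_id, controls$batch_id)
  if (anyNA(m))
    stop("no control for batch(es): ",
         paste(unique(samples$batch_id[is.na(m)]), collapse = ", "))
  L0 <- controls$L0[m]; Ld <- controls$Ld[m]
  if (any(Ld <= L0) || any(L0 <= 0))
    stop("degenerate control: need 0 < L0 < Ld in every batch")
  if (any(samples$Lk <= 0)) stop("heat-kill conductance Lk must be positive")
  if (any(samples$Lt <= 0) || any(samples$Lt > samples$Lk + 1e-9))
    stop("need 0 < Lt <= Lk for every sample")
  Rt <- samples$Lt / samples$Lk
  R0 <- L0 / Ld
  raw <- 100 * (Rt - R0) / (1 - R0)
  out <- samples
  out$Rt <- Rt
  out$R0 <- R0
  out$injury_raw <- raw
  out$injury <- if (clamp) pmin(pmax(raw, 0), 100) else raw
  out
}

#' Select the informative pair of freeze-test temperatures
#'
#' Cold-hardiness summaries use the two freeze treatments with mean injury
#' nearest 50% across populations, which maximizes differentiation among
#' populations. Ties are broken toward the colder temperature.
#'
#' @param injury injury table from [injury_index()] with `seedlot_id` and
#'   `test_temperature` columns.
#' @return list with `temperatures` (length-2 numeric, warmer first) and
#'   `means` (named mean injury per available temperature).
#' @export
select_test_temperatures <- function(injury) {
  stopifnot(all(c("seedlot_id", "test_temperature", "injury") %in% names(injury)))
  pop_means <- aggregate(injury ~ seedlot_id + test_temperature, injury, mean)
  tmeans <- tapply(pop_means$injury, pop_means$test_temperature, mean)
  temps <- as.numeric(names(tmeans))
  if (length(temps) < 2)
    stop("at least two distinct test temperatures required")
  ord <- order(abs(tmeans - 50), temps)     # nearest 50%, ties to colder
  sel <- temps[ord[1:2]]
  list(temperatures = sort(sel, decreasing = TRUE),
       means = setNames(as.numeric(tmeans), names(tmeans)))
}

#' Population cold-hardiness least-squares means
#'
#' Summarizes the two selected freeze treatments into one frost-hardiness
#' value per population and chamber by fitting, per chamber, an additive
#' fixed-effects model `injury ~ population + treatment` by least squares and
#' extracting each population's adjusted (LS) mean. With balanced data this
#' equals the simple mean over the two treatments; with a treatment missing
#' for a population it adds the grand treatment contrast instead.
#'
#' @param injury injury table from [injury_index()] with `seedlot_id`,
#'   `chamber_id` and `test_temperature` columns.
#' @param selected length-2 numeric vector of test temperatures (e.g. from
#'   [select_test_temperatures()]`$temperatures`).
#' @return data frame `seedlot_id`, `chamber_id`, `cold_injury` (LS mean).
#'   Populations observed in neither selected treatment within a chamber are
#'   excluded with a message.
#' @export
cold_hardiness_summary <- function(injury, selected) {
  stopifnot(length(selected) == 2)
  d <- injury[injury$test_temperature %in% selected, , drop = FALSE]
  if (!nrow(d)) stop("no observations at the selected temperatures")
  dropped <- setdiff(unique(injury$seedlot_id), unique(d$seedlot_id))
  if (length(dropped))
    message("excluding population(s) with no data at selected temperatures: ",
            paste(dropped, collapse = ", "))
  out <- lapply(split(d, d$chamber_id), function(dc) {
    dc$population <- factor(dc$seedlot_id)
    dc$treatment <- factor(dc$test_temperature)
    if (nlevels(dc$treatment) == 1 || nlevels(dc$population) == 1) {
      ls <- tapply(dc$injury, dc$population, mean)
      return(data.frame(seedlot_id = names(ls),
                        chamber_id = dc$chamber_id[1],
                        cold_injury = as.numeric(ls),
                        stringsAsFactors = FALSE))
    }
    fit <- lm(injury ~ population + treatment, data = dc)
    em <- as.data.frame(emmeans::emmeans(fit, "population"))
    data.frame(seedlot_id = as.character(em$population),
               chamber_id = dc$chamber_id[1],
               cold_injury = em$emmean,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
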