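#' Generate seedlot origins with grouped climate structure
#'
#' Draws `n_seedlots` seed-source records whose eight climate normals follow
#' group-specific multivariate distributions along a boreal-to-valley gradient,
#' with ecosystem variants nested in ecozones nested in the planted groups.
#' Climate invariants hold by construction: `MCMT <= MAT <= MWMT`,
#' `TD = MWMT - MCMT`, `0 <= MSP <= MAP`, and non-negative degree-days.
#'
#' The second return element is the simulation truth used by
#' [simulate_observations()]: per-trait variance magnitudes for the six
#' random terms of the nested common-garden model, the planted group
#' membership of every seedlot, and the structured (climate-driven) part of
#' each seedlot's population effect. The structured part is a group trait
#' profile plus a within-group slope on MAT, rescaled so that the planted
#' among-population variance equals `sigma2[["P"]]` for every trait:
#' a fraction `between_frac` lies between groups, `slope_frac` on the MAT
#' slope, and the remainder is drawn independently per simulation.
#'
#' @param n_seedlots number of seedlots to generate (default 254, the size of
#'   an interior spruce provenance collection).
#' @param n_groups number of planted adaptation groups (default 5: boreal,
#'   montane, sub-boreal, interior valley, maritime archetypes).
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @param species `"spruce"` or `"pine"`; selects the default per-trait
#'   variance magnitudes.
#' @param group_separation multiplier on the spread of group climate centers
#'   (1 = a realistic provincial gradient; larger values give cleanly
#'   separable groups).
#' @param sigma2 optional named list (per trait) of variance magnitudes
#'   `c(P, E, PE, B, L, e)` overriding the species defaults.
#' @param between_frac,slope_frac fractions of the population variance
#'   attributed to the group profile and the within-group MAT slope.
#' @return list with `origins` (data frame, one row per seedlot) and `truth`
#'   (list: `seed`, `species`, `group`, `sigma2`, `trait_means`,
#'   `pop_struct`, `group_profiles`, `between_frac`, `slope_frac`).
#' @export
generate_origins <- function(n_seedlots = 254, n_groups = 5, seed = 1,
                             species = c("spruce", "pine"),
                             group_separation = 1,
                             sigma2 = NULL,
                             between_frac = 0.85, slope_frac = 0.05) {
  species <- match.arg(species)
  if (!is.numeric(n_seedlots) || n_seedlots < 1)
    stop("`n_seedlots` must be a positive count")
  if (!is.numeric(n_groups) || n_groups < 1)
    stop("`n_groups` must be a positive count")
  if (n_seedlots < n_groups)
    stop("`n_seedlots` must be at least `n_groups`")
  if (between_frac + slope_frac > 1)
    stop("`between_frac` + `slope_frac` must not exceed 1")
  n <- as.integer(n_seedlots); g <- as.integer(n_groups)
  set.seed(seed)

  ## group climate centers along a cold-continental -> warm-valley gradient
  u <- if (g == 1) 0 else seq(-1, 1, length.out = g)
  mat_c  <- 3 + 4 * group_separation * u            # mean annual temperature
  dwarm  <- 12 - 2 * u + rnorm(g, 0, 0.5)           # MWMT - MAT offset
  dcold  <- 14 - 6 * u + rnorm(g, 0, 0.8)           # MAT - MCMT offset
  dwarm  <- pmax(dwarm, 2); dcold <- pmax(dcold, 2)
  map_c  <- exp(6.2 + 0.35 * sin(2.5 * u) + rnorm(g, 0, 0.1))  # ~ 400-900 mm
  elev_c <- 700 + 500 * (seq_len(g) %% 2) + rnorm(g, 0, 100)
  lat_c  <- 54 - 4 * u
  lon_c  <- -120 + 3 * u

  group <- sort(rep_len(seq_len(g), n))
  mat  <- rnorm(n, mat_c[group], 0.7 * sqrt(group_separation))
  dw   <- pmax(rnorm(n, dwarm[group], 0.8), 0.5)
  dc   <- pmax(rnorm(n, dcold[group], 1.2), 0.5)
  mwmt <- mat + dw
  mcmt <- mat - dc
  td   <- mwmt - mcmt
  dd5  <- pmax(round(150 * mat + 800 + rnorm(n, 0, 80)), 0)
  dd0  <- pmax(round(-55 * mcmt + 150 + rnorm(n, 0, 60)), 0)
  map  <- round(exp(rnorm(n, log(map_c[group]), 0.12)))
  msp  <- round(map * runif(n, 0.35, 0.55))
  lat  <- round(rnorm(n, lat_c[group], 0.8), 3)
  lon  <- round(rnorm(n, lon_c[group], 1.2), 3)
  elev <- pmax(round(rnorm(n, elev_c[group], 150)), 0)

  ## ecosystem variants (2-6 seedlots each) nested in ecozones nested in groups
  variant <- character(n); ecozone <- character(n)
  for (gg in seq_len(g)) {
    idx <- which(group == gg)
    n_var <- max(1L, round(length(idx) / 4))
    v <- sort(rep_len(seq_len(n_var), length(idx)))
    variant[idx] <- sprintf("V%d.%d", gg, v)
    ecozone[idx] <- sprintf("EZ%d.%d", gg, ceiling(v / 3))
  }

  origins <- data.frame(
    seedlot_id = sprintf("S%03d", seq_len(n)),
    species = species,
    latitude = lat, longitude = lon, elevation = elev,
    MAT = round(mat, 2), MWMT = round(mwmt, 2), MCMT = round(mcmt, 2),
    TD = round(mwmt, 2) - round(mcmt, 2),
    DD5 = dd5, DD0 = dd0, MAP = map, MSP = msp,
    ecosystem_variant = variant, ecozone = ecozone,
    stringsAsFactors = FALSE
  )

  if (is.null(sigma2)) sigma2 <- GENECOL_VARIANCE_DEFAULTS[[species]]
  stopifnot(all(GENECOL_TRAITS %in% names(sigma2)))
  for (tr in GENECOL_TRAITS) {
    if (any(sigma2[[tr]] < 0)) stop("variance magnitudes must be >= 0")
  }

  ## multitrait group profiles: rows are group archetypes, columns traits
  ## (height, diameter, budbreak, budset, cold_injury). Signs encode the
  ## classic syndromes: boreal = hardy/early budbreak/late budset; montane =
  ## slow growth/late budbreak/early budset; valley = fast growth/high injury.
  archetypes <- rbind(
    boreal   = c( 0.0, -0.3, -1.0,  1.0, -1.0),
    montane  = c(-1.0, -0.8,  1.0, -1.0,  0.5),
    subboreal= c( 0.0,  0.0,  0.0,  0.0,  0.0),
    valley   = c( 1.2,  1.0,  0.3,  1.0,  1.0),
    maritime = c( 0.5,  0.6,  1.3,  0.8,  1.2)
  )
  profiles <- matrix(0, g, 5, dimnames = list(NULL, GENECOL_TRAITS))
  k <- min(g, nrow(archetypes))
  profiles[seq_len(k), ] <- archetypes[seq_len(k), ]
  if (g > k) profiles[(k + 1):g, ] <- matrix(rnorm((g - k) * 5), g - k, 5)

  ## structured population effects, rescaled per trait to the planted shares
  mat_dev <- mat - ave(mat, group)                 # within-group MAT deviation
  pop_struct <- matrix(0, n, 5, dimnames = list(origins$seedlot_id,
                                                GENECOL_TRAITS))
  unit <- function(x) {
    s <- sd(x)
    if (is.na(s) || s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
  }
  for (ti in seq_along(GENECOL_TRAITS)) {
    tr <- GENECOL_TRAITS[ti]
    s2p <- sigma2[[tr]][["P"]]
    s1 <- unit(profiles[group, ti])
    s2 <- unit(mat_dev)
    fb <- if (all(s1 == 0)) 0 else between_frac
    fs <- if (all(s2 == 0)) 0 else slope_frac
    pop_struct[, ti] <- s1 * sqrt(fb * s2p) + s2 * sqrt(fs * s2p)
  }

  truth <- list(
    seed = seed, species = species,
    group = setNames(group, origins$seedlot_id),
    sigma2 = sigma2[GENECOL_TRAITS],
    trait_means = GENECOL_TRAIT_MEANS,
    pop_struct = pop_struct,
    group_profiles = profiles,
    between_frac = between_frac, slope_frac = slope_frac
  )
  list(origins = origins, truth = truth)
}

#' Allocate seedlots to an incomplete-block common-garden layout
#'
#' Randomized incomplete-block allocator: within each chamber the
#' `blocks_per_chamber * block_size` slots are filled with each seedlot
#' replicated as evenly as capacity allows (floor or ceiling of
#' capacity / n seedlots), then shuffled into blocks.
#'
#' @param seedlots data frame with a `seedlot_id` column (e.g. from
#'   [generate_origins()]), or a character vector of ids.
#' @param n_chambers,blocks_per_chamber,block_size design constants; the
#'   defaults (4 chambers of 8 blocks x 90 positions) match a two-season
#'   growth-chamber trial of 2880 seedlings.
#' @param seed integer RNG seed.
#' @return data frame with one row per seedling position: `chamber_id`,
#'   `block_id`, `position`, `seedlot_id`.
#' @export
generate_design <- function(seedlots, n_chambers = 4, blocks_per_chamber = 8,
                            block_size = 90, seed = 1) {
  ids <- if (is.data.frame(seedlots)) seedlots$seedlot_id else as.character(seedlots)
  n <- length(ids)
  if (n < 1) stop("no seedlots supplied")
  capacity <- blocks_per_chamber * block_size
  if (capacity < 2 * n)
    stop(sprintf(
      "chamber capacity %d cannot hold 2 replicates of each of %d seedlots",
      capacity, n))
  set.seed(seed)
  out <- vector("list", n_chambers)
  for (ch in seq_len(n_chambers)) {
    base <- capacity %/% n
    extra <- capacity - base * n
    reps <- rep(base, n)
    if (extra > 0) reps[sample.int(n, extra)] <- base + 1
    slots <- sample(rep(ids, times = reps))      # randomized block allocation
    out[[ch]] <- data.frame(
      chamber_id = sprintf("CH%d", ch),
      block_id = rep(sprintf("B%d", seq_len(blocks_per_chamber)),
                     each = block_size),
      position = rep(seq_len(block_size), blocks_per_chamber),
      seedlot_id = slots,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate seedling trait observations under the nested random-effects model
#'
#' Generates the five traits (height, diameter, budbreak, budset, cold injury)
#' as the sum of a grand mean, the seedlot's population effect (the structured
#' climate-driven part from `truth$pop_struct` plus an independent
#' within-simulation draw), chamber, population-by-chamber, block-in-chamber
#' and position-in-block effects, and residual noise, each at the magnitude
#' given by `truth$sigma2`.
#'
#' @param layout design data frame from [generate_design()].
#' @param origins origin table from [generate_origins()].
#' @param truth simulation truth from [generate_origins()]; its `sigma2`
#'   entries may be edited before calling to change the generative magnitudes.
#' @param seed integer RNG seed.
#' @return data frame: `seedling_id`, layout columns, and one column per trait.
#' @export
simulate_observations <- function(layout, origins, truth, seed = 1) {
  unknown <- setdiff(unique(layout$seedlot_id), origins$seedlot_id)
  if (length(unknown))
    stop("layout references unknown seedlot(s): ",
         paste(head(unknown, 5), collapse = ", "))
  set.seed(seed)
  n <- nrow(layout)
  pop_i <- match(layout$seedlot_id, origins$seedlot_id)
  env <- factor(layout$chamber_id)
  blk <- factor(paste(layout$chamber_id, layout$block_id, sep = ":"))
  pe  <- factor(paste(layout$seedlot_id, layout$chamber_id, sep = ":"))
  obs <- data.frame(
    seedling_id = sprintf("T%05d", seq_len(n)),
    layout, stringsAsFactors = FALSE
  )
  npop <- nrow(origins)
  for (tr in GENECOL_TRAITS) {
    v <- truth$sigma2[[tr]]
    f_iid <- max(0, 1 - truth$between_frac - truth$slope_frac)
    u   <- rnorm(npop, 0, sqrt(f_iid * v[["P"]]))
    Ej  <- rnorm(nlevels(env), 0, sqrt(v[["E"]]))
    PEij <- rnorm(nlevels(pe), 0, sqrt(v[["PE"]]))
    Bjk <- rnorm(nlevels(blk), 0, sqrt(v[["B"]]))
    Lkl <- rnorm(n, 0, sqrt(v[["L"]]))            # one seedling per position
    e   <- rnorm(n, 0, sqrt(v[["e"]]))
    obs[[tr]] <- truth$trait_means[[tr]] +
      truth$pop_struct[pop_i, tr] + u[pop_i] +
      Ej[as.integer(env)] + PEij[as.integer(pe)] + Bjk[as.integer(blk)] +
      Lkl + e
  }
  obs
}

#' Simulate an electrolyte-leakage freeze-test batch
#'
#' Each seedling's latent injury at a test temperature follows a logistic
#' injury-temperature curve whose midpoint shifts with the seedling's
#' cold-injury phenotype; conductances are then emitted so that the index of
#' injury computed from them returns exactly the latent injury when
#' `noise = 0`. One control pair (`L0`, `Ld`) is emitted per chamber-by-
#' temperature batch.
#'
#' @param observations seedling table from [simulate_observations()] (uses the
#'   `cold_injury` column and design coordinates).
#' @param temperatures freeze test temperatures in degrees C (at least one).
#' @param seed integer RNG seed.
#' @param noise standard deviation of Gaussian noise added to the relative
#'   conductance `Rt` (0 = exact round trip).
#' @param midpoint,scale logistic curve midpoint (degrees C, for a seedling of
#'   average hardiness) and width (degrees C).
#' @param t50_per_injury shift of the seedling midpoint per unit of the
#'   cold-injury phenotype (degrees C per percent).
#' @param L0,Ld,Lk control and heat-kill conductances (microsiemens).
#' @return list with `samples` (`sample_id`, `seedlot_id`, `chamber_id`,
#'   `batch_id`, `test_temperature`, `Lt`, `Lk`, `injury_true`) and
#'   `controls` (`batch_id`, `L0`, `Ld`).
#' @export
simulate_freeze_batch <- function(observations, temperatures, seed = 1,
                                  noise = 0, midpoint = -13, scale = 2,
                                  t50_per_injury = 0.1,
                                  L0 = 10, Ld = 50, Lk = 60) {
  if (length(temperatures) < 1) stop("at least one test temperature required")
  if (noise < 0) stop("`noise` must be >= 0")
  set.seed(seed)
  R0 <- L0 / Ld
  rows <- vector("list", length(temperatures))
  for (k in seq_along(temperatures)) {
    tt <- temperatures[k]
    t50 <- midpoint + (observations$cold_injury - 50) * t50_per_injury
    inj <- 100 * plogis((t50 - tt) / scale)
    rt <- R0 + (inj / 100) * (1 - R0)
    if (noise > 0) rt <- rt + rnorm(length(rt), 0, noise)
    rt <- pmin(pmax(rt, 1e-9), 1)
    rows[[k]] <- data.frame(
      sample_id = paste0(observations$seedling_id, "@", tt),
      seedlot_id = observations$seedlot_id,
      chamber_id = observations$chamber_id,
      batch_id = paste0(observations$chamber_id, "@", tt),
      test_temperature = tt,
      Lt = rt * Lk, Lk = Lk,
      injury_true = inj,
      stringsAsFactors = FALSE
    )
  }
  samples <- do.call(rbind, rows)
  controls <- data.frame(batch_id = unique(samples$batch_id),
                         L0 = L0, Ld = Ld, stringsAsFactors = FALSE)
  list(samples = samples, controls = controls)
}

#' Write a simulated dataset to disk
#'
#' Writes origins, layout, observations and freeze tables as CSV (snake_case
#' columns, missing values as empty fields) plus the simulation truth as a
#' JSON sidecar.
#'
#' @param dir output directory (created if absent).
#' @param origins,truth,layout,observations pieces from the generators.
#' @param freeze optional list from [simulate_freeze_batch()].
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(dir, origins, truth, layout, observations,
                             freeze = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(origins = "origins.csv", layout = "layout.csv",
             observations = "observations.csv")
  write.csv(origins, file.path(dir, "origins.csv"), row.names = FALSE, na = "")
  write.csv(layout, file.path(dir, "layout.csv"), row.names = FALSE, na = "")
  write.csv(observations, file.path(dir, "observations.csv"),
            row.names = FALSE, na = "")
  if (!is.null(freeze)) {
    write.csv(freeze$samples, file.path(dir, "freeze_samples.csv"),
              row.names = FALSE, na = "")
    write.csv(freeze$controls, file.path(dir, "freeze_controls.csv"),
              row.names = FALSE, na = "")
    files <- c(files, "freeze_samples.csv", "freeze_controls.csv")
  }
  tr <- truth
  tr$pop_struct <- as.data.frame(tr$pop_struct)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "truth.json")
  invisible(file.path(dir, files))
}
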