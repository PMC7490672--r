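#' Markov model of preschool activity states
#'
#' Activity in preschoolers is sporadic: short bouts of movement embedded in
#' long sedentary stretches. The generator models the latent intensity state
#' (SB/LPA/MPA/VPA) at 15-s epoch resolution as a first-order Markov chain.
#'
#' @param transition 4x4 row-stochastic matrix of state transition
#'   probabilities at epoch resolution.
#' @param initial length-4 initial state probability vector; defaults to the
#'   chain's stationary distribution.
#' @return an object of class `activity_state_model`.
#' @export
activity_state_model <- function(transition, initial = NULL) {
  transition <- as.matrix(transition)
  k <- length(intensity_levels())
  if (!all(dim(transition) == k)) {
    abort("transition matrix must be ", k, "x", k)
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12)) {
    abort("invalid model: transition matrix rows must be non-negative and ",
          "sum to 1 (within 1e-12)")
  }
  if (is.null(initial)) initial <- stationary_distribution_of(transition)
  if (!is_prob_vector(initial, tol = 1e-9) || length(initial) != k) {
    abort("invalid model: initial distribution must be a length-", k,
          " probability vector")
  }
  structure(list(transition = transition, initial = initial),
            class = "activity_state_model")
}

# internal: stationary distribution of a row-stochastic matrix
stationary_distribution_of <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Stationary distribution of an activity state model
#' @param model an [activity_state_model()].
#' @return length-4 probability vector.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "activity_state_model"))
  stationary_distribution_of(model$transition)
}

#' Sticky chain with a prescribed stationary distribution
#'
#' Builds the transition matrix `P = s * I + (1 - s) * 1 pi'`, whose
#' stationary distribution is exactly `pi` for any stickiness `s` in `[0, 1)`.
#' Stickiness controls bout persistence: at 15-s epochs, `s = 0.85` gives
#' mean bout lengths of a few epochs to a couple of minutes, matching
#' short-burst preschool activity. The default target occupancy is the
#' observed preschool-day class share 64.2 / 28.0 / 5.5 / 2.3 %.
#'
#' @param stationary target occupancy probabilities (length 4, sums to 1).
#' @param stickiness probability mass kept on the current state.
#' @return an [activity_state_model()].
#' @export
sticky_state_model <- function(stationary = c(0.642, 0.280, 0.055, 0.023),
                               stickiness = 0.85) {
  stationary <- stationary / sum(stationary)
  stopifnot(stickiness >= 0, stickiness < 1)
  k <- length(stationary)
  P <- stickiness * diag(k) +
    (1 - stickiness) * matrix(stationary, k, k, byrow = TRUE)
  activity_state_model(P, initial = stationary)
}

#' Simulate a latent intensity state sequence
#'
#' @param model an [activity_state_model()].
#' @param n_epochs number of epochs to draw (>= 1).
#' @param seed integer seed; the draw is fully reproducible.
#' @return ordered factor of intensity labels of length `n_epochs`.
#' @export
simulate_states <- function(model, n_epochs, seed) {
  stopifnot(inherits(model, "activity_state_model"), n_epochs >= 1)
  k <- nrow(model$transition)
  cum <- t(apply(model$transition, 1, cumsum))
  set.seed(seed)
  u <- stats::runif(n_epochs)
  s <- integer(n_epochs)
  cur <- findInterval(u[1], cumsum(model$initial), left.open = TRUE) + 1L
  s[1] <- cur
  for (i in seq_len(n_epochs)[-1]) {
    cur <- findInterval(u[i], cum[cur, ], left.open = TRUE) + 1L
    s[i] <- cur
  }
  as_intensity(intensity_levels()[s])
}

#' State-conditional count emission model
#'
#' Hip counts per 15-s epoch are drawn, given the latent state, from a
#' right-skewed discretised lognormal (SB additionally zero-inflated to
#' mimic motionless epochs; VPA shifted above the vigorous floor). Wrist
#' counts are linked to hip counts through a strictly increasing function
#' `g` (default `g(x) = 3.2 x`, the approximate wrist/hip scale of
#' published preschool cut points) times a multiplicative lognormal noise
#' factor with unit median and dispersion `sdlog = dispersion`; the product
#' is rounded half-up to an integer. With `dispersion = 0` the wrist count
#' is exactly `round(g(hip))`.
#'
#' Each state's parameter list has elements `meanlog`, `sdlog`, optional
#' `zero_prob` (point mass at zero), optional `offset` (added after the
#' lognormal draw), and `min`/`max` giving the state's count interval on the
#' 15-s scale (the Butte intervals divided by 4). When `pure = TRUE`, draws
#' are rejected until they fall inside `[min, max]`, so hip classification
#' by the Butte cut points recovers the latent state exactly.
#'
#' @param hip per-state parameter lists (names SB, LPA, MPA, VPA).
#' @param linkage positive scalar `s` for `g(x) = s x`, or a strictly
#'   increasing function.
#' @param dispersion lognormal `sdlog` of the wrist noise factor (>= 0).
#' @param pure logical; truncate each state's hip distribution to its
#'   count interval.
#' @return an object of class `count_emission_model`.
#' @export
count_emission_model <- function(
    hip = list(
      SB  = list(meanlog = log(55),   sdlog = 0.65, zero_prob = 0.30,
                 min = 0, max = 205),
      LPA = list(meanlog = log(450),  sdlog = 0.38, min = 206, max = 977),
      MPA = list(meanlog = log(1225), sdlog = 0.11, min = 978, max = 1528),
      VPA = list(meanlog = log(700),  sdlog = 0.60, offset = 1529,
                 min = 1529, max = Inf)
    ),
    linkage = 3.2, dispersion = 0.2, pure = FALSE) {
  stopifnot(is.list(hip), setequal(names(hip), intensity_levels()))
  for (nm in names(hip)) {
    p <- hip[[nm]]
    if (!is.null(p$min) && p$min < 0) {
      abort("invalid model: state ", nm, " has negative count support")
    }
  }
  if (is.numeric(linkage)) {
    stopifnot(length(linkage) == 1, linkage > 0)
    s <- linkage
    g <- function(x) s * x
  } else if (is.function(linkage)) {
    g <- linkage
    grid <- g(seq(0, 4000, by = 25))
    if (any(diff(grid) <= 0)) {
      abort("invalid model: linkage function must be strictly increasing")
    }
  } else abort("linkage must be a positive scalar or a function")
  stopifnot(dispersion >= 0)
  structure(list(hip = hip[intensity_levels()], g = g,
                 dispersion = dispersion, pure = isTRUE(pure)),
            class = "count_emission_model")
}

#' Well-separated emission preset
#'
#' An idealised emission whose state-conditional hip-count supports are
#' disjoint intervals (SB 0-150, LPA 450-850, MPA 1100-1400, VPA 1850-3300
#' counts per 15-s epoch) with gaps wide enough that the midpoint between
#' adjacent class centroids falls inside the gap — so an optimal k-means
#' partition, whose cluster boundaries sit at centroid midpoints, separates
#' the states exactly. In this regime every calibration procedure should
#' recover the reference partition exactly on the observed data; it is the
#' validation regime, not the realistic default.
#'
#' @param dispersion wrist noise dispersion (default 0).
#' @return a [count_emission_model()].
#' @export
well_separated_emission <- function(dispersion = 0) {
  count_emission_model(
    hip = list(
      SB  = list(meanlog = log(50),   sdlog = 0.50, min = 0,    max = 150),
      LPA = list(meanlog = log(550),  sdlog = 0.25, min = 450,  max = 850),
      MPA = list(meanlog = log(1230), sdlog = 0.08, min = 1100, max = 1400),
      VPA = list(meanlog = log(400),  sdlog = 0.50, offset = 1850,
                 min = 1850, max = 3300)
    ),
    linkage = 3.2, dispersion = dispersion, pure = TRUE
  )
}

# internal: draw n hip counts for one state
draw_state_counts <- function(n, par, pure) {
  draw <- function(m) {
    x <- stats::rlnorm(m, par$meanlog, par$sdlog)
    if (!is.null(par$offset)) x <- x + par$offset
    x <- round_half_up(x)
    zp <- par$zero_prob %||% 0
    if (zp > 0 && !pure) x[stats::runif(m) < zp] <- 0
    if (zp > 0 && pure && (par$min %||% 0) == 0) {
      x[stats::runif(m) < zp] <- 0
    }
    x
  }
  x <- draw(n)
  if (pure) {
    lo <- par$min %||% 0
    hi <- par$max %||% Inf
    for (iter in 1:1000) {
      bad <- which(x < lo | x > hi)
      if (!length(bad)) break
      x[bad] <- draw(length(bad))
    }
    if (any(x < lo | x > hi)) {
      abort("pure emission rejection sampling failed; support [", lo, ", ",
            hi, "] has too little mass")
    }
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit paired hip and wrist counts for a state sequence
#'
#' @param states factor of intensity labels (from [simulate_states()]).
#' @param emission a [count_emission_model()].
#' @param seed integer seed.
#' @return list with integer vectors `hip` and `wrist`, each the length of
#'   `states` (counts per epoch).
#' @export
emit_counts <- function(states, emission, seed) {
  stopifnot(inherits(emission, "count_emission_model"), length(states) >= 1)
  states <- as_intensity(states)
  n <- length(states)
  set.seed(seed)
  hip <- integer(n)
  for (nm in intensity_levels()) {
    idx <- which(states == nm)
    if (length(idx)) {
      hip[idx] <- draw_state_counts(length(idx), emission$hip[[nm]],
                                    emission$pure)
    }
  }
  noise <- if (emission$dispersion > 0) {
    exp(stats::rnorm(n, 0, emission$dispersion))
  } else rep(1, n)
  wrist <- as.integer(round_half_up(emission$g(hip) * noise))
  wrist[wrist < 0] <- 0L
  list(hip = hip, wrist = wrist)
}

#' Non-wear block model
#'
#' With probability `prob` per day, one non-wear block of duration drawn
#' uniformly (in whole minutes) from `duration` is overwritten with zero
#' counts on the affected placement(s). Blocks start on whole-minute
#' boundaries (devices are removed and re-attached at the minute scale).
#'
#' @param prob per-day probability of a block.
#' @param duration length-2 integer vector, minutes (min, max).
#' @param placement `"both"`, `"hip"` or `"wrist"`.
#' @return an object of class `nonwear_model`.
#' @export
nonwear_model <- function(prob = 0.1, duration = c(90, 180),
                          placement = c("both", "hip", "wrist")) {
  placement <- match.arg(placement)
  stopifnot(prob >= 0, prob <= 1, length(duration) == 2,
            duration[1] >= 1, duration[2] >= duration[1])
  structure(list(prob = prob, duration = round(duration),
                 placement = placement),
            class = "nonwear_model")
}

#' Overwrite a non-wear block with zeros
#'
#' Applies a [nonwear_model()] to one day's count series and records the
#' ground-truth mask so non-wear detection can be validated against it.
#' A drawn block longer than the day is clipped to the day with a warning.
#'
#' @param counts integer count vector for one day.
#' @param epoch_length epoch length in seconds.
#' @param model a [nonwear_model()].
#' @param seed integer seed.
#' @return list with `counts` (block zeroed), `nonwear` (logical
#'   ground-truth mask, `TRUE` = not worn) and `blocks` (data frame of
#'   start/end minutes, zero rows if no block was drawn).
#' @export
inject_nonwear <- function(counts, epoch_length, model, seed) {
  stopifnot(inherits(model, "nonwear_model"), length(counts) >= 1)
  epm <- 60 / epoch_length
  day_min <- floor(length(counts) / epm)
  mask <- rep(FALSE, length(counts))
  blocks <- data.frame(start_min = integer(), end_min = integer())
  set.seed(seed)
  if (stats::runif(1) < model$prob) {
    dur <- model$duration[1] +
      sample.int(model$duration[2] - model$duration[1] + 1L, 1) - 1L
    if (dur > day_min) {
      warning("non-wear block (", dur, " min) longer than the day (",
              day_min, " min); clipped", call. = FALSE)
      dur <- day_min
    }
    start <- sample.int(day_min - dur + 1L, 1) - 1L
    idx <- seq(start * epm + 1, (start + dur) * epm)
    counts[idx] <- 0L
    mask[idx] <- TRUE
    blocks <- data.frame(start_min = start, end_min = start + dur)
  }
  list(counts = counts, nonwear = mask, blocks = blocks)
}

#' Simulation configuration
#'
#' Defaults mirror the study design the package targets: 34 preschoolers,
#' 3 consecutive preschool days of 5 hours (9 AM-2 PM), 15-second epochs —
#' 1200 epochs per day, 3600 per child, 122,400 in total.
#'
#' @param n_participants number of enrolled participants.
#' @param n_days days per participant.
#' @param day_minutes monitored minutes per day.
#' @param epoch_length epoch length in seconds; `day_minutes * 60` must be
#'   divisible by it.
#' @param seed master seed; together with the config it fully determines
#'   the generated study.
#' @param state_model an [activity_state_model()].
#' @param emission a [count_emission_model()].
#' @param nonwear a [nonwear_model()].
#' @param n_noncompliant number of participants (taken from the end of the
#'   roster) who never wore the wrist device — their wrist counts are all
#'   zero, so they contribute no matched epochs and are excluded downstream.
#'   Used to emulate a recruitment funnel.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 34, n_days = 3,
                              day_minutes = 300, epoch_length = 15,
                              seed = 1,
                              state_model = sticky_state_model(),
                              emission = count_emission_model(),
                              nonwear = nonwear_model(),
                              n_noncompliant = 0) {
  if ((day_minutes * 60) %% epoch_length != 0) {
    abort("day_minutes * 60 must be divisible by epoch_length")
  }
  stopifnot(n_participants >= 1, n_days >= 1,
            n_noncompliant >= 0, n_noncompliant < n_participants)
  structure(list(n_participants = n_participants, n_days = n_days,
                 day_minutes = day_minutes, epoch_length = epoch_length,
                 seed = as.integer(seed), state_model = state_model,
                 emission = emission, nonwear = nonwear,
                 n_noncompliant = n_noncompliant),
            class = "simulation_config")
}

#' Simulate a full paired hip/wrist study
#'
#' Generates, for every participant-day: a latent state sequence, paired
#' hip/wrist epoch counts, and (possibly) a non-wear block per placement.
#' Each stage draws from its own sub-stream of the master seed, so identical
#' configs give identical studies.
#'
#' @param config a [simulation_config()].
#' @return an object of class `accel_study`: a list with `epochs` (one row
#'   per participant-day-epoch: `participant_id`, `day`, `epoch`, `state`,
#'   `hip_count`, `wrist_count`, `hip_nonwear`, `wrist_nonwear`) and
#'   `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_ep <- config$day_minutes * 60 / config$epoch_length
  out <- vector("list", config$n_participants * config$n_days)
  roster <- sprintf("P%03d", seq_len(config$n_participants))
  noncomp <- if (config$n_noncompliant > 0) {
    utils::tail(roster, config$n_noncompliant)
  } else character()
  k <- 0
  for (p in seq_len(config$n_participants)) {
    pid <- roster[p]
    for (d in seq_len(config$n_days)) {
      states <- simulate_states(config$state_model, n_ep,
                                substream_seed(config$seed, "states", p, d))
      cts <- emit_counts(states, config$emission,
                         substream_seed(config$seed, "counts", p, d))
      hip_nw <- inject_nonwear(cts$hip, config$epoch_length, config$nonwear,
                               substream_seed(config$seed, "nonwear-hip",
                                              p, d))
      if (config$nonwear$placement == "both") {
        # one block affects the child, hence both devices
        cts$hip <- hip_nw$counts
        wrist_counts <- cts$wrist
        wrist_counts[hip_nw$nonwear] <- 0L
        wrist_nw <- list(counts = wrist_counts, nonwear = hip_nw$nonwear)
      } else if (config$nonwear$placement == "hip") {
        cts$hip <- hip_nw$counts
        wrist_nw <- list(counts = cts$wrist, nonwear = rep(FALSE, n_ep))
      } else {
        wrist_nw <- inject_nonwear(cts$wrist, config$epoch_length,
                                   config$nonwear,
                                   substream_seed(config$seed,
                                                  "nonwear-wrist", p, d))
        hip_nw <- list(counts = cts$hip, nonwear = rep(FALSE, n_ep))
      }
      hip_counts <- hip_nw$counts
      wrist_counts <- wrist_nw$counts
      hip_mask <- hip_nw$nonwear
      wrist_mask <- wrist_nw$nonwear
      if (pid %in% noncomp) {
        wrist_counts <- rep(0L, n_ep)
        wrist_mask <- rep(TRUE, n_ep)
      }
      k <- k + 1
      out[[k]] <- data.frame(
        participant_id = pid, day = d, epoch = seq_len(n_ep),
        state = as.character(states),
        hip_count = hip_counts, wrist_count = wrist_counts,
        hip_nonwear = hip_mask, wrist_nonwear = wrist_mask,
        stringsAsFactors = FALSE
      )
    }
  }
  epochs <- do.call(rbind, out)
  epochs$state <- as_intensity(epochs$state)
  structure(list(epochs = epochs, config = config), class = "accel_study")
}

#' @export
print.accel_study <- function(x, ...) {
  cfg <- x$config
  cat("<accel_study> ", cfg$n_participants, " participants x ", cfg$n_days,
      " days x ", cfg$day_minutes, " min (", cfg$epoch_length,
      "-s epochs): ", nrow(x$epochs), " epochs\n", sep = "")
  invisible(x)
}

#' Write a simulated study as epoch CSV files
#'
#' One file per participant-day-placement in the package's epoch CSV
#' dialect, plus `manifest.csv` (participant, day, placement, file) and
#' `truth.csv` (latent state and non-wear mask per epoch).
#'
#' @param study an `accel_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "accel_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- study$epochs
  el <- study$config$epoch_length
  manifest <- list()
  i <- 0
  for (key in unique(paste(ep$participant_id, ep$day))) {
    sub <- ep[paste(ep$participant_id, ep$day) == key, ]
    pid <- sub$participant_id[1]; d <- sub$day[1]
    for (pl in c("hip", "wrist")) {
      i <- i + 1
      fn <- sprintf("%s_day%d_%s.csv", pid, d, pl)
      df <- data.frame(
        participant_id = pid, day = d, placement = pl,
        epoch_start = format(
          as.POSIXct("2018-10-01 09:00:00", tz = "UTC") +
            (sub$epoch - 1) * el, "%Y-%m-%dT%H:%M:%S"),
        epoch_length_s = el,
        vm = if (pl == "hip") sub$hip_count else sub$wrist_count
      )
      utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
      manifest[[i]] <- data.frame(participant_id = pid, day = d,
                                  placement = pl, file = fn)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  truth <- ep[, c("participant_id", "day", "epoch", "state",
                  "hip_nonwear", "wrist_nonwear")]
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
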