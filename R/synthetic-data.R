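#' Generator configuration for synthetic ERP cohorts
#'
#' Collects every knob of the synthetic-data generator in one validated list.
#' Defaults mirror the emotional cognitive-reappraisal design the package
#' emulates: 64 channels, a music group of 28 and a control group of 24
#' participants, 90 trials split evenly over the three conditions
#' (\code{Neg}, \code{Neu}, \code{Rea}), epochs from -200 to 5000 ms sampled
#' at 250 Hz, and four underlying microstate templates.
#'
#' @param n_channels number of electrodes.
#' @param n_trials_per_condition trials per condition per participant.
#' @param n_participants named counts, \code{c(music = 28, control = 24)}.
#' @param n_templates number of ground-truth microstate maps.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window epoch limits in ms relative to stimulus onset,
#'   half-open \code{[start, end)}; start must be negative, end positive.
#' @param snr ratio of mean signal GFP to mean noise GFP per trial; must be
#'   positive (use \code{Inf} for noiseless epochs).
#' @param segment_duration_range microstate segment durations are drawn
#'   uniformly from this range (ms).
#' @param plv_target target phase-locking value in \code{[0, 1]} for
#'   phase-coupled channel pairs.
#' @return an object of class \code{ms_config} (a named list).
#' @export
ms_config <- function(n_channels = 64,
                      n_trials_per_condition = 30,
                      n_participants = c(music = 28, control = 24),
                      n_templates = 4,
                      sampling_rate = 250,
                      epoch_window = c(-200, 5000),
                      snr = 5,
                      segment_duration_range = c(50, 200),
                      plv_target = 0.6) {
  n_participants <- unlist(n_participants)   # tolerate JSON-parsed lists
  if (n_trials_per_condition < 0) {
    stop("`n_trials_per_condition` must be nonnegative", call. = FALSE)
  }
  if (any(n_participants < 0)) stop("participant counts must be nonnegative",
                                    call. = FALSE)
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0)) {
    stop("`epoch_window` must straddle stimulus onset: start < 0 < end",
         call. = FALSE)
  }
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  if (plv_target < 0 || plv_target > 1) {
    stop("`plv_target` must lie in [0, 1]", call. = FALSE)
  }
  if (segment_duration_range[1] <= 0 ||
      segment_duration_range[2] < segment_duration_range[1]) {
    stop("`segment_duration_range` must be an increasing positive pair",
         call. = FALSE)
  }
  structure(list(
    n_channels = as.integer(n_channels),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    n_participants = n_participants,
    n_templates = as.integer(n_templates),
    sampling_rate = sampling_rate,
    epoch_window = epoch_window,
    snr = snr,
    segment_duration_range = segment_duration_range,
    plv_target = plv_target
  ), class = "ms_config")
}

conditions_levels <- function() c("Neg", "Neu", "Rea")

#' Randomised trial schedule for the three-condition reappraisal design
#'
#' Builds the trial list of one participant: equal counts of the three
#' conditions, each trial carrying the valence of its picture and of its
#' preceding text description. \code{Neg} pairs a negative picture with a
#' negative description, \code{Rea} (reappraisal) pairs a negative picture
#' with a neutral description, and \code{Neu} pairs neutral with neutral; at
#' the default 30 trials per condition this yields 90 trials with 60 negative
#' and 30 neutral pictures. Trial order is randomised.
#'
#' @param config an \code{\link{ms_config}}.
#' @param seed integer seed; the same seed reproduces the same ordering.
#' @return a data.frame with columns \code{trial_id}, \code{condition},
#'   \code{picture_valence}, \code{description_valence}.
#' @export
make_trial_schedule <- function(config = ms_config(), seed = NULL) {
  n <- config$n_trials_per_condition
  if (n < 0) stop("trial counts must be nonnegative", call. = FALSE)
  cond <- rep(conditions_levels(), each = n)
  pic <- ifelse(cond == "Neu", "neutral", "negative")
  desc <- ifelse(cond == "Neg", "negative", "neutral")
  ord <- with_seed(seed, sample.int(length(cond)))
  data.frame(
    trial_id = seq_along(cond),
    condition = cond[ord],
    picture_valence = pic[ord],
    description_valence = desc[ord],
    stringsAsFactors = FALSE
  )
}

# Deterministic pseudo-montage: electrodes on a sunflower spiral over the
# unit disk. Only relative geometry matters (smooth spatial patterns).
electrode_positions <- function(n_channels) {
  i <- seq_len(n_channels)
  r <- sqrt((i - 0.5) / n_channels)
  theta <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(theta), y = r * sin(theta))
}

#' Generate a set of decorrelated microstate template maps
#'
#' Draws \code{k} smooth dipolar-like scalp maps as random second-order
#' spatial polynomials over a planar electrode layout, average-references
#' each map, scales it to unit GFP, and resamples until all pairwise absolute
#' spatial correlations are at most 0.5, so the clustering problem downstream
#' is nontrivial but identifiable.
#'
#' @param n_channels number of electrodes (must be at least \code{k}).
#' @param k number of templates (at least 2).
#' @param seed integer seed.
#' @param max_attempts resampling budget before giving up.
#' @return a \code{n_channels x k} matrix; columns have zero mean and unit GFP.
#' @export
make_template_set <- function(n_channels, k, seed = NULL, max_attempts = 500) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (n_channels < k) {
    stop("`n_channels` must be at least `k`", call. = FALSE)
  }
  pos <- electrode_positions(n_channels)
  basis <- cbind(pos[, 1], pos[, 2], pos[, 1]^2, pos[, 1] * pos[, 2],
                 pos[, 2]^2)
  with_seed(seed, {
    maps <- matrix(NA_real_, n_channels, k)
    accepted <- 0L
    attempts <- 0L
    while (accepted < k) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not generate decorrelated templates within the attempt ",
             "budget", call. = FALSE)
      }
      cand <- drop(basis %*% stats::rnorm(ncol(basis)))
      cand <- cand - mean(cand)
      if (sqrt(mean(cand^2)) < 1e-8) next
      cand <- cand / sqrt(mean(cand^2))
      ok <- TRUE
      if (accepted > 0L) {
        r <- map_correlation(matrix(cand, 1L), maps[, seq_len(accepted),
                                                    drop = FALSE])
        ok <- all(abs(r) <= 0.5)
      }
      if (ok) {
        accepted <- accepted + 1L
        maps[, accepted] <- cand
      }
    }
    colnames(maps) <- LETTERS[seq_len(k)]
    maps
  })
}

# Piecewise-constant template label sequence over n_samples, with segment
# lengths uniform in the configured ms range and no immediate repeats.
random_label_sequence <- function(n_samples, k, sampling_rate, duration_range) {
  lab <- integer(n_samples)
  pos <- 1L
  prev <- 0L
  lo <- max(1L, round(duration_range[1] / 1000 * sampling_rate))
  hi <- max(lo, round(duration_range[2] / 1000 * sampling_rate))
  while (pos <= n_samples) {
    len <- if (hi > lo) sample(seq(lo, hi), 1L) else lo
    cls <- if (k == 1L) 1L else sample(setdiff(seq_len(k), prev), 1L)
    end <- min(n_samples, pos + len - 1L)
    lab[pos:end] <- cls
    prev <- cls
    pos <- end + 1L
  }
  lab
}

# Smooth positive amplitude envelope: low base level plus Gaussian bumps in
# the post-stimulus window, so the GFP curve shows distinct peaks.
amplitude_envelope <- function(times, n_bumps = 6) {
  post <- range(times[times >= 0])
  centers <- stats::runif(n_bumps, post[1] + 0.05 * diff(post),
                          post[2] - 0.05 * diff(post))
  widths <- stats::runif(n_bumps, 0.02 * diff(post), 0.06 * diff(post))
  env <- rep(0.2, length(times))
  for (b in seq_len(n_bumps)) {
    env <- env + exp(-0.5 * ((times - centers[b]) / widths[b])^2)
  }
  env
}

epoch_times <- function(config) {
  n <- round(diff(config$epoch_window) / 1000 * config$sampling_rate)
  config$epoch_window[1] + (seq_len(n) - 1L) * 1000 / config$sampling_rate
}

new_ms_epochs <- function(data, sampling_rate, times, condition,
                          participant_id = NA_character_,
                          group = NA_character_) {
  structure(list(data = data, sampling_rate = sampling_rate, times = times,
                 condition = condition, participant_id = participant_id,
                 group = group),
            class = "ms_epochs")
}

#' Simulate microstate-structured ERP epochs for one participant
#'
#' Each condition receives its own piecewise-constant sequence of template
#' labels (segment lengths uniform in the configured range); every trial of
#' that condition is the label sequence rendered as template map times a
#' smooth positive amplitude envelope, plus spatially white Gaussian noise
#' scaled so that the ratio of mean signal GFP to mean noise GFP equals
#' \code{config$snr}. Ground truth (templates, per-condition label sequences)
#' is returned alongside the epochs.
#'
#' @param templates \code{channels x k} map matrix, e.g. from
#'   \code{\link{make_template_set}}.
#' @param schedule trial schedule from \code{\link{make_trial_schedule}}.
#' @param config an \code{\link{ms_config}}.
#' @param seed integer seed; identical seeds give bit-identical arrays.
#' @param participant_id,group metadata carried on the epochs.
#' @return a list with \code{epochs} (an \code{ms_epochs}: trials x channels
#'   x samples array plus metadata) and \code{truth} (list with
#'   \code{template_maps} and per-condition \code{label_sequence}).
#' @export
simulate_erp <- function(templates, schedule, config = ms_config(),
                         seed = NULL, participant_id = "P01",
                         group = "control") {
  if (nrow(schedule) == 0L) stop("`schedule` is empty", call. = FALSE)
  if (!is.numeric(config$snr) || config$snr <= 0) {
    stop("`snr` must be > 0", call. = FALSE)
  }
  k <- ncol(templates)
  nch <- nrow(templates)
  times <- epoch_times(config)
  ns <- length(times)
  conds <- conditions_levels()
  with_seed(seed, {
    labels <- lapply(conds, function(cc) {
      random_label_sequence(ns, k, config$sampling_rate,
                            config$segment_duration_range)
    })
    names(labels) <- conds
    envs <- lapply(conds, function(cc) amplitude_envelope(times))
    names(envs) <- conds
    dat <- array(0, dim = c(nrow(schedule), nch, ns))
    for (tr in seq_len(nrow(schedule))) {
      cc <- schedule$condition[tr]
      sig <- templates[, labels[[cc]], drop = FALSE] *
        rep(envs[[cc]], each = nch)
      if (is.finite(config$snr)) {
        noise <- matrix(stats::rnorm(nch * ns), nch, ns)
        noise <- center_columns(noise)
        gfp_n <- sqrt(colMeans(noise^2))
        gfp_s <- sqrt(colMeans(center_columns(sig)^2))
        scale <- mean(gfp_s) / (config$snr * mean(gfp_n))
        sig <- sig + scale * noise
      }
      dat[tr, , ] <- sig
    }
    list(
      epochs = new_ms_epochs(dat, config$sampling_rate, times,
                             schedule$condition, participant_id, group),
      truth = list(template_maps = templates, label_sequence = labels,
                   envelope = envs)
    )
  })
}

# A1(kappa) = I1/I0 is the mean resultant length of a von Mises distribution;
# invert it to hit a requested PLV.
kappa_from_plv <- function(plv_target) {
  if (plv_target <= 0) return(0)
  if (plv_target >= 1) return(Inf)
  a1 <- function(k) {
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  }
  stats::uniroot(function(k) a1(k) - plv_target, lower = 1e-8, upper = 1e5,
                 tol = 1e-10)$root
}

# Best & Fisher (1979) rejection sampler for von Mises(0, kappa) angles.
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (!is.finite(kappa)) return(rep(0, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(ok)
    if (nk > 0L) {
      out[got + seq_len(nk)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + nk
    }
  }
  out
}

#' Simulate a phase-coupled two-channel epoch set
#'
#' Both channels carry a narrowband oscillation with a shared random phase
#' per trial; channel 2 adds a per-trial von Mises phase offset whose
#' concentration is solved numerically so that the population mean resultant
#' length — and hence the expected phase-locking value — equals
#' \code{plv_target}. A target of 1 means zero jitter (identical phases), a
#' target of 0 means uniform jitter.
#'
#' @param n_trials number of trials (at least 1).
#' @param plv_target requested PLV in \code{[0, 1]}.
#' @param n_samples samples per epoch.
#' @param seed integer seed.
#' @param sampling_rate sampling rate in Hz.
#' @param freq oscillation frequency in Hz.
#' @return an \code{ms_epochs} with 2 channels; the true per-trial phase
#'   offsets and the solved concentration are attached as attribute
#'   \code{"truth"}.
#' @export
simulate_phase_coupled_epochs <- function(n_trials, plv_target, n_samples,
                                          seed = NULL, sampling_rate = 250,
                                          freq = 10) {
  if (n_trials < 1) stop("`n_trials` must be at least 1", call. = FALSE)
  if (plv_target < 0 || plv_target > 1) {
    stop("`plv_target` must lie in [0, 1]", call. = FALSE)
  }
  kappa <- kappa_from_plv(plv_target)
  tt <- (seq_len(n_samples) - 1L) / sampling_rate
  with_seed(seed, {
    theta0 <- stats::runif(n_trials, -pi, pi)
    delta <- rvonmises(n_trials, kappa)
    dat <- array(0, dim = c(n_trials, 2L, n_samples))
    for (tr in seq_len(n_trials)) {
      ph <- 2 * pi * freq * tt + theta0[tr]
      dat[tr, 1L, ] <- cos(ph)
      dat[tr, 2L, ] <- cos(ph + delta[tr])
    }
    ep <- new_ms_epochs(dat, sampling_rate, tt * 1000,
                        rep("Neg", n_trials))
    attr(ep, "truth") <- list(kappa = kappa, delta = delta,
                              plv_target = plv_target)
    ep
  })
}

#' Simulate behavioural ratings for a two-group, three-condition design
#'
#' Draws one mean rating per participant and condition from a normal
#' distribution around the configured cell mean and clips to the 1-9 rating
#' scale (valence: 1 extremely negative to 9 highly positive; arousal: 1 calm
#' to 9 aroused).
#'
#' @param groups named participant counts, e.g. \code{c(music = 28,
#'   control = 24)}.
#' @param conditions condition labels (columns of \code{means}).
#' @param effect_config list with \code{means} (groups x conditions matrix of
#'   cell means, dimnames matching) and \code{sd} (common standard
#'   deviation, nonnegative).
#' @param seed integer seed.
#' @return a data.frame with \code{participant_id}, \code{group},
#'   \code{condition}, \code{value}; values lie in \code{[1, 9]}.
#' @export
simulate_ratings <- function(groups = c(music = 28, control = 24),
                             conditions = conditions_levels(),
                             effect_config = list(
                               means = matrix(c(2.5, 5.5, 3.5, 2.3, 5.3, 3.3),
                                              nrow = 2, byrow = TRUE,
                                              dimnames = list(
                                                c("music", "control"),
                                                c("Neg", "Neu", "Rea"))),
                               sd = 0.8),
                             seed = NULL) {
  if (effect_config$sd < 0) stop("rating SD must be nonnegative",
                                 call. = FALSE)
  mu <- effect_config$means
  with_seed(seed, {
    rows <- list()
    pid <- 0L
    for (g in names(groups)) {
      for (i in seq_len(groups[[g]])) {
        pid <- pid + 1L
        vals <- stats::rnorm(length(conditions),
                             mean = mu[g, conditions], sd = effect_config$sd)
        vals <- pmin(9, pmax(1, vals))
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("P%03d", pid), group = g,
          condition = conditions, value = vals, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
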