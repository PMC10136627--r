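# Shared fixtures, built in code at test time.

# Small, fast generator configuration for unit tests.
tiny_config <- function(..., snr = 8) {
  ms_config(n_channels = 16, n_trials_per_condition = 3,
            n_participants = c(music = 3, control = 3), n_templates = 3,
            sampling_rate = 125, epoch_window = c(-104, 904), snr = snr, ...)
}

# One participant's simulated data under the tiny config.
tiny_simulation <- function(seed = 11, snr = 8, n_channels = 16,
                            n_templates = 3) {
  cfg <- tiny_config(snr = snr)
  cfg$n_channels <- as.integer(n_channels)
  cfg$n_templates <- as.integer(n_templates)
  tpl <- make_template_set(n_channels, n_templates, seed = seed + 1)
  sch <- make_trial_schedule(cfg, seed = seed + 2)
  sim <- simulate_erp(tpl, sch, cfg, seed = seed + 3)
  list(config = cfg, templates = tpl, schedule = sch, epochs = sim$epochs,
       truth = sim$truth)
}

# Long measurement table for the mixed design: n1 + n2 participants, three
# conditions, optional condition/group/interaction shifts.
make_measurement_table <- function(n1, n2, cond_shift = c(0, 0, 0),
                                   group_shift = 0, inter = NULL, sd = 1,
                                   rho = 0.3, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  grp <- c(rep("music", n1), rep("control", n2))
  subj <- rnorm(n, sd = sqrt(rho))
  y <- matrix(rnorm(n * 3, sd = sd * sqrt(1 - rho)), n, 3) + subj
  y <- sweep(y, 2L, cond_shift, "+")
  y[grp == "music", ] <- y[grp == "music", ] + group_shift
  if (!is.null(inter)) y[grp == "music", ] <-
    sweep(y[grp == "music", , drop = FALSE], 2L, inter, "+")
  data.frame(participant_id = rep(sprintf("S%03d", seq_len(n)), each = 3),
             group = rep(grp, each = 3),
             condition = rep(c("Neg", "Neu", "Rea"), n),
             value = as.numeric(t(y)), stringsAsFactors = FALSE)
}

# Wrap a trials x channels x samples array as ms_epochs without exporting
# the internal constructor.
as_epochs <- function(data, sampling_rate = 250, times = NULL,
                      condition = NULL) {
  if (is.null(times)) {
    times <- (seq_len(dim(data)[3]) - 1L) * 1000 / sampling_rate
  }
  ep <- simulate_phase_coupled_epochs(1, 1, 2, seed = 1)
  ep$data <- data
  ep$sampling_rate <- sampling_rate
  ep$times <- times
  ep$condition <- condition %||% rep("Neg", dim(data)[1])
  attr(ep, "truth") <- NULL
  ep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
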