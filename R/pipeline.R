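# End-to-end orchestration: synthesize (or load) -> preprocess ->
# microstates -> connectivity -> statistics -> report.

#' Build and validate a pipeline run configuration
#'
#' Bundles the synthetic-generator settings with the analysis parameters of
#' every stage. Unknown keys are rejected before any computation.
#'
#' @param generator an \code{\link{ms_config}} (or list of its arguments).
#' @param band band-pass edges in Hz.
#' @param reject_threshold epoch rejection threshold in microvolts.
#' @param target_rate analysis sampling rate in Hz.
#' @param k_range candidate numbers of microstate classes.
#' @param n_cv_repeats split-half repeats for model selection.
#' @param n_restarts K-means restarts for the final per-participant fits.
#' @param cv_restarts K-means restarts inside cross-validation.
#' @param cv_gfp_peaks cluster only GFP-peak topographies during
#'   cross-validated model selection (default TRUE; peak maps are the
#'   quasi-stable high-SNR topographies microstate clustering conventionally
#'   uses).
#' @param edge_trim fraction of epoch edge samples excluded from gated PLV.
#' @param graph_mode \code{"weighted"} or \code{"binary"} graph metrics.
#' @param graph_threshold edge threshold for binary mode.
#' @param seed master seed for the whole run.
#' @return validated list of class \code{ms_run_config}.
#' @export
run_config <- function(generator = ms_config(), band = c(0.1, 30),
                       reject_threshold = 100, target_rate = NULL,
                       k_range = 3:10, n_cv_repeats = 50, n_restarts = 20,
                       cv_restarts = 5, cv_gfp_peaks = TRUE, edge_trim = 0.05,
                       graph_mode = "weighted", graph_threshold = 0,
                       seed = 1) {
  if (is.list(generator) && !inherits(generator, "ms_config")) {
    generator <- do.call(ms_config, generator)
  }
  cfg <- list(generator = generator, band = band,
              reject_threshold = reject_threshold,
              target_rate = target_rate %||% generator$sampling_rate,
              k_range = k_range, n_cv_repeats = n_cv_repeats,
              n_restarts = n_restarts, cv_restarts = cv_restarts,
              cv_gfp_peaks = cv_gfp_peaks,
              edge_trim = edge_trim, graph_mode = graph_mode,
              graph_threshold = graph_threshold, seed = seed)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param config a list to validate (e.g. parsed from JSON).
#' @export
validate_run_config <- function(config) {
  known <- c("generator", "band", "reject_threshold", "target_rate",
             "k_range", "n_cv_repeats", "n_restarts", "cv_restarts",
             "cv_gfp_peaks", "edge_trim", "graph_mode", "graph_threshold",
             "seed")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0L) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(known, names(config))
  if (length(missing) > 0L) {
    stop("missing config keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(config$generator, "ms_config")) {
    config$generator <- do.call(ms_config, config$generator)
  }
  if (!config$graph_mode %in% c("weighted", "binary")) {
    stop("`graph_mode` must be 'weighted' or 'binary'", call. = FALSE)
  }
  if (config$band[1] <= 0 || config$band[2] <= config$band[1]) {
    stop("`band` must be an increasing positive pair", call. = FALSE)
  }
  structure(config, class = "ms_run_config")
}

participant_seeds <- function(seed, n) {
  # deterministic per-participant streams derived from the master seed,
  # kept below 2^31
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}

#' Run the full microstate-connectivity pipeline on a synthetic cohort
#'
#' Generates a cohort under the configured design (ground-truth templates,
#' per-participant trial schedules and epochs), runs the preprocessing chain,
#' selects the number of microstate classes by split-half cross-validation,
#' aligns individual template sets into a global mean template (classes
#' renamed A, B, ... by descending total labeled time), back-fits it to every
#' participant-condition ERP for durations, computes microstate-gated PLV
#' networks and their graph metrics, simulates behavioural ratings, and runs
#' the mixed-design rmANOVA (with Bonferroni post-hocs) on ratings,
#' durations, Cp and Lp.
#'
#' @param config an \code{ms_run_config} from \code{\link{run_config}}.
#' @param out_dir optional output directory; when given, duration/graph/
#'   ANOVA tables are written as CSV and the run report as JSON.
#' @param verbose print one progress line per stage.
#' @return an \code{ms_run_report}: list with \code{selected_k},
#'   \code{durations}, \code{graph}, \code{ratings}, \code{anova},
#'   \code{counts}, \code{config}.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  config <- validate_run_config(config)
  gen <- config$generator
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  groups <- rep(names(gen$n_participants), gen$n_participants)
  n_part <- length(groups)
  seeds <- participant_seeds(config$seed, n_part + 2L)

  templates <- make_template_set(gen$n_channels, gen$n_templates,
                                 seed = seeds[n_part + 1L])
  say("simulate+preprocess: %d participants", n_part)
  erps <- vector("list", n_part)       # per participant: list by condition
  epochs_clean <- vector("list", n_part)
  counts <- data.frame()
  conds <- conditions_levels()
  for (i in seq_len(n_part)) {
    sch <- make_trial_schedule(gen, seed = seeds[i])
    sim <- simulate_erp(templates, sch, gen, seed = seeds[i],
                        participant_id = sprintf("P%03d", i),
                        group = groups[i])
    ep <- preprocess_epochs(sim$epochs, band = config$band,
                            baseline = c(gen$epoch_window[1], 0),
                            reject_threshold = config$reject_threshold,
                            target_rate = config$target_rate)
    rep_i <- attr(ep, "report")
    rep_i$participant_id <- sprintf("P%03d", i)
    counts <- rbind(counts, rep_i)
    epochs_clean[[i]] <- ep
    erps[[i]] <- lapply(conds, function(cc) average_erp(ep, cc))
    names(erps[[i]]) <- conds
  }

  say("cross-validated model selection (k in %s, %d repeats)",
      paste(range(config$k_range), collapse = ".."), config$n_cv_repeats)
  cv <- cross_validate_k(erps, k_range = config$k_range,
                         n_repeats = config$n_cv_repeats,
                         n_restarts = config$cv_restarts,
                         gfp_peaks_only = isTRUE(config$cv_gfp_peaks),
                         seed = seeds[n_part + 2L])
  k <- cv$k
  say("selected k = %d", k)

  say("individual clustering + permutation alignment")
  indiv <- vector("list", n_part)
  for (i in seq_len(n_part)) {
    maps <- do.call(rbind, lapply(erps[[i]], function(e) t(e$data)))
    indiv[[i]] <- kmeans_microstates(maps, k,
                                     n_restarts = config$n_restarts,
                                     seed = seeds[i])
  }
  ali <- align_templates(indiv)
  global <- ali$global

  # name classes by descending total labeled time in the pooled back-fit
  pooled_counts <- numeric(k)
  segs <- vector("list", n_part)
  for (i in seq_len(n_part)) {
    segs[[i]] <- lapply(erps[[i]], function(e) backfit(global, e))
    for (s in segs[[i]]) {
      pooled_counts <- pooled_counts + tabulate(s$labels, nbins = k)
    }
  }
  ord <- order(pooled_counts, decreasing = TRUE)
  global$maps <- global$maps[, ord, drop = FALSE]
  colnames(global$maps) <- LETTERS[seq_len(k)]
  relabel <- match(seq_len(k), ord)
  for (i in seq_len(n_part)) {
    segs[[i]] <- lapply(segs[[i]], function(s) {
      s$labels <- relabel[s$labels]
      s
    })
  }

  say("durations")
  dur_rows <- list()
  for (i in seq_len(n_part)) for (cc in conds) {
    d <- microstate_durations(segs[[i]][[cc]])
    dur_rows[[length(dur_rows) + 1L]] <- data.frame(
      participant_id = sprintf("P%03d", i), group = groups[i],
      condition = cc, class = names(d), duration_ms = as.numeric(d),
      stringsAsFactors = FALSE)
  }
  durations <- do.call(rbind, dur_rows)

  say("connectivity (PLV networks + graph metrics)")
  graph_rows <- list()
  for (i in seq_len(n_part)) {
    for (cc in conds) {
      idx <- which(epochs_clean[[i]]$condition == cc)
      sub <- epochs_clean[[i]]
      sub$data <- sub$data[idx, , , drop = FALSE]
      sub$condition <- sub$condition[idx]
      ph <- instantaneous_phase(sub, edge_trim = config$edge_trim)
      nets <- microstate_gated_plv(ph, segs[[i]][[cc]])
      for (cls in names(nets)) {
        if (isTRUE(nets[[cls]]$empty)) next
        gm <- graph_metrics(nets[[cls]], mode = config$graph_mode,
                            threshold = config$graph_threshold)
        graph_rows[[length(graph_rows) + 1L]] <- data.frame(
          participant_id = sprintf("P%03d", i), group = groups[i],
          condition = cc, class = cls, cp = gm$cp_mean, lp = gm$lp,
          stringsAsFactors = FALSE)
      }
    }
  }
  graph <- do.call(rbind, graph_rows)

  say("ratings + statistics")
  ratings <- simulate_ratings(groups = gen$n_participants,
                              seed = seeds[n_part + 2L])
  anova_tables <- list()
  rt <- ratings
  anova_tables[["valence"]] <- anova_with_posthoc(rt)
  for (cls in LETTERS[seq_len(k)]) {
    dsub <- durations[durations$class == cls,
                      c("participant_id", "group", "condition",
                        "duration_ms")]
    names(dsub)[4] <- "value"
    anova_tables[[paste0("duration_", cls)]] <- anova_with_posthoc(dsub)
    gsub_ <- graph[graph$class == cls, ]
    if (nrow(gsub_) == n_part * length(conds)) {
      for (metric in c("cp", "lp")) {
        msub <- gsub_[, c("participant_id", "group", "condition", metric)]
        names(msub)[4] <- "value"
        anova_tables[[paste0(metric, "_", cls)]] <- anova_with_posthoc(msub)
      }
    }
  }

  report <- structure(list(
    selected_k = k, cv = cv, global_templates = global,
    durations = durations, graph = graph, ratings = ratings,
    anova = anova_tables, counts = counts,
    config = config, version = as.character(utils::packageVersion("microconn"))
  ), class = "ms_run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

anova_with_posthoc <- function(table) {
  fit <- rm_anova_mixed(table, conditions = conditions_levels())
  ph <- if (isTRUE(fit$degenerate)) NULL else list(
    condition = bonferroni_posthoc(table, "condition",
                                   conditions_levels()),
    group = bonferroni_posthoc(table, "group", conditions_levels()),
    interaction = bonferroni_posthoc(table, "interaction",
                                     conditions_levels()))
  list(anova = fit, posthoc = ph)
}

anova_long_table <- function(anova_tables) {
  rows <- list()
  for (nm in names(anova_tables)) {
    eff <- anova_tables[[nm]]$anova$effects
    eff$measure <- nm
    rows[[nm]] <- eff[, c("measure", "effect", "F", "df1", "df2", "p",
                          "gg_applied")]
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$durations,
                   file.path(out_dir, "durations.csv"), row.names = FALSE)
  utils::write.csv(report$graph,
                   file.path(out_dir, "graph_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ratings,
                   file.path(out_dir, "ratings.csv"), row.names = FALSE)
  utils::write.csv(anova_long_table(report$anova),
                   file.path(out_dir, "anova.csv"), row.names = FALSE)
  cfg <- report$config
  snap <- list(selected_k = report$selected_k, version = report$version,
               seed = cfg$seed,
               config = unclass_deep(cfg))
  jsonlite::write_json(snap, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.ms_run_report <- function(x, ...) {
  cat(sprintf("microconn run: %d participants, selected k = %d\n",
              length(unique(x$durations$participant_id)), x$selected_k))
  cat("ANOVA tables:", paste(names(x$anova), collapse = ", "), "\n")
  invisible(x)
}
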