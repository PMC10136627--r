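# Microstate analysis: GFP, polarity-sensitive topographic K-means, GEV,
# split-half cross-validated choice of the number of classes, permutation
# alignment into a global mean template, back-fitting, durations.

#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp potentials at time
#' t: \code{sqrt(mean((V_i(t) - Vbar(t))^2))} over the N electrodes. It is
#' nonnegative, invariant under re-referencing, and zero only when all
#' channels agree.
#'
#' @param x an \code{ms_erp} or a \code{channels x samples} matrix.
#' @return numeric vector of GFP values, one per sample.
#' @export
compute_gfp <- function(x) {
  m <- if (inherits(x, "ms_erp")) x$data else x
  if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
  if (nrow(m) < 2L) {
    stop("GFP is undefined for fewer than 2 channels", call. = FALSE)
  }
  m <- center_columns(m)
  sqrt(colMeans(m^2))
}

#' Indices of local GFP maxima
#'
#' @param gfp numeric GFP curve.
#' @return integer vector of strict local maxima (interior samples).
#' @export
gfp_peaks <- function(gfp) {
  n <- length(gfp)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  i[gfp[i] > gfp[i - 1L] & gfp[i] >= gfp[i + 1L]]
}

#' Signed spatial correlation between two scalp maps
#'
#' Pearson correlation across channels of the average-referenced maps.
#' Polarity is preserved: a map and its negation correlate at -1.
#'
#' @param map1,map2 numeric channel vectors of equal length.
#' @return correlation in \code{[-1, 1]}.
#' @export
spatial_correlation <- function(map1, map2) {
  drop(map_correlation(matrix(map1, 1L), matrix(map2, ncol = 1L)))
}

new_ms_templates <- function(maps, scope, gev = NA_real_, extra = list()) {
  maps <- scale_unit_gfp(maps)
  colnames(maps) <- LETTERS[seq_len(ncol(maps))]
  structure(c(list(maps = maps, labels = colnames(maps), scope = scope,
                   gev = gev), extra),
            class = "ms_templates")
}

#' Polarity-sensitive topographic K-means clustering
#'
#' Modified K-means on scalp maps using the signed spatial correlation as
#' similarity: unlike polarity-invariant microstate clustering, a map and its
#' negation belong to different classes, as appropriate for time-locked ERP
#' components. Each iteration assigns every map to the template of maximum
#' signed correlation and recomputes each template as the GFP^2-weighted mean
#' direction of its members, renormalised to unit GFP; an empty class is
#' reseeded at the currently worst-fit map. Iterations stop when the
#' assignment is stable or the objective improves by less than \code{tol};
#' the best of \code{n_restarts} random initialisations by GEV is returned.
#'
#' @param maps \code{n_maps x channels} matrix of instantaneous topographies.
#' @param k number of classes (at most \code{nrow(maps)}).
#' @param n_restarts random restarts (default 20).
#' @param seed integer seed.
#' @param max_iter iteration cap per restart.
#' @param tol convergence tolerance on the objective.
#' @return an \code{ms_templates} (scope \code{"individual"}) with fields
#'   \code{maps} (channels x k, unit GFP), \code{gev}, \code{assignment},
#'   and per-iteration traces \code{objective_trace} and \code{gev_trace}
#'   for the winning restart.
#' @export
kmeans_microstates <- function(maps, k, n_restarts = 20, seed = NULL,
                               max_iter = 500, tol = 1e-6) {
  if (nrow(maps) < k) stop("`k` exceeds the number of maps", call. = FALSE)
  if (k < 1) stop("`k` must be positive", call. = FALSE)
  gfp <- sqrt(rowMeans((maps - rowMeans(maps))^2))
  w <- gfp^2
  xn <- normalize_rows(maps)
  wsum <- sum(w)
  if (wsum == 0) stop("all maps are constant; nothing to cluster",
                      call. = FALSE)
  # k-means++-style seeding in correlation distance: subsequent seeds are
  # drawn with probability proportional to (1 - max corr to chosen seeds)^2,
  # which makes degenerate initialisations (two seeds in one class) rare.
  seed_centroids <- function() {
    idx <- integer(k)
    idx[1] <- sample.int(nrow(xn), 1L, prob = w)
    if (k > 1L) {
      d <- 1 - tcrossprod(xn, xn[idx[1], , drop = FALSE])[, 1]
      for (j in 2:k) {
        p <- pmax(d, 0)^2 * w
        if (sum(p) <= 0) p <- rep(1, length(d))
        idx[j] <- sample.int(nrow(xn), 1L, prob = p)
        d <- pmin(d, 1 - tcrossprod(xn, xn[idx[j], , drop = FALSE])[, 1])
      }
    }
    xn[idx, , drop = FALSE]
  }
  with_seed(seed, {
    best <- NULL
    for (rs in seq_len(n_restarts)) {
      cn <- seed_centroids()
      assign_prev <- rep(0L, nrow(xn))
      obj_trace <- numeric(); gev_trace <- numeric()
      obj_prev <- -Inf
      for (it in seq_len(max_iter)) {
        r <- tcrossprod(xn, cn)
        assign <- max.col(r, ties.method = "first")
        rwin <- r[cbind(seq_len(nrow(r)), assign)]
        for (j in seq_len(k)) {      # reseed empty classes at worst-fit map
          if (!any(assign == j)) {
            worst <- which.min(rwin)
            assign[worst] <- j
            rwin[worst] <- 1
          }
        }
        obj <- sum(w * rwin) / wsum
        gev_trace <- c(gev_trace, sum(w * rwin^2) / wsum)
        obj_trace <- c(obj_trace, obj)
        if (identical(assign, assign_prev) || abs(obj - obj_prev) < tol) {
          assign_prev <- assign
          break
        }
        assign_prev <- assign
        obj_prev <- obj
        for (j in seq_len(k)) {
          members <- which(assign == j)
          cj <- colSums(xn[members, , drop = FALSE] * w[members])
          nrm <- sqrt(sum(cj^2))
          if (nrm > 0) cn[j, ] <- cj / nrm
        }
      }
      r <- tcrossprod(xn, cn)
      assign <- max.col(r, ties.method = "first")
      rwin <- r[cbind(seq_len(nrow(r)), assign)]
      gev <- sum(w * rwin^2) / wsum
      if (is.null(best) || gev > best$gev) {
        best <- list(cn = cn, assign = assign, gev = gev,
                     obj_trace = obj_trace, gev_trace = gev_trace)
      }
    }
    new_ms_templates(t(best$cn), scope = "individual", gev = best$gev,
                     extra = list(assignment = best$assign,
                                  objective_trace = best$obj_trace,
                                  gev_trace = best$gev_trace))
  })
}

#' Global explained variance of a labelled segmentation
#'
#' \code{GEV = sum_t (GFP(t) * corr(map_t, template_label(t)))^2 /
#' sum_t GFP(t)^2}: the GFP^2-weighted share of topographic variance captured
#' by assigning each map to its template. Lies in \code{[0, 1]}; equals 1
#' exactly when every map is collinear with its assigned template.
#'
#' @param maps \code{n_maps x channels} matrix.
#' @param templates \code{channels x k} template matrix.
#' @param labels integer class per map (index into template columns).
#' @return GEV fraction.
#' @export
compute_gev <- function(maps, templates, labels) {
  gfp <- sqrt(rowMeans((maps - rowMeans(maps))^2))
  r <- map_correlation(maps, templates)
  rwin <- r[cbind(seq_len(nrow(maps)), labels)]
  sum((gfp * rwin)^2) / sum(gfp^2)
}

#' Back-fit templates to an ERP
#'
#' Labels every sample's topography with the template class of maximum
#' signed spatial correlation. Ties keep the previous sample's label when it
#' is among the tied classes (temporal smoothness), otherwise the lowest
#' class index.
#'
#' @param templates an \code{ms_templates} or a \code{channels x k} matrix.
#' @param erp an \code{ms_erp} or \code{channels x samples} matrix.
#' @return an \code{ms_segmentation}: list with integer \code{labels},
#'   per-sample winning \code{correlation}, \code{k}, \code{times} and
#'   \code{sampling_rate} (when available).
#' @export
backfit <- function(templates, erp) {
  tpl <- if (inherits(templates, "ms_templates")) templates$maps else templates
  m <- if (inherits(erp, "ms_erp")) erp$data else erp
  r <- map_correlation(t(m), tpl)
  labels <- max.col(r, ties.method = "first")
  mx <- r[cbind(seq_len(nrow(r)), labels)]
  for (t in seq_along(labels)) {       # tie rule: prefer previous label
    tied <- which(r[t, ] >= mx[t] - 0)
    if (length(tied) > 1L && t > 1L && labels[t - 1L] %in% tied) {
      labels[t] <- labels[t - 1L]
      mx[t] <- r[t, labels[t]]
    }
  }
  structure(list(labels = labels, correlation = mx, k = ncol(tpl),
                 times = if (inherits(erp, "ms_erp")) erp$times else NULL,
                 sampling_rate = if (inherits(erp, "ms_erp"))
                   erp$sampling_rate else NULL),
            class = "ms_segmentation")
}

#' Total duration of each microstate class
#'
#' \code{duration(class) = n_samples(class) * 1000 / sampling_rate} ms.
#' Classes never visited get 0; durations over all classes sum to the epoch
#' length.
#'
#' @param segmentation an \code{ms_segmentation} from \code{\link{backfit}}.
#' @param sampling_rate Hz; defaults to the rate stored on the segmentation.
#' @return named numeric vector of per-class durations in ms.
#' @export
microstate_durations <- function(segmentation, sampling_rate = NULL) {
  fs <- sampling_rate %||% segmentation$sampling_rate
  if (is.null(fs)) stop("`sampling_rate` is required", call. = FALSE)
  k <- segmentation$k
  counts <- tabulate(segmentation$labels, nbins = k)
  stats::setNames(counts * 1000 / fs, LETTERS[seq_len(k)])
}

#' Split-half cross-validated selection of the number of microstates
#'
#' For each of \code{n_repeats} repeats the participants are split at random
#' into a training and a testing half; the pooled training topographies are
#' clustered at every k in \code{k_range} and the resulting templates are
#' back-fitted to the pooled testing topographies, recording the test-set
#' GEV. Because back-fitting takes a maximum over templates, the raw test
#' GEV is non-decreasing in k and cannot by itself locate an optimum; the
#' selected k therefore minimises the predictive-residual criterion
#' \code{(1 - testGEV) * ((C - 1) / (C - 1 - k))^2} (C = channel count),
#' the standard cross-validation criterion of microstate analysis, which
#' penalises the degrees of freedom consumed by additional template maps.
#' Per-repeat criteria are aggregated by the median, so an occasional poor
#' clustering solution in one split cannot dominate the selection; ties go
#' to the smallest k.
#'
#' @param erps list with one element per participant: an \code{ms_erp}, a
#'   \code{channels x samples} matrix, or a list of either (e.g. one ERP per
#'   condition, pooled within participant). At least 4 participants.
#' @param k_range candidate numbers of classes (default 3:10).
#' @param n_repeats number of random splits (default 50).
#' @param split training fraction (default 0.5).
#' @param n_restarts K-means restarts per fit (default 5).
#' @param seed integer seed.
#' @param gfp_peaks_only cluster only topographies at local GFP maxima
#'   instead of all samples.
#' @return list with \code{k} (selected), \code{scores} (data.frame:
#'   repeat_id, k, test_gev, cv_criterion) and \code{summary} (per-k mean
#'   test GEV and median criterion).
#' @export
cross_validate_k <- function(erps, k_range = 3:10, n_repeats = 50,
                             split = 0.5, n_restarts = 5, seed = NULL,
                             gfp_peaks_only = FALSE) {
  n <- length(erps)
  if (n < 4L) stop("need at least 4 participants", call. = FALSE)
  part_maps <- lapply(erps, function(e) {
    mats <- if (inherits(e, "ms_erp")) list(e$data)
            else if (is.matrix(e)) list(e)
            else lapply(e, function(x) if (inherits(x, "ms_erp")) x$data
                        else x)
    maps <- do.call(rbind, lapply(mats, t))   # samples x channels
    if (gfp_peaks_only) {
      g <- compute_gfp(t(maps))
      pk <- gfp_peaks(g)
      if (length(pk) >= 2L) maps <- maps[pk, , drop = FALSE]
    }
    maps
  })
  n_train <- round(split * n)
  if (n_train < 2L || n - n_train < 2L) {
    stop("each half must contain at least 2 participants", call. = FALSE)
  }
  n_ch <- ncol(part_maps[[1]])
  if (max(k_range) >= n_ch - 1L) {
    stop("`k_range` must stay below n_channels - 1", call. = FALSE)
  }
  with_seed(seed, {
    rows <- vector("list", n_repeats * length(k_range))
    ri <- 0L
    for (rep_i in seq_len(n_repeats)) {
      ord <- sample.int(n)
      train <- do.call(rbind, part_maps[ord[seq_len(n_train)]])
      test <- do.call(rbind, part_maps[ord[(n_train + 1L):n]])
      for (k in k_range) {
        fit <- kmeans_microstates(train, k, n_restarts = n_restarts)
        seg <- backfit(fit, t(test))
        gev <- compute_gev(test, fit$maps, seg$labels)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          repeat_id = rep_i, k = k, test_gev = gev,
          cv_criterion = (1 - gev) * ((n_ch - 1) / (n_ch - 1 - k))^2)
      }
    }
    scores <- do.call(rbind, rows)
    means <- tapply(scores$test_gev, scores$k, mean)
    crits <- tapply(scores$cv_criterion, scores$k, stats::median)
    ks <- as.integer(names(means))
    k_best <- ks[which.min(crits)]    # which.min takes the first minimum,
    list(k = k_best,                  # i.e. the smallest k on ties
         scores = scores,
         summary = data.frame(k = ks, mean_test_gev = as.numeric(means),
                              median_criterion = as.numeric(crits)))
  })
}

#' Align individual template sets into a global mean template
#'
#' Iterative permutation alignment: given a provisional mean set, each
#' participant's classes are matched to the mean classes by the permutation
#' maximising the total signed spatial correlation (polarity is honoured: a
#' sign-flipped map is not the same class); the mean maps are then recomputed
#' from the permuted individual maps and renormalised. Repeats until the
#' permutations stop changing.
#'
#' @param individual_sets list of \code{ms_templates} (or channels x k
#'   matrices), all with the same k.
#' @param max_iter iteration cap (default 100).
#' @return list with \code{global} (an \code{ms_templates}, scope
#'   \code{"global"}) and \code{permutations} (participants x k integer
#'   matrix: column j of the global set matches column perm[i, j] of
#'   participant i's set).
#' @export
align_templates <- function(individual_sets, max_iter = 100) {
  mats <- lapply(individual_sets, function(s) {
    if (inherits(s, "ms_templates")) s$maps else s
  })
  ks <- vapply(mats, ncol, integer(1))
  if (length(unique(ks)) != 1L) {
    stop("all participants must have the same number of classes",
         call. = FALSE)
  }
  k <- ks[1]
  mean_maps <- scale_unit_gfp(mats[[1]])
  perms <- matrix(rep(seq_len(k), length(mats)), nrow = length(mats),
                  byrow = TRUE)
  for (it in seq_len(max_iter)) {
    new_perms <- perms
    for (i in seq_along(mats)) {
      r <- map_correlation(t(mean_maps), mats[[i]])  # k_mean x k_i
      new_perms[i, ] <- best_assignment(r)$perm
    }
    acc <- matrix(0, nrow(mean_maps), k)
    for (i in seq_along(mats)) {
      acc <- acc + scale_unit_gfp(mats[[i]][, new_perms[i, ], drop = FALSE])
    }
    mean_maps <- scale_unit_gfp(acc / length(mats))
    if (identical(new_perms, perms) && it > 1L) break
    perms <- new_perms
  }
  list(global = new_ms_templates(mean_maps, scope = "global"),
       permutations = perms)
}

#' Match estimated templates to reference templates
#'
#' Optimal one-to-one assignment (over permutations) between two template
#' sets, maximising total signed spatial correlation; used to score template
#' recovery.
#'
#' @param estimated,reference \code{channels x k} matrices or
#'   \code{ms_templates}.
#' @return list with \code{perm} (estimated column matched to each reference
#'   column), \code{correlations} per matched pair, and their \code{mean}.
#' @export
match_templates <- function(estimated, reference) {
  a <- if (inherits(estimated, "ms_templates")) estimated$maps else estimated
  b <- if (inherits(reference, "ms_templates")) reference$maps else reference
  r <- map_correlation(t(b), a)        # reference x estimated
  asg <- best_assignment(r)
  cors <- r[cbind(seq_len(nrow(r)), asg$perm)]
  list(perm = asg$perm, correlations = cors, mean = mean(cors))
}
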