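# Mixed-design repeated-measures ANOVA (within: Condition, between: Group)
# with Mauchly's sphericity test, Greenhouse-Geisser correction and
# Bonferroni post-hoc comparisons.

# Reshape a long measurement table (participant_id, group, condition, value)
# to an n x k wide matrix plus the group factor; errors on incomplete cells.
measurement_wide <- function(table, conditions = NULL) {
  req <- c("participant_id", "group", "condition", "value")
  if (!all(req %in% names(table))) {
    stop("table needs columns participant_id, group, condition, value",
         call. = FALSE)
  }
  conds <- conditions %||% sort(unique(table$condition))
  ids <- unique(table$participant_id)
  y <- matrix(NA_real_, length(ids), length(conds),
              dimnames = list(ids, conds))
  grp <- character(length(ids))
  for (i in seq_along(ids)) {
    sub <- table[table$participant_id == ids[i], ]
    grp[i] <- sub$group[1]
    for (j in seq_along(conds)) {
      v <- sub$value[sub$condition == conds[j]]
      if (length(v) != 1L) {
        stop(sprintf("participant %s: need exactly one value for '%s'",
                     ids[i], conds[j]), call. = FALSE)
      }
      y[i, j] <- v
    }
  }
  list(y = y, group = factor(grp), conditions = conds, ids = ids)
}

# Orthonormal contrasts spanning the space orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

#' Mauchly's test of sphericity for the within-subject factor
#'
#' Tests whether the covariance of the orthonormally contrasted condition
#' scores is spherical, using the chi-square approximation on the pooled
#' within-group residual covariance. With only two within levels sphericity
#' holds trivially (W = 1, p = 1).
#'
#' @param table long measurement table with columns \code{participant_id},
#'   \code{group}, \code{condition}, \code{value}.
#' @param conditions within-factor level order (default: sorted unique).
#' @return list with \code{W}, \code{p}, \code{df}.
#' @export
mauchly_test <- function(table, conditions = NULL) {
  wd <- measurement_wide(table, conditions)
  mauchly_from_wide(wd$y, wd$group)
}

mauchly_from_wide <- function(y, group) {
  k <- ncol(y)
  n <- nrow(y)
  p <- k - 1L
  if (p < 2L) return(list(W = 1, p = 1, df = 0L))
  m <- orthonormal_contrasts(k)
  yw <- y %*% m
  x <- stats::model.matrix(~group)
  r <- qr.resid(qr(x), yw)
  s <- crossprod(r) / (n - ncol(x))
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev)) {
    stop("singular within-subject covariance; sphericity test undefined",
         call. = FALSE)
  }
  W <- det(s) / (sum(diag(s)) / p)^p
  nr <- n - ncol(x)
  f <- 1 - (2 * p^2 + p + 2) / (6 * p * nr)
  chi2 <- -nr * f * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, p = stats::pchisq(chi2, df, lower.tail = FALSE), df = df)
}

# Greenhouse-Geisser epsilon from the pooled residual covariance of the
# contrasted scores (orthonormal contrasts).
gg_epsilon_from_wide <- function(y, group) {
  k <- ncol(y)
  p <- k - 1L
  m <- orthonormal_contrasts(k)
  yw <- y %*% m
  x <- stats::model.matrix(~group)
  r <- qr.resid(qr(x), yw)
  s <- crossprod(r) / (nrow(y) - ncol(x))
  sum(diag(s))^2 / (p * sum(s^2))
}

#' Mixed-design repeated-measures ANOVA
#'
#' Split-plot ANOVA with one within-subject factor (condition, k levels) and
#' one between-subject factor (group, 2 levels), on complete data. Between
#' and within strata are computed via orthonormal within-subject contrasts
#' and Type III linear hypotheses (sum-to-zero group coding), matching
#' standard statistical-software conventions for unbalanced group sizes.
#' When Mauchly's test rejects sphericity at 0.05 (mode \code{"auto"}), the
#' degrees of freedom of the within effects are multiplied by the
#' Greenhouse-Geisser epsilon, giving fractional df as in
#' \code{F(1.391, 70)}-style reports.
#'
#' @param table long measurement table (\code{participant_id}, \code{group},
#'   \code{condition}, \code{value}), complete cases, one value per
#'   participant and condition.
#' @param conditions within-factor level order.
#' @param gg \code{"auto"} (apply when Mauchly p < 0.05), \code{"always"},
#'   or \code{"never"}.
#' @return an object of class \code{ms_anova}: list with \code{effects}
#'   (data.frame: effect, F, df1, df2, p, gg_applied), \code{mauchly},
#'   \code{epsilon}, \code{degenerate} flag.
#' @export
rm_anova_mixed <- function(table, conditions = NULL,
                           gg = c("auto", "always", "never")) {
  gg <- match.arg(gg)
  wd <- measurement_wide(table, conditions)
  y <- wd$y
  group <- wd$group
  n <- nrow(y)
  k <- ncol(y)
  if (nlevels(group) != 2L) {
    stop("`group` must have exactly 2 levels", call. = FALSE)
  }
  if (any(table(group) < 2L)) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  if (stats::sd(as.numeric(y)) == 0) {
    eff <- data.frame(effect = c("condition", "group", "condition:group"),
                      F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                      p = NA_real_, gg_applied = FALSE)
    return(structure(list(effects = eff, mauchly = list(W = NA, p = NA),
                          epsilon = NA_real_, degenerate = TRUE),
                     class = "ms_anova"))
  }
  x <- stats::model.matrix(~group, contrasts.arg = list(group = "contr.sum"))
  qx <- qr(x)
  xtxi <- chol2inv(qr.R(qx))

  type3_ss <- function(yv, coef_idx) {
    # Type III SS for one coefficient row, summed over response columns
    b <- qr.coef(qx, yv)
    l <- matrix(0, 1L, ncol(x)); l[1, coef_idx] <- 1
    v <- drop(l %*% xtxi %*% t(l))
    sum((l %*% b)^2) / v
  }

  # Between stratum: participant means
  ybar <- rowMeans(y)
  ssw_g <- k * type3_ss(matrix(ybar, ncol = 1L), 2L)
  res_b <- qr.resid(qx, matrix(ybar, ncol = 1L))
  sse_b <- k * sum(res_b^2)
  df_b <- n - 2L
  f_group <- (ssw_g / 1) / (sse_b / df_b)
  p_group <- stats::pf(f_group, 1, df_b, lower.tail = FALSE)

  # Within stratum: orthonormal contrast scores
  m <- orthonormal_contrasts(k)
  yw <- y %*% m
  ss_cond <- type3_ss(yw, 1L)
  ss_inter <- type3_ss(yw, 2L)
  sse_w <- sum(qr.resid(qx, yw)^2)
  df1 <- k - 1L
  df2 <- (n - 2L) * (k - 1L)
  f_cond <- (ss_cond / df1) / (sse_w / df2)
  f_inter <- (ss_inter / df1) / (sse_w / df2)

  mau <- mauchly_from_wide(y, group)
  eps <- gg_epsilon_from_wide(y, group)
  apply_gg <- switch(gg, always = TRUE, never = FALSE,
                     auto = is.finite(mau$p) && mau$p < 0.05)
  d1 <- if (apply_gg) df1 * eps else df1
  d2 <- if (apply_gg) df2 * eps else df2
  p_cond <- stats::pf(f_cond, d1, d2, lower.tail = FALSE)
  p_inter <- stats::pf(f_inter, d1, d2, lower.tail = FALSE)

  eff <- data.frame(
    effect = c("condition", "group", "condition:group"),
    F = c(f_cond, f_group, f_inter),
    df1 = c(d1, 1, d1),
    df2 = c(d2, df_b, d2),
    p = c(p_cond, p_group, p_inter),
    gg_applied = c(apply_gg, FALSE, apply_gg),
    stringsAsFactors = FALSE
  )
  structure(list(effects = eff, mauchly = mau, epsilon = eps,
                 degenerate = FALSE,
                 ss = list(condition = ss_cond, group = ssw_g,
                           interaction = ss_inter, error_within = sse_w,
                           error_between = sse_b)),
            class = "ms_anova")
}

#' @export
print.ms_anova <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate data: all values identical; F undefined\n")
    return(invisible(x))
  }
  cat("Mixed-design repeated-measures ANOVA\n")
  cat(sprintf("Mauchly W = %.4f, p = %.4f; GG epsilon = %.4f\n",
              x$mauchly$W, x$mauchly$p, x$epsilon))
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    cat(sprintf("%-16s F(%.3f, %.3f) = %.3f, p = %.4g%s\n", e$effect,
                e$df1, e$df2, e$F, e$p,
                if (e$gg_applied) " (GG-corrected)" else ""))
  }
  invisible(x)
}

#' Bonferroni-corrected post-hoc comparisons
#'
#' Pairwise follow-up tests for one effect of the mixed design: paired
#' t-tests between condition pairs (within effect), an independent t-test
#' between groups (between effect), or independent group comparisons within
#' each condition (interaction). Each raw p is multiplied by the number of
#' comparisons for the effect and capped at 1.
#'
#' @param table long measurement table.
#' @param effect \code{"condition"}, \code{"group"} or
#'   \code{"interaction"}.
#' @param conditions within-factor level order.
#' @return data.frame with \code{comparison}, \code{estimate}, \code{t},
#'   \code{df}, \code{p}, \code{p_adj}.
#' @export
bonferroni_posthoc <- function(table,
                               effect = c("condition", "group",
                                          "interaction"),
                               conditions = NULL) {
  effect <- match.arg(effect)
  wd <- measurement_wide(table, conditions)
  y <- wd$y; group <- wd$group; conds <- wd$conditions
  rows <- list()
  if (effect == "condition") {
    prs <- utils::combn(seq_along(conds), 2L)
    for (c_i in seq_len(ncol(prs))) {
      a <- prs[1, c_i]; b <- prs[2, c_i]
      tt <- stats::t.test(y[, a], y[, b], paired = TRUE)
      rows[[c_i]] <- data.frame(
        comparison = paste(conds[a], "vs", conds[b]),
        estimate = unname(tt$estimate), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value)
    }
  } else if (effect == "group") {
    g <- levels(group)
    tt <- stats::t.test(rowMeans(y)[group == g[1]],
                        rowMeans(y)[group == g[2]], var.equal = TRUE)
    rows[[1]] <- data.frame(comparison = paste(g[1], "vs", g[2]),
                            estimate = unname(diff(rev(tt$estimate))),
                            t = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value)
  } else {
    g <- levels(group)
    for (j in seq_along(conds)) {
      tt <- stats::t.test(y[group == g[1], j], y[group == g[2], j],
                          var.equal = TRUE)
      rows[[j]] <- data.frame(
        comparison = sprintf("%s vs %s | %s", g[1], g[2], conds[j]),
        estimate = unname(diff(rev(tt$estimate))),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}
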