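# Brute-force split-plot oracle: explicit design-matrix projections with
# sum-to-zero coding, orthonormal within contrasts and Type III hypotheses.
# Independent of rm_anova_mixed's internals (no shared helper calls).
oracle_rm_anova <- function(table, conditions = c("Neg", "Neu", "Rea")) {
  wide <- reshape(table, idvar = c("participant_id", "group"),
                  timevar = "condition", direction = "wide")
  y <- as.matrix(wide[, paste0("value.", conditions)])
  g <- factor(wide$group)
  n <- nrow(y)
  k <- ncol(y)
  gi <- ifelse(g == levels(g)[1], 1, -1)
  x <- cbind(1, gi)
  proj_ss <- function(resp, col) {
    # SS of the Type III hypothesis that coefficient `col` is zero, summed
    # over response columns: (L b)' (L (X'X)^-1 L')^-1 (L b)
    xtxi <- solve(t(x) %*% x)
    b <- xtxi %*% t(x) %*% resp
    l <- matrix(0, 1, 2); l[1, col] <- 1
    sum(vapply(seq_len(ncol(resp)), function(v) {
      drop((l %*% b[, v])^2 / (l %*% xtxi %*% t(l)))
    }, numeric(1)))
  }
  resid_ss <- function(resp) {
    h <- x %*% solve(t(x) %*% x) %*% t(x)
    sum(((diag(n) - h) %*% resp)^2)
  }
  cm <- contr.helmert(k)
  cm <- sweep(cm, 2, sqrt(colSums(cm^2)), "/")
  yw <- y %*% cm
  ybar <- matrix(rowMeans(y), ncol = 1)
  f_group <- (k * proj_ss(ybar, 2) / 1) / (k * resid_ss(ybar) / (n - 2))
  f_cond <- (proj_ss(yw, 1) / (k - 1)) /
    (resid_ss(yw) / ((n - 2) * (k - 1)))
  f_inter <- (proj_ss(yw, 2) / (k - 1)) /
    (resid_ss(yw) / ((n - 2) * (k - 1)))
  c(condition = f_cond, group = f_group, interaction = f_inter)
}

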