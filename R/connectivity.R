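# Phase-locking-value connectivity gated by microstate labels, and graph
# metrics of the resulting networks.

# Analytic signal of a real vector via the frequency-domain construction:
# positive frequencies doubled, negative zeroed.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of epoched signals
#'
#' Computes the analytic signal of every trial and channel (Hilbert
#' transform) and returns its phase angle. Assumes band-limited input (run
#' the preprocessing chain first). A fraction of samples at each epoch edge
#' is flagged unreliable, since the analytic signal is distorted there.
#'
#' @param epochs an \code{ms_epochs}.
#' @param edge_trim fraction of samples flagged at each edge (default 0.05).
#' @return an \code{ms_phase}: list with \code{phase} (trials x channels x
#'   samples, radians in (-pi, pi]), \code{valid} (logical per sample),
#'   \code{times}, \code{sampling_rate}.
#' @export
instantaneous_phase <- function(epochs, edge_trim = 0.05) {
  d <- epochs$data
  if (length(d) == 0L || dim(d)[1] == 0L) stop("no epochs", call. = FALSE)
  if (all(d == 0)) {
    stop("zero signal: instantaneous phase is undefined", call. = FALSE)
  }
  ph <- array(0, dim = dim(d))
  for (tr in seq_len(dim(d)[1])) for (ch in seq_len(dim(d)[2])) {
    ph[tr, ch, ] <- Arg(analytic_signal(d[tr, ch, ]))
  }
  ns <- dim(d)[3]
  trim <- floor(edge_trim * ns)
  valid <- rep(TRUE, ns)
  if (trim > 0) {
    valid[seq_len(trim)] <- FALSE
    valid[(ns - trim + 1L):ns] <- FALSE
  }
  structure(list(phase = ph, valid = valid, times = epochs$times,
                 sampling_rate = epochs$sampling_rate),
            class = "ms_phase")
}

#' Phase-locking value time course for one channel pair
#'
#' \code{PLV(t) = |mean over trials of exp(i * (phi(t) - psi(t)))|}: the
#' modulus of the across-trials mean unit phasor of the phase difference.
#' Equals 1 for perfectly locked phases at a sample, and tends to 0 for
#' inconsistent phase relations as the trial count grows.
#'
#' @param phase an \code{ms_phase}.
#' @param pair integer vector of two channel indices.
#' @return numeric vector of PLV in \code{[0, 1]}, one per sample.
#' @export
plv_timecourse <- function(phase, pair) {
  ph <- phase$phase
  if (dim(ph)[1] < 1L) stop("need at least one trial", call. = FALSE)
  dphi <- ph[, pair[1], , drop = FALSE] - ph[, pair[2], , drop = FALSE]
  z <- exp(1i * dphi)
  as.numeric(Mod(apply(z, 3L, mean)))
}

# Full channels x channels x samples PLV array via one complex cross-product
# per sample.
plv_array <- function(phase) {
  ph <- phase$phase
  nt <- dim(ph)[1]; nch <- dim(ph)[2]; ns <- dim(ph)[3]
  out <- array(0, dim = c(nch, nch, ns))
  for (t in seq_len(ns)) {
    z <- exp(1i * ph[, , t, drop = FALSE][, , 1, drop = TRUE])
    if (nt == 1L) z <- matrix(z, nrow = 1L)
    m <- Mod(crossprod(Conj(z), z)) / nt
    out[, , t] <- m
  }
  out
}

#' Average PLV networks per microstate class
#'
#' Computes the per-sample all-pairs PLV matrix and averages it over the
#' samples carrying each microstate label (edge-flagged samples excluded),
#' yielding one connectivity network per microstate.
#'
#' @param phase an \code{ms_phase} whose time axis matches
#'   \code{segmentation}.
#' @param segmentation an \code{ms_segmentation} from \code{\link{backfit}}.
#' @return named list (class letters) of \code{ms_plv_network}s: symmetric
#'   \code{adjacency} in \code{[0,1]} with zero diagonal, \code{microstate},
#'   \code{n_trials}, \code{n_samples} (gated samples averaged). A class
#'   with no gated samples yields \code{n_samples = 0}, \code{empty = TRUE}
#'   and an all-NA adjacency.
#' @export
microstate_gated_plv <- function(phase, segmentation) {
  if (dim(phase$phase)[3] != length(segmentation$labels)) {
    stop("segmentation and phase tensor have different time axes",
         call. = FALSE)
  }
  arr <- plv_array(phase)
  k <- segmentation$k
  nt <- dim(phase$phase)[1]
  out <- vector("list", k)
  names(out) <- LETTERS[seq_len(k)]
  for (j in seq_len(k)) {
    idx <- which(segmentation$labels == j & phase$valid)
    if (length(idx) == 0L) {
      adj <- matrix(NA_real_, dim(arr)[1], dim(arr)[2])
      out[[j]] <- structure(list(adjacency = adj, microstate = names(out)[j],
                                 n_trials = nt, n_samples = 0L,
                                 empty = TRUE),
                            class = "ms_plv_network")
      next
    }
    adj <- apply(arr[, , idx, drop = FALSE], c(1L, 2L), mean)
    diag(adj) <- 0
    out[[j]] <- structure(list(adjacency = adj, microstate = names(out)[j],
                               n_trials = nt, n_samples = length(idx),
                               empty = FALSE),
                          class = "ms_plv_network")
  }
  out
}

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("adjacency must be square", call. = FALSE)
  }
  if (any(adj < 0)) stop("adjacency weights must be nonnegative",
                         call. = FALSE)
  if (max(abs(adj - t(adj))) > 1e-10) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  adj
}

#' Clustering coefficient of a connectivity network
#'
#' Binary mode thresholds the weights and counts, per node, the fraction of
#' realised triangles among its neighbours. Weighted mode uses the
#' geometric-mean triangle intensity on weights normalised by the maximum
#' weight, divided by \code{k (k - 1)} with k the node degree. The mean Cp
#' over nodes indexes local information processing.
#'
#' @param adjacency symmetric nonnegative matrix, zero diagonal.
#' @param mode \code{"weighted"} (default) or \code{"binary"}.
#' @param threshold edge threshold; weights \code{<= threshold} are treated
#'   as absent (binary mode; default 0).
#' @return list with \code{cp_per_node} and \code{cp_mean}.
#' @export
clustering_coefficient <- function(adjacency, mode = c("weighted", "binary"),
                                   threshold = 0) {
  mode <- match.arg(mode)
  adj <- check_adjacency(adjacency)
  diag(adj) <- 0
  if (mode == "binary") {
    a <- (adj > threshold) * 1
    deg <- rowSums(a)
    tri <- diag(a %*% a %*% a) / 2
    denom <- deg * (deg - 1) / 2
    cp <- ifelse(denom > 0, tri / denom, 0)
  } else {
    mx <- max(adj)
    wn <- if (mx > 0) adj / mx else adj
    w3 <- wn^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3) / 2
    deg <- rowSums(adj > 0)
    denom <- deg * (deg - 1) / 2
    cp <- ifelse(denom > 0, tri / denom, 0)
  }
  list(cp_per_node = as.numeric(cp), cp_mean = mean(cp))
}

#' Characteristic path length of a connectivity network
#'
#' Edge lengths are \code{1/weight} in weighted mode (stronger coupling =
#' shorter path) and 1 in binary mode after thresholding; Lp is the mean
#' shortest-path distance over all ordered node pairs with a finite
#' distance, with the number of disconnected pairs reported. Shorter Lp
#' indexes more efficient global information transfer.
#'
#' @param adjacency symmetric nonnegative matrix, zero diagonal; at least 2
#'   nodes.
#' @param mode \code{"weighted"} (default) or \code{"binary"}.
#' @param threshold edge threshold (weights \code{<= threshold} removed).
#' @return list with \code{lp}, \code{n_disconnected_pairs} and the distance
#'   matrix \code{distances}.
#' @export
characteristic_path_length <- function(adjacency,
                                       mode = c("weighted", "binary"),
                                       threshold = 0) {
  mode <- match.arg(mode)
  adj <- check_adjacency(adjacency)
  diag(adj) <- 0
  if (nrow(adj) < 2L) stop("need at least 2 nodes", call. = FALSE)
  a <- adj
  a[a <= threshold] <- 0
  if (mode == "binary") a[a > 0] <- 1
  lengths <- a
  lengths[a > 0] <- 1 / a[a > 0]
  g <- igraph::graph_from_adjacency_matrix(lengths, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  lp <- if (any(finite)) mean(off[finite]) else NA_real_
  list(lp = lp, n_disconnected_pairs = sum(!finite), distances = d)
}

#' Graph metrics (Cp and Lp) of a PLV network
#'
#' @param network an \code{ms_plv_network} or adjacency matrix.
#' @param mode,threshold see \code{\link{clustering_coefficient}} and
#'   \code{\link{characteristic_path_length}}.
#' @return list with \code{cp_mean}, \code{cp_per_node}, \code{lp},
#'   \code{n_disconnected_pairs}.
#' @export
graph_metrics <- function(network, mode = c("weighted", "binary"),
                          threshold = 0) {
  mode <- match.arg(mode)
  adj <- if (inherits(network, "ms_plv_network")) network$adjacency else
    network
  cp <- clustering_coefficient(adj, mode, threshold)
  lp <- characteristic_path_length(adj, mode, threshold)
  list(cp_mean = cp$cp_mean, cp_per_node = cp$cp_per_node, lp = lp$lp,
       n_disconnected_pairs = lp$n_disconnected_pairs)
}
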