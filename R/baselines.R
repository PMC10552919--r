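#' Spherical-spline configuration
#'
#' Classical spherical-spline interpolation constants: spline order `m`,
#' Legendre-series truncation `n_terms`, and ridge regularization `lambda`
#' added to the diagonal of the spline system.
#'
#' @param m Spline order (default 4).
#' @param n_terms Number of Legendre terms (default 7).
#' @param lambda Regularization (default 1e-7).
#' @return A list of class `spline_config`.
#' @export
spline_config <- function(m = 4L, n_terms = 7L, lambda = 1e-7) {
  if (m < 2L) stop("spline order m must be >= 2")
  if (n_terms < 1L) stop("n_terms must be >= 1")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(m = as.integer(m), n_terms = as.integer(n_terms),
                 lambda = lambda), class = "spline_config")
}

# Legendre polynomials P_1..P_n at x via the three-term recurrence.
legendre_upto <- function(x, n) {
  P <- matrix(0, length(x), n)
  P[, 1] <- x
  if (n >= 2L) P[, 2] <- 0.5 * (3 * x^2 - 1)
  if (n >= 3L) {
    pm2 <- rep(1, length(x))  # P_0
    for (k in 2:(n - 1)) {    # builds P_{k+1}
      P[, k + 1] <- ((2 * k + 1) * x * P[, k] - k * P[, k - 1]) / (k + 1)
    }
  }
  P
}

# Spline kernel g(cos angle) = sum_n (2n+1) / (n^m (n+1)^m) * P_n(cos angle)
spline_g <- function(cosang, cfg) {
  n <- seq_len(cfg$n_terms)
  coef <- (2 * n + 1) / (n^cfg$m * (n + 1)^cfg$m)
  P <- legendre_upto(pmin(pmax(cosang, -1), 1), cfg$n_terms)
  as.vector(P %*% coef) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Distance-based baseline: electrodes are projected onto the unit sphere
#' and a smoothing spline built from a truncated Legendre-series kernel is
#' fit to the good electrodes (with a constant term), then evaluated at the
#' bad sites. The map is linear in the data, so a fixed weight vector per
#' bad site underlies the reconstruction.
#'
#' @param positions C x 3 matrix of unit-norm electrode coordinates (all
#'   channels, in montage order).
#' @param data C x L data matrix; rows outside `good_idx` are ignored.
#' @param good_idx Integer indices of the good channels (>= 4 required).
#' @param bad_idx Integer indices of the channels to reconstruct.
#' @param cfg A [spline_config()].
#' @return `length(bad_idx)` x L matrix of reconstructed rows.
#' @export
spherical_spline_interpolate <- function(positions, data, good_idx, bad_idx,
                                         cfg = spline_config()) {
  positions <- as.matrix(positions)
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-6)) positions <- positions / nrm
  good_idx <- as.integer(good_idx); bad_idx <- as.integer(bad_idx)
  if (length(good_idx) < 4L) stop("spherical spline needs at least 4 good channels")
  if (length(intersect(good_idx, bad_idx)))
    stop("good and bad channel sets overlap")
  data <- as.matrix(data)
  ng <- length(good_idx)
  cos_gg <- tcrossprod(positions[good_idx, , drop = FALSE])
  G <- matrix(spline_g(as.vector(cos_gg), cfg), ng, ng)
  sys <- rbind(cbind(G + diag(cfg$lambda, ng), rep(1, ng)),
               c(rep(1, ng), 0))
  inv <- tryCatch(solve(sys),
                  error = function(e)
                    stop("singular spherical-spline system (condition: ",
                         format(kappa(sys)), "); electrode layout degenerate?"))
  cos_bg <- positions[bad_idx, , drop = FALSE] %*% t(positions[good_idx, , drop = FALSE])
  Gb <- matrix(spline_g(as.vector(cos_bg), cfg), length(bad_idx), ng)
  # weights mapping good data -> bad sites: [Gb 1] * inv, columns 1..ng of it
  W <- cbind(Gb, rep(1, length(bad_idx))) %*% inv[, seq_len(ng), drop = FALSE]
  out <- W %*% data[good_idx, , drop = FALSE]
  rownames(out) <- rownames(data)[bad_idx]
  out
}

#' Pearson-correlation interpolation weights for one channel
#'
#' Data-driven baseline: the Pearson correlation between the target channel
#' and every other channel is computed over training data and the
#' correlation vector is normalized by its absolute sum (the same signed
#' normalization the attention model uses), giving fixed interpolation
#' weights with zero self-weight.
#'
#' @param x An `eeg_recording`, a C x T matrix, or a list of
#'   `eeg_segment`s (segments contribute their label as the target row).
#' @param target Target channel index (or name, for recordings).
#' @return A `weight_vector`.
#' @export
pcc_weights <- function(x, target) {
  if (inherits(x, "eeg_recording")) {
    target <- resolve_channel(x$channels, target)
    mat <- x$data
  } else if (is.list(x) && length(x) && inherits(x[[1]], "eeg_segment")) {
    target <- as.integer(target)
    # reassemble full windows from segments whose target matches, else use
    # segments where the channel is good plus its stored label when bad
    mats <- lapply(x, function(s) {
      m <- s$input
      m[s$target, ] <- s$label
      m
    })
    mat <- do.call(cbind, mats)
  } else {
    mat <- as.matrix(x)
    target <- as.integer(target)
  }
  C <- nrow(mat)
  if (C < 2L) stop("correlation weights need at least 2 channels")
  if (ncol(mat) < 3L) stop("correlation weights need at least 3 time points")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds < 1e-12)) {
    bad <- which(sds < 1e-12)
    nm <- rownames(mat)[bad]
    stop("zero-variance channel(s), correlation undefined: ",
         paste(if (is.null(nm)) bad else nm, collapse = ", "))
  }
  r <- as.vector(stats::cor(t(mat))[target, -target])
  good <- setdiff(seq_len(C), target)
  simple_weights(r, target, C, good)
}

#' Full PCC weight matrix
#'
#' Row `t` holds [pcc_weights()] for channel `t`; diagonal zero.
#'
#' @param x Input accepted by [pcc_weights()].
#' @param channel_names Optional dimnames.
#' @return C x C signed matrix.
#' @export
pcc_weight_matrix <- function(x, channel_names = NULL) {
  mat <- if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
  C <- nrow(mat)
  W <- matrix(0, C, C)
  for (t in seq_len(C)) W[t, ] <- pcc_weights(mat, t)$weights
  if (inherits(x, "eeg_recording")) channel_names <- x$channels$names
  if (!is.null(channel_names)) dimnames(W) <- list(channel_names, channel_names)
  W
}

#' Interpolate with fixed correlation weights
#'
#' Applies a precomputed `weight_vector` to raw data. Channels in `bad_set`
#' are excluded and the surviving weights are rescaled to unit absolute
#' sum before the weighted sum is taken.
#'
#' @param wv A `weight_vector` (from [pcc_weights()]).
#' @param data C x L data matrix.
#' @param bad_set Indices of bad channels (must include `wv$target`;
#'   default just the target).
#' @return Length-L reconstructed row for `wv$target`.
#' @export
pcc_interpolate <- function(wv, data, bad_set = wv$target) {
  stopifnot(inherits(wv, "weight_vector"))
  data <- as.matrix(data)
  bad_set <- as.integer(bad_set)
  w <- wv$weights
  w[bad_set] <- 0
  tot <- sum(abs(w))
  if (tot < 1e-12)
    stop("degenerate weights: all weight lay on excluded bad channels")
  w <- w / tot
  as.vector(w %*% data)
}
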