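#' Construct a training/testing segment
#'
#' A segment is a fixed-length window of a recording in which one channel
#' has been designated bad: its original values are kept as the label and
#' its row in the input matrix is zero-filled.
#'
#' @param input C x L numeric matrix with the target row zero-filled.
#' @param target Index of the bad channel.
#' @param label Length-L numeric vector of the target row's true values.
#' @param channel_names Optional channel names for the rows of `input`.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(input, target, label, channel_names = rownames(input)) {
  input <- as.matrix(input)
  target <- as.integer(target)
  label <- as.numeric(label)
  if (target < 1L || target > nrow(input)) stop("target index out of range")
  if (length(label) != ncol(input)) stop("label length must equal segment length")
  if (ncol(input) < 2L) stop("segment length must be >= 2")
  if (any(input[target, ] != 0)) stop("target row of a segment must be zero-filled")
  if (any(!is.finite(label))) stop("segment label must be finite")
  structure(list(input = input, target = target, label = label,
                 channel_names = channel_names),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat("<eeg_segment> C=", nrow(x$input), ", L=", ncol(x$input),
      ", target=", x$target,
      if (!is.null(x$channel_names)) paste0(" (", x$channel_names[x$target], ")"),
      "\n", sep = "")
  invisible(x)
}

#' Layer-normalization statistics of a segment
#'
#' Scalar mean and standard deviation pooled over every entry of the good
#' channels (the zero-filled target row is excluded). The standard
#' deviation is the population form, sqrt(mean((V - mu)^2)); a small
#' epsilon stabilizes the downstream division when the data are constant.
#'
#' @param segment An `eeg_segment`.
#' @param epsilon Stabilizer added to sigma before dividing (default 1e-5).
#' @return List of class `norm_stats` with `mu`, `sigma`, `epsilon`.
#' @export
ln_stats <- function(segment, epsilon = 1e-5) {
  stopifnot(inherits(segment, "eeg_segment"))
  good <- setdiff(seq_len(nrow(segment$input)), segment$target)
  if (length(good) == 0L) stop("segment has no good channels")
  v <- segment$input[good, , drop = FALSE]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  structure(list(mu = mu, sigma = sigma, epsilon = epsilon), class = "norm_stats")
}

#' Layer-normalize the good channels of a segment
#'
#' Good-channel row j becomes `gain[j]*(V[j,]-mu)/(sigma+epsilon)+bias[j]`;
#' the target row stays zero. Applied at training time only.
#'
#' @param segment An `eeg_segment`.
#' @param stats [ln_stats()] of the same segment.
#' @param model The `amacw_model` providing gain and bias.
#' @return Normalized C x L matrix.
#' @export
ln_transform <- function(segment, stats, model) {
  stopifnot(inherits(segment, "eeg_segment"), inherits(stats, "norm_stats"))
  C <- nrow(segment$input)
  good <- setdiff(seq_len(C), segment$target)
  denom <- stats$sigma + stats$epsilon
  out <- matrix(0, C, ncol(segment$input))
  out[good, ] <- model$gain[good] * (segment$input[good, , drop = FALSE] - stats$mu) / denom +
    model$bias[good]
  out
}

#' Transform a segment's label into normalized space
#'
#' The label is mapped by the same mu/sigma as the good-channel data but by
#' the target channel's own gain and bias, so predictions and labels live
#' in the same normalized space.
#'
#' @inheritParams ln_transform
#' @return Length-L normalized label.
#' @export
transform_label <- function(segment, stats, model) {
  stopifnot(inherits(segment, "eeg_segment"), inherits(stats, "norm_stats"))
  t <- segment$target
  model$gain[[t]] * (segment$label - stats$mu) / (stats$sigma + stats$epsilon) +
    model$bias[[t]]
}

draw_channel_mask <- function(good, mask_min, mask_max) {
  k <- if (mask_min == mask_max) mask_min else
    sample(seq.int(mask_min, mask_max), 1L)
  if (k == 0L) integer(0) else sample(good, k)
}

#' Randomly zero good channels of a segment (channel masking)
#'
#' Training-time regularization: a count k is drawn uniformly from
#' `mask_min:mask_max` and k distinct good channels (never the target) have
#' their rows zeroed. If the model had concentrated its attention on a
#' masked channel, its prediction collapses toward zero and the loss spikes,
#' forcing attention to spread across channels. The mask is redrawn
#' independently at every epoch; the label is untouched.
#'
#' Uses the current R random number generator state; call `set.seed()`
#' beforehand for reproducibility.
#'
#' @param segment An `eeg_segment`.
#' @param mask_min,mask_max Inclusive bounds of the masked-channel count
#'   (defaults 0 and 5).
#' @return List with `segment` (rows zeroed) and `masked` (integer indices).
#' @export
apply_channel_mask <- function(segment, mask_min = 0L, mask_max = 5L) {
  stopifnot(inherits(segment, "eeg_segment"))
  good <- setdiff(seq_len(nrow(segment$input)), segment$target)
  mask_min <- as.integer(mask_min); mask_max <- as.integer(mask_max)
  if (mask_min < 0L || mask_max < mask_min)
    stop("need 0 <= mask_min <= mask_max")
  if (mask_max > length(good) - 1L)
    stop("mask_max = ", mask_max, " would allow masking all but the target; ",
         "at most ", length(good) - 1L, " channels can be masked in this montage")
  masked <- draw_channel_mask(good, mask_min, mask_max)
  seg <- segment
  if (length(masked)) seg$input[masked, ] <- 0
  list(segment = seg, masked = as.integer(masked))
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_epochs Upper bound on training epochs (default 3000).
#' @param val_interval Epochs between validation checks (default 100).
#' @param plateau_tol Relative validation-loss improvement below which a
#'   check counts as a plateau; two consecutive plateau checks stop
#'   training (default 0.01).
#' @param lr_decay Inverse-time learning-rate decay: the step size at epoch
#'   e is `learning_rate / (1 + lr_decay * e)` (default 0.002). Decaying
#'   the step suppresses the random-walk jitter of near-zero attention
#'   scores, which would otherwise hold a small floor of spurious absolute
#'   weight on irrelevant channels.
#' @param mask_min,mask_max Channel-masking range (defaults 0 and 5).
#' @param batch_size Segments per gradient update (default 16).
#' @param val_fraction Fraction of segments held out for validation
#'   (default 0.10).
#' @param seed Seed controlling the validation split, batch shuffling and
#'   mask draws (default 1).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 3000L,
                         val_interval = 100L, plateau_tol = 0.01,
                         lr_decay = 0.002,
                         mask_min = 0L, mask_max = 5L,
                         batch_size = 16L, val_fraction = 0.10, seed = 1L) {
  cfg <- list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
              val_interval = as.integer(val_interval), plateau_tol = plateau_tol,
              lr_decay = lr_decay,
              mask_min = as.integer(mask_min), mask_max = as.integer(mask_max),
              batch_size = as.integer(batch_size), val_fraction = val_fraction,
              seed = as.integer(seed))
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$mask_min < 0L || cfg$mask_max < cfg$mask_min)
    stop("need 0 <= mask_min <= mask_max")
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  structure(cfg, class = "train_config")
}

#' Read a training configuration from JSON
#'
#' Keys mirror the arguments of [train_config()]; absent keys take the
#' defaults.
#'
#' @param path JSON file path.
#' @return A `train_config`.
#' @export
read_train_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(train_config))
  extra <- setdiff(names(obj), known)
  if (length(extra)) stop("unknown training config keys: ", paste(extra, collapse = ", "))
  do.call(train_config, obj)
}

# Forward pass + analytic gradients for one segment.
# Prediction in normalized space: p = sum_j w_j * xn_j over good channels,
# with masked rows contributing zeros; loss = mean((p - label')^2).
# Returns loss and gradients wrt embeddings, gain, bias.
segment_grad <- function(model, segment, masked = integer(0), want_grad = TRUE) {
  Cn <- model$channels$C
  t <- segment$target
  good <- setdiff(seq_len(Cn), t)
  L <- ncol(segment$input)
  st <- ln_stats(segment)
  denom <- st$sigma + st$epsilon
  u <- (segment$input[good, , drop = FALSE] - st$mu) / denom    # |good| x L
  xn <- model$gain[good] * u + model$bias[good]
  keep <- !(good %in% masked)
  if (any(!keep)) xn[!keep, ] <- 0
  ut <- (segment$label - st$mu) / denom
  yn <- model$gain[[t]] * ut + model$bias[[t]]

  E <- model$embeddings
  s <- as.vector(E[good, , drop = FALSE] %*% E[t, ])
  A <- sum(abs(s))
  if (!is.finite(A) || A < 1e-12)
    stop("degenerate scores during training: sum|score| ~ 0")
  w <- s / A
  p <- as.vector(w %*% xn)
  r <- p - yn
  loss <- mean(r^2)
  if (!want_grad) return(list(loss = loss))

  c2 <- 2 / L
  dLdw <- c2 * as.vector(xn %*% r)                    # |good|
  dLds <- (dLdw - sign(s) * sum(w * dLdw)) / A
  gE <- matrix(0, Cn, model$embed_dim)
  gE[t, ] <- as.vector(dLds %*% E[good, , drop = FALSE])
  gE[good, ] <- gE[good, , drop = FALSE] + outer(dLds, E[t, ])
  gg <- numeric(Cn); gb <- numeric(Cn)
  ru <- as.vector(u %*% r)
  sr <- sum(r)
  gg[good] <- ifelse(keep, c2 * w * ru, 0)
  gb[good] <- ifelse(keep, c2 * w * sr, 0)
  # The label transform is a data transformation: no gradient flows through
  # the target channel's gain/bias. Backpropagating through the label lets
  # the model shrink all gains jointly, scaling prediction and label toward
  # zero together -- a degenerate optimum that destroys the raw-space
  # weights. The target's gain/bias still learn whenever that channel plays
  # the good-channel role in other segments.
  list(loss = loss, gE = gE, gg = gg, gb = gb)
}

adam_init <- function(model) {
  z <- function(x) array(0, dim = if (is.matrix(x)) dim(x) else length(x))
  list(t = 0L,
       mE = z(model$embeddings), vE = z(model$embeddings),
       mg = z(model$gain), vg = z(model$gain),
       mb = z(model$bias), vb = z(model$bias))
}

adam_update <- function(model, opt, gE, gg, gb, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  step <- function(m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^opt$t)
    vh <- v / (1 - beta2^opt$t)
    list(m = m, v = v, delta = lr * mh / (sqrt(vh) + eps))
  }
  sE <- step(opt$mE, opt$vE, gE); opt$mE <- sE$m; opt$vE <- sE$v
  sg <- step(opt$mg, opt$vg, gg); opt$mg <- sg$m; opt$vg <- sg$v
  sb <- step(opt$mb, opt$vb, gb); opt$mb <- sb$m; opt$vb <- sb$v
  model$embeddings <- model$embeddings - sE$delta
  model$gain <- model$gain - as.vector(sg$delta)
  model$bias <- model$bias - as.vector(sb$delta)
  list(model = model, opt = opt)
}

#' One gradient step on a batch of segments
#'
#' For each segment: layer-normalization statistics are computed, the good
#' channels and the label are normalized, a fresh channel mask is drawn,
#' the masked prediction is compared to the normalized label by MSE, and
#' the batch-mean gradients update embeddings, gain and bias with one Adam
#' step.
#'
#' @param model An `amacw_model`.
#' @param batch List of `eeg_segment`s sharing the model's channel count.
#' @param opt Optimizer state from a previous call, or `NULL` to start.
#' @param config A [train_config()].
#' @return List with `loss` (batch mean, pre-update), `model`, `opt`.
#' @export
training_step <- function(model, batch, opt = NULL, config = train_config(),
                          lr = config$learning_rate) {
  if (is.null(opt)) opt <- adam_init(model)
  C <- model$channels$C
  gE <- matrix(0, C, model$embed_dim); gg <- numeric(C); gb <- numeric(C)
  loss <- 0
  for (seg in batch) {
    if (nrow(seg$input) != C) stop("segment channel count differs from model")
    good <- setdiff(seq_len(C), seg$target)
    masked <- draw_channel_mask(good, config$mask_min,
                                min(config$mask_max, length(good) - 1L))
    gr <- segment_grad(model, seg, masked)
    if (!is.finite(gr$loss)) stop("training diverged: non-finite loss")
    loss <- loss + gr$loss
    gE <- gE + gr$gE; gg <- gg + gr$gg; gb <- gb + gr$gb
  }
  n <- length(batch)
  upd <- adam_update(model, opt, gE / n, gg / n, gb / n, lr)
  list(loss = loss / n, model = upd$model, opt = upd$opt)
}

#' Validation loss of a model
#'
#' Mean per-segment MSE in normalized space with layer normalization
#' enabled and channel masking disabled; no parameters are updated and no
#' randomness is used.
#'
#' @param model An `amacw_model`.
#' @param segments Non-empty list of `eeg_segment`s.
#' @return Scalar mean MSE.
#' @export
validate <- function(model, segments) {
  if (length(segments) == 0L) stop("validation needs at least one segment")
  mean(vapply(segments, function(s)
    segment_grad(model, s, integer(0), want_grad = FALSE)$loss, numeric(1)))
}

#' Train an attention channel-weighting model
#'
#' Holds out `val_fraction` of the segments for validation, then runs
#' mini-batch Adam with per-segment layer normalization and channel
#' masking. Every `val_interval` epochs the validation loss is measured
#' (masking disabled); when the relative improvement between consecutive
#' checks falls below `plateau_tol` twice in a row, training stops. The
#' returned model is the checkpoint with the lowest validation loss.
#' Fully reproducible under `config$seed`.
#'
#' @param model An initialized `amacw_model`.
#' @param segments List of at least 2 `eeg_segment`s.
#' @param config A [train_config()].
#' @param verbose Print a line at each validation check.
#' @return An object of class `amacw_fit`: list with `model` (best
#'   checkpoint), `history` (data frame: epoch, train_loss, val_loss with
#'   `NA` between checks), `epochs_run`, `best_val_loss`.
#' @export
train <- function(model, segments, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "amacw_model"))
  if (length(segments) < 2L) stop("training needs at least 2 segments")
  C <- model$channels$C
  max_mask <- min(vapply(segments, function(s)
    length(setdiff(seq_len(nrow(s$input)), s$target)), integer(1))) - 1L
  if (config$mask_max > max_mask)
    stop("mask_max = ", config$mask_max, " too large for this montage; at most ",
         max_mask, " channels can be masked")
  set.seed(config$seed)
  n <- length(segments)
  n_val <- max(1L, round(config$val_fraction * n))
  if (n_val >= n) stop("validation split leaves no training segments")
  val_idx <- sample(n, n_val)
  val_segs <- segments[val_idx]
  tr_segs <- segments[-val_idx]

  opt <- adam_init(model)
  best <- list(val = Inf, model = model)
  prev_val <- NA_real_
  plateaus <- 0L
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  epochs_run <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(tr_segs))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      stp <- training_step(model, tr_segs[idx], opt, config,
                           lr = config$learning_rate / (1 + config$lr_decay * epoch))
      model <- stp$model; opt <- stp$opt
      ep_loss <- ep_loss + stp$loss; nb <- nb + 1L
    }
    epochs_run <- epoch
    vl <- NA_real_
    if (epoch %% config$val_interval == 0L) {
      vl <- validate(model, val_segs)
      if (verbose)
        message(sprintf("epoch %d: train %.6g  val %.6g", epoch, ep_loss / nb, vl))
      if (vl < best$val) best <- list(val = vl, model = model)
      if (!is.na(prev_val)) {
        rel <- (prev_val - vl) / max(prev_val, .Machine$double.eps)
        plateaus <- if (rel < config$plateau_tol) plateaus + 1L else 0L
      }
      prev_val <- vl
    }
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, ep_loss / nb)
    hist_val <- c(hist_val, vl)
    if (plateaus >= 2L) break
  }
  if (!is.finite(best$val)) {   # never hit a validation check
    best <- list(val = validate(model, val_segs), model = model)
  }
  out_model <- best$model
  out_model$meta <- c(out_model$meta,
                      list(epochs_trained = epochs_run, best_val_loss = best$val,
                           train_seed = config$seed))
  structure(list(model = out_model,
                 history = data.frame(epoch = hist_epoch, train_loss = hist_train,
                                      val_loss = hist_val),
                 epochs_run = epochs_run, best_val_loss = best$val),
            class = "amacw_fit")
}

#' @export
print.amacw_fit <- function(x, ...) {
  cat("<amacw_fit> ", x$epochs_run, " epochs, best validation loss ",
      signif(x$best_val_loss, 5), "\n", sep = "")
  invisible(x)
}

#' Write a training log as delimited text
#'
#' @param fit An `amacw_fit`.
#' @param path Output TSV path (columns epoch, train_loss, val_loss).
#' @return `path`, invisibly.
#' @export
write_training_log <- function(fit, path) {
  stopifnot(inherits(fit, "amacw_fit"))
  utils::write.table(fit$history, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
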