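#' Initialize an attention channel-weighting model
#'
#' The model holds one learnable embedding vector per channel plus a
#' per-channel layer-normalization gain and bias. A channel's embedding row
#' serves both as its query (when it is the bad channel) and as its key
#' (when it is a good channel); there are no projection matrices, so the
#' learnable scalar count is exactly `C*d + 2*C`.
#'
#' Embeddings are drawn i.i.d. normal(0, 0.1) from a seeded generator; gains
#' start at 1 and biases at 0. The same seed always yields the same model.
#'
#' @param channels A [channel_set] with at least 2 channels.
#' @param embed_dim Embedding dimension `d` (>= 1); 20 and 35 are the two
#'   reference sizes for a 17-channel montage.
#' @param seed Integer seed for the embedding initialization.
#' @return An object of class `amacw_model` with elements `channels`,
#'   `embed_dim`, `embeddings` (C x d), `gain`, `bias`, `seed`, `meta`.
#' @export
amacw_model <- function(channels, embed_dim = 20L, seed = 1L) {
  stopifnot(inherits(channels, "channel_set"))
  C <- channels$C
  if (C < 2L) stop("invalid montage: interpolation needs at least one good channel (C >= 2)")
  embed_dim <- as.integer(embed_dim)
  if (embed_dim < 1L) stop("embed_dim must be >= 1")
  seed <- as.integer(seed)
  E <- local({
    set.seed(seed)
    matrix(stats::rnorm(C * embed_dim, mean = 0, sd = 0.1), nrow = C, ncol = embed_dim)
  })
  rownames(E) <- channels$names
  structure(list(channels = channels, embed_dim = embed_dim,
                 embeddings = E,
                 gain = stats::setNames(rep(1, C), channels$names),
                 bias = stats::setNames(rep(0, C), channels$names),
                 seed = seed, meta = list()),
            class = "amacw_model")
}

#' @export
print.amacw_model <- function(x, ...) {
  cat("<amacw_model> C=", x$channels$C, " channels, embed_dim=", x$embed_dim,
      ", ", parameter_count(x), " learnable parameters\n", sep = "")
  if (!is.null(x$meta$epochs_trained))
    cat("  trained for ", x$meta$epochs_trained, " epochs (val loss ",
        signif(x$meta$best_val_loss, 4), ")\n", sep = "")
  invisible(x)
}

#' Count learnable scalars of a model
#'
#' `C*d` embedding entries plus `C` gains plus `C` biases.
#'
#' @param model An `amacw_model`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  stopifnot(inherits(model, "amacw_model"))
  C <- model$channels$C
  as.integer(C * model$embed_dim + 2L * C)
}

resolve_channel <- function(model_or_set, ch) {
  names <- if (inherits(model_or_set, "amacw_model")) model_or_set$channels$names
           else model_or_set$names
  if (is.character(ch)) {
    idx <- match(ch, names)
    if (anyNA(idx)) stop("unknown channel: ", paste(ch[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(ch)
    if (any(idx < 1L | idx > length(names))) stop("channel index out of range")
    idx
  }
}

#' Attention scores between a bad channel and the good channels
#'
#' The score of good channel `j` for target `t` is the dot product of their
#' embedding rows, `score[j] = <e_t, e_j>`. The target's own embedding is
#' never used as a key.
#'
#' @param model An `amacw_model`.
#' @param target Bad-channel index or name.
#' @param good Indices or names of the good channels (must not include the
#'   target; defaults to all other channels).
#' @return Named numeric vector of scores over `good`.
#' @export
attention_scores <- function(model, target,
                             good = setdiff(seq_len(model$channels$C), resolve_channel(model, target))) {
  stopifnot(inherits(model, "amacw_model"))
  t <- resolve_channel(model, target)
  g <- resolve_channel(model, good)
  if (length(g) == 0L) stop("no good channels available for interpolation")
  if (t %in% g) stop("target channel cannot be its own key")
  s <- as.vector(model$embeddings[g, , drop = FALSE] %*% model$embeddings[t, ])
  stats::setNames(s, model$channels$names[g])
}

#' Convert attention scores to signed interpolation weights
#'
#' Each score is divided by the sum of absolute scores, so the weights keep
#' the scores' signs (negatively correlated channels receive negative
#' weights) and have unit absolute sum. Softmax would suppress negative
#' scores; this normalization does not.
#'
#' @param scores Numeric vector of scores over the good channels.
#' @param target Index of the bad channel in the full montage.
#' @param C Total channel count of the montage.
#' @param good Integer indices of the good channels that `scores` aligns
#'   with; defaults to all channels except `target`.
#' @return An object of class `weight_vector`: list with `target`, `good`,
#'   and `weights`, a length-`C` signed vector that is zero at the target
#'   and at every channel outside `good`.
#' @export
simple_weights <- function(scores, target, C = length(scores) + 1L,
                           good = setdiff(seq_len(C), target)) {
  scores <- as.numeric(scores)
  target <- as.integer(target)
  good <- as.integer(good)
  if (length(scores) != length(good))
    stop("scores and good-channel index set differ in length")
  if (target %in% good) stop("target channel cannot carry a weight")
  denom <- sum(abs(scores))
  if (!is.finite(denom) || denom < 1e-12)
    stop("degenerate scores: sum of absolute attention scores is ~0, ",
         "weights are undefined (model untrained or collapsed)")
  w <- numeric(C)
  w[good] <- scores / denom
  structure(list(target = target, good = good, weights = w),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> target channel ", x$target, ", ",
      length(x$good), " good channels, sum|w| = ",
      format(sum(abs(x$weights))), "\n", sep = "")
  invisible(x)
}

#' Interpolation weights of a model for one bad channel
#'
#' Convenience composition of [attention_scores()] and [simple_weights()].
#'
#' @inheritParams attention_scores
#' @return A `weight_vector`.
#' @export
channel_weights <- function(model, target,
                            good = setdiff(seq_len(model$channels$C), resolve_channel(model, target))) {
  t <- resolve_channel(model, target)
  g <- resolve_channel(model, good)
  simple_weights(attention_scores(model, t, g), t, model$channels$C, g)
}

#' Reconstruct bad channels of a data segment
#'
#' Test-time interpolation: each bad channel is reconstructed independently
#' as the weighted sum of the raw good-channel rows (no normalization is
#' applied at test time). All bad channels are excluded both from the key
#' set and from the weighted sum, so a reconstruction never depends on
#' another bad channel's (zero-filled) data.
#'
#' @param model A trained `amacw_model`.
#' @param data C x L numeric matrix; rows in `bad_set` are ignored.
#' @param bad_set Indices or names of the bad channels.
#' @return A `length(bad_set)` x L matrix of reconstructed rows, rownames
#'   set to the bad channels' names, in the order of `bad_set`.
#' @export
interpolate_segment <- function(model, data, bad_set) {
  stopifnot(inherits(model, "amacw_model"))
  data <- as.matrix(data)
  C <- model$channels$C
  if (nrow(data) != C) stop("data must have ", C, " rows (one per channel)")
  bad <- resolve_channel(model, bad_set)
  good <- setdiff(seq_len(C), bad)
  if (length(good) == 0L) stop("no good channels available for interpolation")
  out <- matrix(0, nrow = length(bad), ncol = ncol(data),
                dimnames = list(model$channels$names[bad], NULL))
  for (i in seq_along(bad)) {
    wv <- channel_weights(model, bad[i], good)
    out[i, ] <- as.vector(wv$weights[good] %*% data[good, , drop = FALSE])
  }
  out
}

#' Full signed weight matrix of a model
#'
#' Row `t` holds the interpolation weights used when channel `t` alone is
#' bad; the diagonal is identically zero and every row has unit absolute
#' sum. This is the matrix visualized in weight-distribution maps.
#'
#' @param model An `amacw_model`.
#' @return C x C signed numeric matrix with channel dimnames.
#' @export
weight_matrix <- function(model) {
  stopifnot(inherits(model, "amacw_model"))
  C <- model$channels$C
  W <- matrix(0, C, C, dimnames = list(model$channels$names, model$channels$names))
  for (t in seq_len(C)) W[t, ] <- channel_weights(model, t)$weights
  W
}

#' Serialize a model to a portable JSON file
#'
#' Writes channel names, positions, embedding dimension, embeddings, gain,
#' bias, seed and training metadata with full double precision, so that
#' [read_model()] round-trips bit-exactly.
#'
#' @param model An `amacw_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "amacw_model"))
  # doubles are stored as %.17g strings: 17 significant digits round-trip
  # IEEE-754 binary64 exactly, which plain JSON number formatting does not
  num <- function(x) sprintf("%.17g", as.numeric(x))
  obj <- list(format = "amacw_model", version = 1L,
              channel_names = model$channels$names,
              positions = if (is.null(model$channels$positions)) NULL else
                num(model$channels$positions),
              embed_dim = model$embed_dim,
              embeddings = num(model$embeddings),
              gain = num(model$gain), bias = num(model$bias),
              seed = model$seed, meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_model()].
#' @return The `amacw_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "amacw_model")) stop("not an amacw model file: ", path)
  pos <- if (is.null(obj$positions)) NULL else
    matrix(as.numeric(obj$positions), ncol = 3)
  ch <- channel_set(obj$channel_names, pos)
  E <- matrix(as.numeric(obj$embeddings), nrow = ch$C, ncol = obj$embed_dim)
  rownames(E) <- ch$names
  structure(list(channels = ch, embed_dim = as.integer(obj$embed_dim),
                 embeddings = E,
                 gain = stats::setNames(as.numeric(obj$gain), ch$names),
                 bias = stats::setNames(as.numeric(obj$bias), ch$names),
                 seed = as.integer(obj$seed),
                 meta = if (is.null(obj$meta)) list() else obj$meta),
            class = "amacw_model")
}
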