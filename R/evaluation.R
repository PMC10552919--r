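#' Mean squared error between a true and a reconstructed signal
#'
#' @param truth,estimate Equal-length numeric vectors.
#' @return Nonnegative scalar, `mean((truth - estimate)^2)`.
#' @export
mse <- function(truth, estimate) {
  truth <- as.numeric(truth); estimate <- as.numeric(estimate)
  if (length(truth) != length(estimate))
    stop("truth and estimate differ in length (", length(truth), " vs ",
         length(estimate), ")")
  if (length(truth) < 1L) stop("mse needs at least one sample")
  mean((truth - estimate)^2)
}

#' Aggregate per-case MSEs into a condition-level error
#'
#' The error reported for a bad-channel-count condition is the arithmetic
#' mean of the per-case MSEs.
#'
#' @param case_mses Non-empty numeric vector.
#' @return Scalar mean.
#' @export
aggregate_error <- function(case_mses) {
  case_mses <- as.numeric(case_mses)
  if (length(case_mses) == 0L) stop("no case errors to aggregate")
  mean(case_mses)
}

#' Build interpolator functions for the benchmark harness
#'
#' Each returns a `function(input, bad_set)` producing a
#' `length(bad_set) x L` matrix of reconstructed rows.
#'
#' @param model A trained `amacw_model`.
#' @return An interpolator closure.
#' @rdname interpolators
#' @export
amacw_interpolator <- function(model) {
  force(model)
  function(input, bad_set) interpolate_segment(model, input, bad_set)
}

#' @param positions C x 3 unit-sphere electrode coordinates, or a
#'   [channel_set] carrying positions.
#' @param cfg A [spline_config()].
#' @rdname interpolators
#' @export
spline_interpolator <- function(positions, cfg = spline_config()) {
  if (inherits(positions, "channel_set")) {
    if (is.null(positions$positions))
      stop("channel set has no electrode positions; the spherical spline needs them")
    positions <- positions$positions
  }
  force(positions); force(cfg)
  function(input, bad_set) {
    good <- setdiff(seq_len(nrow(input)), bad_set)
    spherical_spline_interpolate(positions, input, good, bad_set, cfg)
  }
}

#' @param weight_mat C x C matrix of per-target weights (row t = weights
#'   for reconstructing channel t), e.g. from [pcc_weight_matrix()].
#' @rdname interpolators
#' @export
pcc_interpolator <- function(weight_mat) {
  force(weight_mat)
  function(input, bad_set) {
    out <- matrix(0, length(bad_set), ncol(input))
    for (i in seq_along(bad_set)) {
      t <- bad_set[i]
      good <- setdiff(seq_len(nrow(input)), bad_set)
      wv <- structure(list(target = t, good = good,
                           weights = weight_mat[t, ]), class = "weight_vector")
      out[i, ] <- pcc_interpolate(wv, input, bad_set)
    }
    rownames(out) <- rownames(input)[bad_set]
    out
  }
}

#' Paired benchmark of interpolation methods
#'
#' Cuts the recording into test windows, draws `n_bad` bad channels per
#' window (identical draws for every method, so comparisons are paired)
#' and reports the mean MSE per method and bad-channel count, plus a Sum
#' column across counts. Within a case the MSE is first averaged across
#' that case's bad channels, then across cases. A method failure on a case
#' is recorded as `NA` and the run continues.
#'
#' @param methods Named list of interpolator functions
#'   (`function(input, bad_set) -> matrix`).
#' @param rec The test `eeg_recording`.
#' @param n_bad_range Bad-channel counts to evaluate (default 1:5).
#' @param L Test window length (default 2000).
#' @param seed Seed for the shared bad-channel draws.
#' @return An object of class `eval_report`: list with `table` (methods x
#'   conditions data frame incl. Sum), `case_mses` (per method, per
#'   condition numeric vectors), `n_cases`, and `meta`.
#' @export
run_benchmark <- function(methods, rec, n_bad_range = 1:5, L = 2000L, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("methods must be a named list of interpolator functions")
  conds <- as.integer(n_bad_range)
  cases_by_cond <- lapply(conds, function(nb)
    make_test_cases(rec, L = L, n_bad = nb, seed = seed + nb))
  names(cases_by_cond) <- as.character(conds)
  case_mses <- list()
  tab <- matrix(NA_real_, length(methods), length(conds),
                dimnames = list(names(methods), as.character(conds)))
  for (m in names(methods)) {
    case_mses[[m]] <- list()
    for (ci in seq_along(conds)) {
      cases <- cases_by_cond[[ci]]
      errs <- vapply(cases, function(cs) {
        tryCatch({
          recon <- methods[[m]](cs$input, cs$bad_set)
          mean(vapply(seq_along(cs$bad_set), function(i)
            mse(cs$labels[i, ], recon[i, ]), numeric(1)))
        }, error = function(e) NA_real_)
      }, numeric(1))
      case_mses[[m]][[as.character(conds[ci])]] <- errs
      if (all(is.na(errs))) tab[m, ci] <- NA_real_
      else tab[m, ci] <- aggregate_error(errs[!is.na(errs)])
    }
  }
  df <- as.data.frame(tab)
  df$Sum <- rowSums(tab)
  structure(list(table = df, case_mses = case_mses,
                 n_cases = vapply(cases_by_cond, length, integer(1)),
                 meta = list(L = L, seed = seed, n_bad_range = conds,
                             fs = rec$fs, C = rec$channels$C)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> mean MSE by number of bad channels (",
      paste(x$n_cases, collapse = "/"), " cases per condition)\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' Write a benchmark report
#'
#' Writes the condition table as TSV and the full report (including
#' per-case MSEs and metadata) as JSON.
#'
#' @param report An `eval_report`.
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_eval_report <- function(report, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(path_tsv))
    utils::write.table(cbind(method = rownames(report$table), report$table),
                       path_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(report[c("table", "case_mses", "n_cases", "meta")],
                         path_json, digits = NA, auto_unbox = TRUE)
  invisible(report)
}

#' Export a signed weight map
#'
#' Writes the C x C interpolation-weight matrix (diagonal zero) as
#' tab-delimited text and optionally renders a heat map with a diverging
#' palette (blue = negative, white = zero, red = positive).
#'
#' @param x An `amacw_model`, or a C x C weight matrix (e.g. from
#'   [pcc_weight_matrix()]).
#' @param path Output TSV path.
#' @param png_path Optional PNG path for the heat map.
#' @return The weight matrix, invisibly.
#' @export
export_weight_map <- function(x, path, png_path = NULL) {
  W <- if (inherits(x, "amacw_model")) weight_matrix(x) else as.matrix(x)
  utils::write.table(cbind(channel = rownames(W), as.data.frame(W)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 600)
    on.exit(grDevices::dev.off())
    lim <- max(abs(W))
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
    C <- nrow(W)
    graphics::image(seq_len(C), seq_len(C), t(W[C:1, , drop = FALSE]),
                    zlim = c(-lim, lim), col = pal, axes = FALSE,
                    xlab = "good channel", ylab = "bad channel")
    graphics::axis(1, at = seq_len(C), labels = colnames(W), las = 2, cex.axis = 0.7)
    graphics::axis(2, at = seq_len(C), labels = rev(rownames(W)), las = 2, cex.axis = 0.7)
    graphics::box()
  }
  invisible(W)
}

#' Read back an exported weight map
#'
#' @param path TSV written by [export_weight_map()].
#' @return The weight matrix.
#' @export
read_weight_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df[[1]]
  W
}

#' Best fixed interpolation weights for a target channel
#'
#' Numerical oracle: finds the weight vector with unit absolute sum that
#' minimizes the reconstruction MSE of `target` over the given data, by
#' quasi-Newton optimization of an unnormalized parameterization
#' (`w = v / sum(|v|)`) started from the least-squares solution.
#'
#' @param data C x T matrix (or `eeg_recording`).
#' @param target Target channel index.
#' @return List with `weights` (length C, zero at target, unit absolute
#'   sum) and `mse` (the oracle's reconstruction MSE).
#' @export
best_fixed_weights <- function(data, target) {
  if (inherits(data, "eeg_recording")) data <- data$data
  data <- as.matrix(data)
  C <- nrow(data)
  target <- as.integer(target)
  good <- setdiff(seq_len(C), target)
  X <- t(data[good, , drop = FALSE])
  y <- data[target, ]
  v0 <- as.vector(stats::lm.fit(X, y)$coefficients)
  v0[is.na(v0)] <- 0
  if (sum(abs(v0)) < 1e-12) v0 <- rep(1 / length(good), length(good))
  obj <- function(v) {
    s <- sum(abs(v))
    if (s < 1e-12) return(1e12)
    w <- v / s
    mean((as.vector(X %*% w) - y)^2)
  }
  fit <- stats::optim(v0 / sum(abs(v0)), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  w <- numeric(C)
  w[good] <- fit$par / sum(abs(fit$par))
  list(weights = w, mse = fit$value)
}
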