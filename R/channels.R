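#' Construct a channel set
#'
#' A channel set names the electrodes of a montage in recording order and,
#' optionally, carries idealized unit-sphere 3-D positions. Positions are
#' needed only by the spherical-spline baseline; the attention model is
#' position-free.
#'
#' @param names Character vector of unique channel labels.
#' @param positions Optional numeric matrix (one row per channel, columns
#'   x/y/z) of unit-norm electrode coordinates. Rows are normalized to unit
#'   length; a row of zeros is an error.
#' @return An object of class `channel_set` with elements `names`, `C` and
#'   `positions` (possibly `NULL`).
#' @export
channel_set <- function(names, positions = NULL) {
  names <- as.character(names)
  if (length(names) < 1L) stop("channel set needs at least one channel")
  if (anyDuplicated(names)) {
    stop("duplicate channel labels: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != length(names) || ncol(positions) != 3L)
      stop("positions must be a ", length(names), " x 3 matrix")
    storage.mode(positions) <- "double"
    nrm <- sqrt(rowSums(positions^2))
    if (any(!is.finite(nrm)) || any(nrm < 1e-8))
      stop("electrode positions must be nonzero finite coordinates")
    positions <- positions / nrm
    rownames(positions) <- names
  }
  structure(list(names = names, C = length(names), positions = positions),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat("<channel_set> ", x$C, " channels",
      if (is.null(x$positions)) " (no positions)" else " (with positions)",
      "\n", sep = "")
  cat(" ", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' Read a montage file
#'
#' Reads a delimited montage of electrode names and optional 3-D coordinates.
#' The expected format is CSV with a header `name,x,y,z` (coordinates may be
#' omitted, leaving a single `name` column).
#'
#' @param path Path to the montage file.
#' @return A [channel_set].
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"name" %in% names(df)) stop("montage file must have a 'name' column: ", path)
  pos <- NULL
  if (all(c("x", "y", "z") %in% names(df))) pos <- as.matrix(df[, c("x", "y", "z")])
  channel_set(df$name, pos)
}

#' The packaged 17-channel 10-20 montage
#'
#' Idealized unit-sphere coordinates for 17 electrodes of the international
#' 10-20 system (Fp1/Fp2, F7/F3/Fz/F4/F8, T7/C3/Cz/C4/T8, P7/P3/Pz/P4/P8).
#' Rim electrodes sit on the equator, Fz/Cz/Pz/C3/C4 on the sagittal and
#' coronal great circles, and F3/F4/P3/P4 at great-circle midpoints between
#' their midline and rim neighbours.
#'
#' @return A [channel_set] with 17 channels and positions.
#' @export
standard_montage_1020 <- function() {
  read_montage(system.file("extdata", "montage_1020_17.csv", package = "amacw",
                           mustWork = TRUE))
}

#' Subset a recording to named channels
#'
#' Restricts a recording to the channels in `keep`, in the order given.
#' Used to reduce heterogeneous montages to a common 10-20 subset before
#' training or evaluation.
#'
#' @param rec An `eeg_recording`.
#' @param keep Character vector of channel names to retain.
#' @return The subset `eeg_recording`.
#' @export
select_channels <- function(rec, keep) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- as.character(keep)
  missing <- setdiff(keep, rec$channels$names)
  if (length(missing))
    stop("channels not present in recording: ", paste(missing, collapse = ", "))
  idx <- match(keep, rec$channels$names)
  pos <- rec$channels$positions
  eeg_recording(channel_set(keep, if (is.null(pos)) NULL else pos[idx, , drop = FALSE]),
                rec$data[idx, , drop = FALSE], rec$fs)
}
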