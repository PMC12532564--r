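#' Standardise a model table
#'
#' Continuous model columns are centred and scaled to observed-cell mean 0
#' and SD 1 (denominator `n - 1`); binary indicator columns are left on
#' their 0/1 scale and flagged as unscaled. Effects estimated on the
#' standardised scale are therefore in SD units of the response per 1-SD
#' change of a continuous predictor and per 0-to-1 change of a binary
#' predictor.
#'
#' @param mtab model table from [expand_categoricals()] (or any data frame
#'   whose columns match `bs$columns$column`).
#' @param bs a `blsem_blocks` object.
#' @return list with `table` (standardised data frame) and `scale` (a
#'   `blsem_scale` data frame with columns `column`, `center`, `scale`,
#'   `scaled`).
#' @export
standardize <- function(mtab, bs) {
  stopifnot(inherits(bs, "blsem_blocks"))
  cols <- bs$columns
  stopifnot(all(cols$column %in% names(mtab)))
  out <- mtab[, cols$column, drop = FALSE]
  center <- numeric(nrow(cols)); scale <- rep(1, nrow(cols))
  scaled <- cols$type == "continuous"
  for (i in seq_len(nrow(cols))) {
    if (!scaled[i]) next
    x <- out[[i]]
    mu <- mean(x, na.rm = TRUE)
    sd <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(sd) || sd <= 0)
      stop("zero-variance continuous column `", cols$column[i],
           "` cannot be standardised", call. = FALSE)
    out[[i]] <- (x - mu) / sd
    center[i] <- mu; scale[i] <- sd
  }
  info <- data.frame(column = cols$column, center = center, scale = scale,
                     scaled = scaled, stringsAsFactors = FALSE)
  class(info) <- c("blsem_scale", "data.frame")
  list(table = out, scale = info)
}

#' Map a standardised table back to the original scale
#'
#' Inverse of [standardize()]: multiplies each scaled column by its stored
#' SD and adds back its mean.
#'
#' @param stab standardised data frame.
#' @param scale a `blsem_scale` data frame.
#' @return data frame on the original scale.
#' @export
destandardize_table <- function(stab, scale) {
  out <- stab
  for (i in seq_len(nrow(scale))) {
    cn <- scale$column[i]
    if (!cn %in% names(out) || !scale$scaled[i]) next
    out[[cn]] <- out[[cn]] * scale$scale[i] + scale$center[i]
  }
  out
}
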