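#' The feedback rating grid
#'
#' Feedback ratings are presented as the mean of three integer ratings on the
#' 1--8 Likert scale, displayed to one decimal. The resulting grid runs from
#' 1.0 to 8.0 in (approximate) steps of 0.3: 1.0, 1.3, 1.7, 2.0, 2.3, 2.7,
#' ..., 7.7, 8.0. The grid contains every integer rating, so a feedback value
#' can match a participant's own rating exactly (a zero-discrepancy trial),
#' and it is closed under reverse coding: `9 - g` is on the grid for every
#' grid value `g`.
#'
#' @return Numeric vector of the 22 admissible feedback values.
#' @export
#' @examples
#' feedback_grid()
feedback_grid <- function() {
  round(seq(3L, 24L) / 3, 1)
}

#' Snap values to the feedback grid
#'
#' Maps each value to the nearest admissible feedback value; ties round
#' upward. Values outside \[1, 8\] are clamped to the grid endpoints.
#'
#' @param x Numeric vector.
#' @return Numeric vector of grid values, same length as `x`.
#' @export
#' @examples
#' snap_to_feedback_grid(c(0.2, 5.49, 5.51, 9))
snap_to_feedback_grid <- function(x) {
  stopifnot(is.numeric(x))
  g <- feedback_grid()
  mid <- (g[-length(g)] + g[-1]) / 2
  g[findInterval(x, mid, left.open = TRUE) + 1L]
}

#' Test grid membership
#'
#' @param x Numeric vector.
#' @return Logical vector: is each value (to one decimal) an admissible
#'   feedback value? `NA` values yield `NA`.
#' @export
is_on_feedback_grid <- function(x) {
  out <- round(x, 1) %in% feedback_grid()
  out[is.na(x)] <- NA
  out
}

# Integer index of a grid value: k such that value == round(k/3, 1), k in 3:24.
# Integer first ratings r map to k = 3r, which makes discrepancy arithmetic on
# the grid exact. NA-safe.
grid_index <- function(x) {
  idx <- match(round(x, 1), feedback_grid())
  idx + 2L
}

grid_value <- function(k) {
  round(k / 3, 1)
}
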