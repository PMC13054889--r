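#' Weighted geometric-mean score combination
#'
#' Combines component scores into a single reward by the weighted geometric
#' mean `(prod v_i^{w_i})^{1 / sum w_i}`. Components with weight 0 are
#' excluded from the product but are still carried in logs, which is how a
#' control run records a reward without letting it steer: set its weight to
#' zero. A zero-valued component with positive weight annihilates the
#' combined score (no epsilon flooring), matching hard-filter semantics.
#'
#' @param values numeric vector of component scores; values are clipped to
#'   \[0, 1\] before combining. Non-finite values are an error.
#' @param weights non-negative weights, recycled if scalar; at least one
#'   must be positive.
#' @return A number in \[0, 1\].
#' @examples
#' combine_scores(c(0.729, 0.7, 0.6))                 # equal weights
#' combine_scores(c(0.2, 0.7, 0.6), c(0, 1, 1))       # first is logged-only
#' @export
combine_scores <- function(values, weights = 1) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(values)))
    stop("component values must be finite", call. = FALSE)
  weights <- rep_len(as.numeric(weights), length(values))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  if (sum(weights) == 0)
    stop("at least one component weight must be positive", call. = FALSE)
  values <- pmin(pmax(values, 0), 1)
  active <- weights > 0
  v <- values[active]
  w <- weights[active]
  if (any(v == 0)) return(0)
  exp(sum(w * log(v)) / sum(w))
}
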