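#' @importFrom rlang abort warn inform .data
#' @importFrom stats rpois rbinom rbeta rnbinom qbeta runif rnorm cor
#'   plogis pt integrate model.matrix quantile sd var
#' @importFrom utils head tail
NULL

abort_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "strawyield_validation_error")
}

check_prob <- function(x, field, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort_field(field, "must be a probability in [0, 1]")
  }
  if (!is.null(len) && length(x) != len) {
    abort_field(field, sprintf("must have length %d", len))
  }
  invisible(x)
}

check_nonneg <- function(x, field, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort_field(field, "must be non-negative")
  }
  if (!is.null(len) && length(x) != len) {
    abort_field(field, sprintf("must have length %d", len))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_field(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")),
          class = "strawyield_validation_error")
  }
  invisible(df)
}

#' Log-odds and inverse log-odds
#'
#' `logit()` maps a probability in the open interval (0, 1) to the real
#' line; `inv_logit()` is its exact inverse. Probabilities of exactly 0 or
#' 1 are rejected because their logit is infinite.
#'
#' @param p Numeric vector of probabilities, strictly inside (0, 1).
#' @param x Numeric vector on the logit scale.
#' @return Numeric vector of the same length.
#' @examples
#' logit(0.5)
#' inv_logit(logit(0.25))
#' @export
logit <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    abort_field("p", "must lie strictly inside (0, 1); logit is infinite at 0 and 1")
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  plogis(x)
}
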