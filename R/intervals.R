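# Common container for every interval estimate of R produced by the package.

#' Construct an interval estimate
#'
#' @param lower,upper interval endpoints (`lower <= upper`).
#' @param level nominal coverage in (0, 1).
#' @param method one of `"asymptotic"`, `"bp"`, `"bt"`, `"hpd"`.
#' @param clipped logical; were the endpoints truncated to \[0, 1\]?
#' @return An object of class `"interval_estimate"`.
#' @export
interval_estimate <- function(lower, upper, level, method, clipped = FALSE) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper,
            level > 0, level < 1,
            method %in% c("asymptotic", "bp", "bt", "hpd"))
  structure(list(lower = lower, upper = upper, level = level,
                 method = method, clipped = isTRUE(clipped)),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%d%% %s interval: (%.4f, %.4f)  length %.4f%s\n",
              round(100 * x$level), x$method, x$lower, x$upper,
              x$upper - x$lower,
              if (x$clipped) "  [clipped to [0,1]]" else ""))
  invisible(x)
}
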