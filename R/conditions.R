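# Classed conditions so callers can distinguish bad input from metrics that
# are mathematically undefined on the given counts (zero denominators,
# degenerate marginals). Undefined metrics are never silently coerced to 0.

stop_undefined <- function(msg, metric = NULL, call. = FALSE) {
  cond <- structure(
    class = c("metricomp_undefined_metric", "metricomp_error",
              "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1), metric = metric)
  )
  stop(cond)
}

stop_input <- function(msg) {
  cond <- structure(
    class = c("metricomp_input_error", "metricomp_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

warn_metricomp <- function(msg, class = "metricomp_warning") {
  warning(structure(
    class = c(class, "metricomp_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Evaluate a metric expression, returning NA_real_ (plus the message) when it
# signals an undefined-metric condition. Used by aggregate reports.
catch_undefined <- function(expr) {
  tryCatch(
    list(value = expr, undefined = NULL),
    metricomp_undefined_metric = function(e) {
      list(value = NA_real_, undefined = conditionMessage(e))
    }
  )
}

is_binary01 <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x == 0 | x == 1)
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 ||
      x != round(x)) {
    stop_input(sprintf("'%s' must be a single non-negative integer count", name))
  }
  as.numeric(x)
}
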