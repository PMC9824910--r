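#' Specify how landmark rows are localized around a query
#'
#' Localization turns the landmark dataset into a weighted sample centered
#' at the query subject's current value of one or two landmark variables.
#' The reserved name `"time"` resolves to the visit time and reproduces
#' classical landmark analysis; any covariate (for instance an eGFR-like
#' biomarker) can serve instead. A uniform kernel makes weighting identical
#' to caliper matching; the Epanechnikov kernel down-weights smoothly with
#' distance. The bandwidth is either fixed per variable or adaptive via the
#' span: the gamma-th quantile of the distances between the query value and
#' all training values, so a fraction gamma of rows always falls inside the
#' support.
#'
#' @param variables one or two covariate names (or `"time"`).
#' @param kernel `"epanechnikov"` (default) or `"uniform"`.
#' @param span adaptive-bandwidth span gamma in (0, 1]; exactly one of
#'   `span`/`bandwidth` must be supplied.
#' @param bandwidth fixed positive bandwidth, one value per landmark
#'   variable (recycled if scalar).
#' @param standardize divide each landmark variable by its training-set
#'   standard deviation before computing distances (default `TRUE`), so
#'   that spans are comparable across variables on different scales.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(variables, kernel = c("epanechnikov", "uniform"),
                        span = NULL, bandwidth = NULL, standardize = TRUE) {
  kernel <- match.arg(kernel)
  variables <- as.character(variables)
  if (length(variables) < 1 || length(variables) > 2) {
    stop("between 1 and 2 landmark variables are supported")
  }
  if (is.null(span) == is.null(bandwidth)) {
    stop("exactly one of 'span' or 'bandwidth' must be set")
  }
  if (!is.null(span) && (span <= 0 || span > 1)) {
    stop("span must lie in (0, 1]")
  }
  if (!is.null(bandwidth)) {
    if (any(bandwidth <= 0)) stop("bandwidth must be positive")
    bandwidth <- rep_len(bandwidth, length(variables))
  }
  structure(list(variables = variables, kernel = kernel, span = span,
                 bandwidth = bandwidth, standardize = isTRUE(standardize)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  bw <- if (is.null(x$span)) {
    paste0("h = ", paste(signif(x$bandwidth, 4), collapse = ", "))
  } else {
    paste0("span = ", x$span)
  }
  cat("<kernel_spec> ", x$kernel, " kernel on (",
      paste(x$variables, collapse = ", "), "), ", bw,
      if (x$standardize) ", standardized" else "", "\n", sep = "")
  invisible(x)
}

#' Evaluate a localization kernel
#'
#' The Epanechnikov kernel is \eqn{(4h)^{-1}(1-u^2) 1(|u| \le 1)} and the
#' uniform kernel \eqn{(2h)^{-1} 1(|u| \le 1)}, with \eqn{u = d/h}. The
#' multiplicative constants are irrelevant to weighted partial-likelihood
#' maximization (weight scale cancels) and are kept as written.
#'
#' @param kernel `"epanechnikov"` or `"uniform"`.
#' @param distance nonnegative distance(s) from the query.
#' @param bandwidth positive bandwidth h.
#' @return Kernel value(s), zero outside `[-h, h]`.
#' @export
kernel_value <- function(kernel = c("epanechnikov", "uniform"),
                         distance, bandwidth) {
  kernel <- match.arg(kernel)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  u <- distance / bandwidth
  inside <- abs(u) <= 1
  if (kernel == "epanechnikov") {
    ifelse(inside, (1 - u^2) / (4 * bandwidth), 0)
  } else {
    ifelse(inside, 1 / (2 * bandwidth), 0)
  }
}

#' Span-based adaptive bandwidth
#'
#' Returns the \eqn{\lceil \gamma N \rceil}-th smallest of the distances
#' between the query and the training values of the landmark variable (an
#' order-statistic quantile, no interpolation), so a uniform kernel with
#' this bandwidth matches at least that many rows. A zero quantile (heavily
#' tied data at the query value) falls back to the smallest strictly
#' positive distance.
#'
#' @param distances nonnegative distances from the query to every training
#'   row.
#' @param span gamma in (0, 1].
#' @return Positive bandwidth.
#' @export
span_bandwidth <- function(distances, span) {
  if (length(distances) == 0) stop("no distances supplied")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  k <- ceiling(span * length(distances))
  h <- sort(distances, partial = k)[k]
  if (h == 0) {
    pos <- distances[distances > 0]
    if (length(pos) == 0) {
      stop("degenerate localization: all distances are zero")
    }
    h <- min(pos)
  }
  h
}

#' Compute localization weights over a landmark dataset
#'
#' Per landmark variable, absolute distances between the query value and
#' every row (after optional standardization by the training standard
#' deviation) are converted to kernel weights; with two variables the row
#' weight is the product of the per-variable kernels, so a row must fall
#' inside the support of both to stay matched.
#'
#' @param data a `landmark_dataset`.
#' @param spec a [kernel_spec()].
#' @param query_point numeric vector of landmark-variable values at the
#'   query, one per variable in `spec` (named or in the same order).
#' @param min_events minimum weighted event count among positive-weight
#'   rows (default 10); fewer triggers a sparse-neighborhood error with the
#'   smallest feasible span in the message.
#' @return A `gla_weights` object: `weights` (one per row), `query_point`,
#'   `bandwidths`, `effective_rows`, `effective_events`.
#' @export
compute_weights <- function(data, spec, query_point, min_events = 10) {
  stopifnot(inherits(data, "landmark_dataset"), inherits(spec, "kernel_spec"))
  vars <- spec$variables
  if (length(query_point) != length(vars)) {
    stop("query_point must have one value per landmark variable")
  }
  if (!is.null(names(query_point)) && all(vars %in% names(query_point))) {
    query_point <- query_point[vars]
  }
  n <- nrow(data)
  w <- rep(1, n)
  bws <- numeric(length(vars))
  for (k in seq_along(vars)) {
    col <- landmark_column(data, vars[k])
    d <- abs(query_point[[k]] - col)
    if (is.null(spec$span)) {
      # fixed bandwidths act on the variable's original scale (caliper)
      h <- spec$bandwidth[k]
    } else {
      if (spec$standardize) {
        s <- stats::sd(col)
        if (is.finite(s) && s > 0) d <- d / s
      }
      h <- span_bandwidth(d, spec$span)
    }
    bws[k] <- h
    w <- w * kernel_value(spec$kernel, d, h)
  }
  eff_rows <- sum(w > 0)
  # event count discounted by relative weight; equals the plain count of
  # matched event rows under a uniform kernel
  eff_events <- sum(w / max(w) * data$event)
  if (eff_rows == 0) stop("degenerate localization: all weights are zero")
  if (eff_events < min_events) {
    stop("sparse neighborhood: only ", eff_events, " event(s) among ",
         eff_rows, " positive-weight rows (minimum ", min_events,
         "); enlarge the span or bandwidth",
         if (!is.null(spec$span)) suggest_span(data, spec, query_point,
                                              min_events) else "")
  }
  structure(list(weights = w, query_point = unlist(query_point),
                 bandwidths = stats::setNames(bws, vars),
                 effective_rows = eff_rows, effective_events = eff_events),
            class = "gla_weights")
}

# smallest grid span meeting the event guard, for the sparse-neighborhood
# diagnostic
suggest_span <- function(data, spec, query_point, min_events) {
  for (g in seq(0.05, 1, by = 0.05)) {
    sp <- spec
    sp$span <- g
    ok <- tryCatch({
      wv <- suppressWarnings(compute_weights(data, sp, query_point,
                                             min_events = 0))
      wv$effective_events >= min_events
    }, error = function(e) FALSE)
    if (ok) {
      return(paste0(" (smallest feasible span on a 0.05 grid: ", g, ")"))
    }
  }
  ""
}

# resolve a landmark-variable name, honoring the reserved name "time"
landmark_column <- function(data, var) {
  if (identical(var, "time")) {
    return(data$visit_time)
  }
  if (!var %in% names(data)) {
    stop("landmark variable '", var, "' not found in the landmark dataset")
  }
  data[[var]]
}

#' @export
print.gla_weights <- function(x, ...) {
  cat("<gla_weights> ", x$effective_rows, " matched rows, ",
      x$effective_events, " events; bandwidth(s): ",
      paste(signif(x$bandwidths, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}
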