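#' Read a paleoenvironment series from TSV
#'
#' Two columns: age before present (Myr) and the value of the variable
#' (metres for a paleoelevation history, per-mil d18O or degrees for a
#' temperature proxy). A header row is optional; column names or indices can
#' be selected.
#'
#' @param file path to a tab-separated file.
#' @param age_col,value_col column names or indices.
#' @return a `data.frame` with columns `age` and `value`, class
#'   `"paleo_series"`.
#' @export
read_paleo_series <- function(file, age_col = 1, value_col = 2) {
  first <- strsplit(readLines(file, n = 1), "\t")[[1]]
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  df <- read.delim(file, header = header, stringsAsFactors = FALSE)
  paleo_series(df[[age_col]], df[[value_col]])
}

#' @rdname read_paleo_series
#' @param age,value numeric vectors (ages in Myr before present, >= 0).
#' @export
paleo_series <- function(age, value) {
  if (length(age) != length(value)) stop("age and value lengths differ")
  if (any(!is.finite(age)) || any(!is.finite(value)))
    stop("non-finite entries in the paleo series")
  if (any(age < 0)) stop("ages must be >= 0 (Myr before present)")
  if (length(unique(age)) < 2) stop("need at least 2 distinct ages")
  structure(data.frame(age = age, value = value),
            class = c("paleo_series", "data.frame"))
}

#' Smooth a paleoenvironment series into a covariate curve E(t)
#'
#' Fits a penalized cubic smoothing spline to the series; the smoothing
#' penalty defaults to generalized cross-validation. With `smoothing = 0`
#' (or too few points for a penalized fit) a natural interpolating cubic
#' spline is used, which passes through every (averaged) point. Duplicate
#' ages are averaged first, and the fit does not depend on row order.
#'
#' @param series a `paleo_series` (or any data.frame with `age`, `value`).
#' @param smoothing non-negative penalty (the `lambda` of
#'   [stats::smooth.spline()]); `NULL` selects it by GCV; `0` interpolates.
#' @param units free-text unit label carried along for reporting.
#' @return an object of class `"env_curve"`: a smooth evaluator over
#'   `[0, max(age)]` with constant extrapolation beyond the tabulated range
#'   (rate models need E(t) over the whole tree depth, and clamping avoids
#'   wild spline extrapolation).
#' @export
#' @examples
#' s <- paleo_series(c(0, 10, 20), c(5, 5, 5))
#' cv <- fit_env_curve(s, smoothing = 0)
#' env_value(cv, 7) # 5
fit_env_curve <- function(series, smoothing = NULL, units = "") {
  age <- series$age
  value <- series$value
  # average duplicates, sort by age
  agg <- tapply(value, age, mean)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (length(x) < 2) stop("need at least 2 distinct ages")
  interpolate <- (!is.null(smoothing) && smoothing == 0) ||
    length(x) < 4 || sd(y) == 0
  if (interpolate) {
    fun <- splinefun(x, y, method = "natural")
    lam <- 0
  } else if (is.null(smoothing)) {
    sp <- smooth.spline(x, y, cv = FALSE)
    fun <- function(t) predict(sp, t)$y
    lam <- sp$lambda
  } else {
    if (smoothing < 0) stop("smoothing must be non-negative")
    sp <- smooth.spline(x, y, lambda = smoothing)
    fun <- function(t) predict(sp, t)$y
    lam <- smoothing
  }
  structure(list(fun = fun, t_min = x[1], t_max = x[length(x)],
                 smoothing = lam, units = units),
            class = "env_curve")
}

#' Evaluate an environment curve
#'
#' Deterministic, continuous evaluation of E(t) at times before present.
#' Times beyond the tabulated range are clamped to the boundary value;
#' negative times are an error (the present is t = 0).
#'
#' @param curve an `"env_curve"` from [fit_env_curve()].
#' @param t times before present (Myr), `t >= 0`.
#' @return numeric vector of curve values.
#' @export
env_value <- function(curve, t) {
  if (any(t < 0)) stop("t must be >= 0 (time before present)")
  tc <- pmin(pmax(t, curve$t_min), curve$t_max)
  as.numeric(curve$fun(tc))
}

#' @export
print.env_curve <- function(x, ...) {
  cat(sprintf("env_curve over [%.3g, %.3g] Myr, smoothing %.4g %s\n",
              x$t_min, x$t_max, x$smoothing,
              if (nzchar(x$units)) paste0("(", x$units, ")") else ""))
  invisible(x)
}
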