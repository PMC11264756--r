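#' Fast chlorophyll-a fluorescence transients and the JIP test
#'
#' A fluorescence transient is the polyphasic O-J-I-P rise recorded on a
#' dark-adapted leaf between roughly 10 microseconds and 1 second after the
#' onset of saturating light. The JIP test reduces the curve to a handful of
#' marks (F0 at 50 us, F300 at 300 us, FJ at 2 ms, FM at the maximum) from
#' which quantum-efficiency and performance parameters are derived.
#'
#' @name ojip
NULL

#' Construct a fluorescence transient
#'
#' @param sample_id single character label.
#' @param times acquisition times in seconds, strictly increasing.
#' @param values fluorescence intensities (arbitrary units), same length as
#'   `times`, non-negative.
#'
#' @return An object of class `"transient"`: a list with elements
#'   `sample_id`, `times`, `values`.
#' @examples
#' tr <- transient("s1", c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1), 500 * (1:6))
#' @export
transient <- function(sample_id, times, values) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length", call. = FALSE)
  if (length(times) < 10L)
    warning("transient '", sample_id, "' has fewer than 10 points")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("non-finite time or fluorescence value in '", sample_id, "'",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing in '", sample_id, "'",
         call. = FALSE)
  if (any(times <= 0))
    stop("times must be positive (seconds) in '", sample_id, "'",
         call. = FALSE)
  if (any(values < 0))
    stop("negative fluorescence in '", sample_id, "'", call. = FALSE)
  structure(list(sample_id = sample_id, times = times, values = values),
            class = "transient")
}

#' @export
print.transient <- function(x, ...) {
  cat(sprintf("<transient '%s': %d points, %.3g-%.3g s, F %.4g-%.4g a.u.>\n",
              x$sample_id, length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read fluorescence transients from a delimited file
#'
#' Expects columns `sample_id`, `time_s`, `fluorescence`. Rows are grouped by
#' `sample_id`, sorted by time, and replicate readings at exactly the same
#' time are averaged.
#'
#' @param file path to a CSV/TSV file, or a connection.
#' @param sep field separator, default `","`.
#'
#' @return A named list of [transient()] objects, one per `sample_id`.
#' @export
read_transients <- function(file, sep = ",") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  needed <- c("sample_id", "time_s", "fluorescence")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tab$time_s <- as.numeric(tab$time_s)
  tab$fluorescence <- as.numeric(tab$fluorescence)
  if (any(is.na(tab$time_s)) || any(is.na(tab$fluorescence)))
    stop("non-numeric time_s or fluorescence values", call. = FALSE)
  out <- lapply(split(tab, tab$sample_id), function(d) {
    # average duplicate times, then sort
    agg <- stats::aggregate(fluorescence ~ time_s, data = d, FUN = mean)
    agg <- agg[order(agg$time_s), ]
    transient(as.character(d$sample_id[1L]), agg$time_s, agg$fluorescence)
  })
  out[unique(as.character(tab$sample_id))]
}

#' Extract JIP marks from a transient
#'
#' Reads F0, F300 and FJ at configurable mark times (defaults 50 us, 300 us
#' and 2 ms) by interpolation linear in log10(time) -- appropriate because
#' OJIP acquisitions are log-spaced -- and takes FM as the global maximum of
#' the curve, so transients that peak before the end of acquisition are
#' handled. An optional 3-point running-median filter can be applied first
#' for noisy inputs.
#'
#' @param x a [transient()].
#' @param t_f0,t_f300,t_fj mark times in seconds.
#' @param smooth logical; apply a 3-point median filter before reading marks.
#'
#' @return An object of class `"jip_marks"`: named numeric vector with
#'   elements `F0`, `F300`, `FJ`, `FM`.
#' @examples
#' tr <- simulate_transient(seed = 1)
#' extract_marks(tr)
#' @export
extract_marks <- function(x, t_f0 = 50e-6, t_f300 = 300e-6, t_fj = 2e-3,
                          smooth = FALSE) {
  stopifnot(inherits(x, "transient"))
  v <- x$values
  if (smooth && length(v) >= 3L)
    v <- stats::runmed(v, k = 3L, endrule = "keep")
  marks <- c(F0 = t_f0, F300 = t_f300, FJ = t_fj)
  rng <- range(x$times)
  out_of_range <- marks < rng[1L] | marks > rng[2L]
  if (any(out_of_range))
    stop("mark time(s) ", paste(names(marks)[out_of_range], collapse = ", "),
         " outside the acquired time range [", rng[1L], ", ", rng[2L],
         "] s of '", x$sample_id, "'", call. = FALSE)
  fm <- max(v)
  vals <- stats::approx(log10(x$times), v, xout = log10(marks))$y
  names(vals) <- names(marks)
  if (fm <= vals[["F0"]])
    stop("degenerate transient '", x$sample_id, "': FM <= F0", call. = FALSE)
  structure(c(vals, FM = fm), class = "jip_marks")
}

#' @export
print.jip_marks <- function(x, ...) {
  cat("JIP marks (a.u.):\n")
  print(unclass(x), ...)
  invisible(x)
}

as_jip_marks <- function(m) {
  m <- unlist(m)
  if (!all(c("F0", "F300", "FJ", "FM") %in% names(m)))
    stop("marks must contain F0, F300, FJ, FM", call. = FALSE)
  if (any(m[c("F0", "F300", "FJ", "FM")] <= 0))
    stop("all marks must be positive", call. = FALSE)
  m
}

#' Maximum potential quantum efficiency of PSII
#'
#' `FV/FM = (FM - F0) / FM`, the dark-adapted maximum quantum yield of
#' primary photochemistry.
#'
#' @param marks a `"jip_marks"` object or named vector with `F0` and `FM`.
#' @return Numeric scalar in (0, 1).
#' @examples
#' fv_fm(c(F0 = 500, F300 = 900, FJ = 1500, FM = 2500)) # 0.8
#' @export
fv_fm <- function(marks) {
  m <- as_jip_marks(marks)
  if (m[["FM"]] <= m[["F0"]])
    stop("FV/FM undefined: FM must exceed F0", call. = FALSE)
  unname((m[["FM"]] - m[["F0"]]) / m[["FM"]])
}

#' Initial slope M0 and relative variable fluorescence VJ
#'
#' `M0 = 4 * (F300 - F0) / (FM - F0)` approximates the initial slope of the
#' relative variable fluorescence curve (per ms, with F300 read at 300 us);
#' `VJ = (FJ - F0) / (FM - F0)` is the relative variable fluorescence at the
#' J step (2 ms). `VJ = 1` (FJ at the maximum) is returned but makes the
#' downstream performance index undefined.
#'
#' @inheritParams fv_fm
#' @return Named numeric vector `c(M0 = , VJ = )`.
#' @examples
#' m0_vj(c(F0 = 500, F300 = 900, FJ = 1500, FM = 2500)) # M0 0.8, VJ 0.5
#' @export
m0_vj <- function(marks) {
  m <- as_jip_marks(marks)
  fv <- m[["FM"]] - m[["F0"]]
  if (fv <= 0)
    stop("M0/VJ undefined: FM must exceed F0", call. = FALSE)
  c(M0 = 4 * (m[["F300"]] - m[["F0"]]) / fv,
    VJ = (m[["FJ"]] - m[["F0"]]) / fv)
}

#' Performance index on absorption basis (PIabs)
#'
#' Composite JIP-test index combining reaction-centre density, trapping
#' probability and electron-transport probability:
#' \deqn{PI_{ABS} = \frac{1 - F_0/F_M}{M_0/V_J} \cdot \frac{F_M - F_0}{F_0}
#'   \cdot \frac{1 - V_J}{V_J}}
#'
#' The `variant` argument controls the middle term. `"standard"` (default)
#' uses the usual reaction-centre term `(FM - F0) / F0`. `"as_printed"` uses
#' the dimensionally anomalous literal form `(FM / F0) / F0` that sometimes
#' appears in print; it is provided so either reading can be reproduced, and
#' the variant used is recorded in tabulated output.
#'
#' @inheritParams fv_fm
#' @param variant `"standard"` or `"as_printed"`.
#' @return Numeric scalar > 0.
#' @examples
#' m <- c(F0 = 500, F300 = 900, FJ = 1500, FM = 2500)
#' pi_abs(m)                         # 2.0
#' pi_abs(m, variant = "as_printed") # 0.005
#' @export
pi_abs <- function(marks, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  m <- as_jip_marks(marks)
  mv <- m0_vj(m)
  if (mv[["VJ"]] <= 0 || mv[["VJ"]] >= 1)
    stop("PIabs undefined: VJ must lie strictly in (0, 1)", call. = FALSE)
  if (mv[["M0"]] <= 0)
    stop("PIabs undefined: M0 must be positive", call. = FALSE)
  rc_term <- switch(variant,
    standard   = (m[["FM"]] - m[["F0"]]) / m[["F0"]],
    as_printed = (m[["FM"]] / m[["F0"]]) / m[["F0"]])
  (1 - m[["F0"]] / m[["FM"]]) / (mv[["M0"]] / mv[["VJ"]]) *
    rc_term * (1 - mv[["VJ"]]) / mv[["VJ"]]
}

#' JIP parameters for a set of transients
#'
#' Convenience wrapper: extracts marks from each transient and tabulates the
#' marks together with M0, VJ, FV/FM and PIabs.
#'
#' @param transients a list of [transient()] objects (as returned by
#'   [read_transients()]) or a single transient.
#' @param variant passed to [pi_abs()].
#' @param ... passed to [extract_marks()].
#' @return A data frame with one row per sample: `sample_id`, `F0`, `F300`,
#'   `FJ`, `FM`, `M0`, `VJ`, `FvFm`, `PIabs`, `variant`.
#' @export
jip_parameters <- function(transients, variant = c("standard", "as_printed"),
                           ...) {
  variant <- match.arg(variant)
  if (inherits(transients, "transient")) transients <- list(transients)
  rows <- lapply(transients, function(tr) {
    m <- extract_marks(tr, ...)
    mv <- m0_vj(m)
    data.frame(sample_id = tr$sample_id,
               F0 = m[["F0"]], F300 = m[["F300"]], FJ = m[["FJ"]],
               FM = m[["FM"]], M0 = mv[["M0"]], VJ = mv[["VJ"]],
               FvFm = fv_fm(m), PIabs = pi_abs(m, variant),
               variant = variant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
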