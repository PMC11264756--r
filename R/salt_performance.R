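#' Relative salinity values, reduction factors and the salt performance index
#'
#' A variety panel is measured on two salinity platforms (low = 4 dS/m,
#' medium = 8 dS/m) at up to three growth stages (leaf3, boot, flowering),
#' with six replicates per cell. The screening statistic works on relative
#' values (medium-platform mean / low-platform mean), on reduction factors
#' (relative value at leaf 3 / relative value at flowering, a decline
#' magnitude under progressive salinity), and on the salt performance index
#' \deqn{SPI = \log_{10} A + n \log_{10} B}
#' where A and B are the relative values of the selected marker parameter at
#' leaf 3 and at late flowering, and n is the integer significant reduction
#' factor weighting the flowering-stage decline.
#'
#' @name salt_performance
NULL

.stages <- c("leaf3", "boot", "flowering")
.platforms <- c("low", "medium")

check_panel <- function(panel, parameters) {
  needed <- c("variety", "stage", "platform", "replicate", parameters)
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols))
    stop("panel is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(panel$platform), .platforms)
  if (length(bad))
    stop("unknown platform level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(panel)
}

#' Relative (medium/low salinity) values per variety, stage and parameter
#'
#' For every (variety, stage, parameter) cell the relative value is the mean
#' over replicates on the medium-salinity platform divided by the mean on the
#' low-salinity platform. Dry matter, where present, yields the dry-matter
#' gain (medium/low mass ratio) in the same way. Cells with fewer than six
#' replicates are used with a warning; a zero low-platform mean is an error
#' naming the cell.
#'
#' @param panel long data frame with columns `variety`, `stage` (one of
#'   `leaf3`, `boot`, `flowering`), `platform` (`low`/`medium`),
#'   `replicate`, and one column per measured parameter.
#' @param parameters character vector of parameter columns to use; default
#'   all of `NPQ`, `ETR`, `FvFm`, `A`, `PIabs`, `dry_matter` that are
#'   present.
#' @return Data frame `variety`, `stage`, `parameter`, `relative_value`,
#'   `n_medium`, `n_low` (replicates behind each mean).
#' @export
relative_values <- function(panel, parameters = NULL) {
  if (is.null(parameters))
    parameters <- intersect(c("NPQ", "ETR", "FvFm", "A", "PIabs",
                              "dry_matter"), names(panel))
  check_panel(panel, parameters)
  rows <- list()
  for (p in parameters) {
    d <- panel[!is.na(panel[[p]]), c("variety", "stage", "platform")]
    d$value <- panel[[p]][!is.na(panel[[p]])]
    if (!nrow(d)) next
    agg <- stats::aggregate(value ~ variety + stage + platform, data = d,
                            FUN = mean)
    cnt <- stats::aggregate(value ~ variety + stage + platform, data = d,
                            FUN = length)
    med <- agg[agg$platform == "medium", ]
    low <- agg[agg$platform == "low", ]
    m <- merge(med, low, by = c("variety", "stage"),
               suffixes = c("_medium", "_low"))
    if (!nrow(m)) next
    cm <- cnt[cnt$platform == "medium", ]
    cl <- cnt[cnt$platform == "low", ]
    m <- merge(m, stats::setNames(cm[c("variety", "stage", "value")],
                                  c("variety", "stage", "n_medium")),
               by = c("variety", "stage"))
    m <- merge(m, stats::setNames(cl[c("variety", "stage", "value")],
                                  c("variety", "stage", "n_low")),
               by = c("variety", "stage"))
    if (any(m$value_low == 0)) {
      bad <- m[m$value_low == 0, ][1L, ]
      stop("low-platform mean is zero for variety ", bad$variety,
           ", stage ", bad$stage, ", parameter ", p, call. = FALSE)
    }
    if (any(m$n_medium < 6 | m$n_low < 6))
      warning("parameter ", p, ": some cells have fewer than 6 replicates")
    rows[[p]] <- data.frame(variety = m$variety, stage = m$stage,
                            parameter = p,
                            relative_value = m$value_medium / m$value_low,
                            n_medium = m$n_medium, n_low = m$n_low,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dry-matter gain per variety
#'
#' The ratio of dry-matter mass at medium salinity to that at low salinity,
#' taken from the post-harvest `dry_matter` records of a panel.
#'
#' @inheritParams relative_values
#' @return Data frame `variety`, `dm_gain`.
#' @export
dm_gain <- function(panel) {
  rel <- relative_values(panel, parameters = "dry_matter")
  if (is.null(rel) || !nrow(rel))
    stop("no dry_matter records in panel", call. = FALSE)
  agg <- stats::aggregate(relative_value ~ variety, data = rel, FUN = mean)
  stats::setNames(agg, c("variety", "dm_gain"))
}

#' Stage-to-stage reduction factors
#'
#' The reduction factor RF of a parameter for a variety is its relative
#' value at leaf 3 divided by its relative value at late flowering; RF > 1
#' indicates a decline under progressive salinity. Significance of the
#' decline is assessed per variety and parameter by a one-way ANOVA contrast
#' between the replicate-level relative values (each medium-platform
#' replicate divided by its cell's low-platform mean) at leaf 3 versus
#' flowering, at level `alpha`. Cells with fewer than 3 replicates are
#' excluded from significance testing (RF still reported, `significant` NA).
#'
#' @inheritParams relative_values
#' @param alpha significance level of the stage contrast (default 0.01).
#' @return Data frame `variety`, `parameter`, `RF`, `p_value`,
#'   `significant`.
#' @export
reduction_factors <- function(panel, parameters = NULL, alpha = 0.01) {
  if (is.null(parameters))
    parameters <- intersect(c("NPQ", "ETR", "FvFm", "A", "PIabs"),
                            names(panel))
  rel <- relative_values(panel, parameters)
  rel <- rel[rel$stage %in% c("leaf3", "flowering"), ]
  rows <- list()
  for (p in parameters) {
    for (v in unique(rel$variety[rel$parameter == p])) {
      r <- rel[rel$parameter == p & rel$variety == v, ]
      r_l3 <- r$relative_value[r$stage == "leaf3"]
      r_fl <- r$relative_value[r$stage == "flowering"]
      if (!length(r_l3) || !length(r_fl)) next
      if (r_fl == 0)
        stop("flowering relative value is zero for variety ", v,
             ", parameter ", p, ": RF undefined", call. = FALSE)
      # replicate-level relative values for the contrast
      reps <- replicate_relatives(panel, v, p)
      pv <- NA_real_
      if (all(table(reps$stage) >= 3L) &&
          length(unique(reps$stage)) == 2L) {
        # degenerate contrasts (e.g. replicate-free toy panels) yield NA
        pv <- tryCatch(one_way_anova(reps$rel, reps$stage)$p,
                       error = function(e) NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variety = v, parameter = p, RF = r_l3 / r_fl, p_value = pv,
        significant = if (is.na(pv)) NA else pv <= alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# medium-platform replicates scaled by the low-platform cell mean,
# restricted to the leaf3/flowering stages of one variety x parameter
replicate_relatives <- function(panel, variety, parameter) {
  d <- panel[panel$variety == variety &
               panel$stage %in% c("leaf3", "flowering") &
               !is.na(panel[[parameter]]), ]
  out <- list()
  for (s in intersect(c("leaf3", "flowering"), unique(d$stage))) {
    lowm <- mean(d[[parameter]][d$stage == s & d$platform == "low"])
    med <- d[[parameter]][d$stage == s & d$platform == "medium"]
    if (!is.finite(lowm) || lowm == 0 || !length(med)) next
    out[[s]] <- data.frame(stage = s, rel = med / lowm,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Select the marker parameter and the SPI weight n
#'
#' Among parameters whose stage decline is significant and of consistent
#' sign (RF > 1) in at least `consistency` of the varieties (default all of
#' them, i.e. a significant reduction across all varieties), picks the one
#' with the largest mean RF. The SPI weight is `n = max(1, round(mean RF))`.
#' Ties on mean RF are broken by the larger fraction of significant
#' varieties, then lexicographically by parameter name, so the choice does
#' not depend on input order.
#'
#' @param rfs data frame from [reduction_factors()].
#' @param consistency minimum fraction of varieties that must show a
#'   significant decline (default 1).
#' @return List with `parameter`, `n`, `mean_RF`, and the per-parameter
#'   candidate table.
#' @export
select_marker <- function(rfs, consistency = 1) {
  stopifnot(all(c("variety", "parameter", "RF", "significant") %in%
                  names(rfs)))
  if (length(unique(rfs$variety)) < 2L)
    stop("marker selection needs at least 2 varieties", call. = FALSE)
  cand <- do.call(rbind, lapply(split(rfs, rfs$parameter), function(d) {
    ok <- !is.na(d$significant) & d$significant & d$RF > 1
    data.frame(parameter = d$parameter[1L], mean_RF = mean(d$RF),
               frac_significant = mean(ok), stringsAsFactors = FALSE)
  }))
  rownames(cand) <- NULL
  eligible <- cand[cand$frac_significant >= consistency, ]
  if (!nrow(eligible))
    stop("no parameter shows a consistent significant decline in >= ",
         round(100 * consistency), "% of varieties; lower `consistency` ",
         "or set the marker manually", call. = FALSE)
  ord <- order(-eligible$mean_RF, -eligible$frac_significant,
               eligible$parameter)
  best <- eligible[ord[1L], ]
  list(parameter = best$parameter,
       n = max(1L, as.integer(round(best$mean_RF))),
       mean_RF = best$mean_RF, candidates = cand)
}

#' Salt performance index
#'
#' `SPI = log10(A) + n * log10(B)` per variety, where A is the relative
#' value of the marker parameter at leaf 3 and B its relative value at late
#' flowering. Varieties that hold their marker value until flowering under
#' salinity (B near 1) score near 0; strong late declines are penalised n
#' times as heavily as early ones.
#'
#' @param rel data frame from [relative_values()].
#' @param marker parameter name to use (e.g. `"PIabs"`).
#' @param n integer reduction-factor weight (>= 1).
#' @param base logarithm base, default 10.
#' @return Data frame of class `"spi"`: `variety`, `A_rel`, `B_rel`, `n`,
#'   `SPI`.
#' @examples
#' # A_rel = 1.2, B_rel = 0.6, n = 2  ->  SPI = -0.3645
#' @export
spi <- function(rel, marker, n, base = 10) {
  stopifnot(is.numeric(n), n >= 1)
  r <- rel[rel$parameter == marker & rel$stage %in% c("leaf3", "flowering"), ]
  if (!nrow(r))
    stop("no relative values for marker '", marker, "'", call. = FALSE)
  a <- r[r$stage == "leaf3", c("variety", "relative_value")]
  b <- r[r$stage == "flowering", c("variety", "relative_value")]
  m <- merge(stats::setNames(a, c("variety", "A_rel")),
             stats::setNames(b, c("variety", "B_rel")), by = "variety")
  if (any(m$A_rel <= 0 | m$B_rel <= 0))
    stop("relative values must be positive: SPI takes their logarithm",
         call. = FALSE)
  m$n <- n
  m$SPI <- log(m$A_rel, base) + n * log(m$B_rel, base)
  class(m) <- c("spi", "data.frame")
  m
}

#' @export
print.spi <- function(x, ...) {
  cat(sprintf("Salt performance index (n = %d) for %d varieties\n",
              x$n[1L], nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Correlations of SPI with the relative marker value and dry-matter gain
#'
#' Pearson correlation (r, R squared, two-sided p) of SPI against the
#' flowering-stage relative marker value and, where dry matter is available,
#' against the dry-matter gain. The paired scatter table is returned for
#' plotting.
#'
#' @param spis `"spi"` data frame from [spi()].
#' @param rel data frame from [relative_values()] (for the marker column).
#' @param dm optional data frame `variety`, `dm_gain` from [dm_gain()].
#' @param marker marker parameter name; default taken from the SPI input's
#'   provenance is not stored, so pass the same marker used for [spi()].
#' @return List of class `"spi_correlations"` with elements `marker`
#'   and `dm_gain`, each `list(r, r_squared, p, n)`, plus `data`.
#' @export
spi_correlations <- function(spis, rel, dm = NULL, marker = "PIabs") {
  b <- rel[rel$parameter == marker & rel$stage == "flowering",
           c("variety", "relative_value")]
  d <- merge(as.data.frame(spis)[c("variety", "SPI")], b, by = "variety")
  names(d)[names(d) == "relative_value"] <- "marker_rel"
  if (!is.null(dm)) d <- merge(d, dm, by = "variety", all.x = TRUE)
  if (nrow(d) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  pearson <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) return(NULL)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance: correlation undefined", call. = FALSE)
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p = ct$p.value, n = length(x))
  }
  out <- list(marker = pearson(d$SPI, d$marker_rel),
              dm_gain = if (!is.null(dm)) pearson(d$SPI, d$dm_gain),
              data = d)
  class(out) <- "spi_correlations"
  out
}

#' @export
print.spi_correlations <- function(x, ...) {
  cat("SPI correlations (Pearson):\n")
  show <- function(lbl, s) {
    if (is.null(s)) return()
    cat(sprintf("  %-22s r = %.3f  R^2 = %.3f  p = %.3g  (n = %d)\n",
                lbl, s$r, s$r_squared, s$p, s$n))
  }
  show("vs relative marker", x$marker)
  show("vs dry-matter gain", x$dm_gain)
  invisible(x)
}
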