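#' Relative expression by the 2^-ddCt method
#'
#' Threshold-cycle (Ct) tables from paired control (low-salinity) and
#' treated (medium-salinity) samples are converted to fold changes with a
#' designated reference gene: `dCt = Ct_target - Ct_reference` within each
#' condition (replicate Cts averaged first), `ddCt = dCt_treated -
#' dCt_control`, fold = `2^-ddCt`. Amplification efficiency is fixed at 2
#' (pure doubling per cycle); no efficiency correction is applied.
#'
#' @param ct data frame with columns `sample` (variety id), `condition`
#'   (`control` / `treated`), `gene`, `Ct` (cycles, > 0). Replicates are
#'   extra rows.
#' @param reference reference gene id (default `"EF1"`).
#' @param log2_fold also return the log2 fold-change matrix (equal to
#'   `-ddCt` exactly).
#' @return List of class `"ddct"` with `fold` (matrix varieties x genes),
#'   `ddct`, `sd_ddct` (SD propagated from replicate Ct SDs, reported for
#'   information), and optionally `log2_fold`. Genes missing a condition in
#'   a sample are skipped with a warning; a missing reference Ct is an
#'   error naming the cell.
#' @examples
#' ct <- data.frame(
#'   sample = "V1", condition = rep(c("treated", "control"), each = 2),
#'   gene = rep(c("g1", "EF1"), 2), Ct = c(20, 18, 22, 18))
#' ddct(ct)$fold  # 4: two fewer cycles to threshold after normalisation
#' @export
ddct <- function(ct, reference = "EF1", log2_fold = FALSE) {
  stopifnot(all(c("sample", "condition", "gene", "Ct") %in% names(ct)))
  if (any(!is.finite(ct$Ct)) || any(ct$Ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  bad <- setdiff(unique(ct$condition), c("control", "treated"))
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  samples <- unique(as.character(ct$sample))
  genes <- setdiff(unique(as.character(ct$gene)), reference)
  fold <- ddmat <- sdmat <- matrix(NA_real_, length(samples), length(genes),
                                   dimnames = list(samples, genes))
  for (s in samples) {
    for (cond in c("control", "treated")) {
      ref <- ct$Ct[ct$sample == s & ct$condition == cond &
                     ct$gene == reference]
      if (!length(ref))
        stop("missing reference (", reference, ") Ct for sample ", s,
             ", condition ", cond, call. = FALSE)
    }
    for (g in genes) {
      vals <- lapply(c("control", "treated"), function(cond) {
        tgt <- ct$Ct[ct$sample == s & ct$condition == cond & ct$gene == g]
        ref <- ct$Ct[ct$sample == s & ct$condition == cond &
                       ct$gene == reference]
        list(dct = mean(tgt) - mean(ref),
             var = (if (length(tgt) > 1) stats::var(tgt) / length(tgt) else 0) +
                   (if (length(ref) > 1) stats::var(ref) / length(ref) else 0),
             n = length(tgt))
      })
      if (any(vapply(vals, function(v) v$n == 0L, logical(1)))) {
        warning("gene ", g, " missing a condition for sample ", s,
                "; skipped")
        next
      }
      dd <- vals[[2L]]$dct - vals[[1L]]$dct
      ddmat[s, g] <- dd
      fold[s, g] <- 2^(-dd)
      sdmat[s, g] <- sqrt(vals[[1L]]$var + vals[[2L]]$var)
    }
  }
  out <- list(fold = fold, ddct = ddmat, sd_ddct = sdmat,
              reference = reference)
  if (log2_fold) out$log2_fold <- -ddmat
  class(out) <- "ddct"
  out
}

#' @export
print.ddct <- function(x, ...) {
  cat(sprintf("2^-ddCt fold changes (reference gene %s):\n", x$reference))
  print(round(x$fold, 3))
  invisible(x)
}

#' Hierarchical ordering of an expression matrix for heatmap display
#'
#' Average-linkage clustering on Euclidean distances of the log2 fold
#' changes, the conventional ordering behind clustered expression heatmaps.
#'
#' @param x a `"ddct"` result or a numeric fold-change matrix.
#' @return List with `row_order`, `col_order` (index vectors) and the two
#'   `hclust` objects.
#' @export
expression_clustering <- function(x) {
  m <- if (inherits(x, "ddct")) x$fold else as.matrix(x)
  lm2 <- log2(m)
  hr <- stats::hclust(stats::dist(lm2), method = "average")
  hc <- stats::hclust(stats::dist(t(lm2)), method = "average")
  list(row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}
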