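#' One-way ANOVA, Duncan's multiple range test, correlation matrices
#'
#' Group comparisons used throughout the screening: a classical one-way
#' ANOVA across varieties or treatments, Duncan's multiple range test with a
#' compact letter display for post-hoc separation of group means, and
#' pairwise Pearson correlation matrices.
#'
#' @name group_stats
NULL

check_groups <- function(values, group, min_per_group = 2L) {
  stopifnot(length(values) == length(group))
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- as.character(group[ok])
  n <- table(group)
  if (length(n) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(n < min_per_group))
    stop("every group needs at least ", min_per_group, " values",
         call. = FALSE)
  list(values = values, group = factor(group, levels = unique(group)))
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via [stats::aov()]; the p value
#' comes from the F distribution.
#'
#' @param values numeric response vector.
#' @param group group labels, same length.
#' @return List `F`, `df1`, `df2`, `p`, `MSE` (within-group mean square).
#' @export
one_way_anova <- function(values, group) {
  d <- check_groups(values, group)
  within_var <- tapply(d$values, d$group, stats::var)
  if (all(within_var == 0) )
    stop("zero within-group variance in every group: F undefined",
         call. = FALSE)
  fit <- stats::aov(values ~ group, data = d)
  tab <- summary(fit)[[1L]]
  list(F = tab[1L, "F value"], df1 = tab[1L, "Df"], df2 = tab[2L, "Df"],
       p = tab[1L, "Pr(>F)"], MSE = tab[2L, "Mean Sq"])
}

# Duncan protection-level critical range for a span of p ordered means:
# R_p = q(1 - alpha_p; p, df) * sqrt(MSE / n), alpha_p = 1 - (1-alpha)^(p-1),
# with q the studentized-range quantile.
duncan_ranges <- function(k, df_error, mse, n, alpha) {
  p <- 2:k
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  q <- stats::qtukey(1 - alpha_p, nmeans = p, df = df_error)
  stats::setNames(q * sqrt(mse / n), paste0("R", p))
}

#' Duncan's multiple range test with compact letter display
#'
#' Group means are ordered and every span of p consecutive ordered means is
#' compared against the critical range `R_p = q(1 - alpha_p; p, df_error) *
#' sqrt(MSE / n)`, where `alpha_p = 1 - (1 - alpha)^(p - 1)` is Duncan's
#' protection level and q is the studentized-range quantile. The standard
#' protection rule applies: a pair is declared non-significant if any span
#' containing it fails its range test, so declarations are consistent by
#' construction. Letters are assigned with the insert-and-absorb algorithm:
#' groups sharing a letter are connected by a chain of non-significant
#' comparisons.
#'
#' Unbalanced designs fall back to the harmonic mean of the group sizes with
#' a warning.
#'
#' @inheritParams one_way_anova
#' @param alpha significance level (default 0.05).
#' @return Object of class `"duncan"`: list with `means` (data frame
#'   `group`, `mean`, `n`, `letters`, sorted by descending mean),
#'   `critical_ranges`, `MSE`, `df_error`, `alpha`, and the logical matrix
#'   `different` of pairwise decisions (ordered-mean indexing).
#' @export
duncan_mrt <- function(values, group, alpha = 0.05) {
  d <- check_groups(values, group)
  av <- one_way_anova(d$values, d$group)
  means <- tapply(d$values, d$group, mean)
  sizes <- tapply(d$values, d$group, length)
  n <- sizes[1L]
  if (length(unique(sizes)) > 1L) {
    n <- length(sizes) / sum(1 / sizes)
    warning("unbalanced groups: using the harmonic mean n = ",
            signif(n, 4), " for critical ranges")
  }
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  ranges <- duncan_ranges(k, av$df2, av$MSE, n, alpha)
  # exceeds[i,j]: the raw range test for ordered means i..j (i < j)
  different <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  nonsig_span <- matrix(FALSE, k, k)
  for (span in if (k >= 2) k:2 else integer(0)) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (m[i] - m[j] <= ranges[[paste0("R", span)]])
        nonsig_span[i, j] <- TRUE
    }
  }
  # protection: a pair (i,j) differs iff its own span test exceeds R_p and
  # no enclosing span was non-significant
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      enclosed_ns <- FALSE
      for (a in seq_len(i)) {
        for (b in j:k) {
          if (nonsig_span[a, b]) { enclosed_ns <- TRUE; break }
        }
        if (enclosed_ns) break
      }
      different[i, j] <- different[j, i] <- !enclosed_ns && !nonsig_span[i, j]
    }
  }
  letters_vec <- cld_insert_absorb(!different)
  out <- list(means = data.frame(group = names(m), mean = unname(m),
                                 n = unname(sizes[ord]),
                                 letters = letters_vec,
                                 stringsAsFactors = FALSE),
              critical_ranges = ranges, MSE = av$MSE, df_error = av$df2,
              alpha = alpha, different = different)
  class(out) <- "duncan"
  out
}

# Compact letter display by insert-and-absorb on a symmetric "same"
# (non-significance) matrix over means already sorted descending.
cld_insert_absorb <- function(same) {
  k <- nrow(same)
  cols <- list(rep(TRUE, k)) # start with one letter covering everything
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (same[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          # split the offending letter column into two
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      # absorb: drop columns whose membership is a subset of another's
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a == b || drop[a] || drop[b]) next
          if (all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
            drop[a] <- TRUE
          else if (a < b && identical(cols[[a]], cols[[b]]))
            drop[b] <- TRUE
        }
      }
      cols <- cols[!drop]
    }
  }
  # order letters by first (highest-mean) member
  first <- vapply(cols, function(col) which(col)[1L], integer(1))
  cols <- cols[order(first)]
  vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(cols, function(col) col[i], logical(1)))],
           collapse = "")
  }, character(1))
}

#' @export
print.duncan <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, df error = %d, MSE = %.4g)\n",
              x$alpha, x$df_error, x$MSE))
  print.data.frame(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise Pearson r with two-sided t-test p values over the numeric
#' columns of a table (rows = varieties or observations). Constant columns
#' are flagged and excluded.
#'
#' @param table data frame or matrix of numeric columns; >= 3 rows.
#' @return List of class `"correlation_matrix"` with matrices `r`,
#'   `r_squared`, `p` (symmetric, unit diagonal on `r`), and `excluded`.
#' @export
correlation_matrix <- function(table) {
  x <- as.data.frame(table)
  x <- x[vapply(x, is.numeric, logical(1))]
  if (nrow(x) < 3L)
    stop("need at least 3 rows", call. = FALSE)
  const <- vapply(x, function(col) stats::sd(col, na.rm = TRUE) == 0,
                  logical(1))
  excluded <- names(x)[const]
  if (length(excluded)) {
    warning("constant column(s) excluded: ",
            paste(excluded, collapse = ", "))
    x <- x[!const]
  }
  if (ncol(x) < 2L)
    stop("need at least 2 non-constant columns", call. = FALSE)
  k <- ncol(x)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(names(x), names(x))
  diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ct <- stats::cor.test(x[[i]], x[[j]])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, r_squared = r^2, p = p, excluded = excluded),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Pearson correlation matrix (r):\n")
  print(round(x$r, 3))
  invisible(x)
}
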