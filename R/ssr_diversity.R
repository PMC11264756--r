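#' SSR genotypes, diversity statistics and Shannon-information AMOVA
#'
#' Genotypes are diploid band-score calls ("a/b", top band / bottom band)
#' at SSR (microsatellite) loci. Per-locus diversity is summarised by allele
#' counts and frequencies, observed heterozygosity, gene diversity
#' (expected heterozygosity) and the polymorphism information content.
#' Population differentiation is partitioned by Shannon information: the
#' pooled allelic entropy at each locus splits exactly into the mean
#' within-population entropy plus the among-population mutual information,
#' and 2N times each component (N = allele copies) is a chi-square
#' distributed G statistic. Variance components come from a standard
#' two-level AMOVA on allele mismatch distances, and P values from random
#' reassignment of individuals to populations.
#'
#' @name ssr_diversity
NULL

#' Construct an SSR genotype matrix
#'
#' @param a1,a2 character matrices (individuals x loci) of allele labels:
#'   first (top band) and second (bottom band) allele of each diploid call.
#'   `NA` in both marks a missing call.
#' @param individuals,loci optional id vectors; default from dimnames.
#' @return Object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(a1, a2, individuals = rownames(a1),
                            loci = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(all(dim(a1) == dim(a2)))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing calls: both alleles must be present or both NA",
         call. = FALSE)
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(list(individuals = individuals, loci = loci,
                 a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d individuals x %d loci, %.1f%% missing>\n",
              length(x$individuals), length(x$loci),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Read an SSR genotype table
#'
#' CSV with individuals in rows and loci in columns; cells are diploid
#' band-score calls `"a/b"` (equal labels mean homozygous) or `NA`/empty for
#' missing. The first column holds individual ids.
#'
#' @param file path or connection.
#' @param sep field separator.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(file, sep = ",") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, row.names = 1L,
                           check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(tab)
  split_call <- function(cell) {
    if (is.na(cell)) return(c(NA_character_, NA_character_))
    parts <- strsplit(cell, "/", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) parts <- c(parts, parts)
    if (length(parts) != 2L)
      stop("malformed genotype call '", cell, "'", call. = FALSE)
    trimws(parts)
  }
  a1 <- m; a2 <- m
  for (j in seq_len(ncol(m))) {
    parsed <- vapply(m[, j], split_call, character(2))
    a1[, j] <- parsed[1L, ]; a2[, j] <- parsed[2L, ]
  }
  genotype_matrix(a1, a2, rownames(tab), colnames(tab))
}

#' Convert presence/absence band scores to diploid calls
#'
#' SSR gels scored as present (1) / missing (0) bands are converted per
#' individual and marker: two scored bands become a heterozygous call with
#' the top band first, one band a homozygote, none a missing call; more
#' than two scored bands is an error (not interpretable as a diploid call).
#' Band labels are ordered by decreasing fragment position, i.e. the first
#' label in sorted order is taken as the top band.
#'
#' @param x long data frame with columns `individual`, `locus`, `band`
#'   (label identifying the band within the locus), `present` (0/1).
#' @return A [genotype_matrix()].
#' @export
bands_to_genotypes <- function(x) {
  stopifnot(all(c("individual", "locus", "band", "present") %in% names(x)))
  inds <- unique(as.character(x$individual))
  locs <- unique(as.character(x$locus))
  a1 <- matrix(NA_character_, length(inds), length(locs),
               dimnames = list(inds, locs))
  a2 <- a1
  for (l in locs) {
    xl <- x[x$locus == l, ]
    for (i in inds) {
      bands <- sort(as.character(xl$band[xl$individual == i &
                                           xl$present == 1]))
      if (length(bands) > 2L)
        stop("individual ", i, ", locus ", l, ": ", length(bands),
             " scored bands cannot form a diploid call", call. = FALSE)
      if (length(bands) == 2L) { a1[i, l] <- bands[1L]; a2[i, l] <- bands[2L] }
      if (length(bands) == 1L) { a1[i, l] <- bands;     a2[i, l] <- bands }
    }
  }
  genotype_matrix(a1, a2, inds, locs)
}

#' Per-locus diversity summaries
#'
#' Allele frequencies are estimated from allele counts over non-missing
#' calls (missing calls excluded locus-wise). Observed heterozygosity Ho is
#' the fraction of heterozygous individuals; gene diversity (expected
#' heterozygosity) is `He = 1 - sum(p_i^2)`; the polymorphism information
#' content is `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param g a [genotype_matrix()].
#' @return Data frame of class `"locus_summary"`: `locus`, `n` (typed
#'   individuals), `allele_count`, `Ho`, `He`, `PIC`; per-locus frequency
#'   vectors in the `"frequencies"` attribute. All-missing loci are dropped
#'   with a warning.
#' @export
locus_summaries <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  rows <- list(); freqs <- list()
  for (l in g$loci) {
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    ok <- !is.na(a1)
    if (!any(ok)) {
      warning("locus ", l, " has no non-missing calls; excluded")
      next
    }
    alleles <- c(a1[ok], a2[ok])
    counts <- table(alleles)
    p <- as.numeric(counts) / sum(counts)
    names(p) <- names(counts)
    sp2 <- sum(p^2)
    rows[[l]] <- data.frame(
      locus = l, n = sum(ok), allele_count = length(p),
      Ho = mean(a1[ok] != a2[ok]),
      He = 1 - sp2,
      PIC = 1 - sp2 - (sp2^2 - sum(p^4)),
      stringsAsFactors = FALSE)
    freqs[[l]] <- p
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "frequencies") <- freqs
  class(out) <- c("locus_summary", "data.frame")
  out
}

#' Panel-level diversity aggregates
#'
#' @param summaries a `"locus_summary"` data frame from [locus_summaries()].
#' @return List: `n_loci`, `total_alleles`, `mean_alleles_per_locus`,
#'   `Ho_range`, `PIC_range`, `PIC_mean`, `He_mean`.
#' @export
panel_summary <- function(summaries) {
  stopifnot(nrow(summaries) >= 1L)
  list(n_loci = nrow(summaries),
       total_alleles = sum(summaries$allele_count),
       mean_alleles_per_locus = mean(summaries$allele_count),
       Ho_range = range(summaries$Ho),
       PIC_range = range(summaries$PIC),
       PIC_mean = mean(summaries$PIC),
       He_mean = mean(summaries$He))
}

# integer allele codes with global bin offsets; returns list(codes = n x 2L
# matrix of global bin ids (NA for missing), locus_of_bin, n_bins)
encode_alleles <- function(g) {
  L <- length(g$loci)
  codes1 <- matrix(NA_integer_, nrow(g$a1), L)
  codes2 <- codes1
  offsets <- integer(L); locus_of_bin <- integer(0)
  off <- 0L
  for (j in seq_len(L)) {
    lv <- sort(unique(c(g$a1[, j], g$a2[, j])))
    lv <- lv[!is.na(lv)]
    codes1[, j] <- off + match(g$a1[, j], lv)
    codes2[, j] <- off + match(g$a2[, j], lv)
    locus_of_bin <- c(locus_of_bin, rep(j, length(lv)))
    offsets[j] <- off
    off <- off + length(lv)
  }
  list(codes = cbind(codes1, codes2), locus_of_bin = locus_of_bin,
       n_bins = off)
}

# entropy sum(-f log f) per locus from a bin-count vector
locus_entropy <- function(counts, locus_of_bin, n_loci) {
  tot <- as.numeric(rowsum(counts, locus_of_bin))  # allele copies per locus
  xlogx <- ifelse(counts > 0, counts * log(counts), 0)
  s <- as.numeric(rowsum(xlogx, locus_of_bin))
  out <- rep(NA_real_, n_loci)
  present <- sort(unique(locus_of_bin))
  out[present] <- ifelse(tot > 0, log(pmax(tot, 1)) - s / pmax(tot, 1), NA)
  out # entropy in nats, NA where locus absent
}

# pairwise squared allele-mismatch distances between individuals
allele_mismatch_d2 <- function(g) {
  n <- length(g$individuals)
  d2 <- matrix(0, n, n)
  for (l in seq_along(g$loci)) {
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    for (i in seq_len(n - 1L)) {
      if (is.na(a1[i])) next
      for (j in (i + 1L):n) {
        if (is.na(a1[j])) next
        # shared allele copies under best matching of the two diploid calls
        shared <- (a1[i] == a1[j]) + (a2[i] == a2[j])
        shared_x <- (a1[i] == a2[j]) + (a2[i] == a1[j])
        mis <- 2L - max(shared, shared_x)
        d2[i, j] <- d2[i, j] + mis
        d2[j, i] <- d2[i, j]
      }
    }
  }
  d2
}

# Shannon partition for one assignment of individuals to populations.
# Returns per-dataset sums over loci of 2*N_l*I and the mean I components.
shannon_partition <- function(enc, pop_index, n_pops, n_loci) {
  lob <- enc$locus_of_bin
  pooled <- tabulate(enc$codes[!is.na(enc$codes)], nbins = enc$n_bins)
  present <- sort(unique(lob))
  N_l <- numeric(n_loci)
  N_l[present] <- as.numeric(rowsum(pooled, lob))
  H_tot <- locus_entropy(pooled, lob, n_loci)
  H_tot[!is.finite(H_tot)] <- 0
  # weighted within-population entropy per locus
  H_within <- numeric(n_loci)
  for (p in seq_len(n_pops)) {
    cp <- enc$codes[pop_index == p, , drop = FALSE]
    counts <- tabulate(cp[!is.na(cp)], nbins = enc$n_bins)
    n_pl <- numeric(n_loci)
    n_pl[present] <- as.numeric(rowsum(counts, lob))
    H_p <- locus_entropy(counts, lob, n_loci)
    w <- ifelse(N_l > 0, n_pl / N_l, 0)
    H_within <- H_within + w * ifelse(is.na(H_p) | n_pl == 0, 0, H_p)
  }
  I_among_l <- pmax(H_tot - H_within, 0)
  list(I_within = mean(H_within), I_among = mean(I_among_l),
       G_among = sum(2 * N_l * I_among_l),
       G_within = sum(2 * N_l * H_within),
       G_total = sum(2 * N_l * H_tot))
}

# two-level AMOVA variance components from a squared-distance matrix
amova_components <- function(d2, pop_index, n_pops) {
  n <- length(pop_index)
  ssd_total <- sum(d2[upper.tri(d2)]) / n
  ssd_within <- 0
  sizes <- tabulate(pop_index, nbins = n_pops)
  for (p in seq_len(n_pops)) {
    idx <- which(pop_index == p)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ssd_within <- ssd_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- n_pops - 1L
  df_within <- n - n_pops
  var_within <- ssd_within / df_within
  n0 <- (n - sum(sizes^2) / n) / df_among
  var_among <- (ssd_among / df_among - var_within) / n0
  list(var_among = var_among, var_within = var_within,
       df_among = df_among, df_within = df_within)
}

#' Assemble a Shannon AMOVA table from its components
#'
#' Adds the total row and the variation proportions to among/within G
#' statistics and variance components; the identities `G_total = G_among +
#' G_within`, `var_total = var_among + var_within` and `pct_among +
#' pct_within = 100` hold by construction.
#'
#' @param df_among,df_within degrees of freedom.
#' @param g_among,g_within chi-square G statistics.
#' @param var_among,var_within variance components.
#' @param p_among,p_within optional P values.
#' @return Data frame with rows `among`, `within`, `total` and columns
#'   `source`, `df`, `G`, `variance`, `pct`, `p`.
#' @export
amova_table <- function(df_among, df_within, g_among, g_within,
                        var_among, var_within,
                        p_among = NA_real_, p_within = NA_real_) {
  var_total <- var_among + var_within
  data.frame(
    source = c("among", "within", "total"),
    df = c(df_among, df_within, df_among + df_within),
    G = c(g_among, g_within, g_among + g_within),
    variance = c(var_among, var_within, var_total),
    pct = c(100 * var_among / var_total, 100 * var_within / var_total, 100),
    p = c(p_among, p_within, NA_real_),
    stringsAsFactors = FALSE)
}

#' Shannon-information analysis of molecular variance
#'
#' At each locus the pooled allelic Shannon entropy (natural log) is
#' partitioned into the mean within-population entropy plus the
#' among-population mutual information; `2 * N * I` (N = allele copies at
#' the locus) is a chi-square distributed G statistic, and the G statistics
#' are summed over loci, so `G_total = G_among + G_within` exactly.
#' Variance components and variation proportions come from a standard
#' two-level AMOVA on pairwise allele mismatch distances. P values are
#' permutation based: individuals are randomly reassigned to populations
#' (sizes fixed); `p_among` is the fraction of permutations whose among
#' G statistic is at least the observed one, `p_within` the fraction whose
#' within variance component is at most the observed one, both with the
#' +1 / (permutations + 1) correction. Results are reproducible given
#' `seed`.
#'
#' @param g a [genotype_matrix()].
#' @param pops named character/factor vector or data frame (`individual`,
#'   `population`) assigning every individual to a population; >= 2
#'   populations.
#' @param permutations number of random reassignments (default 999; 0
#'   skips P values).
#' @param seed optional integer seed for the permutations.
#' @return Object of class `"shannon_amova"`: list with `table` (from
#'   [amova_table()]), `I_within`, `I_among`, and the call parameters.
#' @export
shannon_amova <- function(g, pops, permutations = 999, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.data.frame(pops))
    pops <- stats::setNames(as.character(pops$population),
                            as.character(pops$individual))
  pops <- pops[g$individuals]
  if (any(is.na(pops)))
    stop("every individual needs a population assignment", call. = FALSE)
  pop_f <- factor(as.character(pops))
  n_pops <- nlevels(pop_f)
  if (n_pops < 2L)
    stop("need at least 2 populations", call. = FALSE)
  if (any(tabulate(pop_f) == 0L))
    stop("empty population", call. = FALSE)
  pop_index <- as.integer(pop_f)
  n_loci <- length(g$loci)

  enc <- encode_alleles(g)
  d2 <- allele_mismatch_d2(g)
  obs <- shannon_partition(enc, pop_index, n_pops, n_loci)
  vc <- amova_components(d2, pop_index, n_pops)

  p_among <- p_within <- NA_real_
  if (permutations > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    n <- length(pop_index)
    ge_among <- 0L; le_within <- 0L
    for (b in seq_len(permutations)) {
      perm <- pop_index[sample.int(n)]
      sp <- shannon_partition(enc, perm, n_pops, n_loci)
      if (sp$G_among >= obs$G_among - 1e-12) ge_among <- ge_among + 1L
      vcp <- amova_components(d2, perm, n_pops)
      if (vcp$var_within <= vc$var_within + 1e-12) le_within <- le_within + 1L
    }
    p_among <- (1 + ge_among) / (permutations + 1)
    p_within <- (1 + le_within) / (permutations + 1)
  }

  out <- list(table = amova_table(vc$df_among, vc$df_within,
                                  obs$G_among, obs$G_within,
                                  vc$var_among, vc$var_within,
                                  p_among, p_within),
              I_within = obs$I_within, I_among = obs$I_among,
              n_pops = n_pops, permutations = permutations, seed = seed)
  class(out) <- "shannon_amova"
  out
}

#' @export
print.shannon_amova <- function(x, ...) {
  cat(sprintf(
    "Shannon statistics of molecular variance (%d populations, %d permutations)\n",
    x$n_pops, x$permutations))
  tab <- x$table
  tab$G <- round(tab$G, 2); tab$variance <- round(tab$variance, 3)
  tab$pct <- round(tab$pct, 1)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Evanno delta-K statistic
#'
#' Post-processing of clustering log-probabilities: for each interior K,
#' `deltaK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))` — the
#' absolute second-order rate of change of the mean data log-probability
#' across successive K, scaled by the replicate spread at K. A sharp peak
#' flags the most likely number of clusters.
#'
#' @param runs data frame with columns `K`, `lnP` (one row per replicate
#'   run; a `replicate` column is allowed and ignored).
#' @return Data frame `K`, `mean_lnP`, `sd_lnP`, `deltaK` (NA at boundary
#'   K and where sd = 0, the latter with a warning).
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "lnP") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L)
    stop("need at least 3 consecutive K values", call. = FALSE)
  if (any(diff(ks) != 1L))
    stop("K values must be consecutive integers", call. = FALSE)
  reps <- table(runs$K)
  if (any(reps < 2L))
    stop("need at least 2 replicate runs per K", call. = FALSE)
  m <- tapply(runs$lnP, runs$K, mean)[as.character(ks)]
  s <- tapply(runs$lnP, runs$K, stats::sd)[as.character(ks)]
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1L, length(ks))]) {
    if (s[i] == 0) {
      warning("sd(LnP) = 0 at K = ", ks[i], ": deltaK undefined")
      next
    }
    dk[i] <- abs(m[i + 1L] - 2 * m[i] + m[i - 1L]) / s[i]
  }
  data.frame(K = ks, mean_lnP = unname(m), sd_lnP = unname(s), deltaK = dk)
}
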