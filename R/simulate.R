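#' Synthetic inputs with known ground truth
#'
#' Generators for every input the pipeline consumes: polyphasic OJIP
#' fluorescence transients, variety x stage x platform measurement panels
#' with configurable salinity depressions, island-model SSR genotypes with
#' a planted differentiation level, random peptides, and Ct tables with
#' known fold changes. Each generator is deterministic given its seed, and
#' its outputs satisfy the invariants of the module that consumes them.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Simulate an OJIP fluorescence transient
#'
#' Phenomenological model of the polyphasic rise: a sum of saturating
#' exponentials,
#' `F(t) = F0 + (FM - F0) * sum_k w_k (1 - exp(-t / tau_k))`,
#' with phases J, I and P at time constants near 0.5, 10 and 100 ms,
#' sampled log-uniformly on \[1e-5, 1\] s with the JIP mark times (50 us,
#' 300 us, 2 ms) included exactly, plus optional additive Gaussian noise.
#' The `"truth"` attribute records the noiseless skeleton values at the
#' mark times and its maximum, i.e. the generating marks a perfect
#' extractor should recover.
#'
#' @param F0,FM target origin and plateau fluorescence (a.u.), `F0 < FM`.
#' @param weights non-negative phase weights summing to 1 (J, I, P).
#' @param tau phase time constants in seconds, increasing.
#' @param noise_sd additive noise SD (a.u.).
#' @param n number of log-spaced samples.
#' @param sample_id label.
#' @param seed optional integer seed (noise only).
#' @return A [transient()] with attribute `truth` (named vector `F0`,
#'   `F300`, `FJ`, `FM`).
#' @export
simulate_transient <- function(F0 = 500, FM = 2500,
                               weights = c(J = 0.5, I = 0.3, P = 0.2),
                               tau = c(J = 5e-4, I = 1e-2, P = 1e-1),
                               noise_sd = 0, n = 120,
                               sample_id = "sim", seed = NULL) {
  stopifnot(F0 < FM, all(weights >= 0), length(weights) == length(tau),
            all(diff(tau) > 0))
  weights <- weights / sum(weights)
  marks <- c(5e-5, 3e-4, 2e-3)
  times <- sort(unique(c(10^seq(-5, 0, length.out = n), marks)))
  skeleton <- function(t)
    F0 + (FM - F0) *
      colSums(weights * (1 - exp(-outer(tau, t, function(tk, tt) tt / tk))))
  f <- skeleton(times)
  truth <- c(skeleton(marks), max(f))
  names(truth) <- c("F0", "F300", "FJ", "FM")
  if (noise_sd > 0)
    f <- with_seed(seed, pmax(f + stats::rnorm(length(f), 0, noise_sd), 0))
  tr <- transient(sample_id, times, f)
  attr(tr, "truth") <- truth
  tr
}

.default_depression <- rbind(
  PIabs = c(leaf3 = 0.90, boot = 0.60, flowering = 0.39),
  A     = c(leaf3 = 0.85, boot = 0.70, flowering = 0.53),
  ETR   = c(leaf3 = 0.90, boot = 0.80, flowering = 0.69),
  NPQ   = c(leaf3 = 0.95, boot = 0.88, flowering = 0.79),
  FvFm  = c(leaf3 = 0.98, boot = 0.94, flowering = 0.89))

.default_baseline <- c(PIabs = 6, A = 25, ETR = 150, NPQ = 2, FvFm = 0.80)

#' Simulate a stage-measurement panel
#'
#' Emulates a two-platform (low = 4 dS/m, medium = 8 dS/m) variety trial
#' with six replicates per cell and three growth stages. Low-platform
#' values fluctuate around per-parameter baselines; medium-platform values
#' are the baseline times a configurable stage x parameter depression
#' (medium/low ratio), so the planted reduction factor of a parameter is
#' `depression[param, "leaf3"] / depression[param, "flowering"]` (default
#' marker PIabs: 0.90 / 0.39 = 2.31). Varieties differ through a latent
#' tolerance that scales their late-stage depressions, and the dry-matter
#' gain is generated to correlate with the planted salt performance index
#' at level `dm_cor`. Dry matter is recorded post-harvest, i.e. only on
#' flowering-stage rows.
#'
#' @param n_varieties number of varieties (labelled V1, V2, ...).
#' @param depression matrix parameter x stage of medium/low ratios in
#'   (0, 1].
#' @param baseline named vector of low-platform parameter levels.
#' @param replicate_cv multiplicative replicate noise (coefficient of
#'   variation).
#' @param variety_sd SD of the latent log-tolerance scaling late-stage
#'   depressions across varieties.
#' @param dm_cor planted correlation between dry-matter gain (log scale)
#'   and the planted SPI.
#' @param n_replicates replicates per cell (default 6).
#' @param seed optional integer seed.
#' @return Data frame of stage measurements (`variety`, `stage`,
#'   `platform`, `replicate`, one column per parameter, `dry_matter`),
#'   with the planted per-variety truth in the `"truth"` attribute.
#' @export
simulate_panel <- function(n_varieties = 18,
                           depression = .default_depression,
                           baseline = .default_baseline,
                           replicate_cv = 0.05, variety_sd = 0.15,
                           dm_cor = 0.8, n_replicates = 6, seed = NULL) {
  stopifnot(all(depression > 0), all(depression <= 1),
            replicate_cv >= 0, dm_cor >= -1, dm_cor <= 1)
  params <- rownames(depression)
  stopifnot(all(params %in% names(baseline)))
  with_seed(seed, {
    varieties <- paste0("V", seq_len(n_varieties))
    z <- stats::rnorm(n_varieties)                  # latent salt tolerance
    eps <- stats::rnorm(n_varieties)
    # per-variety depressions: tolerance inflates/deflates late stages
    dep_v <- lapply(seq_len(n_varieties), function(i) {
      d <- depression
      d[, "boot"] <- pmin(1, d[, "boot"] * exp(variety_sd / 2 * z[i]))
      d[, "flowering"] <- pmin(1, d[, "flowering"] * exp(variety_sd * z[i]))
      d
    })
    marker <- params[1L]
    spi_planted <- vapply(dep_v, function(d)
      log10(d[marker, "leaf3"]) + 2 * log10(d[marker, "flowering"]),
      numeric(1))
    s <- if (stats::sd(spi_planted) > 0)
      (spi_planted - mean(spi_planted)) / stats::sd(spi_planted)
      else rep(0, n_varieties)
    dm_gain_v <- 0.6 * exp(0.25 * (dm_cor * s + sqrt(1 - dm_cor^2) * eps))
    rows <- list()
    for (i in seq_len(n_varieties)) {
      for (st in colnames(depression)) {
        for (pl in c("low", "medium")) {
          fac <- if (pl == "low") rep(1, length(params))
                 else dep_v[[i]][params, st]
          vals <- vapply(seq_along(params), function(k) {
            baseline[[params[k]]] * fac[k] *
              exp(stats::rnorm(n_replicates, 0, replicate_cv))
          }, numeric(n_replicates))
          colnames(vals) <- params
          dm <- if (st == "flowering") {
            base_dm <- 120
            (if (pl == "low") base_dm else base_dm * dm_gain_v[i]) *
              exp(stats::rnorm(n_replicates, 0, replicate_cv))
          } else rep(NA_real_, n_replicates)
          rows[[length(rows) + 1L]] <- data.frame(
            variety = varieties[i], stage = st, platform = pl,
            replicate = seq_len(n_replicates), vals, dry_matter = dm,
            stringsAsFactors = FALSE)
        }
      }
    }
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    attr(panel, "truth") <- list(
      marker = marker, depression = depression, dep_by_variety = dep_v,
      spi_planted = stats::setNames(spi_planted, varieties),
      dm_gain = stats::setNames(dm_gain_v, varieties))
    panel
  })
}

#' Simulate island-model SSR genotypes
#'
#' Ancestral allele frequencies per locus are Dirichlet(1, ..., 1);
#' population frequencies follow the Balding--Nichols model, i.e.
#' Dirichlet with parameters `p * (1 - FST) / FST`, which has mean `p` and
#' the planted differentiation `FST` (at `FST = 0` every population uses
#' the ancestral frequencies exactly). Diploid calls are drawn
#' independently; allele labels are letters with `"a"` the top band.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (recycled to `n_pops`).
#' @param n_loci number of SSR loci.
#' @param alleles_per_locus integer vector (recycled) of allele counts per
#'   locus, each in 2..5; default sampled uniformly from 2:5.
#' @param fst planted differentiation in \[0, 1).
#' @param missing_rate fraction of calls set to missing.
#' @param seed optional integer seed.
#' @return List with `genotypes` (a [genotype_matrix()]) and `populations`
#'   (named vector individual -> population label).
#' @export
simulate_genotypes <- function(n_pops = 2, n_per_pop = 9, n_loci = 30,
                               alleles_per_locus = NULL, fst = 0,
                               missing_rate = 0, seed = NULL) {
  stopifnot(fst >= 0, fst < 1, n_pops >= 2)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  with_seed(seed, {
    if (is.null(alleles_per_locus))
      alleles_per_locus <- sample(2:5, n_loci, replace = TRUE)
    alleles_per_locus <- rep_len(alleles_per_locus, n_loci)
    stopifnot(all(alleles_per_locus >= 2), all(alleles_per_locus <= 5))
    n <- sum(n_per_pop)
    inds <- paste0("ind", seq_len(n))
    pops <- stats::setNames(rep(paste0("pop", seq_len(n_pops)), n_per_pop),
                            inds)
    loci <- paste0("SSR", seq_len(n_loci))
    a1 <- matrix(NA_character_, n, n_loci, dimnames = list(inds, loci))
    a2 <- a1
    rdirichlet <- function(alpha) {
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      g / sum(g)
    }
    for (l in seq_len(n_loci)) {
      k <- alleles_per_locus[l]
      labs <- letters[seq_len(k)]
      p_anc <- rdirichlet(rep(1, k))
      row0 <- 0L
      for (pp in seq_len(n_pops)) {
        p_pop <- if (fst == 0) p_anc
                 else rdirichlet(p_anc * (1 - fst) / fst)
        idx <- row0 + seq_len(n_per_pop[pp])
        draw1 <- sample(labs, length(idx), replace = TRUE, prob = p_pop)
        draw2 <- sample(labs, length(idx), replace = TRUE, prob = p_pop)
        a1[idx, l] <- pmin(draw1, draw2)   # "a" scored as the top band
        a2[idx, l] <- pmax(draw1, draw2)
        row0 <- row0 + n_per_pop[pp]
      }
    }
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n * n_loci) < missing_rate, n, n_loci)
      a1[miss] <- NA; a2[miss] <- NA
    }
    list(genotypes = genotype_matrix(a1, a2, inds, loci),
         populations = pops)
  })
}

#' Simulate random peptides
#'
#' Uniform random sequences over the 20 standard amino acids, for
#' exercising the physicochemical calculators.
#'
#' @param n number of peptides.
#' @param length_range min/max length (sampled uniformly).
#' @param seed optional integer seed.
#' @return Data frame `id`, `sequence`.
#' @export
simulate_proteins <- function(n = 8, length_range = c(100, 450),
                              seed = NULL) {
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    data.frame(
      id = paste0("prot", seq_len(n)),
      sequence = vapply(lens, function(L)
        paste0(sample(.aa20, L, replace = TRUE), collapse = ""),
        character(1)),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a Ct table with known fold changes
#'
#' Builds control/treated Ct records around a reference gene so that the
#' planted `2^-ddCt` fold changes are exactly those requested (before
#' optional replicate noise).
#'
#' @param fold numeric matrix varieties x genes of planted fold changes
#'   (> 0).
#' @param reference reference gene id.
#' @param ref_ct reference-gene Ct level.
#' @param base_dct control-condition dCt of every target gene.
#' @param sd replicate noise SD in cycles.
#' @param replicates technical replicates per record.
#' @param seed optional integer seed.
#' @return Data frame `sample`, `condition`, `gene`, `Ct`.
#' @export
simulate_ct <- function(fold, reference = "EF1", ref_ct = 18,
                        base_dct = 2, sd = 0, replicates = 3,
                        seed = NULL) {
  fold <- as.matrix(fold)
  stopifnot(all(fold > 0))
  if (is.null(rownames(fold)))
    rownames(fold) <- paste0("V", seq_len(nrow(fold)))
  if (is.null(colnames(fold)))
    colnames(fold) <- paste0("gene", seq_len(ncol(fold)))
  with_seed(seed, {
    rows <- list()
    for (s in rownames(fold)) {
      for (cond in c("control", "treated")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, condition = cond, gene = reference,
          Ct = ref_ct + stats::rnorm(replicates, 0, sd),
          stringsAsFactors = FALSE)
        for (g in colnames(fold)) {
          ct0 <- ref_ct + base_dct -
            (if (cond == "treated") log2(fold[s, g]) else 0)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, condition = cond, gene = g,
            Ct = ct0 + stats::rnorm(replicates, 0, sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
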