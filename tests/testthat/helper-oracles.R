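# Independent oracles used across tests. These deliberately re-derive
# results by brute force or closed form, never by calling the code path
# they check.

# Classic recursive Duncan procedure on means sorted descending: test the
# range of the whole ordered subset against its critical range; if
# non-significant, every pair inside is non-significant and recursion
# stops; otherwise recurse into the two (size - 1) ordered subsets. A pair
# differs iff no subset covering it was ever declared non-significant and
# its own span test exceeds its critical range.
duncan_oracle <- function(means_sorted, ranges) {
  k <- length(means_sorted)
  nonsig <- matrix(FALSE, k, k)
  recurse <- function(i, j) {
    if (j <= i) return(invisible())
    span <- j - i + 1L
    if (means_sorted[i] - means_sorted[j] <= ranges[[paste0("R", span)]]) {
      for (a in i:(j - 1L)) for (b in (a + 1L):j) nonsig[a, b] <<- TRUE
    } else {
      recurse(i, j - 1L)
      recurse(i + 1L, j)
    }
  }
  recurse(1L, k)
  different <- matrix(FALSE, k, k)
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
    different[a, b] <- different[b, a] <- !nonsig[a, b]
  different
}

# Interpolation linear in log10(time), written out by hand.
loglin_interp <- function(t1, v1, t2, v2, t) {
  frac <- (log10(t) - log10(t1)) / (log10(t2) - log10(t1))
  v1 + frac * (v2 - v1)
}

# A genotype matrix realising prescribed per-locus allele counts (2..5),
# using three individuals per matrix.
genotypes_with_counts <- function(counts) {
  stopifnot(all(counts >= 1), all(counts <= 5))
  n_loci <- length(counts)
  a1 <- matrix(NA_character_, 3, n_loci)
  a2 <- a1
  for (l in seq_len(n_loci)) {
    labs <- letters[seq_len(counts[l])]
    calls <- switch(as.character(counts[l]),
      "1" = list(c("a", "a"), c("a", "a"), c("a", "a")),
      "2" = list(c("a", "b"), c("a", "a"), c("b", "b")),
      "3" = list(c("a", "b"), c("b", "c"), c("a", "c")),
      "4" = list(c("a", "b"), c("c", "d"), c("a", "a")),
      "5" = list(c("a", "b"), c("c", "d"), c("e", "e")))
    for (i in 1:3) { a1[i, l] <- calls[[i]][1]; a2[i, l] <- calls[[i]][2] }
  }
  genotype_matrix(a1, a2, paste0("ind", 1:3), paste0("L", seq_len(n_loci)))
}

# small balanced toy panel: two platforms x stages with prescribed
# medium/low ratios and no replicate noise
toy_panel <- function(ratios, base = c(PIabs = 6, A = 25),
                      varieties = c("V1", "V2"), reps = 6) {
  rows <- list()
  for (v in varieties) for (st in names(ratios)) for (pl in c("low", "medium")) {
    fac <- if (pl == "low") 1 else ratios[[st]]
    rows[[length(rows) + 1L]] <- data.frame(
      variety = v, stage = st, platform = pl, replicate = seq_len(reps),
      PIabs = base[["PIabs"]] * fac, A = base[["A"]] * fac,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
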