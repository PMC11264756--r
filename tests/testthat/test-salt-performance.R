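test_that("relative values are platform-mean ratios with the right degenerate handling", {
  p <- toy_panel(c(leaf3 = 0.5, flowering = 0.5))
  rel <- relative_values(p)
  expect_true(all(abs(rel$relative_value - 0.5) < 1e-12))

  # identical platforms give 1 everywhere
  p1 <- toy_panel(c(leaf3 = 1, flowering = 1))
  expect_true(all(abs(relative_values(p1)$relative_value - 1) < 1e-12))

  # zero low-platform mean names the offending cell
  p0 <- p
  p0$PIabs[p0$platform == "low" & p0$stage == "leaf3" &
             p0$variety == "V1"] <- 0
  expect_error(relative_values(p0, "PIabs"), "V1.*leaf3.*PIabs")
})

test_that("a configured 40% medium-salinity depression yields relative values near 0.6", {
  dep <- .toy_dep <- matrix(0.6, 5, 3,
    dimnames = list(c("PIabs", "A", "ETR", "NPQ", "FvFm"),
                    c("leaf3", "boot", "flowering")))
  panel <- simulate_panel(depression = dep, variety_sd = 0,
                          replicate_cv = 0.03, seed = 3)
  rel <- relative_values(panel, c("PIabs", "A", "ETR", "NPQ", "FvFm"))
  expect_equal(mean(rel$relative_value), 0.6, tolerance = 0.02)
  expect_true(all(abs(rel$relative_value - 0.6) < 0.1))
})

test_that("relative values are invariant to rescaling a parameter", {
  panel <- simulate_panel(n_varieties = 4, seed = 5)
  rel1 <- relative_values(panel, "PIabs")
  panel$PIabs <- panel$PIabs * 137.5
  rel2 <- relative_values(panel, "PIabs")
  expect_equal(rel1$relative_value, rel2$relative_value, tolerance = 1e-12)
})

test_that("reduction factors are leaf3/flowering ratios of relative values", {
  p <- toy_panel(c(leaf3 = 0.9, flowering = 0.45))
  rfs <- suppressWarnings(reduction_factors(p, c("PIabs", "A")))
  expect_true(all(abs(rfs$RF - 2) < 1e-12))

  p1 <- toy_panel(c(leaf3 = 0.7, flowering = 0.7))
  rfs1 <- suppressWarnings(reduction_factors(p1, c("PIabs", "A")))
  expect_true(all(abs(rfs1$RF - 1) < 1e-12))
})

test_that("a planted uniform stage decline is recovered as RF = f and n = round(f)", {
  dep <- rbind(PIabs = c(leaf3 = 0.9, boot = 0.6, flowering = 0.45),
               A = c(leaf3 = 0.9, boot = 0.7, flowering = 0.60))
  panel <- simulate_panel(n_varieties = 6, depression = dep,
                          baseline = c(PIabs = 6, A = 25),
                          variety_sd = 0, replicate_cv = 0.03, seed = 9)
  rfs <- reduction_factors(panel, c("PIabs", "A"))
  expect_equal(mean(rfs$RF[rfs$parameter == "PIabs"]), 2, tolerance = 0.05)
  sel <- select_marker(rfs)
  expect_equal(sel$parameter, "PIabs")
  expect_equal(sel$n, 2L)
})

test_that("marker selection prefers the largest significant mean RF and breaks ties order-invariantly", {
  mk <- function(param, rf, sig) data.frame(
    variety = paste0("V", seq_along(rf)), parameter = param, RF = rf,
    p_value = ifelse(sig, 1e-4, 0.5), significant = sig,
    stringsAsFactors = FALSE)
  rfs <- rbind(mk("PIabs", rep(2.3, 4), rep(TRUE, 4)),
               mk("A", rep(1.6, 4), rep(TRUE, 4)),
               mk("NPQ", rep(1.2, 4), rep(TRUE, 4)))
  sel <- select_marker(rfs)
  expect_equal(sel$parameter, "PIabs")
  expect_equal(sel$n, 2L)

  # single consistent parameter: n floors at round(1.4) = 1
  sel1 <- select_marker(mk("ETR", rep(1.4, 4), rep(TRUE, 4)))
  expect_equal(sel1$parameter, "ETR")
  expect_equal(sel1$n, 1L)

  # ties on mean RF: larger fraction significant wins, in either row order
  tied <- rbind(mk("B_par", rep(1.8, 4), c(TRUE, TRUE, TRUE, TRUE)),
                mk("A_par", rep(1.8, 4), c(TRUE, TRUE, TRUE, FALSE)))
  sel_fwd <- select_marker(tied, consistency = 0.5)
  sel_rev <- select_marker(tied[rev(seq_len(nrow(tied))), ],
                           consistency = 0.5)
  expect_equal(sel_fwd$parameter, "B_par")
  expect_equal(sel_rev$parameter, sel_fwd$parameter)

  # exact ties on RF and significance fall back to lexicographic order
  tied2 <- rbind(mk("zeta", rep(1.8, 4), rep(TRUE, 4)),
                 mk("alpha", rep(1.8, 4), rep(TRUE, 4)))
  expect_equal(select_marker(tied2)$parameter, "alpha")
  expect_equal(select_marker(tied2[sample(8), ])$parameter, "alpha")

  # nothing consistent -> selection error advising an override
  none <- rbind(mk("PIabs", rep(2, 4), c(TRUE, FALSE, TRUE, FALSE)))
  expect_error(select_marker(none), "consistent|manual")
})

test_that("SPI follows log10(A) + n log10(B) with its scaling laws", {
  rel <- data.frame(variety = "V1",
                    stage = c("leaf3", "flowering"),
                    parameter = "PIabs",
                    relative_value = c(1, 1),
                    stringsAsFactors = FALSE)
  expect_equal(spi(rel, "PIabs", 2)$SPI, 0)

  rel$relative_value <- c(1.2, 0.6)
  s <- spi(rel, "PIabs", 2)
  expect_equal(s$SPI, log10(1.2) + 2 * log10(0.6), tolerance = 1e-12)
  expect_equal(round(s$SPI, 4), -0.3645)

  rel$relative_value <- c(1.2, 0)
  expect_error(spi(rel, "PIabs", 2), "positive")

  # strictly increasing in A and in B; doubling B adds exactly n log10(2)
  base <- function(a, b) {
    r <- data.frame(variety = "V1", stage = c("leaf3", "flowering"),
                    parameter = "PIabs", relative_value = c(a, b))
    spi(r, "PIabs", 3)$SPI
  }
  expect_true(all(diff(vapply(c(.5, 1, 2, 4), base, numeric(1), b = .7)) > 0))
  expect_true(all(diff(vapply(c(.5, 1, 2, 4), base, numeric(1), a = .7)) > 0))
  expect_equal(base(0.9, 1.2) - base(0.9, 0.6), 3 * log10(2),
               tolerance = 1e-12)
})

test_that("SPI correlations recover planted relationships", {
  # perfectly collinear synthetic relation
  rel <- data.frame(variety = paste0("V", 1:6),
                    stage = "flowering", parameter = "PIabs",
                    relative_value = seq(0.4, 0.9, 0.1))
  spis <- data.frame(variety = paste0("V", 1:6),
                     SPI = 2 * log10(seq(0.4, 0.9, 0.1)))
  co <- spi_correlations(spis, rel, marker = "PIabs")
  expect_lt(abs(co$marker$r_squared -
                  cor(spis$SPI, rel$relative_value)^2), 1e-12)

  # SPI against itself is r = 1
  co_self <- spi_correlations(
    spis, rel, dm = data.frame(variety = spis$variety, dm_gain = spis$SPI),
    marker = "PIabs")
  expect_equal(co_self$dm_gain$r, 1, tolerance = 1e-9)

  # zero variance is an error
  spis0 <- data.frame(variety = paste0("V", 1:6), SPI = rep(0.2, 6))
  expect_error(spi_correlations(spis0, rel, marker = "PIabs"),
               "zero variance")
})

test_that("the planted dry-matter correlation is recovered on average", {
  rs <- vapply(1:60, function(s) {
    panel <- simulate_panel(dm_cor = 0.8, seed = 1000 + s)
    rel <- relative_values(panel)
    sp <- spi(rel, "PIabs", 2)
    spi_correlations(sp, rel, dm = dm_gain(panel),
                     marker = "PIabs")$dm_gain$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.1)
})
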