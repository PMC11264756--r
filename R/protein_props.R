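#' Physicochemical characterisation of protein sequences
#'
#' ProtParam-style descriptors of a protein from its amino-acid sequence:
#' length, average molecular weight, isoelectric point, GRAVY (grand
#' average of hydropathy, Kyte--Doolittle), Ikai's aliphatic index and
#' Guruprasad's dipeptide instability index. All constant tables below are
#' the published values of the respective methods.
#'
#' @name protein_props
NULL

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# average residue masses (Da): amino-acid average mass minus one water
.water_mass <- 18.01524
.aa_avg_mass <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
) - .water_mass

# Kyte-Doolittle hydropathy
.kd_hydropathy <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# side-chain pKa sets: Bjellqvist (ExPASy convention) and EMBOSS
.pka_sets <- list(
  bjellqvist = list(
    nterm = 7.5, cterm = 3.55,
    pos = c(K = 10.0, R = 12.0, H = 5.98),
    neg = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)),
  emboss = list(
    nterm = 8.6, cterm = 3.6,
    pos = c(K = 10.8, R = 12.5, H = 6.5),
    neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)))

# Guruprasad dipeptide instability weight values; rows = first residue,
# columns = second residue, alphabetical ACDEFGHIKLMNPQRSTVWY
.diwv <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(.aa20, .aa20))

check_seq <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(gsub("[\\s*]", "", seq, perl = TRUE))
  if (!nchar(seq)) stop("empty ", what, call. = FALSE)
  res <- strsplit(seq, "")[[1L]]
  bad <- which(!res %in% .aa20)
  if (length(bad))
    stop("non-standard residue(s) '",
         paste(unique(res[bad]), collapse = "','"), "' at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  res
}

#' Read protein sequences from a FASTA file
#'
#' @param file path to a FASTA file.
#' @return Data frame `id`, `sequence` (uppercased), `aa_count`,
#'   `standard` (TRUE when only the 20 standard residues occur; records
#'   with ambiguous residues are flagged with a warning and refused by the
#'   pI / instability calculators).
#' @export
read_fasta <- function(file) {
  aas <- Biostrings::readAAStringSet(file)
  if (!length(aas)) stop("no FASTA records in ", file, call. = FALSE)
  seqs <- toupper(as.character(aas))
  if (any(nchar(seqs) == 0))
    stop("empty FASTA record: ",
         names(aas)[which(nchar(seqs) == 0)[1L]], call. = FALSE)
  standard <- !grepl(paste0("[^", paste(.aa20, collapse = ""), "]"), seqs)
  if (any(!standard))
    warning("record(s) with non-standard residues: ",
            paste(sub("\\s.*", "", names(aas))[!standard], collapse = ", "))
  data.frame(id = sub("\\s.*", "", names(aas)), sequence = unname(seqs),
             aa_count = nchar(seqs), standard = standard,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water. Additive up to a water:
#' `mol_weight(paste0(s1, s2)) = mol_weight(s1) + mol_weight(s2) - 18.015`.
#'
#' @param seq amino-acid string (standard residues).
#' @return Molecular weight in Da.
#' @examples
#' mol_weight("G")  # 75.07
#' @export
mol_weight <- function(seq) {
  res <- check_seq(seq)
  sum(.aa_avg_mass[res]) + .water_mass
}

#' Net charge of a peptide at a given pH
#'
#' Henderson--Hasselbalch charge over the termini and the ionisable side
#' chains (D, E, C, Y negative; H, K, R positive) with the chosen pKa set.
#'
#' @param seq amino-acid string.
#' @param pH numeric vector of pH values.
#' @param pka `"bjellqvist"` (ExPASy convention, default) or `"emboss"`.
#' @return Net charge, vectorised over `pH`.
#' @export
charge_at_ph <- function(seq, pH, pka = c("bjellqvist", "emboss")) {
  res <- check_seq(seq)
  set <- .pka_sets[[match.arg(pka)]]
  counts_pos <- table(factor(res, levels = names(set$pos)))
  counts_neg <- table(factor(res, levels = names(set$neg)))
  pos_pk <- c(set$nterm, rep(set$pos, counts_pos))
  neg_pk <- c(set$cterm, rep(set$neg, counts_neg))
  colSums(1 / (1 + 10^(outer(-pos_pk, pH, `+`)))) -
    colSums(1 / (1 + 10^(outer(neg_pk, -pH, `+`))))
}

#' Isoelectric point
#'
#' pH at which the net Henderson--Hasselbalch charge is zero, found by
#' bisection on \[0, 14\] to a tolerance of 1e-3 pH units.
#'
#' @inheritParams charge_at_ph
#' @param tol bisection tolerance in pH units.
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(seq, pka = c("bjellqvist", "emboss"),
                              tol = 1e-3) {
  pka <- match.arg(pka)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge_at_ph(seq, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte--Doolittle hydropathy over all residues; positive values mark
#' hydrophobic proteins.
#'
#' @inheritParams mol_weight
#' @return GRAVY value (dimensionless).
#' @examples
#' gravy("AILV")  # 3.575
#' @export
gravy <- function(seq) {
  res <- check_seq(seq)
  mean(.kd_hydropathy[res])
}

#' Aliphatic index
#'
#' Ikai's relative volume occupied by aliphatic side chains:
#' `X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with X the mole percentages.
#'
#' @inheritParams mol_weight
#' @return Aliphatic index (dimensionless).
#' @export
aliphatic_index <- function(seq) {
  res <- check_seq(seq)
  x <- 100 * table(factor(res, levels = .aa20)) / length(res)
  unname(x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]]))
}

#' Instability index
#'
#' Guruprasad's dipeptide-weight index `(10 / L) * sum DIWV(d)` over the
#' L - 1 consecutive dipeptides d; values above 40 predict an unstable
#' protein.
#'
#' @inheritParams mol_weight
#' @return Instability index (dimensionless); requires length >= 2.
#' @export
instability_index <- function(seq) {
  res <- check_seq(seq)
  if (length(res) < 2L)
    stop("instability index needs at least one dipeptide", call. = FALSE)
  idx <- cbind(res[-length(res)], res[-1L])
  (10 / length(res)) * sum(.diwv[idx])
}

#' Tabulate physicochemical properties of protein records
#'
#' Computes the full descriptor set for each record of a FASTA file or of
#' a `data.frame(id, sequence)`. Records with non-standard residues get
#' `NA` for pI and instability index (with a warning at read time) and an
#' ambiguity-free subset is required for the other descriptors.
#'
#' @param x path to a FASTA file, or a data frame with columns `id` and
#'   `sequence`.
#' @param pka passed to [isoelectric_point()].
#' @return Data frame `id`, `aa_count`, `instability_index`,
#'   `aliphatic_index`, `gravy`, `pI`, `MW` (column order mirroring the
#'   usual characterisation tables).
#' @export
protein_properties <- function(x, pka = "bjellqvist") {
  recs <- if (is.character(x) && length(x) == 1L) read_fasta(x)
          else as.data.frame(x)
  stopifnot(all(c("id", "sequence") %in% names(recs)))
  rows <- lapply(seq_len(nrow(recs)), function(i) {
    s <- toupper(recs$sequence[i])
    ok <- !grepl(paste0("[^", paste(.aa20, collapse = ""), "]"), s)
    data.frame(
      id = recs$id[i], aa_count = nchar(s),
      instability_index = if (ok) instability_index(s) else NA_real_,
      aliphatic_index = if (ok) aliphatic_index(s) else NA_real_,
      gravy = if (ok) gravy(s) else NA_real_,
      pI = if (ok) isoelectric_point(s, pka) else NA_real_,
      MW = if (ok) mol_weight(s) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
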