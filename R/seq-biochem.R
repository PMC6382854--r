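# Small sequence and biochemistry computations: Kyte-Doolittle hydropathy
# windows, substitution-matrix residue classing, fluorescent-labeling
# stoichiometry and circular-dichroism normalization.

# Kyte & Doolittle (1982) hydropathy scale
.KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# BLOSUM62 substitution scores, standard 20-residue alphabet
.BLOSUM62 <- local({
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  m <- matrix(c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4),
    nrow = 20, byrow = TRUE, dimnames = list(aa, aa))
  m
})

#' Substitution score between two residues
#'
#' @param a,b Single uppercase standard amino-acid letters.
#' @return The BLOSUM62 score.
#' @export
substitution_score <- function(a, b) {
  if (!all(c(a, b) %in% rownames(.BLOSUM62)))
    stop("non-standard residue: ", paste(setdiff(c(a, b), rownames(.BLOSUM62)),
                                         collapse = ", "))
  .BLOSUM62[a, b]
}

.split_seq <- function(sequence) {
  s <- toupper(gsub("\\s", "", sequence))
  strsplit(s, "")[[1L]]
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding unweighted mean of the per-residue Kyte-Doolittle hydropathy
#' values. Scores are reported only where the full window fits, so the
#' profile has `length(sequence) - window + 1` values, centered on
#' residues `(window + 1)/2 ..`.
#'
#' @param sequence Amino-acid string (standard 20-letter alphabet).
#' @param window Odd window length `<=` sequence length (default 5).
#' @return A `hydropathy_profile`: list with `sequence`, `window`,
#'   `center` (residue indices) and `scores`, each in \[-4.5, 4.5\].
#' @examples
#' kyte_doolittle("YYVQS")$scores   # -0.54
#' @export
kyte_doolittle <- function(sequence, window = 5L) {
  res <- .split_seq(sequence)
  if (!all(res %in% names(.KD_SCALE)))
    stop("non-standard residue: ",
         paste(unique(setdiff(res, names(.KD_SCALE))), collapse = ", "))
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("`window` must be odd")
  if (window > length(res)) stop("`window` longer than sequence")
  v <- .KD_SCALE[res]
  cs <- cumsum(c(0, v))
  n <- length(res) - window + 1L
  scores <- (cs[(window + 1L):(window + n)] - cs[1:n]) / window
  structure(list(sequence = paste(res, collapse = ""), window = window,
                 center = seq_len(n) + (window - 1L) %/% 2L,
                 scores = unname(scores)),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> %d residues, window %d, score range [%.2f, %.2f]\n",
              nchar(x$sequence), x$window, min(x$scores), max(x$scores)))
  invisible(x)
}

#' Classify aligned residue pairs as identical / similar / dissimilar
#'
#' Per aligned position: `identical` when the letters match, otherwise
#' `similar` when the BLOSUM62 substitution score is >= 0, otherwise
#' `dissimilar`. Gap characters (`-` or `.`) are classed dissimilar.
#'
#' @param seq_a,seq_b Equal-length aligned amino-acid strings.
#' @return Character vector of classes, one per position.
#' @examples
#' classify_pairs("IV", "VV")   # similar, identical
#' @export
classify_pairs <- function(seq_a, seq_b) {
  a <- .split_seq(seq_a); b <- .split_seq(seq_b)
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  gap <- c("-", ".")
  vapply(seq_along(a), function(i) {
    if (a[i] %in% gap || b[i] %in% gap) return("dissimilar")
    if (a[i] == b[i]) return("identical")
    if (substitution_score(a[i], b[i]) >= 0) "similar" else "dissimilar"
  }, character(1))
}

#' Concentration of a dye-protein conjugate
#'
#' `conjugate (mg/mL) = ((A280 - A490 * CF) / eps_protein) * df`, the
#' standard absorbance correction for dye bleed-through at 280 nm.
#'
#' @param A280 Absorbance at 280 nm.
#' @param A490 Absorbance at the dye maximum (490 nm).
#' @param CF Dye correction factor at 280 nm (0.1 for CF488A).
#' @param eps_protein Protein extinction coefficient per mg/mL
#'   (0.803 for the His-tagged CC1 N-terminus).
#' @param df Dilution factor.
#' @return Conjugate concentration in mg/mL; an error flags
#'   over-correction when `A490 * CF >= A280`.
#' @export
conjugate_concentration <- function(A280, A490, CF = 0.1,
                                    eps_protein = 0.803, df = 1) {
  stopifnot(eps_protein > 0, CF >= 0, CF <= 1, df > 0)
  if (A490 * CF >= A280)
    stop("over-correction: A490 * CF >= A280")
  (A280 - A490 * CF) / eps_protein * df
}

#' Degree of labeling
#'
#' `DOL = (A490 * Mwt * df) / (eps_dye * conjugate)`: mean dye molecules
#' per protein molecule.
#'
#' @param A490 Absorbance at the dye maximum.
#' @param conjugate Conjugate concentration in mg/mL (> 0), from
#'   [conjugate_concentration()].
#' @param Mwt Protein molecular weight in Da (16,122 for the His-tagged
#'   CC1 N-terminus).
#' @param eps_dye Dye molar extinction coefficient (70,000 for CF488A).
#' @param df Dilution factor.
#' @return The degree of labeling (dimensionless).
#' @export
degree_of_labeling <- function(A490, conjugate, Mwt = 16122,
                               eps_dye = 70000, df = 1) {
  if (conjugate <= 0) stop("`conjugate` must be > 0")
  stopifnot(Mwt > 0, eps_dye > 0, df > 0)
  (A490 * Mwt * df) / (eps_dye * conjugate)
}

#' Mean residue ellipticity
#'
#' `thetaMRW = (theta * 0.1) / (n * c * d)` converts a recorded circular
#' dichroism signal in millidegrees to deg cm^2 dmol^-1 per residue.
#'
#' @param theta_mdeg Recorded ellipticity in millidegrees (vectorized
#'   over wavelengths).
#' @param n_residues Number of amino-acid residues (> 0).
#' @param conc_mol_per_l Sample concentration in mol/L (> 0).
#' @param path_cm Cuvette path length in cm (> 0).
#' @return Mean residue ellipticity, same length as `theta_mdeg`.
#' @export
mean_residue_ellipticity <- function(theta_mdeg, n_residues,
                                     conc_mol_per_l, path_cm) {
  if (n_residues <= 0 || conc_mol_per_l <= 0 || path_cm <= 0)
    stop("`n_residues`, `conc_mol_per_l` and `path_cm` must be > 0")
  (theta_mdeg * 0.1) / (n_residues * conc_mol_per_l * path_cm)
}
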