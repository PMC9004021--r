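#' @useDynLib powsolve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 4-term Gaussian X-ray scattering factor coefficients (International Tables
# for Crystallography Vol. C, Table 6.1.1.4): f(s) = c + sum_j a_j exp(-b_j s^2)
# with s = sin(theta)/lambda in 1/Angstrom.
.scatter_table <- local({
  m <- rbind(
    H  = c(0.493002, 0.322912, 0.140191, 0.040810,
           10.5109, 26.1257, 3.14236, 57.7997, 0.003038),
    C  = c(2.31000, 1.02000, 1.58860, 0.865000,
           20.8439, 10.2075, 0.568700, 51.6512, 0.215600),
    N  = c(12.2126, 3.13220, 2.01250, 1.16630,
           0.005700, 9.89330, 28.9975, 0.582600, -11.5290),
    O  = c(3.04850, 2.28680, 1.54630, 0.867000,
           13.2771, 5.70110, 0.323900, 32.9089, 0.250800),
    F  = c(3.53920, 2.64120, 1.51700, 1.02430,
           10.2825, 4.29440, 0.261500, 26.1476, 0.277600),
    S  = c(6.90530, 5.20340, 1.43790, 1.58630,
           1.46790, 22.2151, 0.253600, 56.1720, 0.866900),
    Cl = c(11.4604, 7.19640, 6.25560, 1.64550,
           0.010400, 1.16620, 18.5194, 47.7784, -9.55740),
    Cu = c(13.3380, 7.16760, 5.61580, 1.67350,
           3.58280, 0.247000, 11.3966, 64.8126, 1.19100))
  list(a = m[, 1:4], b = m[, 5:8], c = m[, 9])
})

# Covalent radii in Angstrom (Cordero et al. 2008 consensus values),
# used for the intermolecular contact filter.
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                     S = 1.05, Cl = 1.02, Cu = 1.32)

# Average atomic volume increments in Angstrom^3 (Hofmann 2002), used to
# estimate the molar volume V/Z of a molecule for the cell-volume filter.
.volume_increments <- c(H = 5.08, C = 13.87, N = 11.8, O = 11.39, F = 11.17,
                        S = 24.6, Cl = 25.8, Cu = 9.38)

# Atomic masses (g/mol) for density cross-checks.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                    S = 32.06, Cl = 35.45, Cu = 63.546)

#' Elements supported by the shipped scattering, radius and volume tables
#' @return character vector of element symbols
#' @export
supported_elements <- function() rownames(.scatter_table$a)
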