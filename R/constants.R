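# Physical constants (CODATA 2018) and amino-acid reference data used
# throughout the package. Internal.

.kB <- 1.380649e-23       # Boltzmann constant, J/K
.N_AVOGADRO <- 6.02214076e23  # 1/mol
.PLANCK_H <- 6.62607015e-34   # Planck constant, J s
.MU0 <- 4 * pi * 1e-7         # vacuum permeability, T m/A
.GAMMA_H <- 2.6752218744e8    # 1H gyromagnetic ratio, rad/s/T
.GAMMA_N15 <- 2.7126e7        # |15N| gyromagnetic ratio, rad/s/T
.WATER_MASS <- 18.0153        # Da, one water added on hydrolysis

# Average (not monoisotopic) residue masses of the 20 canonical amino
# acids as incorporated in a peptide chain, Da.
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.AA_CODES <- names(.RESIDUE_MASS)

# Split a sequence string into residue letters, rejecting non-canonical
# symbols by name.
.split_residues <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("sequence must be a non-empty character scalar", call. = FALSE)
  }
  res <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), .AA_CODES)
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  res
}

.celsius_to_kelvin <- function(temp_c) temp_c + 273.15
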