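## Physical constants and chemical reference tables used throughout.

## Mass of the proton in Da (fixed project-wide; all charging is by
## protonation, no other adducts are modelled).
PROTON_MASS <- 1.007276

## Nominal isotopologue spacing used for charge-state reading:
## the 13C - 12C mass difference, Th at z = 1.
ISOTOPE_SPACING <- 1.00336

## SI constants (CODATA 2018) for the Mason-Schamp conversion.
.ELEMENTARY_CHARGE <- 1.602176634e-19   # C
.BOLTZMANN         <- 1.380649e-23      # J/K
.LOSCHMIDT         <- 2.6867811e25      # m^-3, gas number density at 273.15 K, 101325 Pa
.ATOMIC_MASS_UNIT  <- 1.66053906660e-27 # kg

## Default drift gas: N2 (monoisotopic-ish average for reduced mass).
N2_MASS <- 28.00615

## Isotope masses (Da) and abundances per element, IUPAC 2021 values.
## Elements supported for peptide compositions: C, H, N, O, S.
.ISOTOPES <- list(
  C = data.frame(mass = c(12.0, 13.0033548378),
                 ab   = c(0.9893, 0.0107)),
  H = data.frame(mass = c(1.0078250319, 2.0141017780),
                 ab   = c(0.999885, 0.000115)),
  N = data.frame(mass = c(14.0030740052, 15.0001088984),
                 ab   = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146221, 16.9991315, 17.9991604),
                 ab   = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
                 ab   = c(0.9499, 0.0075, 0.0425, 0.0001))
)

.ELEMENTS <- names(.ISOTOPES)

## Monoisotopic mass of each element's lightest (principal) isotope.
.MONO_MASS <- vapply(.ISOTOPES, function(x) x$mass[1], numeric(1))

## Average atomic weights (IUPAC 2021 conventional values).
.AVG_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

## Elemental composition of each amino-acid residue (peptide-bonded,
## i.e. minus one water relative to the free amino acid).
.RESIDUES <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)
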