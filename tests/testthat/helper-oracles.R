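## Independent oracles and shared fixtures for the test suite.

## Monomer used throughout: the capped PHF6 hexapeptide.
PHF6 <- "Ac-VQIVYK-NH2"
M_PHF6 <- compositionMass(peptideComposition(PHF6))

## Brute-force isotopologue enumeration for small compositions
## (every atom picks an isotope independently; aggregate nearby masses).
## Independent of the package's convolution path.
bruteEnvelope <- function(counts, z = 1, minAbundance = 1e-4) {
  iso <- imsOligo:::.ISOTOPES
  atoms <- rep(names(counts), counts)
  stopifnot(length(atoms) <= 8)
  choices <- lapply(atoms, function(el) seq_len(nrow(iso[[el]])))
  combos <- expand.grid(choices)
  mass <- numeric(nrow(combos))
  ab <- rep(1, nrow(combos))
  for (j in seq_along(atoms)) {
    tab <- iso[[atoms[j]]]
    mass <- mass + tab$mass[combos[[j]]]
    ab <- ab * tab$ab[combos[[j]]]
  }
  o <- order(mass)
  mass <- mass[o]
  ab <- ab[o]
  grp <- cumsum(c(TRUE, diff(mass) > 0.25))
  m <- vapply(split(seq_along(mass), grp),
              function(i) sum(mass[i] * ab[i]) / sum(ab[i]), numeric(1))
  a <- vapply(split(ab, grp), sum, numeric(1))
  a <- a / sum(a)
  keep <- a >= minAbundance
  a <- a[keep] / sum(a[keep])
  m <- m[keep]
  list(mz = unname((m + z * 1.007276) / z), abundance = unname(a))
}

## Minimal in-memory dataset builder.
makeDataset <- function(mz, mobility, intensity, ...) {
  IMMSDataset(data.frame(mz = mz, mobility = mobility,
                         intensity = intensity), ...)
}

## A random isobaric-family simulation with known truth, used by the
## synthetic-recovery properties: family ratio 2:1 or 3:1, strictly
## decreasing planted mobilities, collision-cell fragmentation on.
recoveryCase <- function(seed, collisionFraction = 0.35) {
  set.seed(seed)
  ratio <- sample(2:3, 1)
  K <- sample(4:6, 1)
  gaps <- stats::runif(K - 1, 0.04, 0.12)
  mob <- round(2.0 - cumsum(c(0, gaps)), 3)
  species <- data.frame(n = ratio * seq_len(K), z = seq_len(K),
                        mobility = mob,
                        abundance = stats::runif(K, 20, 100))
  cfg <- simulationConfig(PHF6, species,
                          collisionFraction = collisionFraction,
                          quadWindow = c(oligomerMz(M_PHF6, ratio, 1), 5),
                          noise = c(0.002, 0.005), seed = seed)
  list(config = cfg, species = species, ratio = ratio)
}

runRecovery <- function(seed, collisionFraction = 0.35) {
  case <- recoveryCase(seed, collisionFraction)
  sim <- simulateDataset(case$config)
  fam <- case$species[, c("n", "z")]
  res <- assignByCoincidence(sim$dataset, M_PHF6, fam, peptide = PHF6)
  list(case = case, result = res)
}

## Members whose planted monomer-loss products give >= 2 observable
## fragment channels: charge >= 2 and the heavy product inside the
## instrument range (the (1,1) product always is).
detectableMembers <- function(species, mzRange = c(50, 3000)) {
  heavy <- oligomerMz(M_PHF6, species$n - 1L, pmax(species$z - 1L, 1L))
  species[species$z >= 2 & heavy >= mzRange[1] & heavy <= mzRange[2], ,
          drop = FALSE]
}
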