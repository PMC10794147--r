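## Shared fixtures, built once per test run.

## Energy settings used throughout: fixed-Gse mode with uniform Gmc = 5,
## Gse = 3 (the canonical 1-bond-unfavourable / 2-bond-favourable regime,
## with closed-form worked values), and the concentration realising Gmc = 5
## at u0 = 1 M.
fixParams <- energyParams(Gse = 3, alpha = 0, u0 = 1)
concGmc5 <- exp(-5) * 1e9   # nM such that -log(c/u0) = 5

## mini multifarious fixtures
uniqSmall <- makeFixtureSystem(1, shapes = c("smallL", "smallT"),
                               variant = "unique")
checkerHAM <- makeFixtureSystem(1, shapes = c("H", "A", "M"),
                                variant = "checker")
checkerSmall <- makeFixtureSystem(1, shapes = c("smallH", "smallL", "smallT"),
                                  variant = "checker")

## classification benchmark settings for the checker fixture: base pattern
## 50 nM, Gse = 11 RT puts the system in the nucleation-limited regime
## (Gse < Gmc(50 nM) = 16.8 < 2 Gse)
flagParams <- energyParams(Gse = 11)
flagCenters <- list(H = c(4, 3), A = c(10, 3), M = c(5, 6))
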