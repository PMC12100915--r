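# Shared simulated datasets, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]]))
    .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A mid-size dataset with every artifact class planted.
artifactSim <- function() {
  fixture("artifact", function() {
    cfg <- simConfig(seed = 101, nFragments = 2000,
                     duplicateRate = 0.05, lowMapqRate = 0.05,
                     secondaryRate = 0.05, unmappedRate = 0.05,
                     discordantChromRate = 0.05, outwardRate = 0.05,
                     mitoFraction = 0.02)
    simulateDataset(cfg, dir = file.path(tempdir(), "fix_artifact"))
  })
}

# A clean dataset (no artifacts) for feature-caller tests.
cleanSim <- function() {
  fixture("clean", function() {
    cfg <- simConfig(seed = 202, nFragments = 1500)
    simulateDataset(cfg, dir = file.path(tempdir(), "fix_clean"))
  })
}
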