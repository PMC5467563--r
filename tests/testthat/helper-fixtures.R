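# Shared fixtures, built once per test run. The small superfamily keeps unit
# tests fast; the default-condition superfamily backs the end-to-end checks.

.fixtures <- new.env(parent = emptyenv())

small_config <- function() {
  synthConfig(seed = 7, membersPerFamily = 10L, queriesPerFamily = 5L,
              unplacedPerSubgroup = 5L, unplacedSf = 5L)
}

small_superfamily <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generateSuperfamily(small_config())
  .fixtures$small
}

small_calibrated <- function() {
  if (is.null(.fixtures$small_cal)) {
    sf <- small_superfamily()
    db <- c(sf$sequences,
            shuffleResidues(sf$sequences[seq(1, length(sf$sequences), by = 4)],
                            seed = 99))
    .fixtures$small_cal <- calibrateHierarchy(sf$hierarchy, db)
  }
  .fixtures$small_cal
}

default_superfamily <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- generateSuperfamily(synthConfig(seed = 1))
  .fixtures$default
}

default_calibrated <- function() {
  if (is.null(.fixtures$default_cal)) {
    sf <- default_superfamily()
    db <- c(sf$sequences,
            shuffleResidues(sf$sequences[seq(1, length(sf$sequences), by = 4)],
                            seed = 99))
    .fixtures$default_cal <- calibrateHierarchy(sf$hierarchy, db)
  }
  .fixtures$default_cal
}

default_network <- function() {
  if (is.null(.fixtures$default_net)) {
    sf <- default_superfamily()
    classified <- sf$truth$id[!is.na(sf$truth$family)]
    .fixtures$default_net <- buildNetwork(sf$sequences[classified],
                                          maxEvalue = 1)
  }
  .fixtures$default_net
}
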