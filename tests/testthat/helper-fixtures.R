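# Shared fixtures, generated in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# noise-free sagittal phantom, grades 1..5, no herniation
sagCleanAllGrades <- function() fixture("sagClean", function() {
  generateSagittal(phantomConfig(noiseSigma = 0, seed = 11), discSpecs(1:5))
})

# noisy sagittal phantom with two herniated discs
sagHerniated <- function() fixture("sagHern", function() {
  generateSagittal(phantomConfig(seed = 12),
                   discSpecs(c(2, 3, 2, 4, 3),
                             herniated = c(TRUE, FALSE, TRUE, FALSE, FALSE)))
})

# a small trained reference diagnosis model (shared across tests)
smallDiagnosisModel <- function() fixture("diagModel", function() {
  diagnosisClosedLoop(nPerClass = 40, seed = 21)
})

# equally spaced vertical chain
straightChain <- function(n = 6, spacing = 60) {
  pointChain(cbind(0, spacing * (seq_len(n) - 1)))
}

# point-in-convex-polygon test via cross products (polygon rows in order)
pointInRect <- function(pt, rect) {
  n <- nrow(rect)
  s <- vapply(seq_len(n), function(i) {
    a <- rect[i, ]; b <- rect[i %% n + 1, ]
    (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  }, 0)
  all(s >= -1e-9) || all(s <= 1e-9)
}
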