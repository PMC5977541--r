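# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, builder(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

regularPolygon <- function(cx = 0, cy = 0, r = 10, n = 48L) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(phi), cy + r * sin(phi))
}

ellipsePolygon <- function(a, b, cx = 0, cy = 0, n = 64L) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + a * cos(phi), cy + b * sin(phi))
}

# small strong-effect cohort + features shared across modeling tests
smallStrongCohort <- function() {
  cachedFixture("strongCohort", function() {
    cfg <- cohortConfig(nPatientsPerClass = 8L, patchesPerPatient = 3L,
                        seed = 2024L)
    coh <- suppressMessages(generateCohort(cfg))
    fd <- suppressMessages(cohortFeatureMatrix(coh))
    list(cohort = coh, featureData = fd)
  })
}

# patient-structured pure-noise modeling data (no real signal)
noiseModelingData <- function(nPatients = 30L, patchesPerPatient = 4L,
                              p = 60L, seed = 77L) {
  withr::with_seed(seed, {
    pid <- rep(sprintf("P%02d", seq_len(nPatients)),
               each = patchesPerPatient)
    y <- rep(rep(0:1, each = nPatients / 2), each = patchesPerPatient)
    X <- matrix(rnorm(nPatients * patchesPerPatient * p),
                nPatients * patchesPerPatient, p)
    colnames(X) <- sprintf("f%03d", seq_len(p))
    list(X = X, y = y, patientIds = pid)
  })
}

# all labeled spanning trees on n nodes via Pruefer sequences (exhaustive
# MST oracle for small n)
pruferTrees <- function(n) {
  if (n == 2) return(list(cbind(1L, 2L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  lapply(seq_len(nrow(seqs)), function(r) {
    prufer <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in prufer) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    for (k in seq_along(prufer)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, prufer[k])
      degree[leaf] <- 0L
      degree[prufer[k]] <- degree[prufer[k]] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  })
}
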