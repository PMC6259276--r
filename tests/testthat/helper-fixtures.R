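# Shared fixtures, memoised so the expensive chemistry runs once per session.
.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# all 26 embedded + charged conformers of the packaged series
seriesConformers <- function() memo("confs", {
  embedConformers(compoundSmilesTable(compoundTable()))
})

# the aligned set (template: compound 10)
seriesAligned <- function() memo("aligned", alignSet(seriesConformers()))

# a complete pipeline run on the packaged series, with timing attached
seriesPipeline <- function() memo("pipeline", {
  t0 <- Sys.time()
  run <- suppressMessages(runPipeline())
  attr(run, "elapsedSec") <- as.numeric(Sys.time()) - as.numeric(t0)
  run
})

# single atom at the origin with unit-ish properties, for closed-form fields
singleAtomConformer <- function(element = "C", charge = 0)
  conformer(element, c(0, 0, 0), charge = charge)

# a 1-point grid at the stated offset from the origin
pointGrid <- function(x, y = 0, z = 0)
  new("GridSpec", origin = c(x, y, z), spacing = 1, dims = c(1L, 1L, 1L),
      margin = 0)

# tiny deterministic regression problem with more samples than columns
toyRegression <- function(n = 8, k = 4, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  beta <- rnorm(k)
  y <- as.numeric(X %*% beta) + rnorm(n, sd = 0.1)
  list(X = X, y = y, beta = beta)
}
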