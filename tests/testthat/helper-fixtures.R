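# Shared fixtures.  Heavy simulate-then-reconstruct runs are computed once
# per session and memoised, so several test files can assert against the
# same experiment.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# 8x8 captures, 16x16 object grid: oracle-comparison scale
tinyConfig <- function() {
  opticalConfig(lrShape = c(8L, 8L), hrUpsample = 2L)
}

# 16x16 captures, 64x64 object grid: fast reconstruction scale
smallConfig <- function() {
  opticalConfig(lrShape = c(16L, 16L))
}

smallTissue <- function() {
  memo("smallTissue",
       makePhantom(phantomSpec("tissue", size = 64L, seed = 2L)))
}

smallStack <- function() {
  memo("smallStack", simulateStack(smallTissue(), smallConfig()))
}

# one modest joint reconstruction shared by several contract tests
smallRecon <- function() {
  memo("smallRecon",
       reconstruct(smallStack(), optimizerSpec(epochs = 60L)))
}

randomComplexObject <- function(n, pixelSize, seed) {
  set.seed(seed)
  complexObject(
    phase = matrix(stats::runif(n * n, -0.8, 0.8), n, n),
    absorption = matrix(stats::runif(n * n, 0, 1), n, n),
    pixelSize = pixelSize)
}
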