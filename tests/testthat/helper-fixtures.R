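## Shared fixtures, built once per test run. Heavy intermediates (a default
## phantom taken through preprocessing and segmentation) are cached so
## several test files can reuse them.

.fixtures <- new.env()

fixturePhantom <- function() {
  if (is.null(.fixtures$ph))
    .fixtures$ph <- generatePhantom(phantomSpec(seed = 11L))
  .fixtures$ph
}

fixturePre <- function() {
  if (is.null(.fixtures$pre))
    .fixtures$pre <- preprocessImage(phantomImage(fixturePhantom()))
  .fixtures$pre
}

fixtureSeg <- function() {
  if (is.null(.fixtures$seg)) {
    pre <- fixturePre()
    .fixtures$seg <- segmentLungs(pre$enhanced, pre$mask, seed = 11L)
  }
  .fixtures$seg
}

## truth-aligned quadrant masks for Dice checks
quadrantTruthDice <- function(seg, truth) {
  quads <- lungscreen:::.quadrantMasks(truth@lungMask)
  vapply(1:4, function(q)
    diceScore(segMasks(seg)[[q]], truth@lungMask & quads[[q]]), numeric(1))
}

## two-region piecewise-constant test image
twoRegionImage <- function(n = 32L, a = 0.3, b = 0.8) {
  img <- matrix(a, n, n)
  img[, (n %/% 2 + 1):n] <- b
  img
}
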