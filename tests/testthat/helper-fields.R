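# Shared fixtures: small synthetic fields and the standard preprocessing
# chain, built in code at test time.

# background-correct a channel (and optionally denoise) with the defaults
# used throughout the tests
correctChannel <- function(stack, role, denoise = FALSE, ballRadius = 50) {
  img <- rollingBall(mip(stack, role), ballRadius)
  if (denoise) img <- medianDenoise(img, 3L)
  img
}

# full dna-channel segmentation of a generated field
segmentField <- function(fld, params = segParams(), denoise = FALSE, ...) {
  segmentNuclei(correctChannel(fld$image, "dna", denoise = denoise),
                params, ...)
}

# per-cell detected values aligned to ground-truth rows (unmatched dropped)
alignToTruth <- function(map, truth, values, ids = seq_along(values)) {
  m <- matchSegmentation(map, truth)
  ok <- m$labelOfCell > 0
  list(det = unname(values[match(m$labelOfCell[ok], ids)]),
       truth = gtCells(truth)[ok, , drop = FALSE],
       matched = sum(ok))
}

# tiny hand-built stack: one rectangular "nucleus" per channel value given
flatStack <- function(h, w, channels) {
  ImageStack(lapply(channels, function(v) matrix(v, h, w)))
}
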