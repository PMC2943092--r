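# Threshold probing: iterative region growing that separates enhanced
# vessels from background in a matched-filter response image.  Seed pixels
# are taken above a high percentile of the positive responses; connected
# regions containing a seed are grown by lowering a probe threshold in fixed
# decrements down to a floor, a region being frozen at its previous extent
# if growing it would exceed the maximum allowed size; regions outside the
# accepted size range at the floor are discarded.

#' Threshold probing segmentation of a response image
#'
#' @param response a \linkS4class{ResponseImage} (or numeric matrix)
#' @param seedQuantile quantile of positive responses above which pixels
#'   seed a region (default 0.95)
#' @param floorFraction lower bound on the probe floor as a fraction of
#'   the seed threshold (default 0.2)
#' @param nSteps number of probe-threshold decrements between seed level
#'   and floor
#' @param minPx,maxPx accepted region size range in pixels
#' @param seedFactor,floorFactor,noiseQuantile thresholds relative to the
#'   noise scale of the response, estimated as the \code{noiseQuantile}
#'   magnitude of the negative responses (vessels only push the response
#'   positive, so the negative tail is a vessel-free noise yardstick);
#'   the seed threshold is capped at \code{seedFactor} times this scale,
#'   making probing robust to how much of the frame the vessels cover
#' @return a \linkS4class{CenterlineImage} holding the binary vessel mask
#'   (not yet thinned); an all-zero response yields an empty mask
#' @export
thresholdProbe <- function(response, seedQuantile = 0.95,
                           floorFraction = 0.2, nSteps = 10L,
                           minPx = 30L, maxPx = 50000L,
                           seedFactor = 3, floorFactor = 1,
                           noiseQuantile = 0.99) {
  r <- if (is(response, "ResponseImage")) response@responses else response
  pos <- r[r > 0]
  if (length(pos) == 0L)
    return(new("CenterlineImage", mask = matrix(FALSE, nrow(r), ncol(r)),
               guaranteedThin = FALSE))
  noiseScale <- if (any(r < 0)) {
    -stats::quantile(r[r < 0], 1 - noiseQuantile, names = FALSE)
  } else 0
  # the positive-response quantile under-shoots when vessels cover little
  # of the frame (ripple dominates the positives), so the negative-tail
  # scale acts as a floor for the seed level; region growing down to the
  # probe floor still recovers weaker connected branches
  tSeed <- max(stats::quantile(pos, seedQuantile, names = FALSE),
               seedFactor * noiseScale)
  tFloor <- max(floorFactor * noiseScale, floorFraction * tSeed)
  tFloor <- min(tFloor, tSeed)
  thresholds <- seq(tSeed, tFloor, length.out = nSteps + 1L)
  cur <- r >= tSeed                        # seed regions
  for (t in thresholds[-1]) {
    lab <- EBImage::bwlabel(r >= t)
    if (max(lab) == 0) next
    sizes <- tabulate(lab[lab > 0])
    seeded <- unique(lab[cur & lab > 0])
    seeded <- seeded[seeded > 0]
    grow <- seeded[sizes[seeded] <= maxPx]
    frozen <- setdiff(seeded, grow)
    nxt <- matrix(lab %in% grow, nrow(r), ncol(r))
    if (length(frozen) > 0)                 # keep previous extent of regions
      nxt <- nxt | (cur & matrix(lab %in% frozen, nrow(r), ncol(r)))
    cur <- nxt
  }
  lab <- EBImage::bwlabel(cur)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minPx & sizes <= maxPx)
    cur <- matrix(lab %in% keep, nrow(r), ncol(r))
  }
  new("CenterlineImage", mask = cur, guaranteedThin = FALSE)
}
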