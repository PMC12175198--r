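#' @include extract.R
NULL

#' Digital refocus of a capture stack
#'
#' Recovers the acquisition defocus without mechanical adjustment.
#' `"joint_opt"` runs a full reconstruction with the defocus free and
#' returns its estimate; `"sweep"` runs short reconstructions with the
#' defocus frozen at each candidate of a grid over `zRange` and returns
#' the candidate with the lowest final loss (ties broken towards the
#' smallest `|z|`).  The sweep focus score is the reconstruction loss
#' after a short fixed budget, staying inside the model-fitting framework
#' rather than adding an image-sharpness heuristic.
#'
#' @param stack A [CaptureStack-class].
#' @param mode `"joint_opt"` or `"sweep"`.
#' @param zRange Length-2 finite interval searched (um).
#' @param nCandidates Sweep grid size (>= 3); the joint mode uses a
#'   coarse 11-point grid for its warm start.
#' @param spec [OptimizerSpec-class] used for the reconstructions;
#'   the sweep forces `freeze` to include `"z"`, the joint mode removes
#'   `"z"` from `freeze`.  Default: 20-epoch budget for sweep scoring and
#'   the package defaults for joint mode.
#' @return A [RefocusResult-class]; `atBoundary` flags a sweep argmin on
#'   an endpoint (search range likely too narrow), with a warning.
#' @export
refocus <- function(stack, mode = c("joint_opt", "sweep"),
                    zRange = c(-50, 50), nCandidates = 21L, spec = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(zRange)), length(zRange) == 2L)

  if (mode == "joint_opt") {
    if (is.null(spec)) spec <- optimizerSpec()
    spec@freeze <- setdiff(spec@freeze, "z")
    # The intensity-only objective has a near-degenerate conjugate twin at
    # the mirrored defocus, so a gradient descent started at z = 0 can be
    # captured by the wrong basin for large defocus.  A cheap frozen-z
    # coarse sweep places the start inside the correct basin; z then stays
    # free during the full joint reconstruction.
    sweep <- refocusSweep(stack, zRange, 11L,
                          optimizerSpec(epochs = 10L, seed = spec@seed))
    st0 <- initializeState(stack)
    st0@z <- sweep$zStar
    st <- reconstruct(stack, spec, state = st0)
    return(methods::new("RefocusResult",
      zStar = st@z, zGrid = sweep$zGrid, scoreCurve = sweep$score,
      method = "joint_opt", atBoundary = sweep$atBoundary))
  }

  stopifnot(nCandidates >= 3L)
  if (is.null(spec)) spec <- optimizerSpec(epochs = 20L)
  sweep <- refocusSweep(stack, zRange, nCandidates, spec)
  if (sweep$atBoundary)
    warning("refocus argmin sits on an endpoint of zRange; widen the range")
  methods::new("RefocusResult",
    zStar = sweep$zStar, zGrid = sweep$zGrid, scoreCurve = sweep$score,
    method = "sweep", atBoundary = sweep$atBoundary)
}

refocusSweep <- function(stack, zRange, nCandidates, spec) {
  spec@freeze <- union(spec@freeze, "z")
  zGrid <- seq(zRange[1], zRange[2], length.out = nCandidates)
  score <- vapply(zGrid, function(z) {
    st0 <- initializeState(stack)
    st0@z <- z
    st <- reconstruct(stack, spec, state = st0)
    utils::tail(st@lossHistory, 1)
  }, numeric(1))
  cand <- which(score <= min(score))
  zStar <- zGrid[cand[which.min(abs(zGrid[cand]))]]
  list(zStar = zStar, zGrid = zGrid, score = score,
       atBoundary = zStar %in% zGrid[c(1L, length(zGrid))])
}

setMethod("show", "RefocusResult", function(object) {
  cat(sprintf("RefocusResult (%s): z* = %.2f um%s\n", object@method,
              object@zStar,
              if (object@atBoundary) " [at range boundary]" else ""))
})

#' Reconstruct at a chosen focal plane, suppressing out-of-plane content
#'
#' Runs the reconstruction with the defocus frozen at `focalZ`, so only
#' content of the selected plane is rendered sharply; occluders on other
#' planes (marker strokes, dust, stains on the slide surface) blur into a
#' low-contrast background instead of masking the tissue.  For stacks
#' simulated from a [TwoPlaneScene-class] focused on the tissue, the
#' tissue plane is `focalZ = 0` and the occluder plane renders sharp at
#' `focalZ = -separation`.
#'
#' @param stack A [CaptureStack-class].
#' @param focalZ Defocus at which to reconstruct (um).
#' @param spec [OptimizerSpec-class]; `freeze` is forced to include
#'   `"z"`.
#' @return A list as returned by [extractObject()], with the final
#'   [ReconstructionState-class] appended as `state`.
#' @export
suppressOccluder <- function(stack, focalZ = 0, spec = optimizerSpec()) {
  spec@freeze <- union(spec@freeze, "z")
  st0 <- initializeState(stack)
  st0@z <- focalZ
  st <- reconstruct(stack, spec, state = st0)
  out <- extractObject(st)
  out$state <- st
  out
}
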