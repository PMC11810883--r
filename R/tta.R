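# Test-time-augmentation baseline: invertible spatial transforms applied
# at inference, predictions inverse-mapped and stacked, then aggregated
# and scored by the same machinery as the projection ensemble so the
# comparison isolates the projection mechanism.

.rotCW <- function(m) t(m[nrow(m):1, , drop = FALSE])

.applyToChannels <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  out <- NULL
  for (ch in seq_len(dim(x)[3])) {
    r <- f(x[, , ch])
    if (is.null(out)) out <- array(0, c(dim(r), dim(x)[3]))
    out[, , ch] <- r
  }
  out
}

.rotateK <- function(x, k) {
  k <- k %% 4
  f <- function(m) { for (i in seq_len(k)) m <- .rotCW(m); m }
  .applyToChannels(x, f)
}

.translate <- function(x, dr, dc) {
  f <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    rs <- intersect(seq_len(nrow(m)), seq_len(nrow(m)) + dr)
    cs <- intersect(seq_len(ncol(m)), seq_len(ncol(m)) + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  .applyToChannels(x, f)
}

.makeTransform <- function(name, apply, invert)
  list(name = name, apply = apply, invert = invert)

#' Default set of eight invertible test-time augmentations
#'
#' Identity, rotations by 90/180/270 degrees, horizontal and vertical
#' flips, and two integer translations of \code{translatePx} pixels.
#' Every transform has an exact inverse on the pixel grid (translations
#' lose a \code{translatePx}-wide border band, restored as zeros).
#'
#' @param translatePx magnitude of the translation augmentations
#'   (default 8 px).
#' @return list of transforms, each with \code{name}, \code{apply} and
#'   \code{invert} functions; the identity comes first.
#' @export
defaultAugmentations <- function(translatePx = 8L) {
  t <- translatePx
  list(
    .makeTransform("identity", identity, identity),
    .makeTransform("rot90", function(x) .rotateK(x, 1),
                   function(x) .rotateK(x, 3)),
    .makeTransform("rot180", function(x) .rotateK(x, 2),
                   function(x) .rotateK(x, 2)),
    .makeTransform("rot270", function(x) .rotateK(x, 3),
                   function(x) .rotateK(x, 1)),
    .makeTransform("fliph",
                   function(x) .applyToChannels(x, function(m) m[, ncol(m):1]),
                   function(x) .applyToChannels(x, function(m) m[, ncol(m):1])),
    .makeTransform("flipv",
                   function(x) .applyToChannels(x, function(m) m[nrow(m):1, ]),
                   function(x) .applyToChannels(x, function(m) m[nrow(m):1, ])),
    .makeTransform("shift+", function(x) .translate(x, t, t),
                   function(x) .translate(x, -t, -t)),
    .makeTransform("shift-", function(x) .translate(x, -t, -t),
                   function(x) .translate(x, t, t)))
}

#' Test-time-augmentation prediction stack
#'
#' Applies each augmentation to the slice, predicts, inverse-transforms
#' the probability map, and stacks the results.  The stack is consumable
#' by the same [binarizeEnsemble()] / [entropyMap()] / [uscoreCurves()]
#' path as the projection ensemble.
#'
#' @param predictor a \linkS4class{SegPredictor}.
#' @param image planar rows x cols x channels array.
#' @param augmentations list of transforms from [defaultAugmentations()].
#' @param sourceId identifier stored on the stack.
#' @return a \linkS4class{ProbabilityStack} (count x rows x cols, no
#'   projection centres).
#' @export
predictTTA <- function(predictor, image,
                       augmentations = defaultAugmentations(),
                       sourceId = "slice") {
  stopifnot(is(predictor, "SegPredictor"), length(augmentations) >= 1)
  image <- .checkImage(image)
  gt <- attr(image, "gt")
  d <- dim(image)
  maps <- array(0, c(length(augmentations), d[1], d[2]))
  for (i in seq_along(augmentations)) {
    tr <- augmentations[[i]]
    xi <- tr$apply(image)
    if (!is.null(gt)) attr(xi, "gt") <- tr$apply(gt)
    p <- predictProbability(predictor, xi)
    maps[i, , ] <- tr$invert(p)
  }
  probabilityStack(maps, NULL, sourceId)
}
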