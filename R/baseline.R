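#' Average pairwise-similarity consensus baseline
#'
#' The classic multimodel consensus predictor: each decoy's quality score
#' is its mean pairwise TM-score against all other decoys in the pool
#' (self-similarity excluded). Strong on pools rich in good models, but
#' subject to the central-tendency failure: a large cluster of mutually
#' similar mediocre models drags its members' consensus scores up and wins
#' the top rank.
#'
#' @param tm A [PairwiseMatrix-class] with metric \code{"tm"}.
#' @param targetId Target identifier for the returned set.
#' @return A [PredictionSet-class] of consensus scores.
#' @examples
#' m <- matrix(c(1, .6, .8, .6, 1, .7, .8, .7, 1), 3,
#'             dimnames = list(paste0("d", 1:3), paste0("d", 1:3)))
#' predScores(pssScores(PairwiseMatrix("tm", paste0("d", 1:3), m)))
#' @export
pssScores <- function(tm, targetId = "target") {
  stopifnot(is(tm, "PairwiseMatrix"))
  if (length(tm@ids) < 2L) stop("PSS needs at least 2 decoys")
  PredictionSet(targetId, tm@ids,
                .clip01(.rowMeanOffDiagonal(tm@values)))
}
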