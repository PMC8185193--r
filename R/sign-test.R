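#' Exact paired sign test
#'
#' Classical exact sign test on paired differences. Differences no larger
#' in magnitude than \code{zeroTolerance} are treated as ties and excluded;
#' on the m remaining differences with k positive, the two-sided p-value is
#' the doubled exact binomial tail
#' \deqn{p = \min(1,\; 2\,P(\mathrm{Bin}(m, 1/2) \ge \max(k, m-k))).}
#' With no non-tied differences the test carries no evidence and p = 1.
#' Because the null binomial is symmetric, tail doubling coincides with
#' summing both exact tails (\code{tailMethod = "both"} is provided for
#' completeness and gives identical values here).
#'
#' @param differences numeric vector of paired differences.
#' @param zeroTolerance magnitude at or below which a difference counts as
#'   a tie; default 1e-9 (numerical zero). For tables rounded to 2 decimals
#'   use 0.005 so values equal after rounding count as ties.
#' @param tailMethod \code{"doubled"} (default) or \code{"both"}.
#' @return A [SignTestResult-class] object.
#' @examples
#' exactSignTest(rep(1, 13))   # p = 2 * (1/2)^13 ~ 0.000244
#' exactSignTest(c(0, 0, 0))   # all ties: p = 1
#' @export
exactSignTest <- function(differences, zeroTolerance = 1e-9,
                          tailMethod = c("doubled", "both")) {
  tailMethod <- match.arg(tailMethod)
  if (!length(differences)) {
    stop("need at least one paired difference", call. = FALSE)
  }
  if (any(!is.finite(differences))) {
    stop("differences must be finite", call. = FALSE)
  }
  nz <- differences[abs(differences) > zeroTolerance]
  m <- length(nz)
  k <- sum(nz > 0)
  if (m == 0L) {
    p <- 1
  } else {
    kMax <- max(k, m - k)
    tailUp <- stats::pbinom(kMax - 1L, m, 0.5, lower.tail = FALSE)
    p <- if (tailMethod == "doubled") {
      min(1, 2 * tailUp)
    } else {
      min(1, tailUp + stats::pbinom(m - kMax, m, 0.5))
    }
  }
  new("SignTestResult", nTotal = length(differences), nNonzero = m,
      nPositive = as.integer(k), pTwoSided = p)
}

#' @rdname exactSignTest
#' @param x a [SignTestResult-class].
#' @export
setMethod("pValue", "SignTestResult", function(x) x@pTwoSided)

setMethod("show", "SignTestResult", function(object) {
  cat(sprintf(
    "Exact sign test: %d pairs (%d non-tied, %d positive), p = %.6g\n",
    object@nTotal, object@nNonzero, object@nPositive, object@pTwoSided))
})
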