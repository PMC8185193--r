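#' Convert between cumulative and differential DVH forms
#'
#' \code{toDifferential} takes successive differences of the
#' volume-at-or-above curve: bin \code{[d_i, d_i+1)} receives
#' \code{V[i] - V[i+1]}. Volume still at or above the last grid point is
#' assigned to one trailing bin (with a warning) so total volume is
#' conserved. \code{toCumulative} is the exact inverse on the bin edges.
#'
#' @param x a [CumulativeDVH-class] (for \code{toDifferential}) or a
#'   [DifferentialDVH-class] (for \code{toCumulative}).
#' @param ... unused.
#' @return The converted DVH; the roundtrip reproduces the input to
#'   floating-point accuracy.
#' @examples
#' cdvh <- CumulativeDVH("ovaries", c(0, 10, 20), c(1, 0.4, 0))
#' toDifferential(cdvh)  # bins 0-10: 0.6, 10-20: 0.4
#' @name dvh-conversion
#' @aliases toDifferential toCumulative
NULL

#' @rdname dvh-conversion
setMethod("toDifferential", "CumulativeDVH", function(x, ...) {
  V <- x@volumeAtOrAbove
  d <- x@doseGrid
  v <- -diff(V)
  tail <- V[length(V)]
  if (tail > 1e-9) {
    warning("cumulative DVH ends above zero volume; assigning ",
            signif(tail, 4), " to a trailing bin", call. = FALSE)
    w <- mean(diff(d))
    d <- c(d, d[length(d)] + w)
    v <- c(v, tail)
  }
  DifferentialDVH(x@organ, d, v, totalVolumeCc = x@totalVolumeCc,
                  normalize = TRUE)
})

#' @rdname dvh-conversion
setMethod("toCumulative", "DifferentialDVH", function(x, ...) {
  v <- x@binVolume
  V <- rev(cumsum(rev(c(v, 0))))
  CumulativeDVH(x@organ, x@binEdges, V / V[1L],
                totalVolumeCc = x@totalVolumeCc)
})

#' Rebin a differential DVH onto a uniform dose grid
#'
#' Output bins are \code{[0, width), [width, 2*width), ...} covering the
#' maximum dose; the volume of every input bin is apportioned to output bins
#' in proportion to dose-interval overlap (i.e. dose is taken as uniformly
#' distributed within a bin). Total volume is conserved exactly and the mean
#' dose moves by at most half the bin width.
#'
#' @param x a [DifferentialDVH-class].
#' @param width output bin width in Gy; the default 0.1 Gy is the interval
#'   width the follicle survival summation assumes.
#' @param ... unused.
#' @return A [DifferentialDVH-class] on the uniform grid.
#' @examples
#' d <- DifferentialDVH("ovaries", c(0.05, 0.15), 1)
#' binVolume(rebin(d, 0.1))  # 0.5 / 0.5 split
#' @export
setMethod("rebin", "DifferentialDVH", function(x, width = 0.1, ...) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width <= 0) {
    stop("'width' must be a single positive dose in Gy", call. = FALSE)
  }
  e <- x@binEdges
  v <- x@binVolume
  maxEdge <- e[length(e)]
  nOut <- max(1L, as.integer(ceiling(maxEdge / width - 1e-9)))
  outEdges <- seq(0, by = width, length.out = nOut + 1L)
  outV <- numeric(nOut)
  for (i in seq_along(v)) {
    if (v[i] == 0) next
    lo <- e[i]; hi <- e[i + 1L]
    jLo <- max(1L, as.integer(floor(lo / width - 1e-12)) + 1L)
    jHi <- min(nOut, as.integer(ceiling(hi / width + 1e-12)))
    for (j in jLo:jHi) {
      ov <- min(hi, outEdges[j + 1L]) - max(lo, outEdges[j])
      if (ov > 0) outV[j] <- outV[j] + v[i] * ov / (hi - lo)
    }
  }
  DifferentialDVH(x@organ, outEdges, outV, totalVolumeCc = x@totalVolumeCc,
                  normalize = TRUE)
})

#' Combine two organ DVHs into one
#'
#' Volume-weighted mixture of two differential DVHs on a common dose grid,
#' e.g. merging left and right ovary into the "both ovaries" histogram the
#' follicle survival summation needs. When both inputs carry an absolute
#' volume the mixture weights are proportional to it and the result's
#' \code{totalVolumeCc} is the sum; otherwise the organs are weighted
#' equally (with a warning, since the true volumes are then unknown).
#'
#' @param a,b [DifferentialDVH-class] objects on identical bin edges
#'   (use [rebin()] first).
#' @param organ label for the combined structure.
#' @return A [DifferentialDVH-class].
#' @export
combineOrgans <- function(a, b, organ = "combined") {
  if (length(a@binEdges) != length(b@binEdges) ||
      any(abs(a@binEdges - b@binEdges) > 1e-9)) {
    stop("bin edges differ; rebin() both DVHs to a common grid first",
         call. = FALSE)
  }
  if (!is.na(a@totalVolumeCc) && !is.na(b@totalVolumeCc)) {
    wa <- a@totalVolumeCc
    wb <- b@totalVolumeCc
    cc <- wa + wb
  } else {
    warning("absolute organ volumes unavailable; weighting organs equally",
            call. = FALSE)
    wa <- wb <- 1
    cc <- NA_real_
  }
  v <- (wa * a@binVolume + wb * b@binVolume) / (wa + wb)
  DifferentialDVH(organ, a@binEdges, v, totalVolumeCc = cc,
                  normalize = TRUE)
}

#' Dose summaries of a differential DVH
#'
#' \code{meanDose} is the volume-weighted mean of the bin midpoints
#' \code{(d_i + d_i+1)/2}; \code{maxDose} is the upper edge of the highest
#' bin whose volume exceeds \code{tol}.
#'
#' @param x a [DifferentialDVH-class].
#' @param tol volume below which a bin counts as empty (default 1e-9).
#' @param ... unused.
#' @return Dose in Gy.
#' @name dose-summaries
#' @aliases meanDose maxDose
NULL

#' @rdname dose-summaries
setMethod("meanDose", "DifferentialDVH", function(x, ...) {
  mid <- (x@binEdges[-length(x@binEdges)] + x@binEdges[-1L]) / 2
  sum(mid * x@binVolume) / sum(x@binVolume)
})

#' @rdname dose-summaries
setMethod("maxDose", "DifferentialDVH", function(x, tol = 1e-9, ...) {
  idx <- which(x@binVolume > tol)
  if (!length(idx)) {
    stop("DVH has no bin with volume above tolerance", call. = FALSE)
  }
  x@binEdges[max(idx) + 1L]
})

#' Extract the combined both-ovaries DVH from a plan
#'
#' Uses the \code{"ovaries"} entry when present; otherwise combines
#' \code{"ovary_left"} and \code{"ovary_right"} with [combineOrgans()] after
#' rebinning both to \code{width}.
#'
#' @param plan a [PlanRecord-class].
#' @param width common grid width in Gy used when merging left/right.
#' @return A [DifferentialDVH-class].
#' @export
ovaryDvh <- function(plan, width = 0.1) {
  nm <- names(plan@organs)
  if ("ovaries" %in% nm) return(plan@organs[["ovaries"]])
  if (all(c("ovary_left", "ovary_right") %in% nm)) {
    l <- rebin(plan@organs[["ovary_left"]], width)
    r <- rebin(plan@organs[["ovary_right"]], width)
    if (length(l@binEdges) != length(r@binEdges)) {
      n <- max(length(l@binEdges), length(r@binEdges))
      pad <- function(d) {
        k <- n - length(d@binEdges)
        if (k == 0L) return(d)
        DifferentialDVH(d@organ,
                        seq(0, by = width, length.out = n),
                        c(d@binVolume, rep(0, k)),
                        totalVolumeCc = d@totalVolumeCc, normalize = FALSE)
      }
      l <- pad(l); r <- pad(r)
    }
    return(combineOrgans(l, r, organ = "ovaries"))
  }
  stop("plan for patient ", plan@patientId,
       " has no ovary DVH ('ovaries' or 'ovary_left'+'ovary_right')",
       call. = FALSE)
}
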