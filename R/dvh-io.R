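#' Construct a differential DVH
#'
#' @param organ organ label.
#' @param binEdges strictly increasing dose values in Gy, length B+1.
#' @param binVolume volume per bin, length B. Interpreted as relative
#'   fractions; values on another scale (percent, cc) are normalized to sum
#'   to 1 when \code{normalize = TRUE}.
#' @param totalVolumeCc absolute organ volume in cm^3, or \code{NA}.
#' @param normalize divide \code{binVolume} by its sum (default). With
#'   \code{FALSE} the volumes must already sum to 1 within 1e-6.
#' @return A [DifferentialDVH-class] object.
#' @examples
#' d <- DifferentialDVH("ovaries", c(0, 10, 20), c(0.6, 0.4))
#' meanDose(d)
#' @export
DifferentialDVH <- function(organ, binEdges, binVolume,
                            totalVolumeCc = NA_real_, normalize = TRUE) {
  binEdges <- as.numeric(binEdges)
  binVolume <- as.numeric(binVolume)
  if (normalize) {
    s <- sum(binVolume)
    if (!is.finite(s) || s <= 0) {
      stop("cannot normalize a DVH whose volumes sum to ", s, call. = FALSE)
    }
    binVolume <- binVolume / s
  }
  new("DifferentialDVH", organ = as.character(organ), binEdges = binEdges,
      binVolume = binVolume, totalVolumeCc = as.numeric(totalVolumeCc))
}

#' Construct a cumulative DVH
#'
#' @param organ organ label.
#' @param doseGrid increasing dose values in Gy.
#' @param volumeAtOrAbove fraction of the organ volume receiving at least
#'   each grid dose; non-increasing, starting at 1.
#' @param totalVolumeCc absolute organ volume in cm^3, or \code{NA}.
#' @return A [CumulativeDVH-class] object.
#' @export
CumulativeDVH <- function(organ, doseGrid, volumeAtOrAbove,
                          totalVolumeCc = NA_real_) {
  new("CumulativeDVH", organ = as.character(organ),
      doseGrid = as.numeric(doseGrid),
      volumeAtOrAbove = as.numeric(volumeAtOrAbove),
      totalVolumeCc = as.numeric(totalVolumeCc))
}

#' Construct a plan record
#'
#' @param patientId patient label.
#' @param technique \code{"IFRT"} or \code{"ISRT"}.
#' @param organs named list of [DifferentialDVH-class] objects.
#' @return A [PlanRecord-class] object.
#' @export
PlanRecord <- function(patientId, technique, organs = list()) {
  new("PlanRecord", patientId = as.character(patientId),
      technique = as.character(technique), organs = organs)
}

#' Construct a patient pair
#'
#' @param ifrt,isrt [PlanRecord-class] objects for the same patient, one per
#'   technique.
#' @return A [PatientPair-class] object.
#' @export
PatientPair <- function(ifrt, isrt) {
  new("PatientPair", patientId = ifrt@patientId, ifrt = ifrt, isrt = isrt)
}

#' Slot accessors
#'
#' Read-only accessors for the DVH and plan classes.
#' @param x an object of the matching class.
#' @name accessors
#' @aliases organ binEdges binVolume totalVolumeCc doseGrid volumeAtOrAbove
#'   patientId technique organs
NULL

#' @rdname accessors
setMethod("organ", "DifferentialDVH", function(x) x@organ)
#' @rdname accessors
setMethod("organ", "CumulativeDVH", function(x) x@organ)
#' @rdname accessors
setMethod("binEdges", "DifferentialDVH", function(x) x@binEdges)
#' @rdname accessors
setMethod("binVolume", "DifferentialDVH", function(x) x@binVolume)
#' @rdname accessors
setMethod("totalVolumeCc", "DifferentialDVH", function(x) x@totalVolumeCc)
#' @rdname accessors
setMethod("totalVolumeCc", "CumulativeDVH", function(x) x@totalVolumeCc)
#' @rdname accessors
setMethod("doseGrid", "CumulativeDVH", function(x) x@doseGrid)
#' @rdname accessors
setMethod("volumeAtOrAbove", "CumulativeDVH", function(x) x@volumeAtOrAbove)
#' @rdname accessors
setMethod("patientId", "PlanRecord", function(x) x@patientId)
#' @rdname accessors
setMethod("patientId", "PatientPair", function(x) x@patientId)
#' @rdname accessors
setMethod("technique", "PlanRecord", function(x) x@technique)
#' @rdname accessors
setMethod("organs", "PlanRecord", function(x) x@organs)

setMethod("show", "DifferentialDVH", function(object) {
  cat(sprintf(
    "DifferentialDVH: %s | %d bins over [%.3g, %.3g] Gy | mean %.2f Gy%s\n",
    object@organ, length(object@binVolume),
    object@binEdges[1L], object@binEdges[length(object@binEdges)],
    meanDose(object),
    if (is.na(object@totalVolumeCc)) "" else
      sprintf(" | %.1f cc", object@totalVolumeCc)))
})

setMethod("show", "CumulativeDVH", function(object) {
  cat(sprintf("CumulativeDVH: %s | %d grid points over [%.3g, %.3g] Gy\n",
              object@organ, length(object@doseGrid),
              object@doseGrid[1L], object@doseGrid[length(object@doseGrid)]))
})

setMethod("show", "PlanRecord", function(object) {
  cat(sprintf("PlanRecord: patient %s, %s, %d organ(s): %s\n",
              object@patientId, object@technique, length(object@organs),
              paste(names(object@organs), collapse = ", ")))
})

setMethod("show", "PatientPair", function(object) {
  cat(sprintf("PatientPair: patient %s (IFRT: %d organs; ISRT: %d organs)\n",
              object@patientId, length(object@ifrt@organs),
              length(object@isrt@organs)))
})

.dvhRequiredCols <- c("patient_id", "technique", "organ", "dvh_type",
                      "dose_gy", "volume", "volume_kind")

#' Read a DVH table export
#'
#' Reads the tabular DVH exchange format: one dose/volume point per row,
#' UTF-8, decimal point, with header columns \code{patient_id},
#' \code{technique} (IFRT|ISRT), \code{organ}, \code{dvh_type}
#' (differential|cumulative), \code{dose_gy}, \code{volume},
#' \code{volume_kind} (relative|absolute) and optionally
#' \code{organ_volume_cc}. For differential rows, \code{dose_gy} is the
#' lower edge of each bin and bins are assumed to lie on a uniform grid (the
#' bin width is inferred from the dose spacing; a single-bin organ falls
#' back to \code{defaultWidth}). For cumulative rows, \code{dose_gy} are the
#' grid points of the volume-at-or-above curve, which is converted to
#' differential form. Absolute volumes (cc) are normalized to fractions with
#' the total kept as \code{totalVolumeCc}.
#'
#' @param path CSV file path.
#' @param defaultWidth bin width in Gy used when an organ has a single
#'   differential row (default 0.1).
#' @return A list of [PlanRecord-class] objects, one per (patient,
#'   technique) present in the file.
#' @seealso [pairPatients()] to assemble [PatientPair-class] objects,
#'   [writeDvhTable()] for the inverse.
#' @export
readDvhTable <- function(path, defaultWidth = 0.1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.dvhRequiredCols, names(tab))
  if (length(missing)) {
    stop("DVH table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("DVH table contains no rows", call. = FALSE)
  bad <- which(!is.finite(tab$dose_gy) | tab$dose_gy < 0)
  if (length(bad)) {
    stop("negative or non-numeric dose_gy at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(tab$volume) | tab$volume < 0)
  if (length(bad)) {
    stop("negative or non-numeric volume at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!tab$technique %in% .techniques)
  if (length(bad)) {
    stop("unknown technique label '", tab$technique[bad[1L]], "' at row ",
         bad[1L], " (expected IFRT or ISRT)", call. = FALSE)
  }
  bad <- which(!tab$dvh_type %in% c("differential", "cumulative"))
  if (length(bad)) {
    stop("unknown dvh_type '", tab$dvh_type[bad[1L]], "' at row ", bad[1L],
         call. = FALSE)
  }
  bad <- which(!tab$volume_kind %in% c("relative", "absolute"))
  if (length(bad)) {
    stop("unknown volume_kind '", tab$volume_kind[bad[1L]], "' at row ",
         bad[1L], call. = FALSE)
  }

  plans <- list()
  for (key in unique(paste(tab$patient_id, tab$technique, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- tab[tab$patient_id == parts[1L] & tab$technique == parts[2L], ,
               drop = FALSE]
    organDvhs <- list()
    for (org in unique(sub$organ)) {
      rows <- sub[sub$organ == org, , drop = FALSE]
      rows <- rows[order(rows$dose_gy), , drop = FALSE]
      type <- unique(rows$dvh_type)
      kind <- unique(rows$volume_kind)
      if (length(type) != 1L || length(kind) != 1L) {
        stop("mixed dvh_type or volume_kind for patient ", parts[1L],
             ", organ ", org, call. = FALSE)
      }
      cc <- NA_real_
      if ("organ_volume_cc" %in% names(rows)) {
        ccVals <- rows$organ_volume_cc[is.finite(rows$organ_volume_cc)]
        if (length(ccVals)) cc <- ccVals[1L]
      }
      if (type == "cumulative") {
        V <- rows$volume
        if (kind == "absolute") {
          if (is.na(cc)) cc <- max(V)
          V <- V / max(V)
        }
        d <- toDifferential(CumulativeDVH(org, rows$dose_gy, V,
                                          totalVolumeCc = cc))
      } else {
        lo <- rows$dose_gy
        if (length(lo) > 1L) {
          w <- stats::median(diff(lo))
          edges <- c(lo, lo[length(lo)] + w)
        } else {
          edges <- c(lo, lo + defaultWidth)
        }
        if (kind == "absolute" && is.na(cc)) cc <- sum(rows$volume)
        d <- DifferentialDVH(org, edges, rows$volume, totalVolumeCc = cc)
      }
      organDvhs[[org]] <- d
    }
    plans[[length(plans) + 1L]] <-
      PlanRecord(parts[1L], parts[2L], organDvhs)
  }
  plans
}

#' Write plan records to the DVH table format
#'
#' The inverse of [readDvhTable()]. Because the exchange format carries one
#' dose value per row and assumes uniformly spaced differential bins, every
#' DVH is rebinned to a uniform \code{width} grid before writing.
#'
#' @param plans list of [PlanRecord-class] (or [PatientPair-class], which
#'   contribute both plans).
#' @param path output CSV path.
#' @param width uniform bin width in Gy (default 0.1).
#' @return \code{path}, invisibly.
#' @export
writeDvhTable <- function(plans, path, width = 0.1) {
  expand <- function(p) {
    if (is(p, "PatientPair")) list(p@ifrt, p@isrt) else list(p)
  }
  plans <- unlist(lapply(plans, expand), recursive = FALSE)
  rows <- vector("list", 0L)
  for (p in plans) {
    for (org in names(p@organs)) {
      d <- rebin(p@organs[[org]], width = width)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p@patientId,
        technique = p@technique,
        organ = org,
        dvh_type = "differential",
        dose_gy = d@binEdges[-length(d@binEdges)],
        volume = d@binVolume,
        volume_kind = "relative",
        organ_volume_cc = d@totalVolumeCc,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pair IFRT and ISRT plans by patient
#'
#' @param plans list of [PlanRecord-class] objects.
#' @return A list of [PatientPair-class], one per patient having both
#'   techniques; patients missing a technique raise an error.
#' @export
pairPatients <- function(plans) {
  ids <- vapply(plans, patientId, character(1L))
  tech <- vapply(plans, technique, character(1L))
  out <- list()
  for (id in unique(ids)) {
    i <- which(ids == id & tech == "IFRT")
    s <- which(ids == id & tech == "ISRT")
    if (length(i) != 1L || length(s) != 1L) {
      stop("patient ", id, " needs exactly one IFRT and one ISRT plan",
           call. = FALSE)
    }
    out[[length(out) + 1L]] <- PatientPair(plans[[i]], plans[[s]])
  }
  out
}
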