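# Measure specifications: which (region, hemisphere) volumes are summed
# into the scalar decision variable x.

#' Define a volumetric measure
#'
#' A measure is a named selection of medial-temporal-lobe subregions and
#' hemispheres; its value for a subject is the sum of the selected
#' volumes in cubic millimetres. The measures the analysis uses are the
#' bilateral MTL total (all four regions, both hemispheres — eight
#' terms), the bilateral total of a single region, and single-hemisphere
#' variants.
#'
#' @param name Display name for the measure.
#' @param regions Character vector, subset of
#'   `c("hippocampus", "amygdala", "entorhinal", "parahippocampal")`.
#' @param hemispheres Character vector, subset of `c("left", "right")`.
#' @return An object of class `measure_spec`.
#' @examples
#' measure_spec("left hippocampus", "hippocampus", "left")
#' @export
measure_spec <- function(name, regions, hemispheres = HEMISPHERES) {
  regions <- unique(normalize_region(regions))
  hemispheres <- unique(normalize_hemisphere(hemispheres))
  if (length(regions) == 0L || anyNA(regions))
    stop("regions must be a non-empty subset of: ",
         paste(MTL_REGIONS, collapse = ", "), call. = FALSE)
  if (length(hemispheres) == 0L || anyNA(hemispheres))
    stop("hemispheres must be a non-empty subset of left/right",
         call. = FALSE)
  structure(list(name = name, regions = regions, hemispheres = hemispheres),
            class = "measure_spec")
}

#' @rdname measure_spec
#' @export
mtl_measure <- function() measure_spec("MTL", MTL_REGIONS, HEMISPHERES)

#' @rdname measure_spec
#' @param region A single region name for the bilateral total.
#' @export
region_measure <- function(region)
  measure_spec(paste("total", region), region, HEMISPHERES)

#' @export
print.measure_spec <- function(x, ...) {
  cat("Measure:", x$name, "\n  regions:",
      paste(x$regions, collapse = ", "),
      "\n  hemispheres:", paste(x$hemispheres, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a measure on every subject of a cohort
#'
#' Sums each subject's selected volumes. Every subject must carry every
#' (region, hemisphere) pair the measure requests; a missing pair is an
#' error naming the subject and pair, since a silently short sum would
#' mimic atrophy.
#'
#' @param cohort A [cohort_table()].
#' @param spec A [measure_spec()].
#' @return A data frame with one row per subject: `subject_id`, `group`,
#'   `value` (mm^3), in order of first appearance.
#' @export
measure_values <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(spec, "measure_spec"))
  sel <- cohort[cohort$region %in% spec$regions &
                cohort$hemisphere %in% spec$hemispheres, , drop = FALSE]
  ids <- unique(cohort$subject_id)
  needed <- length(spec$regions) * length(spec$hemispheres)
  cnt <- table(factor(sel$subject_id, levels = ids))
  if (any(cnt < needed)) {
    short <- names(cnt)[cnt < needed][1L]
    have <- sel[sel$subject_id == short, c("region", "hemisphere")]
    want <- expand.grid(region = spec$regions, hemisphere = spec$hemispheres,
                        stringsAsFactors = FALSE)
    miss <- !paste(want$region, want$hemisphere) %in%
             paste(have$region, have$hemisphere)
    stop("subject '", short, "' is missing volume(s) required by measure '",
         spec$name, "': ",
         paste(want$region[miss], want$hemisphere[miss],
               sep = "/", collapse = ", "), call. = FALSE)
  }
  sums <- tapply(sel$volume_mm3, factor(sel$subject_id, levels = ids), sum)
  grp <- cohort$group[match(ids, cohort$subject_id)]
  data.frame(subject_id = ids, group = grp, value = as.numeric(sums),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate a measure on a single subject
#'
#' @param cohort A [cohort_table()] (may hold several subjects).
#' @param subject_id The subject to evaluate.
#' @param spec A [measure_spec()].
#' @return The summed volume in mm^3.
#' @export
measure_value <- function(cohort, subject_id, spec) {
  one <- cohort[cohort$subject_id == subject_id, , drop = FALSE]
  if (nrow(one) == 0L)
    stop("no such subject: ", subject_id, call. = FALSE)
  class(one) <- class(cohort)
  measure_values(one, spec)$value
}
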