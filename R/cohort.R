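#' @keywords internal
"_PACKAGE"

# Canonical vocabularies. All cohort data are keyed on these after
# case-insensitive normalization.
MTL_REGIONS <- c("hippocampus", "amygdala", "entorhinal", "parahippocampal")
HEMISPHERES <- c("left", "right")
GROUPS <- c("AD", "NC")

#' Construct a cohort table of labeled regional brain volumes
#'
#' A cohort table is the package's tidy container for per-subject,
#' per-region, per-hemisphere volumes: a data frame with columns
#' `subject_id`, `group` (`"AD"` or `"NC"`), `region` (one of
#' `r paste0('\x60', MTL_REGIONS, '\x60', collapse = ", ")`),
#' `hemisphere` (`"left"`/`"right"`) and `volume_mm3` (strictly positive,
#' in cubic millimetres). Region and hemisphere strings are normalized
#' case-insensitively; `"para-hippocampal"`/`"parahippocampal gyrus"`
#' style variants map to `"parahippocampal"`.
#'
#' @param x A data frame with the five columns above (extra columns are
#'   dropped).
#' @param provenance Free-text label recording where the cohort came from
#'   (e.g. `"ADNI-AD"`, `"MIRIAD-test"`, `"synthetic"`).
#' @param drop_unknown_regions If `TRUE` (default) rows whose region is not
#'   one of the four medial-temporal-lobe subregions are dropped with a
#'   warning; this is the behaviour wanted when ingesting full FreeSurfer
#'   exports, which list dozens of structures outside the MTL.
#' @return An object of class `cohort_table` (a data frame).
#' @examples
#' df <- data.frame(subject_id = "s1", group = "AD",
#'                  region = "Hippocampus", hemisphere = "LEFT",
#'                  volume_mm3 = 2900)
#' cohort_table(df)
#' @export
cohort_table <- function(x, provenance = "unspecified",
                         drop_unknown_regions = TRUE) {
  required <- c("subject_id", "group", "region", "hemisphere", "volume_mm3")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L)
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- as.data.frame(x)[required]

  x$subject_id <- as.character(x$subject_id)
  if (any(!nzchar(x$subject_id) | is.na(x$subject_id)))
    stop("subject_id must be non-empty for every row", call. = FALSE)

  x$group <- normalize_group(x$group)
  x$region <- normalize_region(x$region)
  x$hemisphere <- normalize_hemisphere(x$hemisphere)

  unknown <- is.na(x$region)
  if (any(unknown)) {
    if (!drop_unknown_regions)
      stop("unknown region value(s) in rows: ",
           paste(utils::head(which(unknown), 5L), collapse = ", "),
           call. = FALSE)
    warning(sum(unknown), " row(s) with regions outside the medial ",
            "temporal lobe were skipped", call. = FALSE)
    x <- x[!unknown, , drop = FALSE]
  }
  if (any(is.na(x$hemisphere)))
    stop("hemisphere must be 'left' or 'right' (rows: ",
         paste(utils::head(which(is.na(x$hemisphere)), 5L), collapse = ", "),
         ")", call. = FALSE)

  vol <- suppressWarnings(as.numeric(x$volume_mm3))
  bad <- !is.finite(vol) | vol <= 0
  if (any(bad))
    stop("volume_mm3 must be a strictly positive number; offending row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  x$volume_mm3 <- vol

  key <- paste(x$subject_id, x$region, x$hemisphere, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, region, hemisphere) entries, e.g. row ",
         which(duplicated(key))[1L], call. = FALSE)

  rownames(x) <- NULL
  attr(x, "provenance") <- provenance
  class(x) <- c("cohort_table", "data.frame")
  x
}

normalize_group <- function(g) {
  g <- toupper(trimws(as.character(g)))
  out <- ifelse(g %in% GROUPS, g, "UNKNOWN")
  bad <- !(g %in% c(GROUPS, "UNKNOWN", "NA", ""))
  if (any(bad))
    stop("unrecognized group label(s): ",
         paste(unique(g[bad]), collapse = ", "),
         " (expected AD or NC)", call. = FALSE)
  out
}

normalize_region <- function(r) {
  r <- tolower(trimws(as.character(r)))
  r <- gsub("[-_ ]", "", r)
  r[r %in% c("parahippocampal", "parahippocampus", "parahippocampalgyrus")] <-
    "parahippocampal"
  r[r %in% c("entorhinal", "entorhinalcortex")] <- "entorhinal"
  ifelse(r %in% MTL_REGIONS, r, NA_character_)
}

normalize_hemisphere <- function(h) {
  h <- tolower(trimws(as.character(h)))
  h[h %in% c("l", "lh", "left")] <- "left"
  h[h %in% c("r", "rh", "right")] <- "right"
  ifelse(h %in% HEMISPHERES, h, NA_character_)
}

#' Read a cohort table from a tidy CSV file
#'
#' Expects the header `subject_id,group,region,hemisphere,volume_mm3`
#' (column names may be remapped through `schema`). Validation is as in
#' [cohort_table()]: positive volumes, unique (subject, region,
#' hemisphere) keys, case-insensitive region/hemisphere normalization,
#' rows with regions outside the MTL skipped with a warning.
#'
#' @param path Path to the CSV file.
#' @param schema Named character vector mapping the canonical column names
#'   to the names used in the file, e.g. `c(volume_mm3 = "Volume")`.
#' @param provenance Provenance label; defaults to the file name.
#' @return A [cohort_table()].
#' @export
load_cohort_csv <- function(path, schema = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        stop("schema maps '", canon, "' to missing column '",
             schema[[canon]], "'", call. = FALSE)
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  cohort_table(df, provenance = provenance)
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort_csv()]; volumes are written with full double
#' precision so a load/write/load round trip is lossless.
#'
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  df$volume_mm3 <- sprintf("%.17g", df$volume_mm3)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  ns <- length(unique(x$subject_id))
  tab <- table(unique(x[c("subject_id", "group")])$group)
  cat("Cohort table:", ns, "subject(s),", nrow(x), "volume rows",
      sprintf("[%s]\n", attr(x, "provenance") %||% "unspecified"))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset a cohort by diagnostic group
#'
#' @param cohort A [cohort_table()].
#' @param group `"AD"`, `"NC"` or `"UNKNOWN"`.
#' @return A [cohort_table()] containing only that group's records.
#' @export
cohort_group <- function(cohort, group) {
  stopifnot(inherits(cohort, "cohort_table"))
  group <- match.arg(group, c(GROUPS, "UNKNOWN"))
  out <- cohort[cohort$group == group, , drop = FALSE]
  attr(out, "provenance") <-
    paste0(attr(cohort, "provenance") %||% "", "/", group)
  class(out) <- class(cohort)
  out
}

#' Number of distinct subjects in a cohort table
#' @param cohort A [cohort_table()].
#' @return Integer count.
#' @export
n_subjects <- function(cohort) length(unique(cohort$subject_id))

# ---- FreeSurfer stats readers -------------------------------------------

parse_fs_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(header) != 1L)
    stop("no '# ColHeaders' line in ", path, call. = FALSE)
  cols <- strsplit(sub("^# ColHeaders\\s+", "", header), "\\s+")[[1L]]
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- strsplit(trimws(data_lines), "\\s+")
  nfield <- lengths(rows)
  if (any(nfield != length(cols))) {
    bad <- which(nfield != length(cols))[1L]
    stop("malformed row in ", path, " (data line ", bad, "): expected ",
         length(cols), " fields, found ", nfield[bad], call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

fs_lookup <- function(tab, struct_col, value_col, wanted, path) {
  if (!all(c(struct_col, value_col) %in% names(tab)))
    stop("columns ", struct_col, "/", value_col, " not found in ", path,
         call. = FALSE)
  idx <- match(wanted, tab[[struct_col]])
  if (anyNA(idx))
    stop("structure(s) missing from ", path, ": ",
         paste(wanted[is.na(idx)], collapse = ", "), call. = FALSE)
  vals <- as.numeric(tab[[value_col]][idx])
  names(vals) <- wanted
  vals
}

#' Read one subject's MTL volumes from FreeSurfer stats files
#'
#' Extracts the medial-temporal-lobe volumes FreeSurfer reports: the
#' hippocampus and amygdala from `aseg.stats` (`Volume_mm3` column,
#' structures `Left-/Right-Hippocampus`, `Left-/Right-Amygdala`) and the
#' entorhinal and parahippocampal cortical gray-matter volumes from the
#' per-hemisphere `?h.aparc.stats` files (`GrayVol` column,
#' Desikan-Killiany names `entorhinal` / `parahippocampal`).
#'
#' @param aseg_path Path to `aseg.stats`.
#' @param aparc_left_path,aparc_right_path Paths to `lh.aparc.stats` and
#'   `rh.aparc.stats`.
#' @param subject_id Subject identifier for the returned record.
#' @param group `"AD"`, `"NC"` or `"UNKNOWN"`.
#' @return A one-subject [cohort_table()] with eight volume rows.
#' @export
load_freesurfer_stats <- function(aseg_path, aparc_left_path,
                                  aparc_right_path, subject_id,
                                  group = "UNKNOWN") {
  aseg <- parse_fs_stats(aseg_path)
  sub_vols <- fs_lookup(
    aseg, "StructName", "Volume_mm3",
    c("Left-Hippocampus", "Right-Hippocampus",
      "Left-Amygdala", "Right-Amygdala"), aseg_path)
  ctx_l <- fs_lookup(parse_fs_stats(aparc_left_path), "StructName", "GrayVol",
                     c("entorhinal", "parahippocampal"), aparc_left_path)
  ctx_r <- fs_lookup(parse_fs_stats(aparc_right_path), "StructName", "GrayVol",
                     c("entorhinal", "parahippocampal"), aparc_right_path)
  df <- data.frame(
    subject_id = subject_id,
    group = group,
    region = c("hippocampus", "hippocampus", "amygdala", "amygdala",
               "entorhinal", "parahippocampal",
               "entorhinal", "parahippocampal"),
    hemisphere = c("left", "right", "left", "right",
                   "left", "left", "right", "right"),
    volume_mm3 = c(sub_vols[["Left-Hippocampus"]],
                   sub_vols[["Right-Hippocampus"]],
                   sub_vols[["Left-Amygdala"]],
                   sub_vols[["Right-Amygdala"]],
                   ctx_l[["entorhinal"]], ctx_l[["parahippocampal"]],
                   ctx_r[["entorhinal"]], ctx_r[["parahippocampal"]]),
    stringsAsFactors = FALSE
  )
  cohort_table(df, provenance = paste0("freesurfer:", subject_id))
}
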