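# Fixture builders: tidy cohort frames and synthetic FreeSurfer stats
# files, generated in code at test time.

toy_volume_df <- function(subject_id, group, volumes) {
  # volumes: named numeric, names "region.hemisphere"
  parts <- strsplit(names(volumes), ".", fixed = TRUE)
  data.frame(subject_id = subject_id, group = group,
             region = vapply(parts, `[[`, "", 1L),
             hemisphere = vapply(parts, `[[`, "", 2L),
             volume_mm3 = unname(volumes), stringsAsFactors = FALSE)
}

full_subject_df <- function(subject_id, group, value = 1.0) {
  grid <- expand.grid(region = lrobserver:::MTL_REGIONS,
                      hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)
  data.frame(subject_id = subject_id, group = group,
             region = grid$region, hemisphere = grid$hemisphere,
             volume_mm3 = rep_len(value, nrow(grid)),
             stringsAsFactors = FALSE)
}

# A cohort where every subject's measure value is specified directly:
# the full value is placed on the left hippocampus and a negligible
# epsilon elsewhere is avoided by using a hippocampus/left-only measure.
scores_cohort <- function(ad_values, nc_values) {
  rows <- list()
  add <- function(vals, grp) lapply(seq_along(vals), function(i)
    toy_volume_df(sprintf("%s%03d", grp, i), grp,
                  c(hippocampus.left = vals[i])))
  df <- do.call(rbind, c(add(ad_values, "AD"), add(nc_values, "NC")))
  cohort_table(df, provenance = "toy")
}

left_hippo_measure <- function()
  measure_spec("left hippocampus", "hippocampus", "left")

# FreeSurfer stats fixtures ------------------------------------------------

write_aseg_fixture <- function(path, volumes, drop = NULL) {
  # volumes: named c("Left-Hippocampus" = ..., ...)
  structs <- data.frame(
    StructName = c("Left-Thalamus", "Left-Hippocampus", "Left-Amygdala",
                   "Right-Hippocampus", "Right-Amygdala", "Brain-Stem"),
    SegId = c(10L, 17L, 18L, 53L, 54L, 16L),
    Volume_mm3 = c(7341.2, NA, NA, NA, NA, 21000.5),
    stringsAsFactors = FALSE)
  structs$Volume_mm3[match(names(volumes), structs$StructName)] <- volumes
  if (!is.null(drop)) structs <- structs[structs$StructName != drop, ]
  lines <- c(
    "# Title Segmentation Statistics",
    "# generating_program mri_segstats",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean",
    sprintf("%3d %3d %6d %10.1f %-20s %8.4f",
            seq_len(nrow(structs)), structs$SegId, 1234L,
            structs$Volume_mm3, structs$StructName, 85.1))
  writeLines(lines, path)
  path
}

write_aparc_fixture <- function(path, entorhinal, parahippocampal,
                                drop = NULL) {
  structs <- data.frame(
    StructName = c("cuneus", "entorhinal", "fusiform", "parahippocampal"),
    GrayVol = c(2981, entorhinal, 9544, parahippocampal),
    stringsAsFactors = FALSE)
  if (!is.null(drop)) structs <- structs[structs$StructName != drop, ]
  lines <- c(
    "# Table of FreeSurfer cortical parcellation anatomical statistics",
    "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg",
    sprintf("%-18s %6d %6d %8.1f %6.3f",
            structs$StructName, 1000L, 700L, structs$GrayVol, 2.5))
  writeLines(lines, path)
  path
}
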