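#' Flatten snapshots to a tidy data frame
#'
#' One row per patient with the diameter, densities, ratios, PD-L1
#' expression, clone count and time to the preset size — the CSV-friendly
#' form of a snapshot list.
#'
#' @param snapshots List of `vp_snapshot` objects.
#' @return Data frame.
#' @export
snapshots_to_df <- function(snapshots) {
  data.frame(
    patient_id = vapply(snapshots, function(s) as.integer(s$patient_id), integer(1)),
    tumor_diameter = vapply(snapshots, `[[`, numeric(1), "tumor_diameter"),
    t(vapply(snapshots, `[[`, numeric(5), "densities")),
    t(vapply(snapshots, `[[`, numeric(3), "ratios")),
    pdl1_expression = vapply(snapshots, `[[`, numeric(1), "pdl1_expression"),
    tcc = vapply(snapshots, `[[`, numeric(1), "tcc"),
    time_to_preset = vapply(snapshots, `[[`, numeric(1), "time_to_preset")
  )
}

#' Serialize one snapshot (parameters and full state) to JSON
#'
#' @param snapshot A `vp_snapshot`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_snapshot_json <- function(snapshot, path) {
  jsonlite::write_json(
    list(
      patient_id = snapshot$patient_id,
      parameters = unclass(snapshot$parameters),
      state = as.list(snapshot$state),
      tumor_diameter = snapshot$tumor_diameter,
      densities = as.list(snapshot$densities),
      ratios = as.list(snapshot$ratios),
      pdl1_expression = snapshot$pdl1_expression,
      tcc = snapshot$tcc,
      time_to_preset = snapshot$time_to_preset
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
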