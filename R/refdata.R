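# ---------------------------------------------------------------------------
# Published proteinase K reference averages shipped with the package
# ---------------------------------------------------------------------------

#' Published proteinase K reference averages
#'
#' Joined-trajectory averages reported for serine protease proteinase K
#' simulated with the protein (P) and the solvent (S) thermostatted
#' separately at 180 or 300 K: structural properties (backbone RMSD,
#' total SASA, native contacts, radius of gyration, secondary-structure
#' residue counts), total mean square fluctuations from essential
#' dynamics, and static/dynamic hydrogen-bond statistics with class
#' breakdowns. These printed values are the inputs to the percent/fold
#' delta arithmetic and the persistency identity checks in the examples
#' and the acceptance script; the package does not attempt to regenerate
#' them (that would require hundreds of nanoseconds of all-atom MD).
#'
#' @return A list of three data frames: `properties`, `tmsf` (nm^2) and
#'   `hbonds`.
#' @examples
#' ref <- reference_tables()
#' ref$tmsf
#' @export
reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "solvdyn",
                                  mustWork = TRUE)
  list(
    properties = read.csv(path("reference_structural_properties.csv"),
                          stringsAsFactors = FALSE),
    tmsf = read.csv(path("reference_tmsf.csv"), stringsAsFactors = FALSE),
    hbonds = read.csv(path("reference_hbonds.csv"),
                      stringsAsFactors = FALSE)
  )
}

#' Reference structural properties as property-table rows
#'
#' Convenience wrapper turning each row of
#' `reference_tables()$properties` into an `sd_property_table` suitable
#' for [compare_tables()].
#'
#' @return Named list of `sd_property_table` rows, keyed by condition
#'   label.
#' @examples
#' tabs <- reference_property_tables()
#' compare_tables(tabs[["P300/S180"]], tabs[["P300/S300"]])
#' @export
reference_property_tables <- function() {
  df <- reference_tables()$properties
  out <- lapply(seq_len(nrow(df)), function(i) {
    property_table_from_values(
      df$label[i],
      rmsd = df$rmsd[i], rmsd_sd = df$rmsd_sd[i],
      sasa = df$sasa[i], sasa_sd = df$sasa_sd[i],
      nnc = df$nnc[i], nnc_sd = df$nnc_sd[i],
      rg = df$rg[i], rg_sd = df$rg_sd[i],
      sse_helix = df$sse_helix[i], sse_helix_sd = df$sse_helix_sd[i],
      sse_sheet = df$sse_sheet[i], sse_sheet_sd = df$sse_sheet_sd[i],
      sse_turn = df$sse_turn[i], sse_turn_sd = df$sse_turn_sd[i])
  })
  names(out) <- df$label
  out
}
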