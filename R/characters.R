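#' Character registry for Anisopteromalus females
#'
#' Returns the registry of the 20 linear measurements used in the
#' morphometric analysis of *Anisopteromalus* females: short abbreviation,
#' character name, measurement definition, and the stereomicroscope
#' magnification at which the character is measured. All measurements are
#' lengths in micrometres, taken on the left-hand side where the character
#' is paired.
#'
#' @return A data frame with columns `abbreviation`, `name`, `definition`
#'   and `magnification` (a positive number, the nominal magnification in x).
#' @examples
#' reg <- character_registry()
#' nrow(reg)      # 20
#' reg$abbreviation
#' @export
character_registry <- function() {
  reg <- data.frame(
    abbreviation = c(
      "eye.b", "eye.d", "eye.h", "gst.b", "gst.l", "hea.b", "hea.h",
      "msc.b", "msc.l", "msp.l", "mss.l", "mv.l", "ool.l", "pdl.flg",
      "pol.l", "ppd.l", "scp.l", "sct.l", "stv.l", "tb3.l"),
    name = c(
      "Eye breadth", "Eye distance", "Eye height", "Gaster breadth",
      "Gaster length", "Head breadth", "Head height", "Mesoscutum breadth",
      "Mesoscutum length", "Malar space", "Mesosoma length", "Marginal vein",
      "OOL", "Pedicel + flagellum", "POL", "Propodeum length",
      "Scape length", "Scutellum length", "Stigmal vein", "Metatibia"),
    definition = c(
      "Greatest breadth of eye, lateral view",
      "Shortest distance between eyes, dorsal view",
      "Greatest length of eye height, lateral view",
      "Greatest breadth of gaster, distance between the outermost lateral edges of the gaster, dorsal view",
      "Length of gaster along median line from posterior edge of nucha to tip of ovipositor sheath, dorsal view",
      "Greatest breadth of head, dorsal view",
      "Distance between lower edge of clypeus and lower edge of anterior ocellus, frontal view",
      "Greatest breadth of mesoscutum just in front of level of tegula, dorsal view",
      "Length of mesoscutum along median line from posterior edge of pronotum to posterior edge of mesoscutum, dorsal view",
      "Distance between the point where malar sulcus enters mouth margin and malar sulcus enters lower edge of eye, lateral view",
      "Length of mesosoma along median line from anterior edge of pronotum collar to posterior edge of nucha, dorsal view",
      "Length of marginal vein, distance between the point at which the submarginal vein touches the leading edge of the wing and the point at which stigmal vein and postmarginal vein unite",
      "Shortest distance between posterior ocellus and eye margin, dorsal view",
      "Combined length of pedicel plus flagellum, outer aspect",
      "Shortest distance between posterior ocelli, dorsal view",
      "Length of propodeum measured along median line from anterior edge to posterior edge of nucha, dorsal view",
      "Length of scape exclusive of radicle, outer aspect",
      "Length of scutellum along median line from posterior edge of mesoscutum to posterior edge of scutellum, dorsal view",
      "Length of stigmal vein, distance between the point at which stigmal vein and postmarginal vein unite apically, and the distal end of the stigma",
      "Length of metatibia, measured along midline, outer aspect"),
    magnification = c(
      150, 150, 150, 100, 70, 100, 100, 100, 150, 150,
      70, 150, 150, 100, 150, 150, 150, 150, 150, 100),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(reg$abbreviation), all(reg$magnification > 0))
  reg
}
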