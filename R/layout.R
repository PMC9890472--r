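#' 64-channel EEG sensor layout
#'
#' Returns the packaged 64-channel montage: an idealized spherical 10-10
#' template (85 mm head radius) with the standard extended 10-20 labels used
#' by 64-channel active-electrode caps. TP9/TP10 double as the mastoid
#' channels for linked-mastoid referencing. The positions are synthetic --
#' constructed geometrically on the sphere, not digitized from a real cap --
#' and are shipped as a plain TSV (`extdata/layout_1010_synthetic_64.tsv`,
#' columns `channel`, `x`, `y`, `z` in meters; x right, y anterior, z up).
#'
#' @param file Optional path to an alternative layout TSV.
#' @return A tibble with columns `channel`, `x`, `y`, `z` and attributes
#'   `mastoids` (channel names) and `radius` (meters).
#' @export
#' @examples
#' lay <- channel_layout()
#' nrow(lay) # 64
channel_layout <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "layout_1010_synthetic_64.tsv",
      package = "popout"
    )
  }
  if (!nzchar(file) || !file.exists(file)) {
    lay <- spherical_layout_table()
  } else {
    lay <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(all(c("channel", "x", "y", "z") %in% names(lay)))
  lay <- tibble::as_tibble(lay)
  attr(lay, "mastoids") <- intersect(c("TP9", "TP10"), lay$channel)
  attr(lay, "radius") <- 0.085
  lay
}

# Geometric construction of the synthetic spherical 10-10 template.
# Inclination is measured from the vertex (Cz); azimuth from the anterior
# midline, positive toward the right ear. The "10% ring" (Fp/T/O line) sits
# at 72 deg inclination; the FT9/TP9/PO9-type sites sit at 90 deg.
spherical_layout_table <- function(radius = 0.085) {
  pt <- function(incl, az) {
    ti <- incl * pi / 180
    ta <- az * pi / 180
    c(
      x = radius * sin(ti) * sin(ta),
      y = radius * sin(ti) * cos(ta),
      z = radius * cos(ti)
    )
  }
  slerp <- function(p, q, f) {
    om <- acos(max(-1, min(1, sum(p * q) / radius^2)))
    (sin((1 - f) * om) * p + sin(f * om) * q) / sin(om)
  }
  ring <- function(az) pt(72, az)
  pos <- list()
  add <- function(name, p) pos[[name]] <<- p

  # ring electrodes
  ring_az <- c(
    Fp1 = -18, Fp2 = 18, AF7 = -36, AF8 = 36, F7 = -54, F8 = 54,
    FT7 = -72, FT8 = 72, T7 = -90, T8 = 90, TP7 = -108, TP8 = 108,
    P7 = -126, P8 = 126, PO7 = -144, PO8 = 144, O1 = -162, O2 = 162,
    Oz = 180
  )
  for (nm in names(ring_az)) add(nm, ring(ring_az[[nm]]))

  # midline
  add("Fz", pt(36, 0))
  add("Cz", pt(0, 0))
  add("CPz", pt(18, 180))
  add("Pz", pt(36, 180))
  add("POz", pt(54, 180))
  # virtual midline anchors for row interpolation (not montage channels)
  fcz <- pt(18, 0)
  afz <- pt(54, 0)

  # interior rows: slerp between the ring electrode and the midline anchor
  interior <- function(left_end, mid, lnames, fracs) {
    for (i in seq_along(fracs)) {
      p <- slerp(pos[[left_end]], mid, fracs[i])
      add(lnames[i], p)
      rname <- sub("7$", "8", sub("5$", "6", sub("3$", "4", sub("1$", "2", lnames[i]))))
      add(rname, c(-p[["x"]], p[["y"]], p[["z"]]))
    }
  }
  interior("F7", pos[["Fz"]], c("F5", "F3", "F1"), c(0.25, 0.5, 0.75))
  interior("FT7", fcz, c("FC5", "FC3", "FC1"), c(0.25, 0.5, 0.75))
  interior("T7", pos[["Cz"]], c("C5", "C3", "C1"), c(0.25, 0.5, 0.75))
  interior("TP7", pos[["CPz"]], c("CP5", "CP3", "CP1"), c(0.25, 0.5, 0.75))
  interior("P7", pos[["Pz"]], c("P5", "P3", "P1"), c(0.25, 0.5, 0.75))
  interior("PO7", pos[["POz"]], "PO3", 0.5)
  interior("AF7", afz, "AF3", 0.5)

  # inferior row (below the ring)
  add("FT9", pt(90, -72))
  add("FT10", pt(90, 72))
  add("TP9", pt(90, -108))
  add("TP10", pt(90, 108))
  add("PO9", pt(90, -144))
  add("PO10", pt(90, 144))

  order64 <- c(
    "Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
    "O1", "Oz", "O2"
  )
  m <- t(vapply(order64, function(nm) pos[[nm]], numeric(3)))
  tibble::tibble(
    channel = order64,
    x = round(unname(m[, 1]), 6),
    y = round(unname(m[, 2]), 6),
    z = round(unname(m[, 3]), 6)
  )
}

# pairwise Euclidean distance matrix for a layout tibble
layout_distances <- function(layout) {
  m <- as.matrix(layout[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(layout$channel, layout$channel)
  d
}
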