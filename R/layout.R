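# 64-channel 10-10 scalp layout --------------------------------------------

# Great-circle interpolation between two unit vectors.
slerp <- function(p, q, frac) {
  p <- p / sqrt(sum(p^2)); q <- q / sqrt(sum(q^2))
  omega <- acos(max(-1, min(1, sum(p * q))))
  if (omega < 1e-12) return(matrix(rep(p, length(frac)), ncol = 3, byrow = TRUE))
  t(vapply(frac, function(f)
    (sin((1 - f) * omega) * p + sin(f * omega) * q) / sin(omega),
    numeric(3)))
}

sph_point <- function(incl_deg, azim_deg) {
  # inclination from vertex; azimuth measured from anterior midline,
  # positive clockwise seen from above (toward the right ear).
  th <- incl_deg * pi / 180; az <- azim_deg * pi / 180
  c(sin(th) * sin(az), sin(th) * cos(az), cos(th))  # x right, y anterior, z up
}

#' Standard 64-channel 10-10 electrode layout
#'
#' Constructs the 64 BioSemi/10-10 electrode positions geometrically on a
#' sphere: the midline and the outer 10% ring carry the canonical angles
#' (18 degree steps), and intermediate rows are placed by great-circle
#' interpolation between the midline electrode and the outer-ring electrode
#' of the same row. Positions are in millimetres on a head of the given
#' radius, with x to the right ear, y to the nasion and z to the vertex.
#'
#' @param radius_mm scalp sphere radius in mm.
#' @return data.frame with columns `label`, `x`, `y`, `z` (mm), 64 rows.
#' @export
layout_1010_64 <- function(radius_mm = 87.5) {
  pos <- list()
  add <- function(label, p) pos[[label]] <<- p

  # outer ring: inclination 72 deg, azimuth every 18 deg
  ring <- c("Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2",
            "Oz", "O1", "PO7", "P7", "TP7", "T7", "FT7", "F7", "AF7", "Fp1")
  for (i in seq_along(ring)) add(ring[i], sph_point(72, (i - 1) * 18))
  add("Iz",  sph_point(90, 180))
  add("P9",  sph_point(90, 360 - 126))   # below P7
  add("P10", sph_point(90, 126))         # below P8

  # midline (anterior positive azimuth 0, posterior 180)
  mid <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0)
  for (nm in names(mid)) add(nm, sph_point(mid[[nm]], 0))
  midp <- c(CPz = 18, Pz = 36, POz = 54)
  for (nm in names(midp)) add(nm, sph_point(midp[[nm]], 180))

  # rows interpolated between midline and outer-ring anchors
  rows <- list(
    list("AFz", "AF7", c(AF3 = 0.5)),
    list("AFz", "AF8", c(AF4 = 0.5)),
    list("Fz",  "F7",  c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    list("Fz",  "F8",  c(F2 = 0.25, F4 = 0.5, F6 = 0.75)),
    list("FCz", "FT7", c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    list("FCz", "FT8", c(FC2 = 0.25, FC4 = 0.5, FC6 = 0.75)),
    list("Cz",  "T7",  c(C1 = 0.25, C3 = 0.5, C5 = 0.75)),
    list("Cz",  "T8",  c(C2 = 0.25, C4 = 0.5, C6 = 0.75)),
    list("CPz", "TP7", c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    list("CPz", "TP8", c(CP2 = 0.25, CP4 = 0.5, CP6 = 0.75)),
    list("Pz",  "P7",  c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    list("Pz",  "P8",  c(P2 = 0.25, P4 = 0.5, P6 = 0.75)),
    list("POz", "PO7", c(PO3 = 0.5)),
    list("POz", "PO8", c(PO4 = 0.5))
  )
  for (r in rows) {
    pts <- slerp(pos[[r[[1]]]], pos[[r[[2]]]], r[[3]])
    for (i in seq_along(r[[3]])) add(names(r[[3]])[i], pts[i, ])
  }

  m <- do.call(rbind, pos)
  out <- data.frame(label = names(pos),
                    x = m[, 1] * radius_mm,
                    y = m[, 2] * radius_mm,
                    z = m[, 3] * radius_mm,
                    stringsAsFactors = FALSE, row.names = NULL)
  stopifnot(nrow(out) == 64L, !anyDuplicated(out$label))
  out
}

#' Pairwise electrode distances
#' @param layout data.frame as from [layout_1010_64()].
#' @return labelled distance matrix in mm.
#' @export
layout_distances <- function(layout) {
  d <- as.matrix(stats::dist(layout[, c("x", "y", "z")]))
  dimnames(d) <- list(layout$label, layout$label)
  d
}

#' Gaussian scalp topography centred on one or more electrodes
#'
#' Builds a smooth channel weighting that peaks at the named electrodes and
#' decays with scalp distance; used by the simulator to project kernel
#' contributions onto the sensor array.
#'
#' @param layout layout data.frame.
#' @param centers character vector of electrode labels.
#' @param fwhm_mm spatial full width at half maximum of each bump.
#' @param signs optional sign (+1/-1) per centre, recycled.
#' @return numeric vector (one weight per channel), max |weight| = 1.
#' @export
gaussian_topography <- function(layout, centers, fwhm_mm = 60, signs = 1) {
  miss <- setdiff(centers, layout$label)
  if (length(miss)) stop_invalid("unknown electrode label(s): ",
                                 paste(miss, collapse = ", "))
  signs <- rep_len(signs, length(centers))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- layout_distances(layout)
  w <- numeric(nrow(layout))
  for (i in seq_along(centers))
    w <- w + signs[i] * exp(-d[, centers[i]]^2 / (2 * sigma^2))
  w / max(abs(w))
}
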