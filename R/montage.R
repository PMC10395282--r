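#' Standard 32-channel driving-EEG montage
#'
#' Channel labels of the 32-electrode actiCAP layout used throughout the
#' package, in recording order.
#'
#' @return Character vector of 32 channel labels.
#' @export
driveload_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "FC1", "FC2", "FC5",
    "FC6", "C3", "C4", "Cz", "T7", "T8", "CP1", "CP2", "CP5", "CP6",
    "P3", "P4", "P7", "P8", "Pz", "PO9", "PO10", "O1", "O2", "Oz",
    "TP9", "TP10")
}

# Idealized spherical 10-20 coordinates: inclination from the vertex and
# azimuth from the nose (negative = left), degrees. Used for spherical-spline
# channel interpolation; only relative geometry matters.
.montage_angles <- function() {
  a <- rbind(
    Fp1 = c(90, -18),  Fp2 = c(90, 18),
    F7  = c(90, -54),  F8  = c(90, 54),
    T7  = c(90, -90),  T8  = c(90, 90),
    P7  = c(90, -126), P8  = c(90, 126),
    O1  = c(90, -162), O2  = c(90, 162),
    Oz  = c(90, 180),
    TP9 = c(113, -99), TP10 = c(113, 99),
    PO9 = c(113, -153), PO10 = c(113, 153),
    F3  = c(56, -29),  F4  = c(56, 29),
    FC5 = c(69, -62),  FC6 = c(69, 62),
    FC1 = c(32, -45),  FC2 = c(32, 45),
    C3  = c(45, -90),  C4  = c(45, 90),
    CP5 = c(69, -118), CP6 = c(69, 118),
    CP1 = c(32, -135), CP2 = c(32, 135),
    P3  = c(56, -151), P4  = c(56, 151),
    Fz  = c(45, 0), Cz = c(0, 0), Pz = c(45, 180))
  colnames(a) <- c("inc", "azi")
  a
}

#' Unit-sphere electrode positions
#'
#' @param labels Channel labels; defaults to the full montage.
#' @return Numeric matrix (channels x 3) of x/y/z unit-sphere coordinates
#'   (x = right, y = anterior, z = up), rownames = labels.
#' @export
electrode_positions <- function(labels = driveload_montage()) {
  ang <- .montage_angles()
  missing <- setdiff(labels, rownames(ang))
  if (length(missing))
    stop("no position known for channel(s): ", paste(missing, collapse = ", "))
  inc <- ang[labels, "inc"] * pi / 180
  azi <- ang[labels, "azi"] * pi / 180
  cbind(x = sin(inc) * sin(azi),
        y = sin(inc) * cos(azi),
        z = cos(inc)) |>
    (\(m) { rownames(m) <- labels; m })()
}

#' Electrode clusters used by the analysis
#'
#' The frontal theta and posterior alpha clusters of the track-load index,
#' the ERP measurement clusters, and the left/right posterior pairs used for
#' lateralized measures.
#'
#' @return Named list of character vectors (and a list of pairs).
#' @export
driveload_clusters <- function() {
  list(
    frontal_theta   = c("F3", "Fz", "F4", "FC1", "FC2"),
    posterior_alpha = c("P3", "Pz", "P4", "PO9", "PO10", "O1", "Oz", "O2"),
    occipital       = c("O1", "Oz", "O2"),
    parietal        = c("CP1", "CP2", "P3", "Pz", "P4"),
    frontocentral   = c("Cz", "FC1", "FC2", "Fz"),
    posterior_pairs = list(c("P7", "P8"), c("PO9", "PO10"), c("O1", "O2")),
    alpha_pair      = c("PO9", "PO10"))
}

# channels free to carry zero-mean compensation weight without touching any
# measurement cluster or lateralized pair
.compensation_channels <- function() {
  c("Fp1", "Fp2", "F7", "F8", "FC5", "FC6", "T7", "T8",
    "C3", "C4", "CP5", "CP6", "TP9", "TP10")
}
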