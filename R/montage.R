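#' Load the packaged 19-channel 10-20 coordinate template
#'
#' A synthetic adult-head template (mm): electrodes placed on a 92.5 mm sphere
#' by the standard 10-20 arc construction (outer ring at 72 degrees
#' inclination, mid ring at 36 degrees, F3/F4/P3/P4 as spherical midpoints of
#' their neighbouring arc positions). It is a geometric stand-in for a
#' digitized template, shipped as a fixed fixture so channel-pair
#' classifications are reproducible.
#'
#' @return data.frame with columns \code{label}, \code{x}, \code{y}, \code{z}
#'   (mm; +x right, +y anterior, +z superior).
#' @export
montage_1020 <- function() {
  path <- system.file("extdata", "montage_1020_synthetic.csv",
                      package = "eegstates")
  if (path == "") path <- file.path("inst", "extdata", "montage_1020_synthetic.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Canonical 19-channel 10-20 channel order
#' @export
channel_order_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# case-insensitive alias table for modern/legacy temporal labels
channel_aliases <- function() {
  c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
}

#' Map arbitrary channel labels onto the canonical 10-20 order
#'
#' Case-insensitive, with the usual modern aliases (T7 -> T3, T8 -> T4,
#' P7 -> T5, P8 -> T6).
#'
#' @param labels character vector of labels.
#' @return integer index into \code{labels} giving the canonical order, with
#'   \code{NA} for canonical channels not present.
#' @export
match_channels <- function(labels) {
  norm <- toupper(trimws(labels))
  ali <- channel_aliases()
  names(ali) <- toupper(names(ali))
  norm <- ifelse(norm %in% names(ali), ali[norm], norm)
  match(toupper(channel_order_1020()), toupper(norm))
}

#' Classify channel pairs by scalp distance
#'
#' Unordered channel pairs are classed by Euclidean template distance:
#' short-range for [80, 130) mm, long-range for >= 130 mm; pairs closer than
#' 80 mm are excluded from connectivity averages (dominated by volume
#' conduction).
#'
#' @param montage data.frame from \code{\link{montage_1020}} (or compatible).
#' @param short_mm,long_mm class boundaries in mm.
#' @return data.frame with one row per unordered pair: \code{i}, \code{j}
#'   (indices into the montage rows), \code{label_i}, \code{label_j},
#'   \code{distance_mm}, \code{class} (excluded/short/long).
#' @export
pair_classification <- function(montage = montage_1020(),
                                short_mm = 80, long_mm = 130) {
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  nch <- nrow(xyz)
  pr <- t(utils::combn(nch, 2))
  d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                     xyz[pr[, 2], , drop = FALSE]) ^ 2))
  cls <- ifelse(d < short_mm, "excluded",
                ifelse(d < long_mm, "short", "long"))
  data.frame(i = pr[, 1], j = pr[, 2],
             label_i = montage$label[pr[, 1]],
             label_j = montage$label[pr[, 2]],
             distance_mm = d, class = cls,
             stringsAsFactors = FALSE)
}
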