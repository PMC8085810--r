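#' Regression constants linking historical measurement schemes
#'
#' Multipliers used to express older cheliceral measurement schemes in the
#' measurement scheme of this package: the three directly comparable legacy
#' columns are "1" (= DSL), "7" (= MDL) and "2" (= HDS); every other
#' dimension is estimated from them by cross-measure regressions
#' (\code{WDS = 0.8280*"2"}, \code{HBS = 1.0727*"2"}, \code{WBS =
#' 0.8935*"2"}, \code{L1 = 0.4076*"2"}, \code{L2 = 0.9214*"7"}, \code{BSL =
#' 0.7956*(DSL - MDL)}, \code{IL = 0.9981*Id}).
#'
#' @format named numeric vector.
#' @export
legacy_constants <- c(IL_per_Id = 0.9981,
                      BSL_per_DSL_minus_MDL = 0.7956,
                      WDS_per_2 = 0.8280,
                      HBS_per_2 = 1.0727,
                      WBS_per_2 = 0.8935,
                      L1_per_2 = 0.4076,
                      L2_per_7 = 0.9214)

#' Convert legacy three-column cheliceral records to full measurement rows
#'
#' The legacy scheme measured idiosomal length \code{Id} and three cheliceral
#' dimensions: "1" (distal segment length), "7" (moveable digit length) and
#' "2" (distal segment height). All remaining dimensions are filled in with
#' the published regression constants (see [legacy_constants]), after which
#' [derive_mechanics()] applies unchanged.
#'
#' @param rows data.frame with columns \code{Id}, \code{m1}, \code{m7},
#'   \code{m2} (and optionally \code{species}).
#' @return data.frame of full specimen measurement rows (one specimen per
#'   input row, \code{n = 1} each).
#' @examples
#' from_buryn_brandl(data.frame(Id = 482, m1 = 97, m7 = 38, m2 = 64))
#' @export
from_buryn_brandl <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("Id", "m1", "m7", "m2") %in% names(rows)))
  with(rows, {
    if (any(is.na(Id) | Id <= 0 | is.na(m1) | m1 <= 0 |
            is.na(m7) | m7 <= 0 | is.na(m2) | m2 <= 0))
      stop("all of Id, m1, m7, m2 must be positive")
  })
  if (any(rows$m1 <= rows$m7))
    stop("non-positive basal segment: m1 <= m7 in row(s) ",
         paste(which(rows$m1 <= rows$m7), collapse = ", "))
  k <- legacy_constants
  out <- data.frame(
    species_id = if ("species" %in% names(rows)) rows$species else
      paste0("legacy_", seq_len(nrow(rows))),
    IL = k[["IL_per_Id"]] * rows$Id,
    DSL = rows$m1,
    BSL = k[["BSL_per_DSL_minus_MDL"]] * (rows$m1 - rows$m7),
    MDL = rows$m7,
    HDS = rows$m2,
    WDS = k[["WDS_per_2"]] * rows$m2,
    HBS = k[["HBS_per_2"]] * rows$m2,
    WBS = k[["WBS_per_2"]] * rows$m2,
    L1 = k[["L1_per_2"]] * rows$m2,
    L2 = k[["L2_per_7"]] * rows$m7,
    widths_equal_heights = FALSE,
    stringsAsFactors = FALSE)
  out
}

#' Convert phytoseiid digit-perimeter records to gape and velocity ratio
#'
#' For records measured as dorsal perimeter of the fixed digit (DPFD),
#' ventral perimeter of the moveable digit (VPMD) and moveable digit height:
#' the best estimate of gape is \code{L2 = VPMD}, the velocity ratio is
#' \code{HeightMD / VPMD} (assuming the condyle is offset proportionately),
#' and \code{DPFD / VPMD} passes through as a plant-feeding index. No force
#' is computable from these records (insufficient dimensions) and the result
#' is marked gape/VR-only.
#'
#' @param DPFD,VPMD,HeightMD positive lengths (um); vectorised.
#' @return data.frame with \code{L2}, \code{VR}, \code{plant_feeding_index}
#'   and \code{gape_vr_only = TRUE}. A ratio at or above 1 is outside the
#'   open unit interval: the VR is set \code{NA} with a warning.
#' @examples
#' from_adar(DPFD = 90.3, VPMD = 100, HeightMD = 47.2)
#' @export
from_adar <- function(DPFD, VPMD, HeightMD) {
  if (any(is.na(VPMD) | VPMD <= 0)) stop("VPMD must be positive")
  if (any(is.na(DPFD) | DPFD <= 0 | is.na(HeightMD) | HeightMD <= 0))
    stop("DPFD and HeightMD must be positive")
  VR <- HeightMD / VPMD
  bad <- VR >= 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with HeightMD >= VPMD give VR outside ",
            "(0,1); set to NA")
    VR[bad] <- NA_real_
  }
  data.frame(L2 = VPMD, VR = VR, plant_feeding_index = DPFD / VPMD,
             gape_vr_only = TRUE)
}

#' Convert reach/width/digit-angle records to partial measurement rows
#'
#' For records measured as cheliceral length, moveable digit length, a single
#' cheliceral width and the angle of the moveable digit: heights and widths
#' are all taken equal to the width; the input lever arm is the mean of a
#' height-regression estimate \code{L1* = 0.4076 * HDS} and a trigonometric
#' estimate \code{L1** = MDL * sin(angle)}; the output lever arm is
#' \code{L2 = MDL}. \code{CL} is carried directly (segment lengths unknown),
#' so [derive_mechanics()] can compute VR and the force indices.
#'
#' @param CL cheliceral length (um).
#' @param MDL moveable digit length (um).
#' @param cheliceral_width single cross dimension (um).
#' @param digit_angle_deg angle of the moveable digit, strictly between 0
#'   and 90 degrees.
#' @return data.frame of partial specimen rows (with \code{CL} but no
#'   \code{BSL}/\code{DSL}).
#' @examples
#' from_liu(CL = 300, MDL = 100, cheliceral_width = 100,
#'          digit_angle_deg = 30)  # L1 = (40.76 + 50)/2, VR = 0.4538
#' @export
from_liu <- function(CL, MDL, cheliceral_width, digit_angle_deg) {
  if (any(is.na(digit_angle_deg) | digit_angle_deg <= 0 |
          digit_angle_deg >= 90))
    stop("digit angle must be strictly between 0 and 90 degrees")
  if (any(CL <= 0 | MDL <= 0 | cheliceral_width <= 0))
    stop("lengths must be positive")
  w <- cheliceral_width
  L1_star <- legacy_constants[["L1_per_2"]] * w
  L1_star2 <- MDL * sin(digit_angle_deg * pi / 180)
  data.frame(CL = CL, MDL = MDL,
             HDS = w, WDS = w, HBS = w, WBS = w,
             L1 = (L1_star + L1_star2) / 2, L2 = MDL,
             widths_equal_heights = FALSE)
}

#' Predict velocity ratio from the moveable-digit length:height ratio
#'
#' For taxa where lever arms cannot be measured directly but the moveable
#' digit's length:height ratio can, VR is predicted by a through-origin
#' regression: \code{VR = slope * MD_ratio}, with the published slope
#' 0.6937. The result is rounded to three decimals for table reproduction.
#'
#' @param MD_ratio moveable digit length : height ratio, positive.
#' @param slope through-origin regression slope (default the published
#'   0.6937).
#' @param digits rounding applied to the result (default 3; use \code{Inf}
#'   for no rounding).
#' @return predicted VR; values at or above 1 are invalid and returned as
#'   \code{NA} with a warning.
#' @examples
#' predict_vr_from_md_ratio(0.349)  # 0.242
#' @export
predict_vr_from_md_ratio <- function(MD_ratio, slope = 0.6937, digits = 3) {
  if (any(is.na(MD_ratio) | MD_ratio <= 0)) stop("MD_ratio must be positive")
  if (length(slope) != 1L || is.na(slope) || slope <= 0)
    stop("slope must be a single positive number")
  vr <- slope * MD_ratio
  if (is.finite(digits)) vr <- round(vr, digits)
  bad <- vr >= 1
  if (any(bad)) {
    warning(sum(bad), " predicted VR value(s) >= 1 flagged invalid (NA)")
    vr[bad] <- NA_real_
  }
  vr
}

#' Through-origin regression of velocity ratio on moveable-digit ratio
#'
#' Least-squares slope with no intercept, \code{sum(x*y) / sum(x^2)}: the
#' reproduction of published predicted values by a single multiplier implies
#' the calibration regression had no intercept.
#'
#' @param MD_ratio,VR_measured paired observations (at least two).
#' @return the fitted slope.
#' @examples
#' fit_md_ratio_slope(c(1, 2), c(0.5, 1.6))  # (0.5 + 3.2)/(1 + 4) = 0.74
#' @export
fit_md_ratio_slope <- function(MD_ratio, VR_measured) {
  ok <- stats::complete.cases(MD_ratio, VR_measured)
  x <- MD_ratio[ok]; y <- VR_measured[ok]
  if (length(x) < 2L) stop("need at least two complete pairs")
  if (all(x == 0)) stop("all MD_ratio values are zero")
  sum(x * y) / sum(x^2)
}
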