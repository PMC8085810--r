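#' Derive chelal lever mechanics from raw cheliceral measurements
#'
#' Computes, for each specimen row, the derived mechanical quantities of the
#' chelal class-1 lever: cheliceral reach \code{CL}, velocity ratio
#' \code{VR = L1/L2}, cheliceral aspect ratio \code{AR = CL / mean(HBS,
#' HDS)}, the two adductor (levator) force estimates and their average, and
#' the chelal crunch-force index.
#'
#' With the mean cross-dimension \code{d = (HDS + WDS + HBS + WBS) / 4}, the
#' pennate-assumption force is \code{F1P = (d/2) * (CL - 1.1 * MDL)} and the
#' circular-assumption force \code{F1C = (pi/2) * d^2}; their average
#' \code{F1AV = (F1P + F1C) / 2} multiplied by the velocity ratio gives the
#' crunch-force index \code{F2AV = F1AV * VR} (maximum estimated force
#' between the digit tips, arbitrary index units — no physical unit is
#' ascribed).
#'
#' \code{CL} is \code{BSL + DSL}, plus \code{BBSL} for three-segmented
#' (uropodoid/holothyrid-style) chelicerae when \code{three_segment =
#' "include"}; a pre-computed \code{CL} column is honoured when the segment
#' lengths are absent (partial legacy records). When
#' \code{widths_equal_heights} is set for a row, \code{WDS} and \code{WBS}
#' are taken equal to \code{HDS} and \code{HBS} before \code{d} is formed.
#'
#' Rows with missing or non-positive required lengths are not dropped but
#' returned with \code{status = "rejected"} and a reason. Geometry with
#' \code{CL <= 1.1 * MDL} would give a non-positive pennate force: such rows
#' get \code{F1P} clamped at 0, \code{status = "degenerate"} and a warning
#' (never a silent negative force). A velocity ratio at or above 0.99 is
#' flagged (\code{status = "flagged"}) as numerically unusable downstream.
#'
#' @param specimens data.frame with columns \code{MDL, HDS, HBS, L1, L2} and
#'   either \code{BSL, DSL} (+ optional \code{BBSL}) or \code{CL}; optional
#'   \code{WDS, WBS}, \code{widths_equal_heights} (logical),
#'   \code{specimen_id}, \code{species_id}.
#' @param three_segment policy for the baso-basal segment of three-segmented
#'   chelicerae: \code{"include"} (default) adds \code{BBSL} to \code{CL};
#'   \code{"ignore"} drops it. The four cross-dimensions entering \code{d}
#'   are always the two-segment ones.
#' @return the input data.frame with columns \code{CL, VR, AR, F1P, F1C,
#'   F1AV, F2AV, status, reason} appended. \code{status} is one of
#'   \code{"ok"}, \code{"degenerate"}, \code{"flagged"}, \code{"rejected"};
#'   force columns are \code{NA} for rejected rows.
#' @examples
#' chela <- data.frame(BSL = 70.8, DSL = 269.7, MDL = 89, HDS = 147.3,
#'                     HBS = 201.8, widths_equal_heights = TRUE,
#'                     L1 = 44.2, L2 = 87.9)
#' derive_mechanics(chela)
#' @seealso [aggregate_species()], [relative_measures()]
#' @export
derive_mechanics <- function(specimens,
                             three_segment = c("include", "ignore")) {
  three_segment <- match.arg(three_segment)
  stopifnot(is.data.frame(specimens))
  df <- specimens
  n <- nrow(df)
  col <- function(nm, default = NA_real_) {
    if (nm %in% names(df)) df[[nm]] else rep(default, n)
  }
  MDL <- col("MDL"); HDS <- col("HDS"); HBS <- col("HBS")
  L1 <- col("L1"); L2 <- col("L2")
  WDS <- col("WDS"); WBS <- col("WBS")
  BSL <- col("BSL"); DSL <- col("DSL"); BBSL <- col("BBSL")
  CLin <- col("CL")
  weq <- col("widths_equal_heights", FALSE)
  weq[is.na(weq)] <- FALSE

  WDS <- ifelse(weq, HDS, WDS)
  WBS <- ifelse(weq, HBS, WBS)

  CL <- ifelse(!is.na(BSL) & !is.na(DSL),
               BSL + DSL +
                 if (three_segment == "include")
                   ifelse(is.na(BBSL), 0, BBSL) else 0,
               CLin)

  status <- rep("ok", n)
  reason <- rep(NA_character_, n)
  bad <- function(x) is.na(x) | x <= 0
  req <- cbind(CL = bad(CL), MDL = bad(MDL), HDS = bad(HDS), HBS = bad(HBS),
               WDS = bad(WDS), WBS = bad(WBS), L1 = bad(L1), L2 = bad(L2))
  rej <- rowSums(req) > 0
  if (any(rej)) {
    reason[rej] <- apply(req[rej, , drop = FALSE], 1, function(z)
      paste0("missing or non-positive: ",
             paste(colnames(req)[z], collapse = ", ")))
    status[rej] <- "rejected"
  }

  d <- (HDS + WDS + HBS + WBS) / 4
  VR <- L1 / L2
  AR <- CL / ((HBS + HDS) / 2)
  F1P <- (d / 2) * (CL - 1.1 * MDL)
  deg <- !rej & F1P <= 0
  if (any(deg)) {
    warning(sum(deg), " record(s) with CL <= 1.1*MDL: degenerate geometry, ",
            "F1P clamped at 0")
    F1P[deg] <- 0
    status[deg] <- "degenerate"
    reason[deg] <- "degenerate geometry (CL <= 1.1*MDL): F1P clamped at 0"
  }
  near1 <- !rej & !deg & VR >= 0.99
  if (any(near1)) {
    status[near1] <- "flagged"
    reason[near1] <- "velocity ratio at or above 0.99"
  }
  F1C <- (pi / 2) * d^2
  F1AV <- (F1P + F1C) / 2
  F2AV <- F1AV * VR

  for (nm in c("CL", "VR", "AR", "F1P", "F1C", "F1AV", "F2AV"))
    df[[nm]] <- ifelse(rej, NA_real_, get(nm))
  df$status <- status
  df$reason <- reason
  df
}

#' Aggregate per-specimen records into a species-level record
#'
#' The canonical aggregation derives the mechanical quantities per specimen
#' first and then averages them (mean-of-ratios), which is why a published
#' species mean of \code{F2AV} generally differs from the force formula
#' applied to the mean measurements. The alternative mode
#' \code{"derive_from_means"} recomputes the derived quantities from the mean
#' raw measurements, which is useful only for cross-checking printed species
#' tables.
#'
#' @param specimens data.frame of specimen measurements for a single species
#'   (see [derive_mechanics()] for columns).
#' @param feeding_code species-level trophic label: \code{"worm_like"},
#'   \code{"microarthropod"}, \code{"polyphagous"}, \code{"omnivore"} or
#'   \code{"unknown"}.
#' @param mode \code{"per_specimen"} (canonical) or \code{"derive_from_means"}.
#' @param ... passed to [derive_mechanics()].
#' @return a one-row data.frame with \code{species_id}, \code{n},
#'   \code{feeding_code}, the mean of every raw and derived column, and the
#'   four relative measures of [relative_measures()].
#' @examples
#' sp <- data.frame(species_id = "sp1", IL = c(500, 520),
#'                  BSL = c(50, 52), DSL = c(120, 124), MDL = c(40, 41),
#'                  HDS = c(30, 31), WDS = c(25, 26), HBS = c(33, 34),
#'                  WBS = c(28, 29), L1 = c(12, 13), L2 = c(37, 38))
#' aggregate_species(sp)
#' @export
aggregate_species <- function(specimens,
                              feeding_code = "unknown",
                              mode = c("per_specimen", "derive_from_means"),
                              ...) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(specimens))
  if (nrow(specimens) < 1L) stop("no specimens supplied")
  sid <- if ("species_id" %in% names(specimens))
    unique(specimens$species_id) else "unspecified"
  if (length(sid) != 1L)
    stop("specimens belong to more than one species_id: ",
         paste(sid, collapse = ", "))

  num <- names(specimens)[vapply(specimens, is.numeric, logical(1))]
  if (mode == "per_specimen") {
    dm <- derive_mechanics(specimens, ...)
    if (any(dm$status == "rejected"))
      stop("cannot aggregate: ", sum(dm$status == "rejected"),
           " rejected specimen record(s)")
    keep <- names(dm)[vapply(dm, is.numeric, logical(1))]
    means <- as.data.frame(lapply(dm[keep], mean))
  } else {
    means <- as.data.frame(lapply(specimens[num], mean))
    means <- derive_mechanics(means, ...)
    means$status <- NULL; means$reason <- NULL
  }
  out <- cbind(data.frame(species_id = sid, n = nrow(specimens),
                          feeding_code = feeding_code,
                          stringsAsFactors = FALSE),
               means)
  if (all(c("IL", "CL", "MDL", "F2AV") %in% names(out))) {
    rel <- relative_measures(out)
    out <- cbind(out, rel)
  }
  out
}

#' Relative (size-standardised) cheliceral measures
#'
#' Relative reach \code{CL/IL}, relative gape \code{MDL/IL} and the degree to
#' which gape dominates reach \code{MDL/CL}, all as percentages, plus the
#' relative crunch force \code{F2AV/IL} as a plain ratio. Values are returned
#' at full precision; the customary display rounding is one decimal for the
#' percentages and two for \code{F2AV/IL}.
#'
#' @param record data.frame (or list) with \code{IL, CL, MDL, F2AV}.
#' @return data.frame with columns \code{CL_IL}, \code{MDL_IL},
#'   \code{MDL_CL} (percent) and \code{F2AV_IL}.
#' @examples
#' relative_measures(data.frame(IL = 469.6, CL = 143.5, MDL = 37.7,
#'                              F2AV = 415.3))  # relative reach 30.6%
#' @export
relative_measures <- function(record) {
  IL <- record$IL; CL <- record$CL; MDL <- record$MDL; F2AV <- record$F2AV
  if (any(is.na(IL) | IL <= 0)) stop("IL must be positive")
  if (any(is.na(CL) | CL <= 0)) stop("CL must be positive")
  data.frame(CL_IL = 100 * CL / IL,
             MDL_IL = 100 * MDL / IL,
             MDL_CL = 100 * MDL / CL,
             F2AV_IL = F2AV / IL)
}

#' Body-size class on the 200-um idiosomal grid
#'
#' Assigns idiosomal index values to 200-um-wide classes with boundaries at
#' 250, 450, 650, 850, ... um, so that the mid-range "generalist" bin is
#' exactly [450, 650), labelled \code{"450-649"}. The grid extends in both
#' directions.
#'
#' @param IL idiosomal index (um), positive.
#' @return character vector of bin labels such as \code{"450-649"}.
#' @examples
#' size_class(c(469.6, 650, 1320.8))
#' @export
size_class <- function(IL) {
  if (any(is.na(IL) | IL <= 0)) stop("IL must be positive")
  lo <- 250 + 200 * floor((IL - 250) / 200)
  sprintf("%d-%d", as.integer(lo), as.integer(lo + 199))
}
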