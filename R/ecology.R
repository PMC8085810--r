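#' Vocabulary of the heuristic trophic profile
#'
#' Eight measure/label-pair mappings: each attribute compares one measure to
#' its data-set mean; a value at or below the mean takes the first label of
#' the pair, above the mean the second. The wording is reproduced exactly as
#' the published profile tables read (note the relative-crunch-force pair
#' maps below-mean to "Powerful grip" and above-mean to "Feeble effort" —
#' the mapping is reproduced, not re-interpreted).
#'
#' @format data.frame with columns \code{measure}, \code{low}, \code{high}.
#' @export
heuristic_vocabulary <- data.frame(
  measure = c("IL", "CL", "CL_IL", "F2AV", "F2AV_IL", "MDL", "MDL_IL",
              "MDL_CL"),
  attribute = c("size", "range", "rel_reach", "prey_toughness", "grip",
                "food_size", "chunk", "mouthful"),
  low = c("Pygmy", "Short range", "Close to", "Wiggler/Soft",
          "Powerful grip", "Small food", "Little chunks", "Tiny mouthfuls"),
  high = c("Giant", "Long range", "Away from", "Hard/Struggles",
           "Feeble effort", "Big prey", "Major grab", "Well stuffed"),
  stringsAsFactors = FALSE)

#' Heuristic verbal trophic profile of a species
#'
#' Splits each of eight measures (IL, CL, CL/IL, F2AV, F2AV/IL, MDL, MDL/IL,
#' MDL/CL) at its data-set mean into a high/low verbal label (see
#' [heuristic_vocabulary]); together the eight labels sketch a species'
#' likely predatory role in colloquial terms. Values exactly at the mean
#' take the low label.
#'
#' @param records data.frame with columns \code{IL, CL, MDL, F2AV} (the
#'   ratio columns \code{CL_IL, MDL_IL, MDL_CL, F2AV_IL} are computed if
#'   absent).
#' @param dataset_means named vector/list of the eight reference means. The
#'   default, \code{NULL}, uses the exact means of the bundled 60-species
#'   study set (see [dataset_means()]); the published rounded means are also
#'   available via \code{dataset_means("printed")} but their rounding flips
#'   one borderline label.
#' @return data.frame with the eight label columns named by attribute.
#' @examples
#' t3 <- load_fixture("T3")
#' heuristic_profile(t3[t3$species == "Alliphis halleri", ])
#' @export
heuristic_profile <- function(records, dataset_means = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("IL", "CL", "MDL", "F2AV")
  if (!all(need %in% names(records)))
    stop("missing measure(s): ",
         paste(setdiff(need, names(records)), collapse = ", "))
  if (anyNA(records[need])) stop("missing measure values")
  df <- records
  if (!all(c("CL_IL", "MDL_IL", "MDL_CL", "F2AV_IL") %in% names(df)))
    df <- cbind(df, relative_measures(df))
  if (is.null(dataset_means)) dataset_means <- dataset_means("exact")
  out <- df[intersect("species", names(df))]
  for (i in seq_len(nrow(heuristic_vocabulary))) {
    v <- heuristic_vocabulary[i, ]
    m <- dataset_means[[v$measure]]
    if (is.null(m) || is.na(m)) stop("no dataset mean for ", v$measure)
    out[[v$attribute]] <- ifelse(df[[v$measure]] <= m, v$low, v$high)
  }
  out
}

#' Reference means of the full study data set
#'
#' Means of the eight profile measures over the 60-species analysis set.
#' \code{"exact"} recomputes them at full precision from the bundled species
#' table (the values the published profile tables are consistent with);
#' \code{"printed"} returns the rounded means as printed under the
#' relative-measures table (IL 676.0, CL 285.4, MDL 87.4, F2AV 1601.4,
#' CL/IL 42.3, MDL/IL 12.7, MDL/CL 29.3, F2AV/IL 2.09).
#'
#' @param which \code{"exact"} (default) or \code{"printed"}.
#' @return named list of eight means.
#' @export
dataset_means <- function(which = c("exact", "printed")) {
  which <- match.arg(which)
  if (which == "printed") {
    tb <- load_fixture("T13_means")
    return(stats::setNames(as.list(tb$mean), tb$measure))
  }
  t3 <- load_fixture("T3")
  rel <- relative_measures(t3)
  as.list(colMeans(cbind(t3[c("IL", "CL", "MDL", "F2AV")], rel)))
}

#' Habitat over/under-representation z-test
#'
#' One-sample z-test of the proportion of species with a worm-like
#' ("crusher") cheliceral design in a habitat against a null proportion
#' (default the study-wide 6/35, used exactly rather than the rounded 17%):
#' \code{z = (k/n - p0) / sqrt(p0 (1 - p0) / n)}, two-sided normal p-value,
#' no multiple-testing correction.
#'
#' @param k number of worm-like-design species in the habitat.
#' @param n number of scored species in the habitat (>= 1).
#' @param p0 null proportion in (0, 1); default \code{6/35}.
#' @return data.frame with \code{k, n, proportion, z, p_value, direction}
#'   (\code{"Over"} if k/n > p0 else \code{"under"}).
#' @examples
#' habitat_test(3, 8)  # z ~= 1.53, two-sided p ~= 0.13, Over
#' @export
habitat_test <- function(k, n, p0 = 6 / 35) {
  if (any(is.na(n) | n < 1)) stop("n must be >= 1")
  if (any(is.na(k) | k < 0 | k > n)) stop("k must lie in [0, n]")
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must lie in (0, 1)")
  prop <- k / n
  z <- (prop - p0) / sqrt(p0 * (1 - p0) / n)
  data.frame(k = k, n = n, proportion = prop, z = z,
             p_value = 2 * stats::pnorm(-abs(z)),
             direction = ifelse(prop > p0, "Over", "under"),
             stringsAsFactors = FALSE)
}
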