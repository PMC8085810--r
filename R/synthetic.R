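#' Configuration for the synthetic morphometric generator
#'
#' Encodes the statistical structure the analysis assumes: a lognormal body
#' size distribution; power-law allometry of each cheliceral measure on body
#' size (defaults are the study's all-data fits, CL = 0.3003*IL^1.0472 and
#' MDL = 0.0338*IL^1.1866, and a cross-dimension exponent of 0.891 on IL —
#' the printed diameter exponent 0.297 against IL^3); the lever-arm
#' regressions L1 = 0.4076*HDS and L2 = 0.9214*MDL; multiplicative lognormal
#' specimen noise; and a Bernoulli feeding-habit label driven by a logit
#' model on the transformed velocity ratio with the published coefficients
#' as default effect sizes.
#'
#' The cross-dimension coefficient \code{hds_a} (default 0.16) is chosen so
#' the expected velocity ratio at the median body size matches the observed
#' study mean (~0.32); the noise scale (sdlog 0.05 per measure) keeps
#' within-species VR variation at the few-percent level, as the stability of
#' the study's species means implies.
#'
#' @param n_species,n_specimens_per_species design size.
#' @param il_meanlog,il_sdlog lognormal body-size parameters (log-um scale).
#' @param cl_a,cl_b,mdl_a,mdl_b,hds_a,hds_b power-law coefficients and
#'   exponents for reach, gape and distal-segment height against IL.
#' @param noise_sdlog multiplicative lognormal noise sd per measure
#'   (strictly positive).
#' @param beta0,beta1 intercept and slope of the label model on
#'   \code{ln(asin(sqrt(VR)))}.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_species = 60, n_specimens_per_species = 10,
                             il_meanlog = log(620), il_sdlog = 0.35,
                             cl_a = 0.3003, cl_b = 1.0472,
                             mdl_a = 0.0338, mdl_b = 1.1866,
                             hds_a = 0.16, hds_b = 0.891,
                             noise_sdlog = 0.05,
                             beta0 = 1.426, beta1 = 2.570,
                             seed = 1L) {
  if (n_species < 1 || n_specimens_per_species < 1)
    stop("need at least one species and one specimen per species")
  if (any(c(il_sdlog, cl_a, cl_b, mdl_a, mdl_b, hds_a, hds_b) <= 0))
    stop("scale and exponent parameters must be positive")
  if (is.na(noise_sdlog) || noise_sdlog <= 0)
    stop("noise sdlog must be strictly positive")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate synthetic specimens and species-level feeding labels
#'
#' Draws species body sizes from the configured lognormal; sets each
#' species' expected measures by the power laws; splits reach into segments
#' so that the legacy regression \code{BSL = 0.7956*(DSL - MDL)} holds in
#' expectation; derives expected lever arms (L1 from height, L2 from gape);
#' multiplies every specimen measure by independent lognormal noise; and
#' draws one feeding-habit label per species from
#' \code{Bernoulli(plogis(beta0 + beta1 * ln(asin(sqrt(VR)))))} at the
#' species' expected velocity ratio. Output is fully reproducible under the
#' configured seed (single PRNG stream, fixed draw order).
#'
#' @param config a [synthetic_config()].
#' @return list with \code{specimens} (one row per specimen, raw measures)
#'   and \code{species} (expected measures, expected VR, \code{p_worm},
#'   binary \code{label}).
#' @examples
#' g <- generate_specimens(synthetic_config(n_species = 5, seed = 42))
#' head(g$specimens)
#' @export
generate_specimens <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  set.seed(cf$seed)
  k <- legacy_constants
  IL_sp <- stats::rlnorm(cf$n_species, cf$il_meanlog, cf$il_sdlog)
  CL <- cf$cl_a * IL_sp^cf$cl_b
  MDL <- cf$mdl_a * IL_sp^cf$mdl_b
  HDS <- cf$hds_a * IL_sp^cf$hds_b
  DSL <- (CL + k[["BSL_per_DSL_minus_MDL"]] * MDL) /
    (1 + k[["BSL_per_DSL_minus_MDL"]])
  BSL <- CL - DSL
  WDS <- k[["WDS_per_2"]] * HDS
  HBS <- k[["HBS_per_2"]] * HDS
  WBS <- k[["WBS_per_2"]] * HDS
  L1 <- k[["L1_per_2"]] * HDS
  L2 <- k[["L2_per_7"]] * MDL
  VR <- pmin(L1 / L2, 1 - 1e-9)
  p_worm <- stats::plogis(cf$beta0 + cf$beta1 * log(asin(sqrt(VR))))
  label <- stats::rbinom(cf$n_species, 1, p_worm)

  species <- data.frame(
    species_id = sprintf("synth%03d", seq_len(cf$n_species)),
    IL = IL_sp, CL = CL, MDL = MDL, HDS = HDS, DSL = DSL, BSL = BSL,
    L1 = L1, L2 = L2, VR = VR, p_worm = p_worm, label = label,
    stringsAsFactors = FALSE)

  nsp <- cf$n_specimens_per_species
  idx <- rep(seq_len(cf$n_species), each = nsp)
  measures <- c("IL", "DSL", "BSL", "MDL", "HDS", "WDS", "HBS", "WBS",
                "L1", "L2")
  exp_mat <- cbind(IL = IL_sp, DSL = DSL, BSL = BSL, MDL = MDL, HDS = HDS,
                   WDS = WDS, HBS = HBS, WBS = WBS, L1 = L1, L2 = L2)
  noise <- matrix(stats::rlnorm(length(idx) * length(measures),
                                meanlog = 0, sdlog = cf$noise_sdlog),
                  nrow = length(idx))
  specimens <- as.data.frame(exp_mat[idx, , drop = FALSE] * noise)
  specimens <- cbind(
    data.frame(specimen_id = sprintf("%s_s%02d", species$species_id[idx],
                                     rep(seq_len(nsp), cf$n_species)),
               species_id = species$species_id[idx],
               stringsAsFactors = FALSE),
    specimens)
  specimens$widths_equal_heights <- FALSE
  list(specimens = specimens, species = species)
}

#' Inject edge-case records for error-path testing
#'
#' Appends (or modifies) records exercising the analysis' defensive paths:
#' \describe{
#'   \item{degenerate_geometry}{a record whose reach does not exceed 1.1x
#'     its gape, so the pennate force would be non-positive;}
#'   \item{vr_near_one}{a record with velocity ratio in (0.99, 1), flagged
#'     downstream;}
#'   \item{missing_widths}{widths blanked and \code{widths_equal_heights}
#'     set.}
#' }
#'
#' @param specimens specimen data.frame from [generate_specimens()].
#' @param scenario one of the three scenario names.
#' @return the modified specimen data.frame.
#' @export
perturb_case <- function(specimens,
                         scenario = c("degenerate_geometry", "vr_near_one",
                                      "missing_widths")) {
  scenario <- match.arg(scenario)
  df <- specimens
  if (scenario == "degenerate_geometry") {
    r <- df[1, ]
    r$specimen_id <- "edge_degenerate"
    tot <- 1.05 * r$MDL                   # CL below 1.1 * MDL
    r$DSL <- tot * 0.8; r$BSL <- tot * 0.2
    df <- rbind(df, r)
  } else if (scenario == "vr_near_one") {
    r <- df[1, ]
    r$specimen_id <- "edge_vr_near_one"
    r$L1 <- 0.995 * r$L2
    df <- rbind(df, r)
  } else {
    df$WDS <- NA_real_
    df$WBS <- NA_real_
    df$widths_equal_heights <- TRUE
  }
  df
}
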