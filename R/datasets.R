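#' Catalogue of bundled study tables
#'
#' Every data table of the study ships as a plain CSV fixture with an md5
#' checksum and expected row count recorded in a manifest; [load_fixture()]
#' validates both at load time.
#'
#' @return data.frame with \code{table_id}, \code{file}, \code{n_rows},
#'   \code{md5} and a one-line description.
#' @export
fixture_catalog <- function() {
  files <- c(
    T2 = "table2_new_species_means.csv",
    T3 = "table3_species_means.csv",
    T5 = "table5_pca_loadings.csv",
    T6 = "table6_phytoseiid_validation.csv",
    T8 = "table8_test_predictions.csv",
    T10 = "table10_cephalisation.csv",
    T11_12 = "table11_12_parasitines.csv",
    T13 = "table13_relative_measures.csv",
    T13_means = "table13_dataset_means.csv",
    T14_15 = "table14_15_heuristics.csv",
    T16 = "table16_habitats.csv",
    T17 = "table17_holothyrids.csv",
    T18 = "table18_opilioacarids.csv",
    buryn_brandl = "buryn_brandl_reconstructed.csv",
    training_labels = "training_labels.csv")
  desc <- c(
    T2 = "morphometric means of the eight newly measured species",
    T3 = "60-species means: size, reach, gape, VR, crunch force, aspect ratio",
    T5 = "PCA loadings and component sds over the eight new species",
    T6 = "phytoseiid validation rows (perimeter index, VR, p(worm-like))",
    T8 = "test-set predictions of the published classifier (33 species)",
    T10 = "printed micro-/mega-cephalic memberships",
    T11_12 = "parasitine validation cohort (MD ratio, VR, feeding call)",
    T13 = "relative measures of the 60-species set",
    T13_means = "printed (rounded) data-set means",
    T14_15 = "heuristic verbal profiles of all 60 species",
    T16 = "habitat counts of worm-like designs with printed directions",
    T17 = "holothyrid estimates (sparse; one three-segment force row)",
    T18 = "opilioacarid estimates incl. 19 complete force rows",
    buryn_brandl = "RECONSTRUCTED legacy rows (Id, '1', '7', '2') inverted from the printed species means",
    training_labels = "species roles and best-effort feeding labels")
  man <- jsonlite::read_json(fixture_path("manifest.json"))
  data.frame(table_id = names(files), file = unname(files),
             n_rows = vapply(unname(files),
                             function(f) man[[f]]$n_rows, numeric(1)),
             md5 = vapply(unname(files),
                          function(f) man[[f]]$md5, character(1)),
             description = unname(desc),
             stringsAsFactors = FALSE)
}

fixture_path <- function(file, dir = NULL) {
  if (is.null(dir)) {
    p <- system.file("extdata", file, package = "mesochela")
    if (p == "") stop("fixture not found: ", file)
    p
  } else file.path(dir, file)
}

#' Load a bundled study table with checksum validation
#'
#' Reads the requested fixture, hard-fails on any checksum or row-count
#' mismatch, and attaches known in-table inconsistencies as row-level flags:
#' the first species of the 60-species table has a printed cheliceral length
#' (143.5) inconsistent with the sum of its printed segment lengths (144.6);
#' one test-set probability row disagrees with the published coefficients by
#' more than coefficient rounding allows; the holothyrid three-segment force
#' row is not reproducible under any documented cross-dimension averaging.
#'
#' @param table_id one of the ids in [fixture_catalog()].
#' @param dir optional directory overriding the installed fixture location
#'   (checksums are still enforced).
#' @return data.frame; flag columns where applicable.
#' @examples
#' t3 <- load_fixture("T3")
#' t3[t3$species == "Veigaia cerva", "CL"]  # 801.5
#' @export
load_fixture <- function(table_id, dir = NULL) {
  ctl <- fixture_catalog()
  if (!table_id %in% ctl$table_id)
    stop("unknown table id: ", table_id, " (known: ",
         paste(ctl$table_id, collapse = ", "), ")")
  row <- ctl[ctl$table_id == table_id, ]
  path <- fixture_path(row$file, dir)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, row$md5))
    stop("checksum mismatch for ", row$file, ": got ", md5,
         ", manifest says ", row$md5)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) != row$n_rows)
    stop("row count mismatch for ", row$file)
  if (table_id == "T3") {
    df$flag_cl_inconsistent <- df$species == "Alliphis halleri"
  } else if (table_id == "T17") {
    df$flag_f2av_unreproduced <- !is.na(df$F2AV)
  }
  df
}

#' Best-effort training and test labels for the classifier
#'
#' The training set comprises the legacy species with a designated feeding
#' type; the test set the legacy species of unknown food type plus the eight
#' newly measured species. Polyphagous (historical code 3) and omnivorous
#' (code 4) species are named in the study; binary worm-like/micro-arthropod
#' training labels are mostly not printed and are returned as
#' \code{"known_but_unprinted"} except where the text states them. Test-set
#' species carry their literature label where one is stated (the labels
#' behind the agreement marks of the prediction table) or
#' \code{"unknown"}/\code{"ambiguous"}.
#'
#' @return data.frame with \code{species}, \code{label}, \code{role}
#'   ("training"/"test") and the species' velocity ratio.
#' @examples
#' tl <- training_labels()
#' tl[tl$species == "Proctolaelaps pygmaeus", "label"]  # omnivore
#' @export
training_labels <- function() {
  lab <- load_fixture("training_labels")
  t3 <- load_fixture("T3")
  merge(lab, t3[c("species", "VR")], by = "species", sort = TRUE)
}

#' The 60-species analysis set with harmonised raw dimensions
#'
#' Joins the measured means of the eight newly studied species with the
#' reconstructed legacy rows converted through [from_buryn_brandl()], giving
#' every species the full dimension set (notably \code{WDS}, needed by
#' [cephalisation()]) alongside the printed derived columns of the species
#' table. For legacy rows the printed \code{VR}, \code{F2AV} and \code{AR}
#' are retained as the authoritative derived values.
#'
#' @return data.frame of 60 rows.
#' @export
analysis_dataset <- function() {
  t3 <- load_fixture("T3")
  t2 <- load_fixture("T2")
  bb <- from_buryn_brandl(load_fixture("buryn_brandl"))
  raw <- rbind(
    data.frame(species = t2$species, WDS = t2$WDS, HDS = t2$HDS,
               stringsAsFactors = FALSE),
    data.frame(species = bb$species_id, WDS = bb$WDS, HDS = bb$HDS,
               stringsAsFactors = FALSE))
  out <- merge(t3, raw, by = "species", sort = FALSE)
  if (nrow(out) != 60L) stop("analysis dataset incomplete")
  out[order(out$species), ]
}
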