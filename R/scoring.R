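#' Default tumor-site risk mapping
#'
#' Site risk categories as used by the Khorana score: very-high-risk sites
#' score 2 points, high-risk sites 1, all other sites 0. The default follows
#' the Khorana site table (stomach/gastroesophageal and pancreas very high;
#' lung, lymphoma, gynecologic/urological, bladder and testicular high), with
#' vocabulary variants of the shipped cohort schema included. Esophageal
#' primaries are counted low-risk (distinct from gastroesophageal-junction
#' adenocarcinoma). Edit or replace the lists to change the mapping.
#'
#' @return A list with character vectors `very_high` and `high`.
#' @export
default_site_risk <- function() {
  list(
    very_high = c("gastric", "gastroesophageal", "stomach", "pancreas"),
    high = c("lung", "lymphoma", "gynecologic", "gynecologic_urological",
             "urological", "bladder", "bladder_urinary", "testicular")
  )
}

normalize_site <- function(x) {
  gsub("[^a-z_]+", "_", tolower(trimws(x)))
}

#' Tumor-site risk category
#'
#' Deterministic lookup of the Khorana site-risk category for a tumor-site
#' label. Unknown sites map to `"low"` (configurable), with a warning.
#' A per-record `override` (e.g. the cohort's `site_risk_override` column)
#' takes precedence over the mapping.
#'
#' @param tumor_site character vector of site labels.
#' @param mapping a mapping as returned by [default_site_risk()].
#' @param override optional character vector in `{low, high, very_high}`.
#' @param unknown category assigned to unmapped sites.
#' @param warn warn when an unmapped site is encountered.
#' @return Character vector in `{"low", "high", "very_high"}` (NA for missing
#'   site with no override).
#' @examples
#' site_risk_category(c("pancreas", "lung", "breast"))
#' @export
site_risk_category <- function(tumor_site, mapping = default_site_risk(),
                               override = NULL, unknown = "low", warn = TRUE) {
  s <- normalize_site(tumor_site)
  out <- rep(unknown, length(s))
  out[s %in% normalize_site(mapping$very_high)] <- "very_high"
  out[s %in% normalize_site(mapping$high)] <- "high"
  known <- c(normalize_site(mapping$very_high), normalize_site(mapping$high),
             "breast", "colon", "rectum", "anus", "prostate", "mesothelioma",
             "head_and_neck", "head_neck", "sarcoma", "esophagus", "skin",
             "neuroendocrine", "appendix", "biliary_tract", "unknown")
  unk <- !is.na(s) & !(s %in% known)
  if (warn && any(unk)) {
    warning("unmapped tumor site(s) assigned '", unknown, "': ",
            paste(unique(tumor_site[unk]), collapse = ", "), call. = FALSE)
  }
  out[is.na(s)] <- NA_character_
  if (!is.null(override)) {
    ok <- !is.na(override) & override %in% c("low", "high", "very_high")
    out[ok] <- override[ok]
  }
  out
}

#' Khorana score components from patient records
#'
#' Derives the five Khorana inputs from a record table: site risk category,
#' anemia (hemoglobin < 10 g/dL or use of red-blood-cell growth factors,
#' three-valued OR), pre-chemotherapy leukocytosis (> 11 000/uL),
#' thrombocytosis (>= 350 x 10^3/uL), and obesity (BMI >= 35). Components
#' whose inputs are missing and not logically forced come back `NA`.
#'
#' @param records a data frame in the cohort schema (see [read_cohort()]).
#' @param mapping tumor-site risk mapping.
#' @param warn warn on unmapped tumor sites.
#' @return Data frame with columns `site_risk`, `anemia_or_esa`,
#'   `leukocytosis`, `thrombocytosis`, `obesity`.
#' @export
khorana_components <- function(records, mapping = default_site_risk(),
                               warn = TRUE) {
  data.frame(
    site_risk = site_risk_category(records$tumor_site, mapping,
                                   override = records$site_risk_override,
                                   warn = warn),
    # base R's | is already three-valued: TRUE | NA is TRUE, FALSE | NA is NA
    anemia_or_esa = (records$hemoglobin_g_dl < 10) |
      records$uses_rbc_growth_factors,
    leukocytosis = records$leukocytes_per_ul > 11000,
    thrombocytosis = records$platelets_per_ul >= 350e3,
    obesity = records$bmi >= 35,
    stringsAsFactors = FALSE
  )
}

#' Khorana score
#'
#' Additive score: 2 points for a very-high-risk site, 1 for a high-risk
#' site, and 1 each for anemia/ESA use, leukocytosis, thrombocytosis and
#' obesity (range 0-6).
#'
#' @param components a data frame from [khorana_components()] (or a
#'   one-row equivalent).
#' @param weights point weights, editable; defaults
#'   `c(very_high = 2, high = 1, component = 1)`.
#' @param na_action `"error"` (default) raises an error naming the missing
#'   component; `"na"` propagates `NA`.
#' @return Integer vector of scores.
#' @examples
#' khorana_score(data.frame(site_risk = "very_high", anemia_or_esa = FALSE,
#'                          leukocytosis = FALSE, thrombocytosis = TRUE,
#'                          obesity = FALSE))
#' @export
khorana_score <- function(components,
                          weights = c(very_high = 2, high = 1, component = 1),
                          na_action = c("error", "na")) {
  na_action <- match.arg(na_action)
  needed <- c("site_risk", "anemia_or_esa", "leukocytosis",
              "thrombocytosis", "obesity")
  miss_col <- setdiff(needed, names(components))
  if (length(miss_col) > 0L) {
    stop("missing component(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  }
  if (na_action == "error") {
    for (col in needed) {
      if (anyNA(components[[col]])) {
        stop("missing component value: ", col, call. = FALSE)
      }
    }
  }
  score <- weights[["very_high"]] * (components$site_risk == "very_high") +
    weights[["high"]] * (components$site_risk == "high") +
    weights[["component"]] * (components$anemia_or_esa +
                                components$leukocytosis +
                                components$thrombocytosis +
                                components$obesity)
  as.integer(score)
}

#' ONKOTEV score components
#'
#' The four binary factors: Khorana score > 2, metastatic disease,
#' macroscopic vascular or lymphatic compression, and previous VTE.
#'
#' @param records a data frame in the cohort schema.
#' @param khorana integer vector of Khorana scores (computed via
#'   [khorana_score()] if not supplied).
#' @param mapping tumor-site risk mapping (used only when `khorana` is
#'   computed here).
#' @return Data frame with logical columns `khorana_gt2`, `metastatic`,
#'   `compression`, `prior_vte`.
#' @export
onkotev_components <- function(records, khorana = NULL,
                               mapping = default_site_risk()) {
  if (is.null(khorana)) {
    khorana <- khorana_score(khorana_components(records, mapping, warn = FALSE),
                             na_action = "na")
  }
  data.frame(
    khorana_gt2 = khorana > 2L,
    metastatic = records$metastatic,
    compression = records$vascular_lymphatic_compression,
    prior_vte = records$prior_vte,
    stringsAsFactors = FALSE
  )
}

#' ONKOTEV score
#'
#' One point per positive factor (Khorana > 2, metastatic disease, vascular
#' or lymphatic compression, previous VTE), summed; range 0-4.
#'
#' @param components data frame from [onkotev_components()].
#' @param na_action `"error"` (default) or `"na"`.
#' @return Integer vector of scores 0-4.
#' @export
onkotev_score <- function(components, na_action = c("error", "na")) {
  na_action <- match.arg(na_action)
  needed <- c("khorana_gt2", "metastatic", "compression", "prior_vte")
  miss_col <- setdiff(needed, names(components))
  if (length(miss_col) > 0L) {
    stop("missing component(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  }
  if (na_action == "error") {
    for (col in needed) {
      if (anyNA(components[[col]])) {
        stop("missing component value: ", col, call. = FALSE)
      }
    }
  }
  as.integer(components$khorana_gt2 + components$metastatic +
               components$compression + components$prior_vte)
}

#' Four-level ONKOTEV stratum
#'
#' Pools scores 3 and 4 into the `">2"` stratum, giving the validation
#' strata `0, 1, 2, >2`.
#'
#' @param score integer ONKOTEV scores (0-4).
#' @return Factor with levels `"0", "1", "2", ">2"`.
#' @export
onkotev_stratum <- function(score) {
  factor(ifelse(score >= 3L, ">2", as.character(score)),
         levels = c("0", "1", "2", ">2"))
}

#' Score a cohort
#'
#' Appends `khorana_score`, `khorana_gt2`, `onkotev_score` and
#' `onkotev_stratum` columns to the cohort's records. The cohort should have
#' passed [complete_case_filter()] so every score is decidable.
#'
#' @param cohort a `cohort`.
#' @param mapping tumor-site risk mapping.
#' @return The cohort with score columns appended.
#' @export
score_cohort <- function(cohort, mapping = default_site_risk()) {
  rec <- cohort_records(cohort)
  comp <- khorana_components(rec, mapping, warn = FALSE)
  ks <- khorana_score(comp, na_action = "na")
  oc <- onkotev_components(rec, khorana = ks)
  os <- onkotev_score(oc, na_action = "na")
  rec$khorana_score <- ks
  rec$khorana_gt2 <- oc$khorana_gt2
  rec$onkotev_score <- os
  rec$onkotev_stratum <- onkotev_stratum(os)
  cohort$records <- rec
  cohort
}
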