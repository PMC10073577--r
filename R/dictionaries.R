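# Editable code dictionaries: which drug codes form each laxative class,
# which ICD-10 prefixes define each covariate condition, and which ICD-10
# codes count as major congenital malformations per organ system.
# All three ship as defaults and round-trip through YAML so users can
# substitute their own database-specific lists.

#' The 17 rhubarb-rhizome Kampo products evaluated as the exposure class
#' @noRd
KRR_PRODUCTS <- c(
  "mashiningan", "daiokanzoto", "otsujito", "bofutsushosan", "tokakujokito",
  "keishikashakuyakudaioto", "junchoto", "crude_daio", "tsudosan",
  "choijokito", "jidabokuippo", "daisaikoto", "daiobotampito",
  "sanoshashinto", "inchinkoto", "jizusoippo", "daijokito"
)

#' Default drug dictionary
#'
#' Maps raw prescription drug codes to the four laxative classes compared in
#' the analysis: magnesium oxide (MgO, the active comparator; WHO-ATC
#' A02AA02), senna glycosides (SG; WHO-ATC A06AB06, excluded from the group
#' comparison because senna shares sennoside A with rhubarb rhizome), the 17
#' Kampo products containing rhubarb rhizome (KRR, the exposure of interest),
#' and daikenchuto (a rhubarb-free Kampo laxative tabulated for context).
#' Kampo products are matched by product name rather than ATC code because
#' Kampo formulations carry no WHO-ATC laxative codes.
#'
#' @param mgo_codes,sg_codes,krr_products,daikenchuto_codes character vectors
#'   of drug codes; defaults are the WHO-ATC codes and standard product names.
#' @return An object of class `drug_dictionary`: a named list of four
#'   pairwise-disjoint code sets.
#' @export
#' @examples
#' d <- drug_dictionary()
#' length(d$krr_products)  # 17 products
drug_dictionary <- function(mgo_codes = "A02AA02",
                            sg_codes = "A06AB06",
                            krr_products = KRR_PRODUCTS,
                            daikenchuto_codes = "daikenchuto") {
  dict <- list(
    mgo_codes = as.character(mgo_codes),
    sg_codes = as.character(sg_codes),
    krr_products = as.character(krr_products),
    daikenchuto_codes = as.character(daikenchuto_codes)
  )
  all_codes <- unlist(dict, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    rlang::abort(sprintf(
      "drug classes must be pairwise disjoint; duplicated code(s): %s",
      paste(unique(all_codes[duplicated(all_codes)]), collapse = ", ")
    ))
  }
  structure(dict, class = "drug_dictionary")
}

#' Default covariate code lists
#'
#' ICD-10 prefixes defining each maternal condition covariate, plus the drug
#' codes treated as suspected teratogens. These are editable defaults, not a
#' validated clinical list: the source study's supplementary lists are not
#' public, so standard chapter-level prefixes are shipped (hypertensive
#' disease I10-I15; diabetes E10-E14 and O24; obesity E66; epilepsy G40;
#' phenylketonuria E70.0; caesarean O82).
#'
#' @param lookback_months months before pregnancy onset included when
#'   searching diagnoses for condition covariates (default 3, matching the
#'   required pre-pregnancy enrollment window).
#' @return A list of class `covariate_codelists`.
#' @export
covariate_codelists <- function(lookback_months = 3) {
  structure(list(
    conditions = list(
      hypertension = c("I10", "I11", "I12", "I13", "I14", "I15"),
      diabetes = c("E10", "E11", "E12", "E13", "E14", "O24"),
      obesity = "E66",
      epilepsy = "G40",
      phenylketonuria = "E70.0",
      caesarean = "O82"
    ),
    teratogen_codes = c("D07BB", "L04AX03", "retinoid", "thalidomide",
                        "valproate", "warfarin"),
    lookback_months = as.integer(lookback_months)
  ), class = "covariate_codelists")
}

#' Default major-congenital-malformation code list
#'
#' ICD-10 codes within Q00-Q89 counted as major congenital malformations
#' (MCM), organised into the ten organ systems used for reporting, together
#' with a minor-malformation exclusion list. Chromosomal abnormalities
#' (Q90-Q99) are not part of the outcome; they are an exclusion criterion
#' applied at cohort construction. The default is a EUROCAT-style
#' prefix list and is editable: analyses of real data should substitute a
#' validated list via [read_mcm_codelist()].
#'
#' @return A list of class `mcm_codelist` with elements `included` (named
#'   list: organ system -> character vector of ICD-10 prefixes),
#'   `excluded_minor` (character vector of prefixes trumping inclusion) and
#'   `chromosomal` (the fixed Q90-Q99 range).
#' @export
mcm_codelist <- function() {
  structure(list(
    included = list(
      nervous = paste0("Q0", 0:7),
      eye_ear_face_neck = paste0("Q1", 0:8),
      circulatory = paste0("Q2", 0:8),
      respiratory = paste0("Q3", 0:4),
      cleft_lip_palate = paste0("Q3", 5:7),
      digestive = c(paste0("Q3", 8:9), paste0("Q4", 0:5)),
      genital = paste0("Q5", c(0:2, 4:6)),
      urinary = paste0("Q6", 0:4),
      musculoskeletal = c(paste0("Q6", 5:9), paste0("Q7", 0:9)),
      other = paste0("Q8", 0:9)
    ),
    # EUROCAT-style minor anomalies excluded from the major count
    excluded_minor = c(
      "Q10.4", "Q10.5", "Q17", "Q18.0", "Q18.1", "Q18.2", "Q27.0",
      "Q38.1", "Q40.1", "Q53", "Q62.5", "Q65.3", "Q65.4", "Q65.5",
      "Q65.6", "Q66", "Q67", "Q69", "Q70", "Q82.5", "Q83.2", "Q84"
    ),
    chromosomal = paste0("Q9", 0:9)
  ), class = "mcm_codelist")
}

#' @rdname drug_dictionary
#' @param path YAML file path.
#' @export
read_drug_dictionary <- function(path) {
  x <- yaml::read_yaml(path)
  drug_dictionary(
    mgo_codes = x$mgo_codes, sg_codes = x$sg_codes,
    krr_products = x$krr_products, daikenchuto_codes = x$daikenchuto_codes
  )
}

#' @rdname drug_dictionary
#' @param dict a `drug_dictionary`.
#' @export
write_drug_dictionary <- function(dict, path) {
  yaml::write_yaml(unclass(dict), path)
  invisible(path)
}

#' @rdname covariate_codelists
#' @param path YAML file path.
#' @export
read_covariate_codelists <- function(path) {
  x <- yaml::read_yaml(path)
  out <- covariate_codelists(lookback_months = x$lookback_months %||% 3)
  if (!is.null(x$conditions)) out$conditions <- lapply(x$conditions, as.character)
  if (!is.null(x$teratogen_codes)) out$teratogen_codes <- as.character(x$teratogen_codes)
  out
}

#' @rdname covariate_codelists
#' @param codelists a `covariate_codelists`.
#' @export
write_covariate_codelists <- function(codelists, path) {
  yaml::write_yaml(unclass(codelists), path)
  invisible(path)
}

#' @rdname mcm_codelist
#' @param path YAML file path.
#' @export
read_mcm_codelist <- function(path) {
  x <- yaml::read_yaml(path)
  out <- structure(x, class = "mcm_codelist")
  # minors may carve out pieces of an included range at equal or finer
  # granularity, but a minor prefix coarser than an included prefix would
  # silently swallow a whole organ-system block
  norm <- function(v) gsub(".", "", toupper(v), fixed = TRUE)
  inc <- norm(unlist(out$included))
  bad <- vapply(norm(out$excluded_minor), function(p) {
    any(startsWith(inc, p) & nchar(inc) > nchar(p))
  }, logical(1))
  if (any(bad)) {
    rlang::abort(sprintf(
      "excluded_minor prefix(es) coarser than an included prefix: %s",
      paste(out$excluded_minor[bad], collapse = ", ")
    ))
  }
  out
}

#' @rdname mcm_codelist
#' @param codelist an `mcm_codelist`.
#' @param path YAML file path.
#' @export
write_mcm_codelist <- function(codelist, path) {
  yaml::write_yaml(unclass(codelist), path)
  invisible(path)
}

# TRUE where `codes` starts with any of `prefixes` (dot-insensitive:
# "Q381" and "Q38.1" both match prefix "Q38.1").
icd_matches <- function(codes, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(codes)))
  norm <- function(x) gsub(".", "", toupper(x), fixed = TRUE)
  codes <- norm(codes)
  prefixes <- norm(prefixes)
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

# Classify raw drug codes into laxative classes; NA class = out of scope.
classify_drug <- function(drug_code, dict) {
  cls <- rep(NA_character_, length(drug_code))
  cls[drug_code %in% dict$mgo_codes] <- "MgO"
  cls[drug_code %in% dict$sg_codes] <- "SG"
  cls[drug_code %in% dict$krr_products] <- "KRR"
  cls[drug_code %in% dict$daikenchuto_codes] <- "daikenchuto"
  cls
}
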