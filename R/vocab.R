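#' Controlled vocabularies for PSQA record fields
#'
#' Categorical record fields (facility, treatment machine, QA device,
#' disease site) are validated against controlled vocabularies, mirroring
#' the drop-down menus of a structured QA entry form. The defaults describe
#' a four-facility university hospital group: each facility runs its own
#' machines and measurement devices. All vocabularies are plain character
#' vectors and can be replaced wholesale to describe a different network.
#'
#' @param facilities,machines,qa_devices,sites Character vectors of allowed
#'   labels. Defaults describe the shipped four-facility network.
#'
#' @return A list of class `psqa_vocab` with elements `facilities`,
#'   `machines`, `qa_devices`, `sites`.
#' @examples
#' vocab <- psqa_vocab()
#' vocab$sites
#' @export
psqa_vocab <- function(facilities = c("UniversityHospital", "KotoToyosu",
                                      "NorthernYokohama", "Fujigaoka"),
                       machines = c("Clinac iX", "Radixact", "Infinity",
                                    "TrueBeam STx", "TrueBeam"),
                       qa_devices = c("ArcCHECK", "Delta4", "Farmer Chamber",
                                      "Exradin A1SL", "Pinpoint Chamber"),
                       sites = psqa_sites()) {
  structure(
    list(
      facilities = as.character(facilities),
      machines = as.character(machines),
      qa_devices = as.character(qa_devices),
      sites = as.character(sites)
    ),
    class = "psqa_vocab"
  )
}

#' @rdname psqa_vocab
#' @export
psqa_sites <- function() {
  c("CNS", "HeadNeck", "Chest", "Pelvis", "Other")
}

#' Default disease-site synonym table
#'
#' Maps free-text disease labels (lower-cased, trimmed, internal whitespace
#' collapsed) to the five canonical site categories. The table is a named
#' character vector (`names` = normalized raw label, values = canonical
#' site) and can be extended or overridden in [normalize_site()].
#'
#' Anatomically adjacent labels are folded into the five categories used
#' for stratified limit derivation: intracranial targets to `CNS`,
#' thoracic to `Chest`, genitourinary/gynaecological to `Pelvis`.
#'
#' @return Named character vector.
#' @examples
#' site_synonyms()[["prostate"]]
#' @export
site_synonyms <- function() {
  c(
    # canonical spellings map to themselves
    "cns" = "CNS", "headneck" = "HeadNeck", "chest" = "Chest",
    "pelvis" = "Pelvis", "other" = "Other",
    # central nervous system
    "central nervous system" = "CNS", "brain" = "CNS",
    "brain mets" = "CNS", "spine" = "CNS",
    # head and neck
    "head and neck" = "HeadNeck", "head & neck" = "HeadNeck",
    "h&n" = "HeadNeck", "hn" = "HeadNeck", "neck" = "HeadNeck",
    "oropharynx" = "HeadNeck", "larynx" = "HeadNeck",
    "nasopharynx" = "HeadNeck",
    # chest
    "lung" = "Chest", "thorax" = "Chest", "breast" = "Chest",
    "esophagus" = "Chest", "oesophagus" = "Chest", "mediastinum" = "Chest",
    # pelvis
    "prostate" = "Pelvis", "cervix" = "Pelvis", "uterus" = "Pelvis",
    "rectum" = "Pelvis", "bladder" = "Pelvis", "anus" = "Pelvis",
    "endometrium" = "Pelvis", "gyn" = "Pelvis",
    # other
    "others" = "Other", "misc" = "Other", "abdomen" = "Other",
    "liver" = "Other", "pancreas" = "Other", "extremity" = "Other"
  )
}

#' Normalize free-text disease-site labels to canonical categories
#'
#' Case, surrounding/internal whitespace and shipped synonyms are resolved
#' to one of the five canonical categories (`CNS`, `HeadNeck`, `Chest`,
#' `Pelvis`, `Other`). A label with no synonym entry returns `"Unmapped"`
#' rather than a guess; record validation treats unmapped sites as errors.
#' The function is vectorized and idempotent.
#'
#' @param x Character vector of raw site labels.
#' @param synonyms Named character vector mapping normalized raw labels to
#'   canonical sites; defaults to [site_synonyms()]. Supply a modified copy
#'   to override (e.g. route `"prostate"` elsewhere).
#'
#' @return Character vector, each element a canonical site or `"Unmapped"`.
#' @examples
#' normalize_site(c("head and neck", "CNS", "prostate", "knee"))
#' @export
normalize_site <- function(x, synonyms = site_synonyms()) {
  key <- tolower(gsub("\\s+", " ", trimws(as.character(x))))
  out <- unname(synonyms[key])
  out[is.na(out) | !nzchar(key)] <- "Unmapped"
  out[is.na(x)] <- "Unmapped"
  out
}
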