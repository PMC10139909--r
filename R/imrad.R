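# Rule-based IMRaD section classification.
#
# A section's title, label and sec-type are concatenated, lowercased and
# matched against cue words/phrases.  Cues ending in "*" match any word
# starting with the stem (so "intro*" hits "Introduction"); plain cues are
# substring matches (so "history" hits "Pre-publication history" — a known,
# deliberate behaviour of this rudimentary classifier).  Group precedence is
# I, M, R, D with first match winning.

IMRAD_LEVELS <- c("I", "M", "R", "D", "NoIMRaD")

#' Default IMRaD cue rule set
#'
#' The rule groups, in precedence order:
#' \describe{
#'   \item{I (introduction/background)}{intro*, overview, background,
#'     history, related work, related stud*, previous work, previous stud*,
#'     review}
#'   \item{M (method)}{method, material, experimental procedure, protocol,
#'     data}
#'   \item{R (result)}{result, finding}
#'   \item{D (conclusion/discussion)}{conclud*, conclusion, summary,
#'     discuss*, future}
#' }
#' Strings matching no cue map to `NoIMRaD`.
#'
#' @return a named list of character vectors (class `imrad_rules`); names
#'   are the labels in precedence order.
#' @export
imrad_rules <- function() {
  structure(list(
    I = c("intro*", "overview", "background", "history", "related work",
          "related stud*", "previous work", "previous stud*", "review"),
    M = c("method", "material", "experimental procedure", "protocol", "data"),
    R = c("result", "finding"),
    D = c("conclud*", "conclusion", "summary", "discuss*", "future")
  ), class = "imrad_rules")
}

#' Map a section string to its IMRaD category
#'
#' @param section_string the concatenation of a section's title, label and
#'   sec-type (any case; surrounding whitespace ignored).
#' @param rules a rule set as returned by [imrad_rules()].
#' @return one of `"I"`, `"M"`, `"R"`, `"D"`, `"NoIMRaD"`.
#' @examples
#' map_imrad("Materials and Methods")   # "M"
#' map_imrad("Pre-publication history") # "I"
#' map_imrad("Acknowledgements")        # "NoIMRaD"
#' @export
map_imrad <- function(section_string, rules = imrad_rules()) {
  s <- stringi::stri_trans_tolower(normalize_ws(section_string))
  if (!nzchar(s)) return("NoIMRaD")
  for (lab in names(rules)) {
    for (cue in rules[[lab]]) {
      if (cue_matches(cue, s)) return(lab)
    }
  }
  "NoIMRaD"
}

cue_matches <- function(cue, s) {
  if (stringi::stri_endswith_fixed(cue, "*")) {
    stem <- stringi::stri_sub(cue, 1, -2)
    ## "word starting with the stem": stem at string start or after a
    ## non-letter boundary
    pat <- paste0("(^|[^\\p{L}])", stringi::stri_replace_all_regex(
      stem, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"))
    stringi::stri_detect_regex(s, pat)
  } else {
    stringi::stri_detect_fixed(s, cue)
  }
}

#' IMRaD label of a text fragment
#'
#' Abstract and back-matter fragments are `NoIMRaD` unconditionally (IMRaD
#' identification is only applied to the main text and the tables/figures
#' within it). Otherwise the fragment's section path is evaluated
#' innermost-first and the first non-`NoIMRaD` result wins, so subsection
#' titles override their parents.
#'
#' @param fragment a fragment from [segment()] (needs `component` and
#'   `section_path`).
#' @param rules a rule set from [imrad_rules()].
#' @return one of `"I"`, `"M"`, `"R"`, `"D"`, `"NoIMRaD"`.
#' @export
label_fragment <- function(fragment, rules = imrad_rules()) {
  if (fragment$component %in% c("abstract", "back")) return("NoIMRaD")
  sp <- fragment$section_path
  if (is.null(sp) || nrow(sp) == 0) return("NoIMRaD")
  for (i in rev(seq_len(nrow(sp)))) {
    s <- paste(sp$title[i], sp$label[i], sp$sec_type[i])
    lab <- map_imrad(s, rules)
    if (lab != "NoIMRaD") return(lab)
  }
  "NoIMRaD"
}
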