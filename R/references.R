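# Bibliography extraction.
#
# One <ref> element is one bibliography item.  Publishers that follow the
# JATS recommendation for multi-work references nest several
# <element-citation>/<mixed-citation>/<nlm-citation> children, each with its
# own id, under a single <ref>; inline <xref rid="..."> markers may point at
# either level, so the registry indexes both.

#' Extract the reference registry from a JATS document
#'
#' Walks every `<ref>` element in document order and builds a registry of
#' [reference entries][ref_registry] covering both the `<ref>` ids and the
#' ids of any nested citation elements (multi-work references). PMIDs are
#' read from `<pub-id pub-id-type="pmid">` descendants.
#'
#' Duplicate `<ref>` ids (a publisher error) keep the first occurrence and
#' raise a warning; a document without a reference list yields an empty
#' registry, not an error.
#'
#' @param doc an `xml_document` (see [xml2::read_xml()]) or a path/string
#'   accepted by it.
#' @return an object of class `ref_registry`: a list with
#'   \describe{
#'     \item{entries}{`data.table` with one row per reference:
#'       `ref_id`, `order_index`, `label`, `xml_pmid`, `raw_text`, and the
#'       list-columns `member_ids`, `member_pmids`.}
#'     \item{id_index}{named integer vector mapping every ref id *and* every
#'       nested member id to its entry's `order_index`.}
#'     \item{id_pmid}{named character vector: per-id XML-tagged PMID
#'       (the member's own PMID for nested member ids).}
#'     \item{label_index}{named integer vector mapping integer labels to
#'       entry positions (first occurrence wins).}
#'   }
#' @examples
#' xml <- paste0(
#'   "<article><back><ref-list>",
#'   "<ref id='B1'><label>1</label><mixed-citation>Smith 2001.",
#'   "<pub-id pub-id-type='pmid'>10000001</pub-id></mixed-citation></ref>",
#'   "</ref-list></back></article>")
#' reg <- extract_references(xml2::read_xml(xml))
#' reg$entries$xml_pmid
#' @export
extract_references <- function(doc) {
  doc <- as_xml_doc(doc)
  refs <- xml2::xml_find_all(doc, ".//ref-list//ref | .//ref[not(ancestor::ref-list)]")
  if (length(refs) == 0) return(empty_registry())

  seen <- character(0)
  rows <- vector("list", length(refs))
  keep <- logical(length(refs))
  for (i in seq_along(refs)) {
    ref <- refs[[i]]
    rid <- chr1(xml2::xml_attr(ref, "id"))
    if (is.na(rid) || !nzchar(rid)) rid <- sprintf("__ref%d", i)
    if (rid %in% seen) {
      cite_warn("duplicate ref id '", rid, "' at positions ",
                match(rid, seen), " and ", i, "; keeping the first")
      next
    }
    seen <- c(seen, rid)
    keep[i] <- TRUE

    cites <- xml2::xml_find_all(
      ref, ".//*[contains(local-name(), 'citation')][@id]")
    member_ids <- setdiff(xml2::xml_attr(cites, "id"), rid)
    member_pmids <- vapply(member_ids, function(mid) {
      node <- xml2::xml_find_first(
        ref, sprintf(".//*[@id='%s']", mid))
      extract_pmid(node)
    }, character(1))

    raw_text <- normalize_ws(xml2::xml_text(ref))
    label_node <- xml2::xml_find_first(ref, "./label")
    label <- if (!inherits(label_node, "xml_missing")) {
      normalize_ws(xml2::xml_text(label_node))
    } else {
      m <- stringi::stri_match_first_regex(raw_text, "^(\\d+)")[, 2]
      chr1(m)
    }

    rows[[i]] <- list(
      ref_id = rid,
      label = chr1(label),
      xml_pmid = extract_pmid(ref),
      raw_text = raw_text,
      member_ids = list(member_ids),
      member_pmids = list(unname(member_pmids))
    )
  }
  rows <- rows[keep]
  entries <- data.table::rbindlist(rows)
  entries[, order_index := seq_len(.N)]
  data.table::setcolorder(entries, c("ref_id", "order_index", "label",
                                     "xml_pmid", "raw_text"))
  build_registry(entries)
}

empty_registry <- function() {
  entries <- data.table::data.table(
    ref_id = character(0), order_index = integer(0), label = character(0),
    xml_pmid = character(0), raw_text = character(0),
    member_ids = list(), member_pmids = list())
  structure(list(entries = entries, id_index = integer(0),
                 id_pmid = character(0), label_index = integer(0)),
            class = "ref_registry")
}

build_registry <- function(entries) {
  id_index <- integer(0)
  id_pmid <- character(0)
  for (i in seq_len(nrow(entries))) {
    rid <- entries$ref_id[i]
    mids <- entries$member_ids[[i]]
    mpmids <- entries$member_pmids[[i]]
    new_ids <- c(rid, mids)
    dup <- new_ids[new_ids %in% names(id_index)]
    if (length(dup)) {
      cite_warn("reference id(s) ", paste(dup, collapse = ", "),
                " appear under more than one entry; keeping the first")
      keep <- !(new_ids %in% names(id_index))
      new_pm <- c(entries$xml_pmid[i], mpmids)[keep]
      new_ids <- new_ids[keep]
    } else {
      new_pm <- c(entries$xml_pmid[i], mpmids)
    }
    idx <- rep.int(i, length(new_ids))
    names(idx) <- new_ids
    names(new_pm) <- new_ids
    id_index <- c(id_index, idx)
    id_pmid <- c(id_pmid, new_pm)
  }
  lab <- suppressWarnings(as.integer(entries$label))
  ok <- !is.na(lab) & !duplicated(lab)
  label_index <- structure(entries$order_index[ok], names = as.character(lab[ok]))
  structure(list(entries = entries, id_index = id_index,
                 id_pmid = id_pmid, label_index = label_index),
            class = "ref_registry")
}

#' @export
print.ref_registry <- function(x, ...) {
  cat(sprintf("<ref_registry> %d entries, %d indexed ids\n",
              nrow(x$entries), length(x$id_index)))
  invisible(x)
}

#' Number of entries in a reference registry
#' @param x a `ref_registry`
#' @export
length.ref_registry <- function(x) nrow(x$entries)

#' Extract the XML-tagged PMID of one reference element
#'
#' Returns the text of the first `<pub-id pub-id-type="pmid">` descendant,
#' whitespace-stripped. Non-numeric pub-id text (publisher tagging error)
#' yields `NA` with a warning; pub-ids in other id spaces (doi, pmcid, ...)
#' are ignored.
#'
#' @param node a `<ref>` or nested citation `xml_node` (or `xml_missing`).
#' @return a digit string or `NA_character_`.
#' @export
extract_pmid <- function(node) {
  if (is.null(node) || inherits(node, "xml_missing")) return(NA_character_)
  pid <- xml2::xml_find_first(node, ".//pub-id[@pub-id-type='pmid']")
  if (inherits(pid, "xml_missing")) return(NA_character_)
  txt <- stringi::stri_trim_both(xml2::xml_text(pid))
  if (!stringi::stri_detect_regex(txt, "^[0-9]{1,8}$")) {
    cite_warn("non-numeric or malformed pmid text '", txt, "'; ignored")
    return(NA_character_)
  }
  txt
}

## resolve one id to its entry position (NA when unknown)
registry_position <- function(registry, id) {
  pos <- registry$id_index[id]
  if (length(pos) == 0) NA_integer_ else unname(pos)
}

## per-id XML-tagged PMID (member ids get their own citation's pmid)
registry_pmid <- function(registry, id) {
  pm <- registry$id_pmid[id]
  if (length(pm) == 0) NA_character_ else unname(pm)
}

as_xml_doc <- function(doc) {
  if (inherits(doc, "xml_document") || inherits(doc, "xml_node")) return(doc)
  xml2::read_xml(doc)
}
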