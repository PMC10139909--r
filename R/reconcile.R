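# Reconciliation of cited-work identifiers.
#
# Three sources are combined per reference: the XML-tagged PMID, an
# Entrez-style list of PMIDs cited by the citing article, and a candidate-ID
# table from an external citation matcher (reference string -> candidate IDs
# with match probabilities and confirming public sources).  The outcome per
# reference is intxt_pmid_source, best_id, best_source and the categorical
# best_id_diff comparing the best ID against the XML-tagged PMID.

BEST_ID_DIFF_LEVELS <- c("SAME", "NONE", "INSERT", "SWAP", "DELETE",
                         "PMID_XML", "NONE_XML")

#' Default reconciliation thresholds
#'
#' `default`: minimum match probability for an unconfirmed PMID candidate.
#' `confirmed_pmid`: lower bar for PMID candidates confirmed by at least one
#' public source. `non_pmid`: bar for candidates in other id spaces.
#' `prefer_margin`: a non-PMID candidate displaces an eligible PMID only
#' when its probability exceeds the PMID's by at least this much.
#'
#' @return named list of numeric thresholds.
#' @export
default_thresholds <- function() {
  list(default = 0.997, confirmed_pmid = 0.99, non_pmid = 0.99,
       prefer_margin = 0.001)
}

#' Source indicator for an XML-tagged PMID
#'
#' `"xml,pmc"` when the XML-tagged PMID is confirmed by the Entrez cited-PMID
#' list of the citing article, `"xml"` when tagged but unconfirmed, and `NA`
#' when the reference carries no XML-tagged PMID.
#'
#' @param xml_pmid digit string or `NA`.
#' @param entrez_cited character vector of PMIDs cited by the citing article.
#' @return `"xml,pmc"`, `"xml"`, or `NA_character_`.
#' @export
pmid_source <- function(xml_pmid, entrez_cited = character(0)) {
  if (is.null(xml_pmid) || length(xml_pmid) == 0 || is.na(xml_pmid)) {
    return(NA_character_)
  }
  if (xml_pmid %in% entrez_cited) "xml,pmc" else "xml"
}

#' Select the best candidate identifier for one reference
#'
#' A candidate is eligible when its match probability reaches its applicable
#' threshold: the default for unconfirmed PMIDs, the lower `confirmed_pmid`
#' bar for PMIDs backed by at least one public source, and the `non_pmid`
#' bar otherwise. Among eligible candidates the best PMID wins unless the
#' best non-PMID's probability exceeds it by at least `prefer_margin`.
#'
#' @param candidates a `data.frame`/`data.table` of candidates sharing one
#'   reference key, with columns `candidate_id`, `id_space` (`"pmid"` or
#'   anything else), `probability`, and `confirmations` (list column or
#'   semicolon-joined string of source tokens).
#' @param thresholds see [default_thresholds()].
#' @return `NULL` when nothing is eligible, else a list with `id`,
#'   `id_space`, `probability`, `confirmations` (character vector).
#' @export
select_best <- function(candidates, thresholds = default_thresholds()) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  conf <- parse_confirmations(candidates$confirmations)
  is_pmid <- candidates$id_space == "pmid"
  thr <- ifelse(is_pmid,
                ifelse(lengths(conf) > 0, thresholds$confirmed_pmid,
                       thresholds$default),
                thresholds$non_pmid)
  eligible <- !is.na(candidates$probability) & candidates$probability >= thr
  if (!any(eligible)) return(NULL)

  pick <- function(idx) {
    if (length(idx) == 0) return(NULL)
    best <- idx[which.max(candidates$probability[idx])]
    list(id = as.character(candidates$candidate_id[best]),
         id_space = as.character(candidates$id_space[best]),
         probability = candidates$probability[best],
         confirmations = conf[[best]])
  }
  best_pmid <- pick(which(eligible & is_pmid))
  best_other <- pick(which(eligible & !is_pmid))
  if (is.null(best_pmid)) return(best_other)
  if (!is.null(best_other) &&
      best_other$probability >= best_pmid$probability + thresholds$prefer_margin) {
    return(best_other)
  }
  best_pmid
}

parse_confirmations <- function(x) {
  if (is.list(x)) {
    lapply(x, function(v) as.character(v[nzchar(v)]))
  } else {
    lapply(stringi::stri_split_fixed(ifelse(is.na(x), "", x), ";"),
           function(v) v[nzchar(v)])
  }
}

#' Classify the difference between the best ID and the XML-tagged PMID
#'
#' For cross-checked references (the matcher saw the reference): `SAME`
#' (both present and equal), `NONE` (neither), `INSERT` (best only), `SWAP`
#' (both, different), `DELETE` (XML only). For references the matcher never
#' saw: `PMID_XML` (XML-tagged PMID present; it becomes the best ID) or
#' `NONE_XML` (no identifier at all).
#'
#' @param best_id matcher-selected id or `NA`.
#' @param xml_pmid XML-tagged PMID or `NA`.
#' @param crosschecked was the reference cross-checked with the matcher?
#' @return one of `r paste(BEST_ID_DIFF_LEVELS, collapse = ", ")`.
#' @export
classify_diff <- function(best_id, xml_pmid, crosschecked) {
  hb <- !is.null(best_id) && length(best_id) > 0 && !is.na(best_id)
  hx <- !is.null(xml_pmid) && length(xml_pmid) > 0 && !is.na(xml_pmid)
  if (!crosschecked) {
    return(if (hx) "PMID_XML" else "NONE_XML")
  }
  if (hb && hx) {
    if (best_id == xml_pmid) "SAME" else "SWAP"
  } else if (hb) {
    "INSERT"
  } else if (hx) {
    "DELETE"
  } else {
    "NONE"
  }
}

#' Reconcile one article's references
#'
#' Computes, for every distinct resolvable reference id of an article, the
#' four reconciliation fields. All inline citations of one reference receive
#' identical values. With no candidate table the output degenerates to the
#' XML-tagged values (`PMID_XML`/`NONE_XML` only).
#'
#' @param ids character vector of reference ids (entry or nested member ids).
#' @param registry the article's [ref_registry][extract_references].
#' @param pmcid the citing article's PMCID (key into the external tables).
#' @param candidates optional candidate table for the whole batch (columns
#'   `pmcid`, `ref_id`, `candidate_id`, `id_space`, `probability`,
#'   `confirmations`).
#' @param entrez_cited optional character vector: PMIDs cited by this
#'   article according to Entrez-style citation data.
#' @param thresholds see [default_thresholds()].
#' @return a `data.table` keyed by `intxt_id` with columns `intxt_pmid`,
#'   `intxt_pmid_source`, `best_id`, `best_source`, `best_id_diff`.
#' @export
reconcile_ids <- function(ids, registry, pmcid, candidates = NULL,
                          entrez_cited = character(0),
                          thresholds = default_thresholds()) {
  ids <- unique(ids)
  out <- vector("list", length(ids))
  cand_dt <- if (!is.null(candidates)) {
    dt <- data.table::as.data.table(candidates)
    dt[dt$pmcid == pmcid]
  } else NULL

  for (i in seq_along(ids)) {
    id <- ids[i]
    xml_pmid <- registry_pmid(registry, id)
    src <- pmid_source(xml_pmid, entrez_cited)
    rows <- if (!is.null(cand_dt)) cand_dt[cand_dt$ref_id == id] else NULL
    crosschecked <- !is.null(rows) && nrow(rows) > 0
    if (crosschecked) {
      sel <- select_best(rows, thresholds)
      best_id <- if (is.null(sel)) NA_character_ else sel$id
      diff <- classify_diff(best_id, xml_pmid, TRUE)
      best_source <- if (is.null(sel)) {
        NA_character_
      } else {
        toks <- sel$confirmations
        if (!is.na(xml_pmid) && identical(sel$id, xml_pmid)) {
          toks <- c("xml", setdiff(toks, "xml"))
        }
        if (length(toks) == 0) toks <- "matcher"
        paste(toks, collapse = ",")
      }
    } else {
      diff <- classify_diff(NA_character_, xml_pmid, FALSE)
      best_id <- if (diff == "PMID_XML") xml_pmid else NA_character_
      best_source <- if (diff == "PMID_XML") src else NA_character_
    }
    out[[i]] <- data.table::data.table(
      intxt_id = id, intxt_pmid = xml_pmid, intxt_pmid_source = src,
      best_id = best_id, best_source = best_source, best_id_diff = diff)
  }
  data.table::rbindlist(out)
}

#' Fill the reconciliation columns of a record table
#'
#' @param records a record `data.table` from [build_records()].
#' @param registry the article's [ref_registry][extract_references].
#' @param candidates,entrez_cited,thresholds see [reconcile_ids()].
#' @return the records, with `intxt_pmid_source`, `best_id`, `best_source`,
#'   `best_id_diff` filled for every citing row.
#' @export
reconcile_records <- function(records, registry, candidates = NULL,
                              entrez_cited = character(0),
                              thresholds = default_thresholds()) {
  if (nrow(records) == 0) return(records)
  citing <- which(!is.na(records$intxt_id))
  if (length(citing) == 0) return(records)
  pmcid <- records$pmcid[1]
  rec <- reconcile_ids(unique(records$intxt_id[citing]), registry, pmcid,
                       candidates, entrez_cited, thresholds)
  m <- match(records$intxt_id[citing], rec$intxt_id)
  for (col in c("intxt_pmid_source", "best_id", "best_source", "best_id_diff")) {
    data.table::set(records, i = citing, j = col, value = rec[[col]][m])
  }
  records
}
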