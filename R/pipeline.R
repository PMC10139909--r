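# End-to-end processing of a single article.

#' Pipeline configuration
#'
#' Bundles every tunable of the extraction pipeline. Serializable to/from a
#' JSON config file (see [read_config()]).
#'
#' @param imrad_rules cue rule set, see [imrad_rules()].
#' @param location_labels component label table, see
#'   [default_location_labels()].
#' @param thresholds reconciliation thresholds, see [default_thresholds()].
#' @param abbreviations tokenizer abbreviation list, see
#'   [default_abbreviations()].
#' @return a list of class `citancer_config`.
#' @export
default_config <- function(imrad_rules = citancer::imrad_rules(),
                           location_labels = default_location_labels(),
                           thresholds = default_thresholds(),
                           abbreviations = default_abbreviations()) {
  structure(list(imrad_rules = imrad_rules,
                 location_labels = location_labels,
                 thresholds = thresholds,
                 abbreviations = abbreviations),
            class = "citancer_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Any subset of the four config blocks (`imrad_rules`, `location_labels`,
#' `thresholds`, `abbreviations`) may be given; missing blocks keep their
#' defaults.
#'
#' @param path JSON file.
#' @return a `citancer_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  if (!is.null(raw$imrad_rules)) {
    cfg$imrad_rules <- structure(lapply(raw$imrad_rules, as.character),
                                 class = "imrad_rules")
  }
  if (!is.null(raw$location_labels)) {
    cfg$location_labels <- unlist(raw$location_labels)
  }
  if (!is.null(raw$thresholds)) {
    cfg$thresholds <- utils::modifyList(cfg$thresholds,
                                        lapply(raw$thresholds, as.numeric))
  }
  if (!is.null(raw$abbreviations)) {
    cfg$abbreviations <- as.character(raw$abbreviations)
  }
  cfg
}

#' Citing-article identifiers from the front matter
#' @param doc an `xml_document`.
#' @return list with `pmcid` and `pmid` (either may be `NA`).
#' @export
article_ids <- function(doc) {
  doc <- as_xml_doc(doc)
  get_id <- function(type) {
    n <- xml2::xml_find_first(
      doc, sprintf(".//front//article-meta/article-id[@pub-id-type='%s']",
                   type))
    if (inherits(n, "xml_missing")) NA_character_ else
      normalize_ws(xml2::xml_text(n))
  }
  pmcid <- get_id("pmc")
  if (is.na(pmcid)) pmcid <- get_id("pmcid")
  if (!is.na(pmcid)) {
    pmcid <- stringi::stri_replace_first_regex(pmcid, "^PMC", "")
  }
  list(pmcid = pmcid, pmid = get_id("pmid"))
}

#' Process one JATS article into sentence records
#'
#' Runs the whole pipeline on one document: reference extraction, component
#' segmentation, inline-citation detection (explicit and implicit),
#' IMRaD labelling, sentence splitting, record assembly, and identifier
#' reconciliation.
#'
#' @param doc path to an XML file, an XML string, or an `xml_document`.
#' @param candidates optional matcher candidate table (see
#'   [reconcile_ids()]); `NULL` disables cross-checking (`PMID_XML` /
#'   `NONE_XML` mode).
#' @param entrez optional Entrez-style cited table with columns `pmcid`,
#'   `cited_pmid`, or a plain character vector of cited PMIDs.
#' @param config a [default_config()] list.
#' @param progression_mode `"component"` or `"maintext"`, see
#'   [build_records()].
#' @param contexts_only drop rows without an inline citation.
#' @return a list of class `citancer_result`:
#'   `records` (the sentence `data.table`), `registry`, and `counts`
#'   (named integer vector: references, explicit/implicit citations,
#'   sentences, citation contexts, references without contexts).
#' @examples
#' art <- generate_article(dialect_config(n_refs = 6, seed = 42))
#' res <- process_article(art$xml)
#' res$counts
#' @export
process_article <- function(doc, candidates = NULL, entrez = NULL,
                            config = default_config(),
                            progression_mode = c("component", "maintext"),
                            contexts_only = FALSE) {
  progression_mode <- match.arg(progression_mode)
  doc <- as_xml_doc(doc)
  ids <- article_ids(doc)
  registry <- extract_references(doc)
  fragments <- segment(doc)

  ann_fragments <- lapply(fragments, function(f) {
    ann <- annotate_markers(f, registry)
    f$imrad <- label_fragment(f, config$imrad_rules)
    if (f$fragment_kind == "table_cell") {
      sentences <- ann$text # one cell = one sentence, no tokenization
    } else {
      sentences <- tokenize(ann$text, config$abbreviations)
    }
    f$sentences <- sentences
    f$citations_by_sentence <- assign_citations(sentences, ann)
    f
  })

  ctx <- list(pmcid = ids$pmcid, pmid = ids$pmid, fragments = ann_fragments)
  records <- build_records(ctx, registry,
                           location_labels = config$location_labels,
                           progression_mode = progression_mode)

  entrez_cited <- entrez_cited_for(entrez, ids$pmcid)
  records <- reconcile_records(records, registry, candidates,
                               entrez_cited, config$thresholds)
  counts <- summarize_counts(ann_fragments, registry)
  if (contexts_only && nrow(records) > 0) {
    records <- records[!is.na(records$intxt_id)]
  }
  structure(list(records = records, registry = registry, counts = counts,
                 pmcid = ids$pmcid, pmid = ids$pmid),
            class = "citancer_result")
}

#' @export
print.citancer_result <- function(x, ...) {
  cat(sprintf("<citancer_result> pmcid=%s: %d rows, %d references\n",
              x$pmcid, nrow(x$records), x$counts[["n_references"]]))
  invisible(x)
}

## split fragment-level citations onto sentences by token span
assign_citations <- function(sentences, ann) {
  cit <- ann$citations
  if (length(sentences) == 0) return(list())
  if (is.null(cit) || nrow(cit) == 0) {
    return(rep(list(empty_citation_table()), length(sentences)))
  }
  ## sentence char offsets in the annotated fragment text (sentences are
  ## consecutive substrings separated by single spaces)
  starts <- integer(length(sentences))
  ends <- integer(length(sentences))
  pos <- 1L
  for (i in seq_along(sentences)) {
    len <- stringi::stri_length(sentences[i])
    starts[i] <- pos
    ends[i] <- pos + len - 1L
    pos <- ends[i] + 2L
  }
  lapply(seq_along(sentences), function(i) {
    sel <- !is.na(cit$start) & cit$start >= starts[i] & cit$start <= ends[i]
    cit[sel]
  })
}

entrez_cited_for <- function(entrez, pmcid) {
  if (is.null(entrez)) return(character(0))
  if (is.character(entrez)) return(entrez)
  dt <- data.table::as.data.table(entrez)
  as.character(dt$cited_pmid[dt$pmcid == pmcid])
}

summarize_counts <- function(ann_fragments, registry) {
  n_refs <- nrow(registry$entries)
  n_sentences <- 0L
  n_contexts <- 0L
  n_explicit <- 0L
  n_implicit <- 0L
  cited_pos <- integer(0)
  for (f in ann_fragments) {
    n_sentences <- n_sentences + length(f$sentences)
    for (cit in f$citations_by_sentence) {
      if (nrow(cit) > 0) {
        n_contexts <- n_contexts + 1L
        n_explicit <- n_explicit + sum(!cit$implicit)
        n_implicit <- n_implicit + sum(cit$implicit)
        pos <- registry$id_index[cit$intxt_id]
        cited_pos <- c(cited_pos, unname(pos[!is.na(pos)]))
      }
    }
  }
  c(n_references = as.integer(n_refs),
    n_sentences = n_sentences,
    n_citation_contexts = n_contexts,
    n_explicit_citations = n_explicit,
    n_implicit_citations = n_implicit,
    n_inline_citations = n_explicit + n_implicit,
    n_refs_without_context = as.integer(n_refs - length(unique(cited_pos))))
}
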