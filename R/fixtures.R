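# Synthetic JATS article generator with ground-truth manifests.
#
# Articles are assembled from a fixed template vocabulary (deterministic
# tokenizer behaviour), with citations planted according to a dialect
# config: flat or nested reference lists, both implicit-range tagging
# styles, all recognized separator variants, and fault injection (markers
# left as plain strings, PMIDs present in the text but untagged).  The
# manifest enumerates every expected output row by construction, so
# pipeline(xml) == manifest is the central end-to-end oracle whenever all
# fault rates are zero.

SEPARATOR_SET <- c("-", "\u2013", "\u2212", "--")

#' Dialect configuration for the article generator
#'
#' @param n_refs number of bibliography entries (default 30, around the
#'   corpus-typical reference-list size).
#' @param nested_ref_rate probability that an entry is a nested multi-work
#'   reference (two tagged member citations).
#' @param implicit_style `"none"`, `"paired_xref"`, `"single_xref"`, or
#'   `"mixed"` — how numeric citation ranges are tagged.
#' @param separator one of `-`, en dash, minus sign, `--`, or `"random"`.
#' @param missing_xref_rate probability that a single-citation marker is
#'   left as a plain string (no xref) — the reference then has no
#'   identifiable citation context.
#' @param untagged_pmid_rate probability that a flat entry's PMID appears
#'   only in the citation string, with no `<pub-id>` tag.
#' @param n_body_sections number of body sections (titles cycle through
#'   IMRaD cue titles and NoIMRaD decoys).
#' @param include_tables,include_figures,include_back include a table (with
#'   caption, cells, and one citing cell), a figure caption, and back
#'   matter.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return a list of class `dialect_config`.
#' @export
dialect_config <- function(n_refs = 30L, nested_ref_rate = 0,
                           implicit_style = c("none", "paired_xref",
                                              "single_xref", "mixed"),
                           separator = "-",
                           missing_xref_rate = 0, untagged_pmid_rate = 0,
                           n_body_sections = 4L,
                           include_tables = TRUE, include_figures = TRUE,
                           include_back = TRUE, seed = 1L) {
  implicit_style <- match.arg(implicit_style)
  stopifnot(n_refs >= 1, n_body_sections >= 1,
            nested_ref_rate >= 0, nested_ref_rate <= 1,
            missing_xref_rate >= 0, missing_xref_rate <= 1,
            untagged_pmid_rate >= 0, untagged_pmid_rate <= 1,
            separator == "random" || separator %in% SEPARATOR_SET)
  structure(list(n_refs = as.integer(n_refs),
                 nested_ref_rate = nested_ref_rate,
                 implicit_style = implicit_style, separator = separator,
                 missing_xref_rate = missing_xref_rate,
                 untagged_pmid_rate = untagged_pmid_rate,
                 n_body_sections = as.integer(n_body_sections),
                 include_tables = include_tables,
                 include_figures = include_figures,
                 include_back = include_back, seed = as.integer(seed)),
            class = "dialect_config")
}

## run expr under a seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

xml_escape <- function(x) {
  x <- stringi::stri_replace_all_fixed(x, "&", "&amp;")
  x <- stringi::stri_replace_all_fixed(x, "<", "&lt;")
  stringi::stri_replace_all_fixed(x, ">", "&gt;")
}

gen_fillers <- function() c(
  "Bone homeostasis depends on a tight balance between resorption and formation.",
  "Osteoclast activity increases markedly under inflammatory conditions.",
  "The signalling cascade is modulated by several extracellular factors.",
  "These observations motivated a systematic comparison across cohorts.",
  "Samples were collected at baseline and after twelve weeks.",
  "The assay followed the protocol of Kim et al. with minor modifications.",
  "Measurements were repeated in three independent replicates.",
  "Expression levels varied substantially between treatment groups.",
  "The model captures the dominant features of the observed kinetics.",
  "Further work is required to establish causality.")

gen_citing_templates <- function() c(
  "Previous studies reported consistent findings %s.",
  "This mechanism has been described in detail %s.",
  "Similar results were obtained in related cohorts %s.",
  "The approach builds on earlier methodology %s.",
  "Comparable effects were documented elsewhere %s.")

## (title, sec_type, expected IMRaD) cycle for body sections; decoys are
## deliberate NoIMRaD titles
gen_section_table <- function() list(
  list(title = "Introduction", sec_type = "", imrad = "I"),
  list(title = "Materials and Methods", sec_type = "", imrad = "M"),
  list(title = "Results", sec_type = "", imrad = "R"),
  list(title = "Discussion", sec_type = "", imrad = "D"),
  list(title = "Patient cohort", sec_type = "methods", imrad = "M"),
  list(title = "Limitations", sec_type = "", imrad = "NoIMRaD"),
  list(title = "Background", sec_type = "", imrad = "I"),
  list(title = "Concluding remarks", sec_type = "", imrad = "D"),
  list(title = "Ethical considerations", sec_type = "", imrad = "NoIMRaD"))

#' Generate one synthetic JATS article with its ground-truth manifest
#'
#' @param config a [dialect_config()].
#' @return a list of class `synthetic_article`:
#'   \describe{
#'     \item{xml}{the article as an XML string.}
#'     \item{manifest}{`data.table` of the expected sentence records
#'       (identical schema to [build_records()] output after
#'       reconciliation without external inputs).}
#'     \item{registry}{`data.table` of expected reference entries
#'       (`ref_id`, `label`, `xml_pmid`, `n_members`).}
#'     \item{ref_flags}{`data.table` (`ref_id`, `has_inline_citation`).}
#'     \item{config}{the input config.}
#'   }
#' @export
generate_article <- function(config = dialect_config()) {
  stopifnot(inherits(config, "dialect_config"))
  with_seed(config$seed, generate_article_impl(config))
}

generate_article_impl <- function(config) {
  n <- config$n_refs
  pmcid <- sprintf("%d", 1000000L + (config$seed %% 8999999L))
  pmid_citing <- sprintf("%d", 90000000L + (config$seed %% 9999999L))
  pmid_base <- 10000000L + (config$seed %% 997L) * 1000L

  ## ---- reference list plan ------------------------------------------
  refs <- vector("list", n)
  for (i in seq_len(n)) {
    nested <- stats::runif(1) < config$nested_ref_rate
    untagged <- !nested && stats::runif(1) < config$untagged_pmid_rate
    base_pm <- pmid_base + i * 10L
    if (nested) {
      members <- list(
        list(id = sprintf("B%da", i), pmid = sprintf("%d", base_pm + 1L)),
        list(id = sprintf("B%db", i), pmid = sprintf("%d", base_pm + 2L)))
      xml_pmid <- members[[1]]$pmid # first pub-id descendant of the ref
    } else {
      members <- list()
      xml_pmid <- if (untagged) NA_character_ else sprintf("%d", base_pm)
    }
    refs[[i]] <- list(ref_id = sprintf("B%d", i), label = i,
                      nested = nested, untagged = untagged,
                      members = members, xml_pmid = xml_pmid,
                      pmid_digits = sprintf("%d", base_pm))
  }

  ## id used when a single explicit xref cites entry i (member for nested)
  single_target <- function(i) {
    if (refs[[i]]$nested) refs[[i]]$members[[1]]$id else refs[[i]]$ref_id
  }
  ## XML-tagged PMID attached to a given resolvable id
  pmid_of_id <- function(id) {
    for (r in refs) {
      if (r$ref_id == id) return(r$xml_pmid)
      for (m in r$members) if (m$id == id) return(m$pmid)
    }
    NA_character_
  }

  ## ---- citation slots ------------------------------------------------
  pick_sep <- function() {
    if (config$separator == "random") {
      SEPARATOR_SET[sample.int(length(SEPARATOR_SET), 1L)]
    } else config$separator
  }
  slots <- list()
  add_slot <- function(kind, entries, sep = NULL) {
    slots[[length(slots) + 1L]] <<- list(kind = kind, entries = entries,
                                         sep = sep)
  }
  reserved_abs <- 1L
  reserved_fig <- if (config$include_figures && n >= 4L) 2L else NA_integer_
  reserved_tbl <- if (config$include_tables && n >= 5L) n else NA_integer_
  body_entries <- setdiff(seq_len(n),
                          c(reserved_abs, reserved_fig, reserved_tbl))
  body_entries <- body_entries[!is.na(body_entries)]

  range_styles <- switch(config$implicit_style,
                         none = character(0),
                         paired_xref = "paired",
                         single_xref = "srange",
                         mixed = c("paired", "srange", "none"))
  style_i <- 0L
  i <- 1L
  while (i <= length(body_entries)) {
    ## maximal run of consecutive entries starting at i
    j <- i
    while (j < length(body_entries) &&
           body_entries[j + 1L] == body_entries[j] + 1L) j <- j + 1L
    run <- body_entries[i:j]
    while (length(run) > 0) {
      w <- min(4L, length(run))
      use_range <- length(range_styles) > 0 && w >= 3L
      if (use_range) {
        style_i <- style_i + 1L
        st <- range_styles[((style_i - 1L) %% length(range_styles)) + 1L]
        if (st == "none") {
          for (e in run[seq_len(w)]) add_slot("single", e)
        } else {
          add_slot(st, run[seq_len(w)], sep = pick_sep())
        }
      } else {
        for (e in run[seq_len(w)]) add_slot("single", e)
      }
      run <- run[-seq_len(w)]
    }
    i <- j + 1L
  }

  ## missing-marker fault: single-citation slots only (ranges stay intact)
  for (k in seq_along(slots)) {
    if (slots[[k]]$kind == "single" &&
        stats::runif(1) < config$missing_xref_rate) {
      slots[[k]]$kind <- "missing"
    }
  }
  abs_missing <- stats::runif(1) < config$missing_xref_rate
  fig_missing <- stats::runif(1) < config$missing_xref_rate
  tbl_missing <- stats::runif(1) < config$missing_xref_rate

  ## ---- render one slot: xml snippet + annotated text + citations -----
  token <- function(id) paste0("|", id, "|")
  render_slot <- function(slot) {
    es <- slot$entries
    if (slot$kind == "missing") {
      lbl <- sprintf("[%d]", es[1])
      return(list(xml = xml_escape(lbl), ann = lbl, citations = list()))
    }
    if (slot$kind == "single") {
      id <- single_target(es[1])
      xml <- sprintf("[<xref ref-type=\"bibr\" rid=\"%s\">%d</xref>]",
                     id, es[1])
      ann <- sprintf("[%s]", token(id))
      return(list(xml = xml, ann = ann, citations = list(
        list(intxt_id = id, intxt_mark = sprintf("%d", es[1]),
             implicit = FALSE))))
    }
    a <- es[1]; b <- es[length(es)]; sep <- slot$sep
    interior <- es[-c(1, length(es))]
    if (slot$kind == "paired") {
      mark_range <- paste0(a, sep, b)
      xml <- sprintf(paste0(
        "[<xref ref-type=\"bibr\" rid=\"B%d\">%d</xref>%s",
        "<xref ref-type=\"bibr\" rid=\"B%d\">%d</xref>]"),
        a, a, xml_escape(sep), b, b)
      imp_tok <- paste(vapply(interior, function(e) token(sprintf("B%d", e)),
                              character(1)), collapse = ",")
      ann <- sprintf("[%s%s%s,%s]", token(sprintf("B%d", a)), sep,
                     token(sprintf("B%d", b)), imp_tok)
      cits <- c(
        list(list(intxt_id = sprintf("B%d", a),
                  intxt_mark = sprintf("%d", a), implicit = FALSE),
             list(intxt_id = sprintf("B%d", b),
                  intxt_mark = sprintf("%d", b), implicit = FALSE)),
        lapply(interior, function(e) {
          list(intxt_id = sprintf("B%d", e), intxt_mark = mark_range,
               implicit = TRUE)
        }))
      return(list(xml = xml, ann = ann, citations = cits))
    }
    ## single_xref range: one xref labelled "a-b"; b and interior implicit
    mark_range <- paste0(a, sep, b)
    tail_entries <- es[-1]
    xml <- sprintf("[<xref ref-type=\"bibr\" rid=\"B%d\">%s</xref>]",
                   a, xml_escape(mark_range))
    imp_tok <- paste(vapply(tail_entries, function(e) token(sprintf("B%d", e)),
                            character(1)), collapse = ",")
    ann <- sprintf("[%s%s%s]", token(sprintf("B%d", a)), sep, imp_tok)
    cits <- c(
      list(list(intxt_id = sprintf("B%d", a), intxt_mark = mark_range,
                implicit = FALSE)),
      lapply(tail_entries, function(e) {
        list(intxt_id = sprintf("B%d", e), intxt_mark = mark_range,
             implicit = TRUE)
      }))
    list(xml = xml, ann = ann, citations = cits)
  }

  ## ---- compose sentences per fragment --------------------------------
  fillers <- gen_fillers()
  citing_templates <- gen_citing_templates()
  filler <- function() fillers[sample.int(length(fillers), 1L)]
  citing_sentence <- function(slot) {
    tpl <- citing_templates[sample.int(length(citing_templates), 1L)]
    r <- render_slot(slot)
    list(xml = sprintf(xml_escape(tpl), r$xml),
         ann = sprintf(tpl, r$ann),
         citations = r$citations)
  }
  plain_sentence <- function() {
    s <- filler()
    list(xml = xml_escape(s), ann = s, citations = list())
  }

  ## fragments accumulate as: component, instance, imrad, kind,
  ## sentences (each a list(xml, ann, citations))
  fragments <- list()
  add_fragment <- function(component, instance, imrad, kind, sentences) {
    fragments[[length(fragments) + 1L]] <<- list(
      component = component, instance = instance, imrad = imrad,
      kind = kind, sentences = sentences)
  }

  ## abstract: two paragraphs, citation in the second
  abs_slot <- list(kind = if (abs_missing) "missing" else "single",
                   entries = reserved_abs)
  add_fragment("abstract", "abstract", "NoIMRaD", "paragraph",
               list(plain_sentence(), plain_sentence()))
  add_fragment("abstract", "abstract", "NoIMRaD", "paragraph",
               list(citing_sentence(abs_slot)))

  ## body sections: distribute body slots round-robin
  sect_tab <- gen_section_table()
  nsec <- config$n_body_sections
  sec_defs <- lapply(seq_len(nsec), function(s) {
    sect_tab[[((s - 1L) %% length(sect_tab)) + 1L]]
  })
  slot_sec <- if (length(slots)) ((seq_along(slots) - 1L) %% nsec) + 1L
              else integer(0)
  body_secs <- vector("list", nsec)
  for (s in seq_len(nsec)) {
    sec <- sec_defs[[s]]
    sl <- slots[slot_sec == s]
    sentences <- list(plain_sentence())
    for (slot in sl) sentences[[length(sentences) + 1L]] <- citing_sentence(slot)
    sentences[[length(sentences) + 1L]] <- plain_sentence()
    add_fragment("body", "body", sec$imrad, "paragraph", sentences)
    body_secs[[s]] <- list(def = sec, sentences = sentences)
  }

  ## table: caption + 2x2 cells (one citing, one extra empty cell in XML)
  last_imrad <- sec_defs[[nsec]]$imrad
  tbl <- NULL
  if (config$include_tables && !is.na(reserved_tbl)) {
    tbl_slot <- list(kind = if (tbl_missing) "missing" else "single",
                     entries = reserved_tbl)
    cite_cell <- render_slot(tbl_slot)
    cells <- list(
      list(xml = "Group", ann = "Group", citations = list()),
      list(xml = "Effect size", ann = "Effect size", citations = list()),
      list(xml = "Treated", ann = "Treated", citations = list()),
      list(xml = sprintf("p &lt; 0.05 %s", cite_cell$xml),
           ann = sprintf("p < 0.05 %s", cite_cell$ann),
           citations = cite_cell$citations))
    cap <- list(xml = "Baseline characteristics of the study cohort.",
                ann = "Baseline characteristics of the study cohort.",
                citations = list())
    add_fragment("table", "table:1", last_imrad, "caption", list(cap))
    for (cell in cells) {
      add_fragment("table", "table:1", last_imrad, "table_cell", list(cell))
    }
    tbl <- cells
  }

  ## figure caption: two sentences, second citing
  fig <- NULL
  if (config$include_figures && !is.na(reserved_fig)) {
    fig_slot <- list(kind = if (fig_missing) "missing" else "single",
                     entries = reserved_fig)
    fig_sent <- list(plain_sentence(), citing_sentence(fig_slot))
    add_fragment("figure", "figure:1", last_imrad, "caption", fig_sent)
    fig <- fig_sent
  }

  ## back matter: acknowledgement paragraph, no citations
  back_sent <- NULL
  if (config$include_back) {
    back_sent <- list(plain_sentence(), plain_sentence())
    add_fragment("back", "back", "NoIMRaD", "paragraph", back_sent)
  }

  ## ---- serialize the XML ---------------------------------------------
  join_xml <- function(sents) paste(vapply(sents, `[[`, "", "xml"),
                                    collapse = " ")
  ref_xml <- vapply(refs, function(r) {
    if (r$nested) {
      members <- paste(vapply(r$members, function(m) {
        sprintf(paste0("<mixed-citation id=\"%s\">Author %s and others ",
                       "(2015) Collected works. <pub-id ",
                       "pub-id-type=\"pmid\">%s</pub-id></mixed-citation>"),
                m$id, m$id, m$pmid)
      }, character(1)), collapse = "")
      sprintf("<ref id=\"%s\"><label>%d</label>%s</ref>",
              r$ref_id, r$label, members)
    } else if (r$untagged) {
      sprintf(paste0("<ref id=\"%s\"><label>%d</label><mixed-citation>",
                     "Author %s (2016) A study of interest. PMID %s",
                     "</mixed-citation></ref>"),
              r$ref_id, r$label, r$ref_id, r$pmid_digits)
    } else {
      sprintf(paste0("<ref id=\"%s\"><label>%d</label><mixed-citation>",
                     "Author %s (2016) A study of interest. <pub-id ",
                     "pub-id-type=\"pmid\">%s</pub-id></mixed-citation></ref>"),
              r$ref_id, r$label, r$ref_id, r$pmid_digits)
    }
  }, character(1))

  sec_xml <- vapply(seq_len(nsec), function(s) {
    sec <- sec_defs[[s]]
    attr_st <- if (nzchar(sec$sec_type)) {
      sprintf(" sec-type=\"%s\"", sec$sec_type)
    } else ""
    inner <- sprintf("<p>%s</p>", join_xml(body_secs[[s]]$sentences))
    if (s == nsec && !is.null(tbl)) {
      inner <- paste0(inner, sprintf(paste0(
        "<table-wrap id=\"T1\"><label>Table 1</label><caption><p>",
        "Baseline characteristics of the study cohort.</p></caption>",
        "<table><tbody>",
        "<tr><td>%s</td><td>%s</td><td></td></tr>",
        "<tr><td>%s</td><td>%s</td></tr>",
        "</tbody></table></table-wrap>"),
        tbl[[1]]$xml, tbl[[2]]$xml, tbl[[3]]$xml, tbl[[4]]$xml))
    }
    if (s == nsec && !is.null(fig)) {
      inner <- paste0(inner, sprintf(paste0(
        "<fig id=\"F1\"><label>Fig. 1</label><caption><p>%s</p>",
        "</caption></fig>"), join_xml(fig)))
    }
    sprintf("<sec%s><title>%s</title>%s</sec>", attr_st, sec$title, inner)
  }, character(1))

  abstract_xml <- sprintf("<abstract><p>%s</p><p>%s</p></abstract>",
                          join_xml(fragments[[1]]$sentences),
                          join_xml(fragments[[2]]$sentences))
  back_xml <- paste0(
    if (!is.null(back_sent)) {
      sprintf("<ack><title>Acknowledgements</title><p>%s</p></ack>",
              join_xml(back_sent))
    } else "",
    "<ref-list><title>References</title>",
    paste(ref_xml, collapse = ""), "</ref-list>")

  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<article article-type=\"research-article\"><front>",
    "<journal-meta><journal-title-group><journal-title>",
    "Journal of Synthetic Osteology</journal-title></journal-title-group>",
    "</journal-meta><article-meta>",
    sprintf("<article-id pub-id-type=\"pmc\">%s</article-id>", pmcid),
    sprintf("<article-id pub-id-type=\"pmid\">%s</article-id>", pmid_citing),
    "<title-group><article-title>A synthetic study of bone remodelling",
    "</article-title></title-group>",
    abstract_xml,
    "</article-meta></front><body>",
    paste(sec_xml, collapse = ""),
    "</body><back>", back_xml, "</back></article>")

  ## ---- manifest -------------------------------------------------------
  manifest <- manifest_from_fragments(fragments, pmcid, pmid_citing,
                                      pmid_of_id)

  cited <- unique(unlist(lapply(fragments, function(f) {
    unlist(lapply(f$sentences, function(s) {
      vapply(s$citations, `[[`, "", "intxt_id")
    }))
  })))
  owner <- function(id) {
    for (r in refs) {
      if (r$ref_id == id) return(r$ref_id)
      for (m in r$members) if (m$id == id) return(r$ref_id)
    }
    NA_character_
  }
  cited_entries <- unique(vapply(cited, owner, character(1)))
  ref_flags <- data.table::data.table(
    ref_id = vapply(refs, `[[`, "", "ref_id"),
    has_inline_citation = vapply(refs, `[[`, "", "ref_id") %in% cited_entries)

  registry <- data.table::data.table(
    ref_id = vapply(refs, `[[`, "", "ref_id"),
    label = as.character(vapply(refs, `[[`, 1L, "label")),
    xml_pmid = vapply(refs, function(r) chr1(r$xml_pmid), character(1)),
    n_members = vapply(refs, function(r) length(r$members), integer(1)))

  structure(list(xml = xml, manifest = manifest, registry = registry,
                 ref_flags = ref_flags, config = config),
            class = "synthetic_article")
}

## expected sentence records from the generator's fragment plan
manifest_from_fragments <- function(fragments, pmcid, pmid_citing,
                                    pmid_of_id) {
  sent_rows <- list()
  for (f in fragments) {
    for (s in f$sentences) {
      sent_rows[[length(sent_rows) + 1L]] <- list(
        instance = f$instance, component = f$component, imrad = f$imrad,
        ann = s$ann, citations = s$citations)
    }
  }
  if (length(sent_rows) == 0) return(empty_records())
  inst <- vapply(sent_rows, `[[`, "", "instance")
  sid <- stats::ave(seq_along(sent_rows), inst, FUN = seq_along)
  tot <- stats::ave(seq_along(sent_rows), inst, FUN = length)
  labels <- default_location_labels()

  out <- vector("list", length(sent_rows))
  for (i in seq_along(sent_rows)) {
    r <- sent_rows[[i]]
    comp <- c(abstract = "abstract", body = "body", table = "table",
              figure = "figure", back = "back")[r$component]
    base <- list(
      pmcid = pmcid, pmid = pmid_citing,
      location = unname(labels[comp]), IMRaD = r$imrad,
      sentence_id = as.integer(sid[i]), total_sentences = as.integer(tot[i]),
      progression = compute_progression(sid[i], tot[i]),
      text = r$ann)
    mk <- function(cit) {
      pm <- if (is.null(cit)) NA_character_ else pmid_of_id(cit$intxt_id)
      data.table::data.table(
        pmcid = base$pmcid, pmid = base$pmid, location = base$location,
        IMRaD = base$IMRaD, sentence_id = base$sentence_id,
        total_sentences = base$total_sentences,
        intxt_id = if (is.null(cit)) NA_character_ else cit$intxt_id,
        intxt_pmid = pm,
        intxt_pmid_source = if (!is.null(cit) && !is.na(pm)) "xml"
                            else NA_character_,
        intxt_mark = if (is.null(cit)) NA_character_ else cit$intxt_mark,
        best_id = if (!is.null(cit) && !is.na(pm)) pm else NA_character_,
        best_source = if (!is.null(cit) && !is.na(pm)) "xml"
                      else NA_character_,
        best_id_diff = if (is.null(cit)) NA_character_
                       else if (!is.na(pm)) "PMID_XML" else "NONE_XML",
        progression = base$progression, text = base$text)
    }
    out[[i]] <- if (length(r$citations) == 0) {
      mk(NULL)
    } else {
      data.table::rbindlist(lapply(r$citations, mk))
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, names(empty_records()))
  res
}

#' Generate a deterministic corpus of synthetic articles
#'
#' Cycles through a grid of dialect overrides; per-article seeds are derived
#' reproducibly from the master seed, so the same call is byte-identical.
#'
#' @param n_articles number of articles.
#' @param config_grid a list of lists of [dialect_config()] argument
#'   overrides (recycled over articles); `NULL` for all-default articles.
#' @param seed master seed.
#' @return list of `synthetic_article` objects.
#' @export
generate_corpus <- function(n_articles, config_grid = NULL, seed = 1L) {
  if (n_articles == 0) return(list())
  if (is.null(config_grid)) config_grid <- list(list())
  lapply(seq_len(n_articles), function(i) {
    overrides <- config_grid[[((i - 1L) %% length(config_grid)) + 1L]]
    overrides$seed <- as.integer(
      (as.numeric(seed) * 1009 + 7919 * i) %% 2147483647)
    cfg <- do.call(dialect_config, overrides)
    generate_article(cfg)
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits `article_<k>.xml` per article, a combined `manifest.tsv` in the
#' pipeline's output schema, and a `configs.json` sidecar.
#'
#' @param corpus output of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifests <- list()
  configs <- list()
  for (i in seq_along(corpus)) {
    art <- corpus[[i]]
    writeLines(art$xml, file.path(dir, sprintf("article_%03d.xml", i)),
               useBytes = TRUE)
    manifests[[i]] <- art$manifest
    configs[[i]] <- unclass(art$config)
  }
  if (length(manifests)) {
    write_tsv(data.table::rbindlist(manifests),
              file.path(dir, "manifest.tsv"))
  }
  jsonlite::write_json(configs, file.path(dir, "configs.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
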