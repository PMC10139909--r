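# Component segmentation.
#
# An article is split into five component kinds: abstract, body (main text),
# table, figure, and back matter.  Within each, text fragments (paragraphs,
# quote blocks, captions, table cells) are collected in document order with
# their enclosing <sec> context.  Fragments keep their xml node so that the
# citation annotator still sees <xref> structure; inline formatting is
# flattened only when text is finally pulled.

COMPONENT_KINDS <- c("abstract", "body", "table", "figure", "back")
FRAGMENT_KINDS <- c("paragraph", "quote", "caption", "table_cell")

#' Segment a JATS article into ordered text fragments
#'
#' Identifies the article components — abstracts (`front//abstract`,
#' `front//trans-abstract`), main text (`body`), tables (`table-wrap`, and
#' `tbody` under `array`), figures (`fig`), and back matter (`back`) — and
#' collects their paragraphs, quote blocks, captions and table cells in
#' document order. Tables and figures nested in body paragraphs are lifted
#' out as their own component instances.
#'
#' @param doc an `xml_document` or something [xml2::read_xml()] accepts.
#' @return a list of fragments; each fragment is a list with fields
#'   `component` (one of `r paste(COMPONENT_KINDS, collapse = ", ")`),
#'   `fragment_kind` (`paragraph`, `quote`, `caption`, `table_cell`),
#'   `instance` (component-instance key, e.g. `"table:1"`), `node` (the
#'   `xml_node`), `text` (whitespace-normalized visible text),
#'   `section_path` (a `data.frame` from [section_context_of()]) and
#'   `order_index` (1-based within the component instance).
#' @export
segment <- function(doc) {
  doc <- as_xml_doc(doc)
  frags <- list()
  counters <- new.env(parent = emptyenv())
  counters$table <- 0L
  counters$figure <- 0L

  add <- function(component, kind, instance, node, text = NULL) {
    frags[[length(frags) + 1L]] <<- list(
      component = component, fragment_kind = kind, instance = instance,
      node = node,
      text = if (is.null(text)) normalize_ws(xml2::xml_text(node)) else text,
      section_path = section_context_of(node),
      order_index = NA_integer_)
  }

  ## --- abstracts -------------------------------------------------------
  abstracts <- xml2::xml_find_all(
    doc, ".//front//abstract | .//front//trans-abstract")
  for (ab in abstracts) {
    for (p in xml2::xml_find_all(ab, ".//p | .//disp-quote[not(.//p)]")) {
      if (has_ancestor(p, "disp-quote")) next
      add("abstract", "paragraph", "abstract", p)
    }
  }

  ## --- body + interleaved tables/figures ------------------------------
  body <- xml2::xml_find_first(doc, ".//body")
  if (!inherits(body, "xml_missing")) {
    nodes <- xml2::xml_find_all(
      body,
      paste0(".//p | .//disp-quote | .//table-wrap | .//fig",
             " | .//array/tbody[not(ancestor::table-wrap)]"))
    for (node in nodes) {
      nm <- xml2::xml_name(node)
      if (nm == "p") {
        if (has_ancestor(node, c("table-wrap", "fig", "disp-quote", "tbody")))
          next
        add("body", "paragraph", "body", node)
      } else if (nm == "disp-quote") {
        if (has_ancestor(node, c("table-wrap", "fig"))) next
        add("body", "quote", "body", node)
      } else if (nm == "table-wrap" || nm == "tbody") {
        if (nm == "tbody" && has_ancestor(node, "table-wrap")) next
        counters$table <- counters$table + 1L
        inst <- sprintf("table:%d", counters$table)
        for (f in table_fragments(node, inst)) frags[[length(frags) + 1L]] <- f
      } else if (nm == "fig") {
        if (has_ancestor(node, "fig")) next
        counters$figure <- counters$figure + 1L
        inst <- sprintf("figure:%d", counters$figure)
        cap <- xml2::xml_find_first(node, "./caption")
        if (!inherits(cap, "xml_missing")) add("figure", "caption", inst, cap)
      }
    }
  }

  ## --- back matter -----------------------------------------------------
  back <- xml2::xml_find_first(doc, ".//back")
  if (!inherits(back, "xml_missing")) {
    for (p in xml2::xml_find_all(back, ".//p")) {
      if (has_ancestor(p, c("table-wrap", "fig", "ref-list", "disp-quote")))
        next
      add("back", "paragraph", "back", p)
    }
    for (q in xml2::xml_find_all(back, ".//disp-quote")) {
      if (has_ancestor(q, c("table-wrap", "fig", "ref-list"))) next
      add("back", "quote", "back", q)
    }
    ## tables/figures in back matter are still table/figure components
    for (tw in xml2::xml_find_all(back, ".//table-wrap")) {
      counters$table <- counters$table + 1L
      inst <- sprintf("table:%d", counters$table)
      for (f in table_fragments(tw, inst)) frags[[length(frags) + 1L]] <- f
    }
  }

  ## drop empty fragments, then number per component instance
  frags <- Filter(function(f) nzchar(f$text), frags)
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(frags)) {
    key <- frags[[i]]$instance
    n <- (get0(key, envir = idx) %||% 0L) + 1L
    assign(key, n, envir = idx)
    frags[[i]]$order_index <- n
  }
  frags
}

## fragments of one table instance: caption first, then cells row-major
table_fragments <- function(node, instance) {
  out <- list()
  cap <- xml2::xml_find_first(node, "./caption")
  if (!inherits(cap, "xml_missing")) {
    out[[length(out) + 1L]] <- list(
      component = "table", fragment_kind = "caption", instance = instance,
      node = cap, text = normalize_ws(xml2::xml_text(cap)),
      section_path = section_context_of(node), order_index = NA_integer_)
  }
  for (cell in table_cell_nodes(node)) {
    out[[length(out) + 1L]] <- list(
      component = "table", fragment_kind = "table_cell", instance = instance,
      node = cell, text = normalize_ws(xml2::xml_text(cell)),
      section_path = section_context_of(node), order_index = NA_integer_)
  }
  Filter(function(f) nzchar(f$text), out)
}

table_cell_nodes <- function(node) {
  ## row-major: iterate rows, then cells within each row
  rows <- xml2::xml_find_all(node, ".//tr")
  unlist(lapply(rows, function(r) {
    as.list(xml2::xml_find_all(r, "./td | ./th"))
  }), recursive = FALSE)
}

#' Extract table cells as text fragments
#'
#' One fragment per `<td>`/`<th>` cell in row-major order; empty cells are
#' skipped. Works both on `<table-wrap>` elements and on bare `<tbody>`
#' elements nested under `<array>` (a tagging style some publishers use for
#' inline arrays).
#'
#' @param table_element a `table-wrap`, `array/tbody`, or `table` node.
#' @return list of table_cell fragments (see [segment()]); cell xrefs are
#'   preserved in the nodes for downstream citation annotation.
#' @export
extract_table_cells <- function(table_element) {
  Filter(function(f) f$fragment_kind == "table_cell",
         table_fragments(table_element, "table:1"))
}

#' Section context of a node
#'
#' Collects, for every `<sec>` ancestor from outermost to innermost, the
#' child `<title>` text, child `<label>` text and the `sec-type` attribute
#' (empty strings when absent).
#'
#' @param node an `xml_node`.
#' @return a `data.frame` with character columns `title`, `label`,
#'   `sec_type`, one row per `<sec>` ancestor (zero rows outside any sec).
#' @export
section_context_of <- function(node) {
  secs <- xml2::xml_find_all(node, "ancestor::sec")
  title <- character(length(secs))
  label <- character(length(secs))
  sec_type <- character(length(secs))
  for (i in seq_along(secs)) {
    t <- xml2::xml_find_first(secs[[i]], "./title")
    l <- xml2::xml_find_first(secs[[i]], "./label")
    title[i] <- if (inherits(t, "xml_missing")) "" else normalize_ws(xml2::xml_text(t))
    label[i] <- if (inherits(l, "xml_missing")) "" else normalize_ws(xml2::xml_text(l))
    st <- xml2::xml_attr(secs[[i]], "sec-type")
    sec_type[i] <- if (is.na(st)) "" else normalize_ws(st)
  }
  data.frame(title = title, label = label, sec_type = sec_type,
             stringsAsFactors = FALSE)
}

has_ancestor <- function(node, names) {
  xp <- paste(sprintf("ancestor::%s", names), collapse = " | ")
  length(xml2::xml_find_all(node, xp)) > 0
}
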