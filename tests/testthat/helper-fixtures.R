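# In-code fixture builders shared by the unit tests.  All fixtures are tiny
# XML strings assembled here; nothing is read from disk.

## minimal JATS article wrapper
jats <- function(body = "", refs = "", front_extra = "", back_extra = "") {
  paste0(
    "<article><front><article-meta>",
    "<article-id pub-id-type=\"pmc\">7000001</article-id>",
    "<article-id pub-id-type=\"pmid\">90000001</article-id>",
    front_extra,
    "</article-meta></front>",
    if (nzchar(body)) paste0("<body>", body, "</body>") else "",
    "<back>", back_extra,
    if (nzchar(refs)) paste0("<ref-list>", refs, "</ref-list>") else "",
    "</back></article>")
}

## n flat refs B1..Bn with labels 1..n and pmids 10000010*, via real XML
ref_block <- function(n, pmids = TRUE) {
  paste(vapply(seq_len(n), function(i) {
    pid <- if (pmids) {
      sprintf("<pub-id pub-id-type=\"pmid\">%d</pub-id>", 10000000L + i)
    } else ""
    sprintf("<ref id=\"B%d\"><label>%d</label><mixed-citation>Ref %d. %s</mixed-citation></ref>",
            i, i, i, pid)
  }, character(1)), collapse = "")
}

make_registry <- local({
  cache <- new.env(parent = emptyenv())
  function(n, pmids = TRUE) {
    key <- paste0(n, pmids)
    if (!is.null(cache[[key]])) return(cache[[key]])
    reg <- extract_references(xml2::read_xml(jats(refs = ref_block(n, pmids))))
    cache[[key]] <- reg
    reg
  }
})

## a single <p> fragment wrapped as segment() would deliver it
p_fragment <- function(inner, component = "body", section_path = NULL) {
  node <- xml2::xml_find_first(
    xml2::read_xml(paste0("<sec><p>", inner, "</p></sec>")), ".//p")
  list(component = component, fragment_kind = "paragraph",
       instance = component, node = node,
       text = citancer:::normalize_ws(xml2::xml_text(node)),
       section_path = section_path %||%
         data.frame(title = character(0), label = character(0),
                    sec_type = character(0)),
       order_index = 1L)
}

xr <- function(rid, marker) {
  sprintf("<xref ref-type=\"bibr\" rid=\"%s\">%s</xref>", rid, marker)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## the osteoporosis worked-example article (two explicit citations)
worked_example_xml <- function() {
  jats(
    body = paste0(
      "<sec><title>Introduction</title><p>",
      "If for any reason this process fails, gradually the person will ",
      "suffer from osteoporosis ", xr("B1", "1"), ", ", xr("B2", "2"),
      ".</p></sec>"),
    refs = ref_block(2))
}

expect_records_equal <- function(got, expected) {
  expect_equal(as.data.frame(got), as.data.frame(expected),
               ignore_attr = TRUE)
}
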