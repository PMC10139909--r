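test_that("abstract and body paragraphs map to their components", {
  xml <- jats(
    front_extra = "<abstract><p>A one.</p><p>A two.</p></abstract>",
    body = "<p>B one.</p><p>B two.</p><p>B three.</p>")
  frags <- segment(xml2::read_xml(xml))
  expect_length(frags, 5L)
  expect_equal(vapply(frags, `[[`, "", "component"),
               c("abstract", "abstract", "body", "body", "body"))
  expect_equal(vapply(frags, `[[`, 0L, "order_index"),
               c(1L, 2L, 1L, 2L, 3L))
})

test_that("tables produce cell + caption fragments; empty cells skipped", {
  tw <- paste0(
    "<table-wrap id=\"T1\"><caption><p>A caption.</p></caption>",
    "<table><tbody>",
    "<tr><td>a</td><td>b</td><td>c</td></tr>",
    "<tr><td>d</td><td></td><td>f</td></tr>",
    "</tbody></table></table-wrap>")
  frags <- segment(xml2::read_xml(jats(body = paste0("<p>Lead.</p>", tw))))
  tab <- Filter(function(f) f$component == "table", frags)
  expect_length(tab, 6L) # 1 caption + 5 non-empty of 6 cells
  expect_equal(vapply(tab, `[[`, "", "fragment_kind"),
               c("caption", rep("table_cell", 5)))
  expect_equal(vapply(tab[-1], `[[`, "", "text"), c("a", "b", "c", "d", "f"))

  ## tbody under array, no table-wrap ancestor
  arr <- "<array><tbody><tr><td>x</td><td>y</td></tr></tbody></array>"
  frags2 <- segment(xml2::read_xml(jats(body = paste0("<p>Lead.</p>", arr))))
  cells <- Filter(function(f) f$fragment_kind == "table_cell", frags2)
  expect_equal(vapply(cells, `[[`, "", "text"), c("x", "y"))

  ## xrefs survive in cell nodes for the annotator
  tw3 <- paste0("<table-wrap><table><tbody><tr><td>see ",
                xr("B1", "1"), "</td></tr></tbody></table></table-wrap>")
  cells3 <- extract_table_cells(
    xml2::xml_find_first(xml2::read_xml(jats(body = tw3)), ".//table-wrap"))
  expect_length(cells3, 1L)
  expect_length(xml2::xml_find_all(cells3[[1]]$node, ".//xref"), 1L)
})

test_that("figures, quotes and back matter are classified", {
  body <- paste0(
    "<sec><title>Results</title><p>Lead text.</p>",
    "<disp-quote><p>Quoted words.</p></disp-quote>",
    "<fig id=\"F1\"><caption><p>A figure caption.</p></caption></fig></sec>")
  xml <- jats(body = body,
              back_extra = "<ack><p>Thanks to everyone.</p></ack>")
  frags <- segment(xml2::read_xml(xml))
  kinds <- vapply(frags, function(f) paste(f$component, f$fragment_kind),
                  character(1))
  expect_equal(kinds, c("body paragraph", "body quote", "figure caption",
                        "back paragraph"))
  ## invariant: no abstract/back table cells
  expect_false(any(vapply(frags, function(f) {
    f$component %in% c("abstract", "back") && f$fragment_kind == "table_cell"
  }, logical(1))))
})

test_that("section_context_of returns ancestors outermost-first", {
  xml <- paste0(
    "<body><sec sec-type=\"results\"><title>Results</title>",
    "<sec><title>Western blot</title><p>Deep text.</p></sec></sec></body>")
  p <- xml2::xml_find_first(xml2::read_xml(xml), ".//p")
  ctx <- section_context_of(p)
  expect_equal(ctx$title, c("Results", "Western blot"))
  expect_equal(ctx$sec_type, c("results", ""))

  ## untitled sec -> all-empty context row
  p2 <- xml2::xml_find_first(
    xml2::read_xml("<body><sec><p>Orphan.</p></sec></body>"), ".//p")
  ctx2 <- section_context_of(p2)
  expect_equal(nrow(ctx2), 1L)
  expect_equal(unlist(ctx2[1, ]), c(title = "", label = "", sec_type = ""))
})

test_that("fragment text concatenation recovers the generated text", {
  art <- generate_article(dialect_config(n_refs = 8, seed = 11))
  frags <- segment(xml2::read_xml(art$xml))
  whole <- paste(vapply(frags, `[[`, "", "text"), collapse = " ")
  ## every manifest sentence (tokens stripped back to markers aside) must
  ## appear; here we check the plain non-citing sentences
  plain <- unique(art$manifest$text[is.na(art$manifest$intxt_id)])
  plain <- setdiff(plain, grep("\\|", plain, value = TRUE))
  for (s in plain) expect_true(grepl(s, whole, fixed = TRUE))
})
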