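test_that("find_explicit resolves rids through the registry", {
  reg <- make_registry(5)
  frag <- p_fragment(paste0("As shown ", xr("B2", "2"), " before."))
  cits <- find_explicit(frag$node, reg)
  expect_length(cits, 1L)
  expect_equal(cits[[1]]$intxt_id, "B2")
  expect_equal(cits[[1]]$intxt_mark, "2")
  expect_false(cits[[1]]$implicit)

  ## multi-id rid: one citation per id, sharing the marker
  frag2 <- p_fragment(paste0("Seen ", xr("B1 B2", "1,2"), " here."))
  cits2 <- find_explicit(frag2$node, reg)
  expect_equal(vapply(cits2, `[[`, "", "intxt_id"), c("B1", "B2"))
  expect_equal(unique(vapply(cits2, `[[`, "", "intxt_mark")), "1,2")

  ## figure xrefs do not resolve -> no citation
  frag3 <- p_fragment(paste0("See ", xr("fig1", "Figure 1"), " there."))
  expect_length(find_explicit(frag3$node, reg), 0L)
})

test_that("is_range_separator accepts exactly the separator class", {
  yes <- c("-", "–", "−", "--", "––", "−−",
           " - ", " –", "-–")
  no <- c(", ", "", ";", "a", "---", "- -", ".")
  for (s in yes) expect_true(is_range_separator(s), label = sprintf("%s", s))
  for (s in no) expect_false(is_range_separator(s), label = sprintf("%s", s))
})

test_that("paired-range expansion returns strictly interior entries", {
  reg <- make_registry(10)
  cit <- function(id) list(intxt_id = id, intxt_mark = "x", implicit = FALSE)
  ## brute-force oracle over every ordered endpoint pair
  for (a in 1:10) for (b in 1:10) {
    got <- suppressWarnings(
      expand_paired_range(cit(paste0("B", a)), cit(paste0("B", b)), reg))
    expected <- if (b - a >= 2) paste0("B", (a + 1):(b - 1)) else character(0)
    expect_equal(vapply(got, `[[`, "", "intxt_id"), expected,
                 label = sprintf("pair %d-%d", a, b))
    expect_true(all(vapply(got, `[[`, TRUE, "implicit")))
  }
  ## reversed endpoints warn
  expect_warning(expand_paired_range(cit("B6"), cit("B3"), reg), "reversed")
})

test_that("single-range expansion enumerates to the right label inclusive", {
  reg <- make_registry(10)
  rng <- function(a, b, sep = "–") {
    list(intxt_id = paste0("B", a),
         intxt_mark = paste0(a, sep, b), implicit = FALSE)
  }
  got <- expand_single_range(rng(3, 6), reg)
  expect_equal(vapply(got, `[[`, "", "intxt_id"), c("B4", "B5", "B6"))
  expect_true(all(vapply(got, `[[`, TRUE, "implicit")))
  ## minus-sign separator behaves identically
  expect_equal(
    vapply(expand_single_range(rng(3, 6, "−"), reg), `[[`, "", "intxt_id"),
    c("B4", "B5", "B6"))
  ## degenerate and reversed ranges
  expect_length(expand_single_range(rng(3, 3), reg), 0L)
  expect_warning(out <- expand_single_range(rng(6, 3), reg), "reversed")
  expect_length(out, 0L)
  ## running past the label set truncates with a warning
  expect_warning(out2 <- expand_single_range(rng(8, 12), reg), "no reference")
  expect_equal(vapply(out2, `[[`, "", "intxt_id"), c("B9", "B10"))
})

test_that("single-range expansion falls back to positions without labels", {
  xml <- jats(refs = paste(sprintf(
    "<ref id=\"R%d\"><mixed-citation>Work %d.</mixed-citation></ref>",
    1:8, 1:8), collapse = ""))
  reg <- extract_references(xml2::read_xml(xml))
  expect_length(reg$label_index, 0L)
  got <- expand_single_range(
    list(intxt_id = "R2", intxt_mark = "2-5", implicit = FALSE), reg)
  expect_equal(vapply(got, `[[`, "", "intxt_id"), c("R3", "R4", "R5"))
})

test_that("annotate_markers rewrites explicit markers in place", {
  reg <- make_registry(3)
  frag <- p_fragment(paste0(
    "gradually the person will suffer from osteoporosis ",
    xr("B1", "1"), ", ", xr("B2", "2"), "."))
  ann <- annotate_markers(frag, reg)
  expect_equal(
    ann$text,
    "gradually the person will suffer from osteoporosis |B1|, |B2|.")
  expect_equal(ann$citations$intxt_id, c("B1", "B2"))
  expect_false(any(ann$citations$implicit))
  ## spans point at the tokens
  expect_equal(
    substr(ann$text, ann$citations$start[1], ann$citations$end[1]), "|B1|")

  ## fragment without citations is untouched
  frag2 <- p_fragment("Nothing cited here.")
  ann2 <- annotate_markers(frag2, reg)
  expect_equal(ann2$text, "Nothing cited here.")
  expect_equal(nrow(ann2$citations), 0L)
})

test_that("annotate_markers expands both range styles with full token sets", {
  reg <- make_registry(10)
  ## paired style
  fragp <- p_fragment(paste0("Known effects [", xr("B3", "3"), "–",
                             xr("B6", "6"), "]."))
  annp <- annotate_markers(fragp, reg)
  expect_equal(annp$text, "Known effects [|B3|–|B6|,|B4|,|B5|].")
  expect_equal(annp$citations$intxt_id, c("B3", "B6", "B4", "B5"))
  expect_equal(annp$citations$implicit, c(FALSE, FALSE, TRUE, TRUE))

  ## single style: token multiset must cover the whole range
  frags <- p_fragment(paste0("Known effects [", xr("B3", "3–6"), "]."))
  anns <- annotate_markers(frags, reg)
  expect_equal(anns$text, "Known effects [|B3|–|B4|,|B5|,|B6|].")
  expect_equal(sort(anns$citations$intxt_id), c("B3", "B4", "B5", "B6"))
  expect_equal(sum(anns$citations$implicit), 3L)
  ## marks carry the visible range for all four citations
  expect_equal(unique(anns$citations$intxt_mark), "3–6")

  ## whitespace around the separator is tolerated in paired style
  fragw <- p_fragment(paste0("Seen [", xr("B2", "2"), " - ",
                             xr("B5", "5"), "]."))
  annw <- annotate_markers(fragw, reg)
  expect_equal(annw$citations$intxt_id, c("B2", "B5", "B3", "B4"))

  ## alphanumeric ranges are not expanded
  fraga <- p_fragment(paste0("Seen [", xr("B2", "2a–2c"), "]."))
  anna <- annotate_markers(fraga, reg)
  expect_equal(anna$citations$intxt_id, "B2")
})

test_that("token conservation holds on generated fixtures", {
  for (style in c("paired_xref", "single_xref", "mixed")) {
    art <- generate_article(dialect_config(
      n_refs = 15, implicit_style = style, separator = "random", seed = 5))
    reg <- extract_references(xml2::read_xml(art$xml))
    frags <- segment(xml2::read_xml(art$xml))
    for (f in frags) {
      ann <- annotate_markers(f, reg)
      toks <- stringi::stri_extract_all_regex(
        ann$text, "\\|[A-Za-z0-9]+\\|")[[1]]
      toks <- if (all(is.na(toks))) character(0) else
        stringi::stri_replace_all_fixed(toks, "|", "")
      expect_equal(sort(toks), sort(ann$citations$intxt_id))
    }
  }
})
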