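# Inline-citation detection and marker annotation.
#
# Explicit inline citations are <xref> elements whose rid resolves in the
# reference registry (xrefs pointing at figures/tables do not resolve and
# are left alone).  Implicitly-mentioned citations come from numeric ranges
# such as "[3-6]": publishers tag these either as two xrefs around a
# separator (paired style) or as one xref whose visible label is the whole
# range (single style).  The recognized separators are hyphen-minus, en dash
# (U+2013), minus sign (U+2212), and doubled runs of these, optionally
# surrounded by whitespace.
#
# Annotation rewrites each explicit marker in place as |ref-id| and appends
# the implicit |ref-id| tokens, comma-separated, immediately after the
# range's closing explicit token, preserving sentence character order.

SEPARATOR_CHARS <- "\\-\u2013\u2212"

## private-use sentinels used while flattening fragment text
.SENT_OPEN <- "\uE000"
.SENT_CLOSE <- "\uE001"

#' Is a piece of text a citation-range separator?
#'
#' @param between_text literal text between two adjacent xrefs (or inside a
#'   single range marker).
#' @return `TRUE` iff the text, with surrounding whitespace stripped, is a
#'   hyphen-minus, en dash (U+2013), minus sign (U+2212), or a doubled run
#'   of these.
#' @examples
#' is_range_separator("\u2013")  # en dash: TRUE
#' is_range_separator(", ")      # list separator: FALSE
#' is_range_separator("--")      # doubled: TRUE
#' @export
is_range_separator <- function(between_text) {
  stringi::stri_detect_regex(
    stringi::stri_trim_both(between_text),
    sprintf("^[%s]{1,2}$", SEPARATOR_CHARS))
}

## parse "a<sep>b" markers; returns list(left, right, sep) or NULL
parse_range_marker <- function(marker) {
  m <- stringi::stri_match_first_regex(
    marker,
    sprintf("^\\s*(\\d+)\\s*([%s]{1,2})\\s*(\\d+)\\s*$", SEPARATOR_CHARS))
  if (is.na(m[1, 1])) return(NULL)
  list(left = as.integer(m[1, 2]), sep = m[1, 3], right = as.integer(m[1, 4]))
}

new_citation <- function(intxt_id, intxt_mark, implicit) {
  list(intxt_id = intxt_id, intxt_mark = intxt_mark, implicit = implicit)
}

#' Find explicit inline citations in a fragment
#'
#' One citation per `rid` token of each `<xref>` whose rid resolves through
#' the registry (an `rid` holding several whitespace-separated ids yields
#' one citation per id, sharing the visible marker). Unresolvable rids —
#' including xrefs pointing at figures and tables — are skipped.
#'
#' @param fragment_element an `xml_node` still containing `<xref>` structure
#'   (e.g. a fragment's `node` from [segment()]).
#' @param registry a [ref_registry][extract_references].
#' @return a list of citations: `intxt_id`, `intxt_mark`, `implicit = FALSE`.
#' @export
find_explicit <- function(fragment_element, registry) {
  xr <- scan_xrefs(fragment_element, registry)
  out <- list()
  for (x in xr) {
    for (id in x$ids) {
      out[[length(out) + 1L]] <- new_citation(id, x$marker, FALSE)
    }
  }
  out
}

## collect resolved xrefs in document order
scan_xrefs <- function(node, registry) {
  xrefs <- xml2::xml_find_all(node, ".//xref")
  out <- list()
  for (x in xrefs) {
    rid <- xml2::xml_attr(x, "rid")
    if (is.na(rid)) next
    ids <- stringi::stri_split_regex(rid, "\\s+")[[1]]
    ids <- ids[nzchar(ids)]
    resolved <- ids[ids %in% names(registry$id_index)]
    if (length(resolved) == 0) next
    out[[length(out) + 1L]] <- list(
      node = x, ids = resolved,
      marker = normalize_ws(xml2::xml_text(x)))
  }
  out
}

#' Expand the implicit citations of a paired-xref range
#'
#' Given the two explicit endpoint citations of a range tagged as
#' `<xref>3</xref>-<xref>6</xref>`, returns the registry entries strictly
#' between the endpoints (registry order), flagged implicit. The endpoints
#' themselves are not returned — they were already emitted as explicit. A
#' reversed or degenerate pair (publisher mis-tagging) yields an empty
#' expansion with a warning.
#'
#' @param first,second explicit citations (lists with `intxt_id`,
#'   `intxt_mark`) whose intervening text satisfied [is_range_separator()].
#' @param registry a [ref_registry][extract_references].
#' @param mark marker text to attach to the implicit citations (defaults to
#'   `first-second`).
#' @return list of implicit citations.
#' @export
expand_paired_range <- function(first, second, registry, mark = NULL) {
  p1 <- registry_position(registry, first$intxt_id)
  p2 <- registry_position(registry, second$intxt_id)
  if (is.na(p1) || is.na(p2)) return(list())
  if (p2 <= p1) {
    if (p2 < p1) {
      cite_warn("reversed citation range ", first$intxt_id, "..",
                second$intxt_id, "; no implicit expansion")
    }
    return(list())
  }
  if (p2 - p1 < 2) return(list())
  if (is.null(mark)) {
    mark <- paste0(first$intxt_mark, "\u2013", second$intxt_mark)
  }
  lapply(registry$entries$ref_id[(p1 + 1L):(p2 - 1L)], function(id) {
    new_citation(id, mark, TRUE)
  })
}

#' Expand the implicit citations of a single-xref range marker
#'
#' For a citation tagged as `<xref rid="B3">3-6</xref>`, the enumeration
#' runs from the label after the left endpoint up to and including the right
#' endpoint's label (the right endpoint has no xref of its own, so it too is
#' implicit). Resolution is by reference label, falling back to registry
#' position offsets when the registry carries no numeric labels; labels in
#' the range with no registry entry truncate the expansion to the resolvable
#' prefix with a warning.
#'
#' @param citation an explicit citation whose `intxt_mark` is a numeric
#'   range (e.g. `"3-6"`, any recognized separator).
#' @param registry a [ref_registry][extract_references].
#' @return list of implicit citations (empty for degenerate ranges).
#' @export
expand_single_range <- function(citation, registry) {
  rng <- parse_range_marker(citation$intxt_mark)
  if (is.null(rng)) return(list())
  a <- rng$left; b <- rng$right
  if (b <= a) {
    if (b < a) cite_warn("reversed range marker '", citation$intxt_mark, "'")
    return(list())
  }
  n <- nrow(registry$entries)
  positions <- integer(0)
  if (length(registry$label_index) > 0) {
    for (k in (a + 1L):b) {
      pos <- registry$label_index[as.character(k)]
      if (is.na(pos)) {
        cite_warn("range '", citation$intxt_mark, "': no reference labelled ",
                  k, "; expanding the resolvable prefix only")
        break
      }
      positions <- c(positions, unname(pos))
    }
  } else {
    posL <- registry_position(registry, citation$intxt_id)
    if (is.na(posL)) return(list())
    want <- (posL + 1L):(posL + (b - a))
    if (any(want > n)) {
      cite_warn("range '", citation$intxt_mark,
                "' runs past the end of the reference list; truncated")
      want <- want[want <= n]
    }
    positions <- want
  }
  lapply(registry$entries$ref_id[positions], function(id) {
    new_citation(id, citation$intxt_mark, TRUE)
  })
}

#' Annotate a fragment's citation markers with |ref-id| tokens
#'
#' Flattens a fragment to text with each explicit citation marker replaced
#' in place by `|id|` (one token per resolved rid, comma-joined for
#' multi-rid xrefs), detects both implicit-range tagging styles, and appends
#' the implicit tokens comma-separated immediately after the range's closing
#' explicit token. So `[<xref rid="B3">3</xref>–<xref rid="B6">6</xref>]`
#' becomes `[|B3|–|B6|,|B4|,|B5|]` and `[<xref rid="B3">3–6</xref>]`
#' becomes `[|B3|–|B4|,|B5|,|B6|]`.
#'
#' @param fragment a fragment from [segment()] (or any list with a `node`).
#' @param registry a [ref_registry][extract_references].
#' @return a list: `text` (annotated, whitespace-normalized) and
#'   `citations`, a `data.table` with columns `intxt_id`, `intxt_mark`,
#'   `implicit`, `start`, `end` (token character spans in `text`), in token
#'   order.
#' @export
annotate_markers <- function(fragment, registry) {
  node <- fragment$node
  xr <- scan_xrefs(node, registry)
  flat <- normalize_ws(flatten_with_sentinels(node, xr))
  if (length(xr) == 0) {
    return(list(text = flat,
                citations = empty_citation_table()))
  }

  k <- length(xr)
  ## per-xref citation sequences and replacement strings
  seqs <- vector("list", k)
  reps <- character(k)
  for (i in seq_len(k)) {
    expl <- lapply(xr[[i]]$ids, function(id) {
      new_citation(id, xr[[i]]$marker, FALSE)
    })
    seqs[[i]] <- expl
    reps[i] <- paste0("|", xr[[i]]$ids, "|", collapse = ",")
    ## single-xref range style
    rng <- parse_range_marker(xr[[i]]$marker)
    if (!is.null(rng) && length(xr[[i]]$ids) == 1) {
      imp <- expand_single_range(expl[[1]], registry)
      if (length(imp) > 0) {
        seqs[[i]] <- c(seqs[[i]], imp)
        reps[i] <- paste0(
          "|", xr[[i]]$ids[1], "|", rng$sep,
          paste0("|", vapply(imp, `[[`, "", "intxt_id"), "|", collapse = ","))
      }
    }
  }

  ## paired-xref range style: separator-only text between two sentinels
  if (k >= 2) {
    for (i in seq_len(k - 1L)) {
      between <- between_sentinels(flat, i, i + 1L)
      if (is.null(between) || !nzchar(stringi::stri_trim_both(between))) next
      if (!is_range_separator(between)) next
      first <- new_citation(tail(xr[[i]]$ids, 1L), xr[[i]]$marker, FALSE)
      second <- new_citation(xr[[i + 1L]]$ids[1L], xr[[i + 1L]]$marker, FALSE)
      mark <- normalize_ws(paste0(xr[[i]]$marker,
                                  stringi::stri_trim_both(between),
                                  xr[[i + 1L]]$marker))
      imp <- expand_paired_range(first, second, registry, mark = mark)
      if (length(imp) > 0) {
        seqs[[i + 1L]] <- c(seqs[[i + 1L]], imp)
        reps[i + 1L] <- paste0(
          reps[i + 1L], ",",
          paste0("|", vapply(imp, `[[`, "", "intxt_id"), "|", collapse = ","))
      }
    }
  }

  ## substitute sentinels, then locate token spans in emission order
  text <- flat
  for (i in seq_len(k)) {
    text <- stringi::stri_replace_first_fixed(
      text, paste0(.SENT_OPEN, i, .SENT_CLOSE), reps[i])
  }
  citations <- do.call(c, seqs)
  spans <- locate_tokens(text, vapply(citations, `[[`, "", "intxt_id"))
  dt <- data.table::data.table(
    intxt_id = vapply(citations, `[[`, "", "intxt_id"),
    intxt_mark = vapply(citations, `[[`, "", "intxt_mark"),
    implicit = vapply(citations, `[[`, TRUE, "implicit"),
    start = spans$start, end = spans$end)
  list(text = text, citations = dt)
}

empty_citation_table <- function() {
  data.table::data.table(
    intxt_id = character(0), intxt_mark = character(0),
    implicit = logical(0), start = integer(0), end = integer(0))
}

## flatten node text, substituting each resolved xref with a sentinel
flatten_with_sentinels <- function(node, xrefs) {
  addr <- vapply(xrefs, function(x) xml2::xml_path(x$node), character(1))
  recurse <- function(n) {
    if (inherits(n, "xml_node") && xml2::xml_name(n) == "xref") {
      i <- match(xml2::xml_path(n), addr)
      if (!is.na(i)) return(paste0(.SENT_OPEN, i, .SENT_CLOSE))
      return(xml2::xml_text(n))
    }
    kids <- xml2::xml_contents(n)
    if (length(kids) == 0) return(xml2::xml_text(n))
    paste(vapply(kids, function(kid) {
      if (xml2::xml_type(kid) == "element") recurse(kid) else xml2::xml_text(kid)
    }, character(1)), collapse = "")
  }
  recurse(node)
}

## text strictly between sentinel i and sentinel j in flat text
between_sentinels <- function(flat, i, j) {
  si <- paste0(.SENT_OPEN, i, .SENT_CLOSE)
  sj <- paste0(.SENT_OPEN, j, .SENT_CLOSE)
  li <- stringi::stri_locate_first_fixed(flat, si)
  lj <- stringi::stri_locate_first_fixed(flat, sj)
  if (is.na(li[1, 2]) || is.na(lj[1, 1]) || lj[1, 1] <= li[1, 2]) return(NULL)
  stringi::stri_sub(flat, li[1, 2] + 1L, lj[1, 1] - 1L)
}

## sequential left-to-right span location of |id| tokens
locate_tokens <- function(text, ids) {
  start <- integer(length(ids))
  end <- integer(length(ids))
  from <- 1L
  for (i in seq_along(ids)) {
    tok <- paste0("|", ids[i], "|")
    loc <- stringi::stri_locate_first_fixed(
      stringi::stri_sub(text, from), tok)
    if (is.na(loc[1, 1])) {
      start[i] <- NA_integer_; end[i] <- NA_integer_
      next
    }
    start[i] <- from + loc[1, 1] - 1L
    end[i] <- from + loc[1, 2] - 1L
    from <- end[i] + 1L
  }
  list(start = start, end = end)
}
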