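# Sentence segmentation and the per-sentence output records.
#
# The splitter is deterministic and abbreviation-aware: a candidate boundary
# is sentence-final punctuation followed by whitespace, accepted only when
# the next character looks like a sentence start and the preceding token is
# neither a known abbreviation nor a single-initial.  |id| citation tokens
# contain no boundary punctuation and are therefore never split.  Table
# cells bypass tokenization entirely: one cell is one sentence.

#' Default abbreviation list for the sentence splitter
#'
#' Lowercased tokens (without the trailing period) after which a period does
#' not end a sentence. Extendable through the pipeline config.
#' @return character vector
#' @export
default_abbreviations <- function() {
  c("fig", "figs", "tab", "tabs", "eq", "eqs", "ref", "refs", "no", "nos",
    "vol", "vols", "ch", "sec", "dr", "mr", "mrs", "ms", "prof", "st",
    "jr", "sr", "e.g", "i.e", "cf", "ca", "al", "vs", "approx", "resp",
    "min", "max", "inc", "ltd", "dept", "univ", "ed", "eds")
}

#' Split annotated text into sentences
#'
#' @param annotated_text a whitespace-normalized string, possibly containing
#'   `|id|` citation tokens.
#' @param abbreviations lowercased abbreviation tokens (periods not ending a
#'   sentence); see [default_abbreviations()].
#' @return character vector of sentences whose concatenation with single
#'   spaces equals the input.
#' @examples
#' tokenize("First sentence. Second |B1|.")
#' tokenize("See Fig. 2 for details.")  # one sentence
#' @export
tokenize <- function(annotated_text, abbreviations = default_abbreviations()) {
  text <- annotated_text
  if (!nzchar(text)) return(character(0))
  chars <- stringi::stri_split_boundaries(text, type = "character")[[1]]
  n <- length(chars)
  breaks <- integer(0)
  i <- 1L
  while (i < n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      ## absorb closing quotes/brackets directly after the punctuation
      j <- i + 1L
      while (j <= n && chars[j] %in% c("\"", "'", ")", "]", "\u201d", "\u2019")) {
        j <- j + 1L
      }
      if (j <= n && chars[j] == " " && j < n &&
          is_sentence_start(chars[j + 1L]) &&
          !(ch == "." && blocked_by_abbreviation(chars, i, abbreviations))) {
        breaks <- c(breaks, j) # break after the space at position j
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(breaks) == 0) return(text)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, n) # drop the inter-sentence space itself
  vapply(seq_along(starts), function(s) {
    paste(chars[starts[s]:ends[s]], collapse = "")
  }, character(1))
}

is_sentence_start <- function(ch) {
  stringi::stri_detect_regex(ch, "^[\\p{Lu}0-9|\\(\\[\"“]$")
}

## TRUE when the token ending at the period position i is an abbreviation
## or a single uppercase initial
blocked_by_abbreviation <- function(chars, i, abbreviations) {
  j <- i - 1L
  while (j >= 1L && !chars[j] %in% c(" ", "(", "[")) j <- j - 1L
  if (j >= i - 1L) return(FALSE) # bare period
  token <- paste(chars[(j + 1L):(i - 1L)], collapse = "")
  low <- stringi::stri_trans_tolower(token)
  if (low %in% abbreviations) return(TRUE)
  ## single capital initial, e.g. "J." in "J. Smith"
  stringi::stri_detect_regex(token, "^\\p{Lu}$")
}

#' Text progression of a sentence within its component
#'
#' The centile position: `ceiling(100 * sentence_id / total_sentences)`, so
#' the last sentence of a component is always 100 and the value lies in
#' 1..100.
#'
#' @param sentence_id 1-based sentence index within the component.
#' @param total_sentences sentence count of the component.
#' @return integer in 1..100 (vectorized).
#' @export
compute_progression <- function(sentence_id, total_sentences) {
  stopifnot(all(sentence_id >= 1), all(total_sentences >= 1),
            all(sentence_id <= total_sentences))
  as.integer(ceiling(100 * sentence_id / total_sentences))
}

RECORD_COLUMNS <- c("pmcid", "pmid", "location", "IMRaD", "sentence_id",
                    "total_sentences", "intxt_id", "intxt_pmid",
                    "intxt_pmid_source", "intxt_mark", "best_id",
                    "best_source", "best_id_diff", "progression", "text")

#' An empty sentence-record table
#'
#' The 14 dataset columns plus the `text` column, with their canonical
#' types: identifiers and labels as character, `sentence_id`,
#' `total_sentences` and `progression` as integer.
#' @return a zero-row `data.table`
#' @export
empty_records <- function() {
  data.table::data.table(
    pmcid = character(0), pmid = character(0), location = character(0),
    IMRaD = character(0), sentence_id = integer(0),
    total_sentences = integer(0), intxt_id = character(0),
    intxt_pmid = character(0), intxt_pmid_source = character(0),
    intxt_mark = character(0), best_id = character(0),
    best_source = character(0), best_id_diff = character(0),
    progression = integer(0), text = character(0))
}

#' Assemble sentence records for one article
#'
#' Takes the per-fragment annotation output and produces one row per
#' citation-free sentence and `k` rows for a sentence hosting `k` inline
#' citations (the rows share `sentence_id`, `text`, `IMRaD` and
#' `progression`). `sentence_id`/`total_sentences` are per component
#' instance; each table and each figure is its own instance. Table cells
#' count as one sentence each.
#'
#' @param article_context a list with `pmcid`, `pmid`, and `fragments` — a
#'   list of annotated fragments, each carrying `component`, `instance`,
#'   `imrad`, `sentences` (character vector) and `citations_by_sentence` (a
#'   list parallel to `sentences` of citation data.tables).
#' @param registry a [ref_registry][extract_references] used to attach the
#'   XML-tagged PMID of each cited work.
#' @param location_labels named character vector mapping component kinds to
#'   the emitted location strings.
#' @param progression_mode `"component"` (default: centiles within each
#'   component instance) or `"maintext"` (body/table/figure sentences take
#'   centiles over the concatenated main text).
#' @return a `data.table` of sentence records (reconciliation columns
#'   still empty; see [reconcile_records()]).
#' @export
build_records <- function(article_context, registry,
                          location_labels = default_location_labels(),
                          progression_mode = c("component", "maintext")) {
  progression_mode <- match.arg(progression_mode)
  frs <- article_context$fragments
  if (length(frs) == 0) return(empty_records())

  ## sentence-level long table first
  rows <- list()
  for (f in frs) {
    for (si in seq_along(f$sentences)) {
      rows[[length(rows) + 1L]] <- list(
        instance = f$instance, component = f$component, imrad = f$imrad,
        sentence = f$sentences[si],
        citations = f$citations_by_sentence[[si]])
    }
  }
  if (length(rows) == 0) return(empty_records())

  inst <- vapply(rows, `[[`, "", "instance")
  sent_id <- stats::ave(seq_along(rows), inst, FUN = seq_along)
  totals <- stats::ave(seq_along(rows), inst, FUN = length)
  if (progression_mode == "maintext") {
    main <- vapply(rows, function(r) {
      r$component %in% c("body", "table", "figure")
    }, logical(1))
    prog <- integer(length(rows))
    prog[!main] <- compute_progression(sent_id[!main], totals[!main])
    if (any(main)) {
      mt_id <- seq_len(sum(main))
      prog[main] <- compute_progression(mt_id, sum(main))
    }
  } else {
    prog <- compute_progression(sent_id, totals)
  }

  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    loc <- unname(location_labels[r$component])
    base <- data.table::data.table(
      pmcid = chr1(article_context$pmcid) %||% NA_character_,
      pmid = chr1(article_context$pmid),
      location = loc, IMRaD = r$imrad,
      sentence_id = as.integer(sent_id[i]),
      total_sentences = as.integer(totals[i]),
      intxt_id = NA_character_, intxt_pmid = NA_character_,
      intxt_pmid_source = NA_character_, intxt_mark = NA_character_,
      best_id = NA_character_, best_source = NA_character_,
      best_id_diff = NA_character_,
      progression = as.integer(prog[i]), text = r$sentence)
    cit <- r$citations
    if (!is.null(cit) && nrow(cit) > 0) {
      base <- base[rep(1L, nrow(cit))]
      base[, intxt_id := cit$intxt_id]
      base[, intxt_mark := cit$intxt_mark]
      base[, intxt_pmid := vapply(cit$intxt_id, function(id) {
        registry_pmid(registry, id)
      }, character(1))]
    }
    out[[i]] <- base
  }
  data.table::rbindlist(out)
}

#' Default component-to-location label table
#' @return named character vector
#' @export
default_location_labels <- function() {
  c(abstract = "abstract", body = "body", table = "table",
    figure = "fig", back = "back")
}

#' Write sentence records as tab-separated values
#'
#' Header row, UTF-8, no quoting; empty optionals serialize as empty
#' fields; internal tabs/newlines in text are replaced by single spaces.
#'
#' @param records a record `data.table` (see [build_records()]).
#' @param sink output file path.
#' @param include_text keep the trailing `text` column (default) or emit
#'   the bare 14-column byte-compatible schema.
#' @return `sink`, invisibly.
#' @export
write_tsv <- function(records, sink, include_text = TRUE) {
  cols <- RECORD_COLUMNS
  if (!include_text) cols <- setdiff(cols, "text")
  out <- data.table::as.data.table(records)[, cols, with = FALSE]
  for (cc in names(out)) {
    if (is.character(out[[cc]])) {
      data.table::set(out, j = cc, value = stringi::stri_replace_all_regex(
        out[[cc]], "[\\t\\n\\r]+", " "))
    }
  }
  data.table::fwrite(out, sink, sep = "\t", quote = FALSE, na = "",
                     bom = FALSE, eol = "\n")
  invisible(sink)
}

#' Read a sentence-record TSV back into a record table
#'
#' The inverse of [write_tsv()]: identifier columns stay character, empty
#' fields become `NA`.
#' @param path TSV file path.
#' @return a record `data.table`.
#' @export
read_tsv_records <- function(path) {
  int_cols <- c("sentence_id", "total_sentences", "progression")
  dt <- data.table::fread(
    path, sep = "\t", quote = "", na.strings = "",
    colClasses = list(character = setdiff(RECORD_COLUMNS, int_cols)),
    integer64 = "character", encoding = "UTF-8", fill = TRUE,
    strip.white = FALSE)
  for (cc in int_cols) {
    if (cc %in% names(dt)) data.table::set(dt, j = cc, value = as.integer(dt[[cc]]))
  }
  dt[]
}
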