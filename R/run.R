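# Batch orchestration: a directory of XML files in, one TSV + JSON summary
# out.  One file's failure never aborts the batch.

#' Batch-process a directory of JATS XML files
#'
#' Processes every `*.xml` file of `input_dir` (lexicographic order)
#' independently through [process_article()], concatenates the sentence
#' records into one TSV, and writes a JSON run summary next to it. Per-file
#' parse failures are recorded in the summary and logged; they do not stop
#' the batch.
#'
#' @param input_dir directory containing `.xml` files.
#' @param output_path path of the output TSV.
#' @param summary_path path for the JSON summary (default:
#'   `output_path` with a `.summary.json` suffix; `NA` to skip).
#' @param candidates_path optional TSV of matcher candidates (columns
#'   `pmcid`, `ref_id`, `candidate_id`, `id_space`, `probability`,
#'   `confirmations` semicolon-joined).
#' @param entrez_path optional TSV of Entrez-style cited PMIDs (columns
#'   `pmcid`, `cited_pmid`).
#' @param config a [default_config()] or a path to a JSON config file.
#' @param contexts_only suppress non-citing sentences.
#' @param include_text emit the `text` column (disable for the bare
#'   14-column schema).
#' @param progression_mode `"component"` or `"maintext"`.
#' @param verbose log one line per file to stderr.
#' @return a `run_summary` list: `n_articles_processed`,
#'   `n_articles_with_contexts`, `n_references`, `n_explicit_citations`,
#'   `n_implicit_citations`, `n_inline_citations`, `n_citation_contexts`,
#'   `n_sentences`, `n_refs_without_context`, and `failures` (a list of
#'   file/error pairs).
#' @export
run_batch <- function(input_dir, output_path,
                      summary_path = NULL,
                      candidates_path = NULL, entrez_path = NULL,
                      config = default_config(),
                      contexts_only = FALSE, include_text = TRUE,
                      progression_mode = c("component", "maintext"),
                      verbose = FALSE) {
  progression_mode <- match.arg(progression_mode)
  if (!dir.exists(input_dir)) {
    stop("input directory does not exist: ", input_dir, call. = FALSE)
  }
  if (is.character(config)) config <- read_config(config)
  files <- sort(list.files(input_dir, pattern = "\\.xml$", full.names = TRUE))

  candidates <- if (!is.null(candidates_path)) {
    data.table::fread(candidates_path, sep = "\t", colClasses = list(
      character = c("pmcid", "ref_id", "candidate_id", "id_space",
                    "confirmations")), na.strings = "")
  } else NULL
  entrez <- if (!is.null(entrez_path)) {
    data.table::fread(entrez_path, sep = "\t",
                      colClasses = "character", na.strings = "")
  } else NULL

  all_records <- list()
  failures <- list()
  tallies <- NULL
  n_with_contexts <- 0L
  for (f in files) {
    res <- tryCatch(
      process_article(f, candidates = candidates, entrez = entrez,
                      config = config,
                      progression_mode = progression_mode,
                      contexts_only = contexts_only),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(
        file = basename(f), error = conditionMessage(res))
      message("FAILED ", basename(f), ": ", conditionMessage(res))
      next
    }
    if (verbose) message("processed ", basename(f), ": ",
                         nrow(res$records), " rows")
    all_records[[length(all_records) + 1L]] <- res$records
    tallies <- if (is.null(tallies)) res$counts else tallies + res$counts
    if (res$counts[["n_citation_contexts"]] > 0) {
      n_with_contexts <- n_with_contexts + 1L
    }
  }

  records <- if (length(all_records)) {
    data.table::rbindlist(all_records)
  } else {
    empty_records()
  }
  write_tsv(records, output_path, include_text = include_text)

  if (is.null(tallies)) {
    tallies <- c(n_references = 0L, n_sentences = 0L,
                 n_citation_contexts = 0L, n_explicit_citations = 0L,
                 n_implicit_citations = 0L, n_inline_citations = 0L,
                 n_refs_without_context = 0L)
  }
  summary <- structure(c(
    list(n_articles_processed = length(files) - length(failures),
         n_articles_with_contexts = n_with_contexts),
    as.list(tallies),
    list(failures = failures)), class = "run_summary")

  if (is.null(summary_path)) {
    summary_path <- paste0(tools::file_path_sans_ext(output_path),
                           ".summary.json")
  }
  if (!is.na(summary_path)) {
    jsonlite::write_json(unclass(summary), summary_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  for (nm in setdiff(names(x), "failures")) {
    cat(sprintf("  %-26s %s\n", nm, x[[nm]]))
  }
  cat(sprintf("  %-26s %d\n", "failures", length(x$failures)))
  invisible(x)
}
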