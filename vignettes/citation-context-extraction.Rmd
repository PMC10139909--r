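---
title: "Extracting citation contexts from JATS XML: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting citation contexts from JATS XML: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citancer)
```

## The extraction model

A JATS article is treated as three interlocking structures:

1. a **reference registry** — the bibliography, where one `<ref>` element
   is one entry, and a nested multi-work reference contributes both its
   parent id and the ids of its `<element-citation>` / `<mixed-citation>` /
   `<nlm-citation>` children to a single index (inline `<xref rid>`
   markers may point at either level);
2. an ordered sequence of **text fragments** grouped into five components
   — abstract, body, table, figure, back matter — each fragment carrying
   its enclosing `<sec>` titles, labels and `sec-type` attributes;
3. the **inline citations**: `<xref>` elements whose `rid` resolves in the
   registry, plus implicitly-mentioned citations recovered from numeric
   range markers.

The pipeline's observable output is one row per sentence (k rows for a
sentence with k inline citations): the 14 columns of the record schema
plus the annotated sentence text, in which every citation marker has been
replaced by a `|ref-id|` token.

Key assumptions, stated explicitly:

* the XML is well-formed; a missing reference list or missing components
  yield fewer rows, never an error;
* only `<pub-id pub-id-type="pmid">` carries a usable cited-work PMID
  (DOIs and other id spaces are deliberately not read at this stage —
  they enter through the external matcher table instead);
* a citation marker with no `<xref>` at all is unrecoverable by design:
  that is a documented limitation of tag-based extraction, and the
  fault-injection tests quantify exactly this mode.

## Implicit citation ranges

Numeric ranges ("[3–6]") appear in two tagging styles. In the *paired*
style both endpoints have xrefs and the text between them is a separator;
the strictly-interior registry entries are emitted as implicit citations.
In the *single* style one xref carries the whole visible range `a–b`; the
enumeration starts after `a` and runs **up to and including** `b`, because
`b` has no xref of its own. A separator is a hyphen-minus, en dash
(U+2013), minus sign (U+2212), or a doubled run of these, optionally
surrounded by whitespace (the whitespace tolerance is our conservative
superset of the tight forms publishers usually print).

Range resolution is by reference *label* (the visible number), falling
back to registry position offsets when the bibliography carries no numeric
labels. Degenerate inputs are handled conservatively and loudly: reversed
ranges expand to nothing with a warning, a label missing from the registry
truncates the expansion to the resolvable prefix with a warning, and
alphanumeric ranges (`3a–3c`) are never expanded.

**Token layout.** The record schema constrains the token *multiset* per
sentence, not the layout of implicit tokens. We append implicit tokens
comma-separated immediately after the range's closing explicit token —
`[|B3|–|B6|,|B4|,|B5|]` (paired), `[|B3|–|B4|,|B5|,|B6|]` (single) — so
that the character order of the original sentence is preserved for
tokenization and spans remain monotone.

## IMRaD labelling

Section strings (title + label + sec-type, lowercased) are matched against
an ordered cue table; `cue*` means "a word starting with cue", plain cues
are substring matches. Substring semantics are a deliberate feature copy:
"Pre-publication history" maps to I via the `history` cue, a known
behaviour of this rudimentary classifier that the tests pin down rather
than hide.

Two orderings are underdetermined by the record schema and fixed here as
declared package choices:

* **group precedence I → M → R → D, first match wins** — so "results and
  discussion" is R. Any precedence is defensible; this one is
  deterministic and documented.
* **innermost-first path evaluation** — a subsection's cue overrides its
  parent ("Discussion > Limitations" is D because "limitations" matches
  nothing and the walk continues outward; "Results > Future directions" is
  D because the innermost cue wins). Subsection titles are more specific,
  hence more trustworthy.

Abstract and back-matter sentences are NoIMRaD unconditionally; tables and
figures inherit the section they sit in. The cue table is a config entry
(`imrad_rules` in the JSON config), so users can extend it.

## Sentence segmentation

No sentence tokenizer ships with the supported R stack, so the package
implements its own deterministic splitter: a boundary is sentence-final
punctuation followed by a space and a sentence-start character (uppercase,
digit, `|`, bracket or quote), vetoed when the preceding token is a known
abbreviation (`Fig.`, `et al.`, `e.g.`, …, configurable) or a single
uppercase initial. Decimals never split (no space after the period);
`|id|` tokens contain no boundary punctuation and are therefore never
split. Table cells bypass tokenization entirely — one cell is one
sentence, whatever punctuation it contains. The splitter is intentionally
simple: determinism and reproducibility are worth more here than coverage
of rare prose, and the generator's vocabulary plus the abbreviation tests
define exactly the behaviour that is guaranteed.

## Sentence numbering and text progression

`sentence_id` and `total_sentences` are assigned per *component instance*:
the abstract is one instance, the body is one, and every table and every
figure is its own (a choice the record schema leaves open; per-instance
numbering keeps `sentence_id` meaningful for tables). Text progression is

\[ \mathrm{progression} = \lceil 100 \cdot \mathrm{sentence\_id} /
\mathrm{total\_sentences} \rceil \in \{1, \dots, 100\}, \]

a ceiling centile: the last sentence of a component is always 100, the
formula is monotone in `sentence_id`, and single-sentence components sit
at 100. Because only the centile *semantics* (not the formula) is fixed by
the schema, the formula is a package choice, tested by exhaustive sweep.
Two scopes are offered: per-component centiles (default) and
`progression_mode = "maintext"`, where body, table and figure sentences
take centiles over the concatenated main text — the scope that matches
positional analyses of where citations fall in an article.

## Identifier reconciliation

Per reference (keyed by the id the xref resolved to, so nested members
reconcile at member granularity):

* `intxt_pmid_source` — `xml,pmc` when the XML-tagged PMID is confirmed by
  the Entrez-style cited list, `xml` when tagged only, empty when absent.
* best-ID selection from the matcher candidate table: eligibility
  thresholds default to 0.997 for an unconfirmed PMID, 0.99 for a PMID
  confirmed by at least one public source, 0.99 for non-PMID id spaces.
  The confirmed/non-PMID bars are stated only as "lower" by the upstream
  tool's description, so they are configuration parameters with those
  defaults.
* PMID preference: among eligible candidates the best PMID wins unless a
  non-PMID's probability exceeds it by at least `prefer_margin`
  (default **0.001**, additive). The margin has to be small: eligible
  PMIDs already have probability ≥ 0.99, so an additive margin of, say,
  0.005 could never be exceeded by any candidate and would make the
  non-PMID preference rule dead code. 0.001 keeps the rule live — a
  non-PMID at 0.9999 displaces a PMID at 0.998 — while still requiring a
  markedly better match.
* `best_id_diff` — the seven-value classification (SAME / NONE / INSERT /
  SWAP / DELETE for cross-checked references, PMID_XML / NONE_XML
  otherwise), with the invariant that `best_id` is empty exactly for NONE,
  DELETE and NONE_XML. "Cross-checked" means the reference key appears in
  the candidate table at all. A selected ID confirmed by no public source
  carries the source token `matcher`; when the selected ID equals the
  XML-tagged PMID, `xml` is prepended to the source list.

With no external inputs the reconciliation degenerates exactly to the
XML-tagged values — that degenerate mode is what the synthetic manifests
encode, so the end-to-end oracle stays independent of the matcher model.

## What the synthetic generator emulates — and what it does not

`generate_article()` produces JATS documents covering: flat and nested
reference lists (nested entries expose member ids and per-member PMIDs;
the parent's PMID is its first member's, because that is what
first-descendant extraction returns); both implicit-range tagging styles
and all four separator variants; abstracts, multi-section bodies with cue
and decoy titles, a table with caption/cells (including an empty cell), a
figure caption, and back matter; and two fault modes — markers left as
plain strings (`missing_xref_rate`) and PMIDs present only in the citation
string (`untagged_pmid_rate`).

Defaults describe a realistic mid-size article: 30 references (the
corpus-typical reference-list size is in the low thirties), four body
sections, one table, one figure. Sentences come from a fixed template
vocabulary so tokenizer behaviour is deterministic; per-article PMIDs are
drawn from disjoint synthetic ranges so SWAP/INSERT scenarios are
constructible.

A green oracle test therefore establishes that the pipeline inverts the
generator's dialect model *exactly* — it does **not** establish coverage
of publisher quirks outside that model: author–year citation styles,
MathML-heavy prose, citation markers split across formatting elements,
tables using unusual row markup, or statistically realistic
citation-count distributions. The fault-injection test establishes the
correct *response* to missing xrefs (the reference is reported as lacking
a context), not recovery of those citations, which is impossible from tags
alone.

## Numerical and degenerate-input choices

* Whitespace normalization (runs → single space, trim) is applied to all
  extracted text before comparison, so manifests are byte-stable.
* Duplicate `<ref>` ids keep the first entry (deterministic downstream
  xref resolution) and warn with both positions.
* An "empty parent" reference whose only content is nested citations
  still gets an entry — xrefs may target the parent id.
* Non-numeric or over-long `pub-id` PMID text is dropped with a warning
  (publisher tagging error), never silently kept.
* TSV output is unquoted; tabs/newlines inside text are replaced by
  single spaces at write time. Empty optionals serialize as empty fields
  and read back as missing.
* The config file is JSON (not YAML): it keeps the package inside its
  declared dependency set, with an identical configuration surface.

## Known limitations

* Citations whose markers carry no `<xref>` are not recoverable.
* Untitled introduction sections map to NoIMRaD (no cue to match).
* Flattened nested references (each sub-work its own `<ref>` with an
  empty parent) resolve to the parent id only; the parent entry is kept
  so the xref at least resolves.
* The tokenizer guarantees behaviour only for the documented abbreviation
  list and sentence shapes; biomedical prose outside it may split
  differently than a statistical tokenizer would.
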