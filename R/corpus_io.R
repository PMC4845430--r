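## Corpus containers and readers: MEDLINE/PubMed XML, JSON-lines, and the
## completeness filter applied before any annotation work.

#' Construct an author entry
#'
#' @param given,family Name parts (free text, may be empty).
#' @param affiliations Character vector of raw affiliation strings, kept
#'   verbatim; country resolution happens later and never rewrites them.
#' @return A list of class `lit_author`.
#' @export
author <- function(given = "", family = "", affiliations = character()) {
  structure(
    list(
      given = squish(given),
      family = squish(family),
      affiliations = as.character(affiliations)
    ),
    class = "lit_author"
  )
}

#' Construct one abstract record
#'
#' @param record_id Unique identifier (e.g. a PMID), coerced to character.
#' @param title,abstract,journal Free text; whitespace is normalized.
#' @param year Integer publication year or `NA` when unknown.
#' @param authors List of [author()] entries.
#' @param keywords Optional character vector; carried through but not
#'   consumed by any analysis stage.
#' @return A list of class `lit_record`.
#' @export
abstract_record <- function(record_id, title = "", abstract = "", year = NA,
                            journal = "", authors = list(),
                            keywords = character()) {
  record_id <- as.character(record_id)
  if (length(record_id) != 1L || is.na(record_id) || !nzchar(record_id)) {
    stop("record_id must be a single non-empty string", call. = FALSE)
  }
  year <- suppressWarnings(as.integer(year[1]))
  if (!is.na(year) && (year < 1800L || year > 2100L)) {
    stop("year out of plausible range [1800, 2100]: ", year, call. = FALSE)
  }
  structure(
    list(
      record_id = record_id,
      title = squish(title),
      abstract = squish(abstract),
      year = year,
      journal = squish(journal),
      authors = authors,
      keywords = as.character(keywords)
    ),
    class = "lit_record"
  )
}

#' Construct a corpus of abstract records
#'
#' @param records List of [abstract_record()] entries.
#' @param provenance Free-text description of where the records came from.
#' @return An object of class `lit_corpus`.
#' @export
corpus <- function(records = list(), provenance = "") {
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate record_id in corpus: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(records = records, provenance = provenance),
    class = "lit_corpus"
  )
}

#' @export
length.lit_corpus <- function(x) length(x$records)

#' @export
print.lit_corpus <- function(x, ...) {
  n_gene <- sum(vapply(x$records, function(r) length(r$genes %||% character()) > 0, logical(1)))
  cat(sprintf(
    "<lit_corpus> %d records (%d gene-annotated)\n  provenance: %s\n",
    length(x$records), n_gene,
    if (nzchar(x$provenance)) x$provenance else "<none>"
  ))
  invisible(x)
}

medline_year <- function(citation) {
  y <- xml2::xml_text(xml2::xml_find_first(
    citation, ".//Article/Journal/JournalIssue/PubDate/Year"
  ))
  if (is.na(y) || !nzchar(y)) {
    ## fall back to the free-text MedlineDate; first 4-digit token wins
    md <- xml2::xml_text(xml2::xml_find_first(
      citation, ".//Article/Journal/JournalIssue/PubDate/MedlineDate"
    ))
    if (!is.na(md)) {
      m <- regmatches(md, regexpr("\\b[0-9]{4}\\b", md))
      if (length(m)) y <- m[1]
    }
  }
  suppressWarnings(as.integer(y))
}

#' Read a MEDLINE/PubMed citation-set XML file
#'
#' Parses the offline equivalent of a PubMed retrieval: a
#' `<PubmedArticleSet>` of `<PubmedArticle>` citations. Missing elements
#' (no abstract, no authors, no year) yield empty fields rather than
#' errors, so that [filter_complete()] can report them.
#'
#' @param path Path to the XML file.
#' @return A [corpus()].
#' @export
read_medline_xml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("malformed MEDLINE XML in ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  citations <- xml2::xml_find_all(doc, ".//MedlineCitation")
  if (length(citations) == 0L) {
    warning("no MedlineCitation elements found in ", path)
    return(corpus(provenance = paste0("medline:", path)))
  }
  records <- lapply(citations, function(ct) {
    pmid <- xml2::xml_text(xml2::xml_find_first(ct, "./PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(ct, ".//Article/ArticleTitle"))
    ## AbstractText may be split into labelled sections; join them
    abs_nodes <- xml2::xml_find_all(ct, ".//Article/Abstract/AbstractText")
    abstract <- paste(vapply(abs_nodes, xml2::xml_text, character(1)),
      collapse = " "
    )
    journal <- xml2::xml_text(xml2::xml_find_first(ct, ".//Article/Journal/Title"))
    authors <- lapply(
      xml2::xml_find_all(ct, ".//Article/AuthorList/Author"),
      function(a) {
        author(
          given = xml2::xml_text(xml2::xml_find_first(a, "./ForeName")) %na% "",
          family = xml2::xml_text(xml2::xml_find_first(a, "./LastName")) %na% "",
          affiliations = vapply(
            xml2::xml_find_all(a, ".//AffiliationInfo/Affiliation"),
            xml2::xml_text, character(1)
          )
        )
      }
    )
    keywords <- vapply(
      xml2::xml_find_all(ct, ".//KeywordList/Keyword"),
      xml2::xml_text, character(1)
    )
    abstract_record(
      record_id = pmid,
      title = title %na% "",
      abstract = abstract,
      year = medline_year(ct),
      journal = journal %na% "",
      authors = authors,
      keywords = keywords
    )
  })
  corpus(records, provenance = paste0("medline:", path))
}

`%na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

record_to_list <- function(r) {
  out <- list(
    schema = 1L,
    record_id = r$record_id,
    title = r$title,
    abstract = r$abstract,
    year = if (is.na(r$year)) NULL else r$year,
    journal = r$journal,
    authors = lapply(r$authors, function(a) {
      list(
        given = a$given, family = a$family,
        affiliations = as.list(a$affiliations)
      )
    }),
    keywords = as.list(r$keywords)
  )
  if (!is.null(r$genes)) out$genes <- as.list(r$genes)
  if (!is.null(r$countries)) out$countries <- as.list(r$countries)
  out
}

list_to_record <- function(l, line_no) {
  if (is.null(l$record_id)) {
    stop("line ", line_no, ": missing record_id", call. = FALSE)
  }
  r <- abstract_record(
    record_id = l$record_id,
    title = l$title %||% "",
    abstract = l$abstract %||% "",
    year = l$year %||% NA,
    journal = l$journal %||% "",
    authors = lapply(l$authors %||% list(), function(a) {
      author(
        given = a$given %||% "",
        family = a$family %||% "",
        affiliations = unlist(a$affiliations %||% character())
      )
    }),
    keywords = unlist(l$keywords %||% character())
  )
  if (!is.null(l$genes)) r$genes <- sort(unique(unlist(l$genes)))
  if (!is.null(l$countries)) r$countries <- sort(unique(unlist(l$countries)))
  r
}

#' Read / write a corpus in JSON-lines format
#'
#' One JSON object per line, with a versioned `"schema"` field. Gene and
#' country annotations, when present, travel inside the same records, so a
#' corpus survives a round trip at any pipeline stage.
#'
#' @param path File path.
#' @return `read_jsonl()` returns a [corpus()]; `write_jsonl()` returns
#'   `path` invisibly.
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(corpus(provenance = paste0("jsonl:", path)))
  }
  records <- lapply(seq_along(lines), function(i) {
    l <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop("line ", i, ": invalid JSON (", conditionMessage(e), ")",
          call. = FALSE
        )
      }
    )
    list_to_record(l, i)
  })
  corpus(records, provenance = paste0("jsonl:", path))
}

#' @rdname read_jsonl
#' @param x A [corpus()].
#' @export
write_jsonl <- function(x, path) {
  stopifnot(inherits(x, "lit_corpus"))
  lines <- vapply(x$records, function(r) {
    jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Keep only records complete enough for analysis
#'
#' Retains records that have a non-empty abstract, a non-empty title, at
#' least one author, and a journal name. A record may fail several checks;
#' every failed check is counted in the removal report. Records without a
#' year are retained here: year-dependent stages drop them themselves, so
#' the completeness filter stays orthogonal to the time axis.
#'
#' @param x A [corpus()].
#' @return The filtered corpus, with a `removal_report` attribute: a named
#'   integer vector over reasons `no_abstract`, `no_title`, `no_authors`,
#'   `no_journal`, plus `n_removed`.
#' @export
filter_complete <- function(x) {
  stopifnot(inherits(x, "lit_corpus"))
  reasons <- c("no_abstract", "no_title", "no_authors", "no_journal")
  report <- stats::setNames(integer(4), reasons)
  keep <- logical(length(x$records))
  for (i in seq_along(x$records)) {
    r <- x$records[[i]]
    bad <- c(
      no_abstract = !nzchar(r$abstract),
      no_title = !nzchar(r$title),
      no_authors = length(r$authors) == 0L,
      no_journal = !nzchar(r$journal)
    )
    keep[i] <- !any(bad)
    report[bad] <- report[bad] + 1L
  }
  out <- corpus(x$records[keep], provenance = x$provenance)
  attr(out, "removal_report") <- c(report, n_removed = sum(!keep))
  out
}
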