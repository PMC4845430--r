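## Resolve raw affiliation strings to countries, offline. The affiliation
## is split on commas into sub-addresses; the query starts at the rightmost
## sub-address (which usually carries the country) and grows leftward until
## it pins down exactly one country. A cache keyed by resolved query
## strings short-circuits repeated gazetteer work without ever changing a
## result.

#' Build a country gazetteer
#'
#' @param rows Data frame with columns `alias`, `canonical`, and optional
#'   `kind` (`"alias"`, the default, or `"hint"`), or a path to a
#'   tab-separated file with those columns (no header). Aliases are
#'   matched by case-insensitive, word-bounded containment in the query;
#'   each alias names exactly one country, and every canonical name is an
#'   alias of itself. Hints are matched by exact (normalized) equality of
#'   the whole query and are consulted only when no alias matches; unlike
#'   aliases, the same hint keyword may point at several countries, which
#'   simply leaves the query ambiguous until more context is added.
#' @return An object of class `country_gazetteer`.
#' @export
build_gazetteer <- function(rows) {
  if (is.character(rows) && length(rows) == 1L && file.exists(rows)) {
    rows <- utils::read.delim(rows,
      header = FALSE, colClasses = "character",
      quote = "", comment.char = ""
    )
    names(rows) <- c("alias", "canonical", "kind")[seq_len(ncol(rows))]
  }
  stopifnot(is.data.frame(rows), nrow(rows) > 0L)
  if (is.null(rows$kind)) rows$kind <- "alias"
  rows$kind[!nzchar(rows$kind)] <- "alias"
  rows$alias <- squish(rows$alias)
  rows$canonical <- squish(rows$canonical)
  rows <- rows[nzchar(rows$alias) & nzchar(rows$canonical), , drop = FALSE]
  aliases <- rows[rows$kind == "alias", c("alias", "canonical")]
  hints <- rows[rows$kind == "hint", c("alias", "canonical")]
  ## canonical names are aliases of themselves
  aliases <- unique(rbind(
    aliases,
    data.frame(alias = unique(rows$canonical), canonical = unique(rows$canonical))
  ))
  dup <- tapply(aliases$canonical, tolower(aliases$alias), function(x) length(unique(x)))
  if (any(dup > 1)) {
    stop(
      "gazetteer alias claimed by several countries: ",
      paste(names(dup)[dup > 1], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      aliases = aliases[order(aliases$alias), , drop = FALSE],
      hints = unique(hints),
      canonical = sort(unique(rows$canonical))
    ),
    class = "country_gazetteer"
  )
}

#' @export
print.country_gazetteer <- function(x, ...) {
  cat(sprintf(
    "<country_gazetteer> %d countries, %d aliases, %d hints\n",
    length(x$canonical), nrow(x$aliases), nrow(x$hints)
  ))
  invisible(x)
}

#' Split an affiliation string into sub-addresses
#'
#' Comma-split, trimmed, with empty fragments dropped; left-to-right order
#' is preserved.
#'
#' @param raw A single raw affiliation string.
#' @return Character vector of sub-addresses (possibly empty).
#' @export
split_affiliation <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return(character())
  parts <- squish(strsplit(raw, ",", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Create an empty resolution cache
#'
#' A mutable environment mapping normalized query strings to canonical
#' countries, with hit/miss counters. The cache is a pure accelerator:
#' with or without it, resolution results are identical.
#'
#' @param path Optional path to a persisted 2-column tab-separated cache
#'   (query, country) to preload.
#' @return An environment of class `geo_cache`.
#' @export
new_geo_cache <- function(path = NULL) {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  if (!is.null(path) && file.exists(path) && file.size(path) > 0) {
    tab <- utils::read.delim(path,
      header = FALSE, colClasses = "character",
      quote = "", comment.char = ""
    )
    for (i in seq_len(nrow(tab))) assign(tab[i, 1], tab[i, 2], envir = e$map)
  }
  class(e) <- "geo_cache"
  e
}

#' @export
print.geo_cache <- function(x, ...) {
  cat(sprintf(
    "<geo_cache> %d keys, %d hits / %d misses\n",
    length(ls(x$map)), x$hits, x$misses
  ))
  invisible(x)
}

#' Persist a resolution cache
#'
#' @param cache A [new_geo_cache()] environment.
#' @param path Output path (tab-separated: query, country).
#' @export
write_geo_cache <- function(cache, path) {
  keys <- sort(ls(cache$map))
  vals <- vapply(keys, function(k) get(k, envir = cache$map), character(1))
  utils::write.table(
    data.frame(keys, vals),
    path,
    sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

normalize_query <- function(x) tolower(squish(x))

## Distinct canonical countries matched by one query string.
## Aliases first (word-bounded containment); hints (exact equality) only
## when no alias matches.
query_countries <- function(query, gazetteer) {
  q <- normalize_query(query)
  al <- gazetteer$aliases
  hit <- vapply(seq_len(nrow(al)), function(i) {
    a <- tolower(al$alias[i])
    pat <- sprintf(
      "(?<![a-z0-9])%s(?![a-z0-9])",
      gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", a)
    )
    grepl(pat, q, perl = TRUE)
  }, logical(1))
  found <- unique(al$canonical[hit])
  if (length(found) == 0L && nrow(gazetteer$hints) > 0L) {
    found <- unique(gazetteer$hints$canonical[
      normalize_query(gazetteer$hints$alias) == q
    ])
  }
  sort(found)
}

#' Resolve a split affiliation to a country
#'
#' Starts from the rightmost sub-address; while the current query matches
#' zero or two-or-more countries, the next sub-address to the left is
#' prepended (joined with `", "`) and the lookup retried. Resolution
#' succeeds on exactly one country. Failure is a status, never an error.
#'
#' @param subaddresses Character vector from [split_affiliation()].
#' @param gazetteer A [build_gazetteer()] object.
#' @param cache Optional [new_geo_cache()]; consulted before the gazetteer
#'   at every escalation step and updated on success.
#' @return A list of class `country_resolution`: `status` (`"resolved"`,
#'   `"unresolved"` or `"ambiguous"`), `country` (present iff resolved),
#'   and `consumed_subaddresses`.
#' @export
resolve_country <- function(subaddresses, gazetteer, cache = NULL) {
  stopifnot(inherits(gazetteer, "country_gazetteer"))
  n <- length(subaddresses)
  res <- function(status, country = NULL, consumed = 0L) {
    structure(
      list(
        status = status, country = country,
        consumed_subaddresses = as.integer(consumed)
      ),
      class = "country_resolution"
    )
  }
  if (n == 0L) return(res("unresolved"))
  last_n_found <- 0L
  for (k in seq_len(n)) {
    query <- paste(subaddresses[(n - k + 1L):n], collapse = ", ")
    key <- normalize_query(query)
    if (!is.null(cache) && exists(key, envir = cache$map)) {
      cache$hits <- cache$hits + 1L
      return(res("resolved", get(key, envir = cache$map), k))
    }
    found <- query_countries(query, gazetteer)
    last_n_found <- length(found)
    if (length(found) == 1L) {
      if (!is.null(cache)) {
        cache$misses <- cache$misses + 1L
        assign(key, found, envir = cache$map)
      }
      return(res("resolved", found, k))
    }
  }
  if (!is.null(cache)) cache$misses <- cache$misses + 1L
  res(if (last_n_found >= 2L) "ambiguous" else "unresolved", consumed = n)
}

#' Countries attributed to one record
#'
#' The union of resolved countries over every affiliation string of every
#' author; unresolved or ambiguous affiliations contribute nothing.
#'
#' @param record An [abstract_record()].
#' @inheritParams resolve_country
#' @return Sorted character vector of canonical country names.
#' @export
countries_of <- function(record, gazetteer, cache = NULL) {
  stopifnot(inherits(record, "lit_record"))
  affs <- unlist(lapply(record$authors, function(a) a$affiliations))
  if (length(affs) == 0L) return(character())
  found <- lapply(unique(affs), function(raw) {
    r <- resolve_country(split_affiliation(raw), gazetteer, cache)
    if (r$status == "resolved") r$country else character()
  })
  sort(unique(unlist(found)))
}

#' Resolve countries for every record of a corpus
#'
#' @param x A [corpus()].
#' @inheritParams resolve_country
#' @return The corpus with a `countries` field filled in on each record.
#' @export
resolve_corpus_countries <- function(x, gazetteer, cache = NULL) {
  stopifnot(inherits(x, "lit_corpus"))
  if (is.null(cache)) cache <- new_geo_cache()
  x$records <- lapply(x$records, function(r) {
    r$countries <- countries_of(r, gazetteer, cache)
    r
  })
  x
}
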