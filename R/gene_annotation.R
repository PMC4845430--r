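## Dictionary-based gene mention recognition with synonym normalization.
## Replaces an online annotation service with an offline matcher: every
## synonym (including protein names listed as synonyms of their gene) maps
## to exactly one canonical symbol.

#' Build a gene synonym lexicon
#'
#' @param rows A data frame with columns `symbol` (canonical gene symbol)
#'   and `synonym`, one pair per row. Each canonical symbol is implicitly a
#'   synonym of itself. A synonym claimed by two or more distinct symbols
#'   is ambiguous: it is dropped from the lexicon and listed in the
#'   `ambiguous` attribute.
#' @return An object of class `gene_lexicon`: a named character vector
#'   mapping synonym -> canonical symbol, with attributes `symbols` and
#'   `ambiguous`.
#' @export
build_lexicon <- function(rows) {
  if (is.character(rows) && length(rows) == 1L && file.exists(rows)) {
    rows <- utils::read.delim(rows,
      header = FALSE, col.names = c("symbol", "synonym"),
      colClasses = "character", quote = "", comment.char = ""
    )
  }
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("lexicon input must be a non-empty data frame (symbol, synonym)",
      call. = FALSE
    )
  }
  sym <- squish(as.character(rows$symbol))
  syn <- squish(as.character(rows$synonym))
  ok <- nzchar(sym) & nzchar(syn)
  sym <- sym[ok]
  syn <- syn[ok]
  if (length(sym) == 0L) stop("lexicon input has no usable rows", call. = FALSE)
  ## every symbol names itself
  syn <- c(syn, unique(sym))
  sym <- c(sym, unique(sym))
  pairs <- unique(data.frame(symbol = sym, synonym = syn, stringsAsFactors = FALSE))
  n_claims <- tapply(pairs$symbol, pairs$synonym, function(s) length(unique(s)))
  ambiguous <- sort(names(n_claims)[n_claims > 1])
  pairs <- pairs[!(pairs$synonym %in% ambiguous), , drop = FALSE]
  map <- stats::setNames(pairs$symbol, pairs$synonym)
  structure(map,
    symbols = sort(unique(pairs$symbol)),
    ambiguous = ambiguous,
    class = "gene_lexicon"
  )
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat(sprintf(
    "<gene_lexicon> %d synonyms -> %d symbols (%d ambiguous synonyms dropped)\n",
    length(x), length(attr(x, "symbols")), length(attr(x, "ambiguous"))
  ))
  invisible(x)
}

## All candidate matches of the lexicon in `text`: one row per start offset
## that begins a synonym, keeping the longest synonym at that offset.
## Matching is case-sensitive for synonyms of <= 3 characters (short
## acronyms collide with ordinary words and place abbreviations) and
## case-insensitive otherwise. Token boundaries are non-alphanumeric
## characters on both sides; hyphens therefore delimit tokens.
lexicon_candidates <- function(text, lexicon) {
  if (!nzchar(text)) {
    return(data.frame(
      start = integer(), len = integer(),
      surface = character(), symbol = character()
    ))
  }
  syns <- names(lexicon)
  short <- nchar(syns) <= 3L
  out <- list()
  for (pass in c("short", "long")) {
    ss <- syns[if (pass == "short") short else !short]
    if (length(ss) == 0L) next
    ## longest alternative first so the regex engine takes the longest
    ## synonym available at each offset
    ss <- ss[order(-nchar(ss), ss)]
    alt <- paste(vapply(ss, function(s) {
      gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
    }, character(1)), collapse = "|")
    ## zero-width wrapper finds overlapping starts; capture carries length
    pat <- sprintf("(?<![A-Za-z0-9])(?=((?:%s)(?![A-Za-z0-9])))", alt)
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = (pass == "long"))[[1]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start")[, 1]
    cl <- attr(m, "capture.length")[, 1]
    surf <- substring(text, cs, cs + cl - 1L)
    key <- if (pass == "long") {
      ## case-insensitive lookup against lowercased synonym table
      lk <- stats::setNames(as.character(lexicon[!short]), tolower(syns[!short]))
      lk[tolower(surf)]
    } else {
      as.character(lexicon[surf])
    }
    out[[pass]] <- data.frame(
      start = cs, len = cl, surface = surf, symbol = key,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out) %||% data.frame(
    start = integer(), len = integer(),
    surface = character(), symbol = character()
  )
}

## Greedy longest-leftmost selection of non-overlapping candidates:
## process by ascending start, then descending length; a candidate is kept
## iff it does not overlap an already kept one.
select_mentions <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$start, -cand$len, cand$symbol), , drop = FALSE]
  kept <- logical(nrow(cand))
  last_end <- 0L # last character (1-based, inclusive) covered so far
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > last_end) {
      kept[i] <- TRUE
      last_end <- cand$start[i] + cand$len[i] - 1L
    }
  }
  cand[kept, , drop = FALSE]
}

#' Annotate one record with gene mentions
#'
#' Finds longest, non-overlapping, token-boundary-respecting matches of
#' the lexicon over the record's title and abstract, and normalizes every
#' match to its canonical symbol. Offsets are 0-based half-open into the
#' concatenation `title + " " + abstract`.
#'
#' @param record An [abstract_record()].
#' @param lexicon A [build_lexicon()] result.
#' @return The record with `mentions` (data frame: `start`, `end`,
#'   `surface`, `symbol`, `field`) and `genes` (sorted unique canonical
#'   symbols) fields added.
#' @export
annotate <- function(record, lexicon) {
  stopifnot(inherits(record, "lit_record"), inherits(lexicon, "gene_lexicon"))
  offset <- nchar(record$title) + 1L # the joining space
  parts <- list(
    title = list(text = record$title, shift = 0L),
    abstract = list(text = record$abstract, shift = offset)
  )
  mention_list <- lapply(names(parts), function(field) {
    p <- parts[[field]]
    sel <- select_mentions(lexicon_candidates(p$text, lexicon))
    if (nrow(sel) == 0L) {
      return(data.frame(
        start = integer(), end = integer(), surface = character(),
        symbol = character(), field = character()
      ))
    }
    data.frame(
      start = sel$start - 1L + p$shift, # to 0-based
      end = sel$start - 1L + p$shift + sel$len,
      surface = sel$surface,
      symbol = sel$symbol,
      field = field,
      stringsAsFactors = FALSE
    )
  })
  mentions <- do.call(rbind, mention_list)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  rownames(mentions) <- NULL
  record$mentions <- mentions
  record$genes <- sort(unique(mentions$symbol))
  record
}

#' Annotate every record of a corpus
#'
#' @param x A [corpus()].
#' @inheritParams annotate
#' @return The corpus with all records annotated.
#' @export
annotate_corpus <- function(x, lexicon) {
  stopifnot(inherits(x, "lit_corpus"))
  x$records <- lapply(x$records, annotate, lexicon = lexicon)
  x
}

#' Keep only records mentioning at least one gene
#'
#' @param x An annotated [corpus()].
#' @return The filtered corpus; the number of removed records is attached
#'   as attribute `n_removed`.
#' @export
filter_gene_bearing <- function(x) {
  stopifnot(inherits(x, "lit_corpus"))
  keep <- vapply(
    x$records,
    function(r) length(r$genes %||% character()) > 0L, logical(1)
  )
  out <- corpus(x$records[keep], provenance = x$provenance)
  attr(out, "n_removed") <- sum(!keep)
  out
}
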