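## Count-based statistics over an annotated, geo-resolved corpus:
## gene-by-country abstract counts, the effort fraction, collaboration
## pairs, top-K rankings, and genes untouched by a given country set.

UNRESOLVED_ROW <- "(unresolved)"

#' Gene-by-country abstract counts
#'
#' Cell (country, gene) counts the abstracts affiliated with that country
#' whose gene set contains that gene: presence per abstract, never token
#' frequency, and a multi-country abstract counts fully toward each of its
#' countries. Records with an empty country set are kept in a reserved
#' `"(unresolved)"` row so that totals stay checkable.
#'
#' @param x An annotated, geo-resolved [corpus()].
#' @return An object of class `gene_country_counts`: a list with `counts`
#'   (integer matrix country x gene), `papers` (abstracts per country,
#'   the row margin), and `gene_totals` (abstracts per gene over the whole
#'   corpus, the column margin).
#' @export
gene_country_counts <- function(x) {
  stopifnot(inherits(x, "lit_corpus"))
  recs <- x$records
  genes <- sort(unique(unlist(lapply(recs, function(r) r$genes %||% character()))))
  rec_countries <- lapply(recs, function(r) {
    cc <- r$countries %||% character()
    if (length(cc) == 0L) UNRESOLVED_ROW else cc
  })
  countries <- sort(unique(unlist(rec_countries)))
  counts <- matrix(0L, length(countries), length(genes),
    dimnames = list(countries, genes)
  )
  papers <- stats::setNames(integer(length(countries)), countries)
  gene_totals <- stats::setNames(integer(length(genes)), genes)
  for (i in seq_along(recs)) {
    g <- recs[[i]]$genes %||% character()
    cc <- rec_countries[[i]]
    papers[cc] <- papers[cc] + 1L
    if (length(g)) {
      counts[cc, g] <- counts[cc, g] + 1L
      gene_totals[g] <- gene_totals[g] + 1L
    }
  }
  structure(
    list(counts = counts, papers = papers, gene_totals = gene_totals),
    class = "gene_country_counts"
  )
}

#' @export
print.gene_country_counts <- function(x, ...) {
  cat(sprintf(
    "<gene_country_counts> %d countries x %d genes, %d abstracts\n",
    nrow(x$counts), ncol(x$counts), sum(x$papers)
  ))
  invisible(x)
}

#' Research effort fractions
#'
#' Effort of country X on gene Y is the number of abstracts from X that
#' mention Y divided by the number of papers published from X. Rows need
#' not sum to 1: a multi-gene abstract contributes to several cells. The
#' reserved unresolved row and any zero-paper country are excluded (the
#' latter with a warning).
#'
#' @param counts A [gene_country_counts()] object.
#' @return Matrix country x gene of fractions in `[0, 1]`, class
#'   `effort_matrix`.
#' @export
effort <- function(counts) {
  stopifnot(inherits(counts, "gene_country_counts"))
  keep <- rownames(counts$counts) != UNRESOLVED_ROW
  zero <- counts$papers[keep] == 0
  if (any(zero)) {
    warning(
      "excluding zero-paper countries: ",
      paste(names(counts$papers[keep])[zero], collapse = ", ")
    )
  }
  rows <- rownames(counts$counts)[keep][!zero]
  m <- counts$counts[rows, , drop = FALSE] / counts$papers[rows]
  structure(m, class = c("effort_matrix", class(m)))
}

#' International collaboration counts
#'
#' A paper affiliated with institutions in `k >= 2` distinct countries
#' increments every unordered pair among them by one.
#'
#' @param x An annotated, geo-resolved [corpus()].
#' @return Data frame `country_a`, `country_b` (sorted within pair and
#'   lexicographically across rows), `n_papers`.
#' @export
collaborations <- function(x) {
  stopifnot(inherits(x, "lit_corpus"))
  pairs <- list()
  for (r in x$records) {
    cc <- sort(r$countries %||% character())
    if (length(cc) >= 2L) {
      pairs[[length(pairs) + 1L]] <- t(utils::combn(cc, 2L))
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(
      country_a = character(), country_b = character(),
      n_papers = integer()
    ))
  }
  all <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(all) <- c("country_a", "country_b")
  agg <- stats::aggregate(
    list(n_papers = rep(1L, nrow(all))),
    by = all, FUN = sum
  )
  agg <- agg[order(agg$country_a, agg$country_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Top-K countries or genes by abstract count
#'
#' Descending by count with ties broken lexicographically by name; the
#' reserved unresolved row never enters a ranking.
#'
#' @param counts A [gene_country_counts()] object.
#' @param axis `"country"` (ranked by abstracts per country) or `"gene"`
#'   (ranked by abstracts mentioning the gene).
#' @param k Number of entries; if larger than the axis, all are returned
#'   with a warning.
#' @return Data frame `name`, `n_abstracts`.
#' @export
top_k <- function(counts, axis = c("country", "gene"), k) {
  stopifnot(inherits(counts, "gene_country_counts"), k >= 1)
  axis <- match.arg(axis)
  v <- if (axis == "country") {
    counts$papers[names(counts$papers) != UNRESOLVED_ROW]
  } else {
    counts$gene_totals
  }
  if (k > length(v)) {
    warning("k = ", k, " exceeds axis size ", length(v), "; returning all")
    k <- length(v)
  }
  ord <- order(-v, names(v))
  head <- ord[seq_len(k)]
  data.frame(
    name = names(v)[head], n_abstracts = unname(v[head]),
    stringsAsFactors = FALSE
  )
}

#' Genes unmentioned by a set of countries
#'
#' Exactly the genes whose counts are zero over every listed country but
#' that are mentioned somewhere in the corpus (column margin > 0).
#'
#' @param counts A [gene_country_counts()] object.
#' @param countries Character vector of country row labels.
#' @return Sorted character vector of gene symbols.
#' @export
unmentioned_by <- function(counts, countries) {
  stopifnot(inherits(counts, "gene_country_counts"))
  missing <- setdiff(countries, rownames(counts$counts))
  if (length(missing)) {
    stop("unknown countries: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- counts$counts[countries, , drop = FALSE]
  hit_elsewhere <- counts$gene_totals > 0
  zero_here <- colSums(sub) == 0
  sort(names(which(zero_here & hit_elsewhere)))
}

#' Export a count or effort matrix as tidy CSV
#'
#' @param m A matrix with country rows and gene columns.
#' @param path Output path.
#' @param value_name Column name for the cell value.
#' @export
write_tidy_matrix <- function(m, path, value_name = "value") {
  df <- data.frame(
    country = rep(rownames(m), times = ncol(m)),
    gene = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    stringsAsFactors = FALSE
  )
  names(df)[3] <- value_name
  df <- df[order(df$country, df$gene), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
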