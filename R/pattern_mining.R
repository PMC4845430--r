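## Transaction databases over countries and years, and frequent-itemset
## mining with closed/maximal filtering. Two mining routes are provided:
## a depth-first enumeration of all frequent itemsets (exact, intended for
## small item universes) and a transaction-intersection miner that
## enumerates closed itemsets directly. The second is the workhorse for
## corpus-scale data, where transactions are long (hundreds of genes per
## country) and the full frequent collection is astronomically large while
## the closed collection stays small.

#' Construct a transaction database
#'
#' @param transactions Named list: one entry per transaction id (a country
#'   name or a year), each a character vector of gene symbols. Empty
#'   transactions are dropped.
#' @return Object of class `transaction_db` with elements `transactions`
#'   (each sorted unique) and `n`.
#' @export
transaction_db <- function(transactions) {
  stopifnot(is.list(transactions))
  if (length(transactions) && is.null(names(transactions))) {
    stop("transactions must be named by country or year", call. = FALSE)
  }
  if (anyDuplicated(names(transactions))) {
    stop("duplicate transaction ids", call. = FALSE)
  }
  transactions <- lapply(transactions, function(t) sort(unique(as.character(t))))
  transactions <- transactions[vapply(transactions, length, integer(1)) > 0L]
  structure(
    list(transactions = transactions, n = length(transactions)),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf(
    "<transaction_db> %d transactions, %d distinct items\n",
    x$n, length(unique(unlist(x$transactions)))
  ))
  invisible(x)
}

#' Build gene-country transactions
#'
#' One transaction per resolved country; its item set holds every gene
#' appearing in at least one abstract affiliated with that country
#' (binary presence, no minimum abstract count). Unresolved records
#' contribute nothing.
#'
#' @param x An annotated, geo-resolved [corpus()].
#' @return A [transaction_db()].
#' @export
build_country_transactions <- function(x) {
  stopifnot(inherits(x, "lit_corpus"))
  acc <- list()
  for (r in x$records) {
    g <- r$genes %||% character()
    if (length(g) == 0L) next
    for (cc in r$countries %||% character()) {
      acc[[cc]] <- c(acc[[cc]], g)
    }
  }
  transaction_db(acc)
}

#' Build gene-year transactions
#'
#' One transaction per distinct publication year; its item set holds every
#' gene mentioned that year. Year-less records are skipped and counted in
#' the `n_skipped` attribute.
#'
#' @param x An annotated [corpus()].
#' @return A [transaction_db()] with attribute `n_skipped`.
#' @export
build_year_transactions <- function(x) {
  stopifnot(inherits(x, "lit_corpus"))
  acc <- list()
  skipped <- 0L
  for (r in x$records) {
    g <- r$genes %||% character()
    if (length(g) == 0L) next
    if (is.na(r$year)) {
      skipped <- skipped + 1L
      next
    }
    y <- as.character(r$year)
    acc[[y]] <- c(acc[[y]], g)
  }
  db <- transaction_db(acc[order(names(acc))])
  attr(db, "n_skipped") <- skipped
  db
}

#' Percent support
#'
#' `100 * count / n`, rounded half-even to two decimals — the scale the
#' mined-itemset reports print.
#'
#' @param count Transactions containing the itemset.
#' @param n Total transactions (> 0).
#' @return Numeric percent in `[0, 100]`.
#' @export
support_pct <- function(count, n) {
  if (any(n == 0)) stop("empty transaction database (n = 0)", call. = FALSE)
  stopifnot(all(count >= 0), all(count <= n))
  round2(100 * count / n)
}

## smallest absolute count meeting a percent threshold
min_count_for <- function(min_support_pct, n) {
  as.integer(ceiling(n * min_support_pct / 100 - 1e-9))
}

itemset_frame <- function(items_list, counts, n) {
  keys <- vapply(items_list, paste, character(1), collapse = ",")
  df <- data.frame(
    items = keys,
    size = vapply(items_list, length, integer(1)),
    support_count = as.integer(counts),
    support_pct = support_pct(counts, n),
    stringsAsFactors = FALSE
  )
  df$closed <- rep(NA, nrow(df))
  df$maximal <- rep(NA, nrow(df))
  ## descending support, then smaller cardinality, then lexicographic
  df <- df[order(-df$support_count, df$size, df$items), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_transactions") <- n
  class(df) <- c("mined_itemsets", class(df))
  df
}

#' Mine all frequent itemsets
#'
#' Depth-first search over the item lattice with transaction-id lists and
#' support pruning. Output is exactly the brute-force collection: every
#' itemset whose percent support meets the threshold, with its exact
#' count. Intended for item universes small enough that the frequent
#' collection is enumerable; for corpus-scale transaction databases use
#' [mine_maximal_closed()].
#'
#' @param db A [transaction_db()].
#' @param min_support_pct Threshold in `(0, 100]`.
#' @return Data frame of class `mined_itemsets`: `items` (comma-joined,
#'   sorted), `size`, `support_count`, `support_pct`, and `closed` /
#'   `maximal` flags left `NA` until [filter_closed_maximal()].
#' @export
mine_frequent <- function(db, min_support_pct) {
  stopifnot(inherits(db, "transaction_db"))
  if (!(min_support_pct > 0 && min_support_pct <= 100)) {
    stop("min_support_pct must be in (0, 100]", call. = FALSE)
  }
  n <- db$n
  if (n == 0L) {
    return(itemset_frame(list(), integer(), 1L)[0, ])
  }
  minc <- max(1L, min_count_for(min_support_pct, n))
  items <- sort(unique(unlist(db$transactions)))
  tid <- lapply(items, function(it) {
    which(vapply(db$transactions, function(t) it %in% t, logical(1)))
  })
  names(tid) <- items
  supp <- vapply(tid, length, integer(1))
  keep <- supp >= minc
  items <- items[keep]
  tid <- tid[keep]
  out_items <- list()
  out_counts <- integer()
  recurse <- function(prefix, prefix_tid, candidates) {
    for (i in seq_along(candidates)) {
      it <- candidates[i]
      new_tid <- if (length(prefix) == 0L) {
        tid[[it]]
      } else {
        intersect(prefix_tid, tid[[it]])
      }
      if (length(new_tid) < minc) next
      new_set <- c(prefix, it)
      out_items[[length(out_items) + 1L]] <<- new_set
      out_counts[[length(out_counts) + 1L]] <<- length(new_tid)
      if (i < length(candidates)) {
        recurse(new_set, new_tid, candidates[(i + 1L):length(candidates)])
      }
    }
  }
  recurse(character(), integer(), items)
  itemset_frame(out_items, out_counts, n)
}

#' Flag closed and maximal itemsets
#'
#' Over a *complete* frequent collection at one threshold: an itemset is
#' maximal if none of its supersets is frequent, and closed if none of its
#' supersets has equal support. (A non-frequent superset always has
#' strictly lower support than a frequent set, so checking within the
#' collection is exact.)
#'
#' @param itemsets A complete [mine_frequent()] result.
#' @return The same frame with `closed` and `maximal` filled in.
#' @export
filter_closed_maximal <- function(itemsets) {
  stopifnot(inherits(itemsets, "mined_itemsets"))
  k <- nrow(itemsets)
  sets <- strsplit(itemsets$items, ",", fixed = TRUE)
  closed <- rep(TRUE, k)
  maximal <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j || itemsets$size[j] <= itemsets$size[i]) next
      if (all(sets[[i]] %in% sets[[j]])) {
        maximal[i] <- FALSE
        if (itemsets$support_count[j] == itemsets$support_count[i]) {
          closed[i] <- FALSE
        }
      }
    }
  }
  itemsets$closed <- closed
  itemsets$maximal <- maximal
  itemsets
}

#' Mine closed (and maximal closed) frequent itemsets directly
#'
#' Enumerates closed itemsets as intersections of transaction subsets
#' (incremental intersection lattice), then keeps those meeting the
#' support threshold. Maximal itemsets are always closed, and every
#' frequent superset of a closed set has a closed frequent superset, so
#' the maximal flag computed within the closed collection equals the flag
#' over the full frequent collection. Exact for any input; efficient
#' whenever the number of distinct closed sets is modest, as it is for
#' country and year transaction databases.
#'
#' @inheritParams mine_frequent
#' @return A `mined_itemsets` frame of the closed frequent itemsets with
#'   `closed`/`maximal` flags set.
#' @export
mine_maximal_closed <- function(db, min_support_pct) {
  stopifnot(inherits(db, "transaction_db"))
  if (!(min_support_pct > 0 && min_support_pct <= 100)) {
    stop("min_support_pct must be in (0, 100]", call. = FALSE)
  }
  n <- db$n
  if (n == 0L) {
    return(itemset_frame(list(), integer(), 1L)[0, ])
  }
  items <- sort(unique(unlist(db$transactions)))
  p <- length(items)
  ## transaction incidence, one logical row per transaction
  tmat <- t(vapply(db$transactions, function(t) items %in% t, logical(p)))
  dim(tmat) <- c(n, p)
  ## closed sets = all intersections of transaction subsets, built
  ## incrementally as bit vectors keyed by their member indices
  closed <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    trow <- tmat[i, ]
    cand <- c(
      lapply(ls(closed), function(k) get(k, envir = closed) & trow),
      list(trow)
    )
    for (s in cand) {
      if (!any(s)) next
      key <- paste(which(s), collapse = ".")
      if (is.null(closed[[key]])) closed[[key]] <- s
    }
  }
  keys <- ls(closed)
  if (length(keys) == 0L) {
    return(itemset_frame(list(), integer(), n))
  }
  smat <- t(vapply(keys, function(k) get(k, envir = closed), logical(p)))
  dim(smat) <- c(length(keys), p)
  sizes <- rowSums(smat)
  ## set i is contained in transaction j iff the overlap has |set i| items
  counts <- as.integer(rowSums((smat %*% t(tmat)) == sizes))
  minc <- max(1L, min_count_for(min_support_pct, n))
  keep <- counts >= minc
  smat <- smat[keep, , drop = FALSE]
  sizes <- sizes[keep]
  counts <- counts[keep]
  sets <- lapply(seq_len(nrow(smat)), function(i) items[smat[i, ]])
  df <- itemset_frame(sets, counts, n)
  df$closed <- rep(TRUE, nrow(df))
  ## maximal: no larger frequent closed set contains it (cross-containment
  ## via inner products: set i inside set j iff overlap == |set i|)
  cross <- smat %*% t(smat)
  has_super <- vapply(seq_len(nrow(smat)), function(i) {
    any(cross[i, ] == sizes[i] & sizes > sizes[i])
  }, logical(1))
  key_by_items <- vapply(sets, paste, character(1), collapse = ",")
  df$maximal <- !has_super[match(df$items, key_by_items)]
  df
}

#' Support of one itemset in a database
#'
#' @param db A [transaction_db()].
#' @param items Character vector of items.
#' @return Integer count of transactions containing all `items`.
#' @export
itemset_support <- function(db, items) {
  stopifnot(inherits(db, "transaction_db"))
  sum(vapply(db$transactions, function(t) all(items %in% t), logical(1)))
}

#' Read / write transaction databases in basket format
#'
#' One transaction per line: `id TAB comma-joined items`.
#'
#' @param db A [transaction_db()].
#' @param path File path.
#' @export
write_baskets <- function(db, path) {
  stopifnot(inherits(db, "transaction_db"))
  lines <- vapply(names(db$transactions), function(id) {
    paste0(id, "\t", paste(db$transactions[[id]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_baskets
#' @export
read_baskets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) {
    stop("malformed basket line ", bad[1], call. = FALSE)
  }
  ids <- vapply(parts, `[`, character(1), 1L)
  items <- lapply(parts, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  transaction_db(stats::setNames(items, ids))
}
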