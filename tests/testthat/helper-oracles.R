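## Independent brute-force oracles and tiny fixture builders shared by the
## test files. Oracles deliberately use naive algorithms (full enumeration)
## so they share no code path with the implementation they check.

## Strip container classes/attributes so frames compare on content only.
plain_df <- function(d) {
  d <- as.data.frame(d)
  class(d) <- "data.frame"
  attr(d, "n_transactions") <- NULL
  rownames(d) <- NULL
  d
}

make_record <- function(id, title = "A title.", abstract = "An abstract.",
                        year = 2010, journal = "J", affs = "Somewhere, USA",
                        genes = NULL, countries = NULL) {
  r <- abstract_record(
    record_id = id, title = title, abstract = abstract, year = year,
    journal = journal,
    authors = if (length(affs)) list(author("A", "B", affs)) else list()
  )
  if (!is.null(genes)) r$genes <- sort(unique(genes))
  if (!is.null(countries)) r$countries <- sort(unique(countries))
  r
}

toy_gazetteer <- function() {
  build_gazetteer(data.frame(
    alias = c("Canada", "Turkey", "USA", "United States"),
    canonical = c("Canada", "Turkey", "United States", "United States"),
    kind = "alias"
  ))
}

is_boundary_char <- function(ch) !grepl("[A-Za-z0-9]", ch)

## Brute-force dictionary matcher: try every synonym at every offset,
## keep longest-leftmost non-overlapping matches. Case policy: synonyms
## of <= 3 characters match exactly, longer ones case-insensitively.
brute_match <- function(text, lexicon) {
  syns <- names(lexicon)
  nc <- nchar(text)
  res <- data.frame(start = integer(), len = integer(), symbol = character())
  pos <- 1L
  while (pos <= nc) {
    best_len <- 0L
    best_sym <- NA_character_
    for (s in syns) {
      ls <- nchar(s)
      if (pos + ls - 1L > nc) next
      sub <- substr(text, pos, pos + ls - 1L)
      hit <- if (ls <= 3L) identical(sub, s) else tolower(sub) == tolower(s)
      if (!hit) next
      before_ok <- pos == 1L || is_boundary_char(substr(text, pos - 1L, pos - 1L))
      after_ok <- pos + ls - 1L == nc ||
        is_boundary_char(substr(text, pos + ls, pos + ls))
      if (before_ok && after_ok && ls > best_len) {
        best_len <- ls
        best_sym <- unname(lexicon[[s]])
      }
    }
    if (best_len > 0L) {
      res <- rbind(res, data.frame(
        start = pos, len = best_len, symbol = best_sym
      ))
      pos <- pos + best_len
    } else {
      pos <- pos + 1L
    }
  }
  res
}

## Brute-force frequent itemset mining: enumerate every non-empty subset
## of the item universe, count support directly, flag closed/maximal by
## superset scan over all subsets.
brute_itemsets <- function(db, min_support_pct) {
  items <- sort(unique(unlist(db$transactions)))
  stopifnot(length(items) <= 14)
  n <- db$n
  subsets <- list()
  for (mask in seq_len(2^length(items) - 1L)) {
    subsets[[mask]] <- items[bitwAnd(mask, 2^(seq_along(items) - 1L)) > 0]
  }
  supp <- vapply(subsets, function(s) {
    sum(vapply(db$transactions, function(t) all(s %in% t), logical(1)))
  }, numeric(1))
  frequent <- 100 * supp / n >= min_support_pct - 1e-9
  is_superset <- function(a, b) length(b) < length(a) && all(b %in% a)
  closed <- maximal <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    if (!frequent[i]) next
    closed[i] <- !any(vapply(seq_along(subsets), function(j) {
      is_superset(subsets[[j]], subsets[[i]]) && supp[j] == supp[i]
    }, logical(1)))
    maximal[i] <- !any(vapply(seq_along(subsets), function(j) {
      is_superset(subsets[[j]], subsets[[i]]) && frequent[j]
    }, logical(1)))
  }
  keep <- which(frequent)
  data.frame(
    items = vapply(subsets[keep], paste, character(1), collapse = ","),
    support_count = as.integer(supp[keep]),
    closed = closed[keep],
    maximal = maximal[keep],
    stringsAsFactors = FALSE
  )
}

## Brute-force betweenness (normalized) and harmonic closeness from an
## adjacency matrix, via explicit shortest-path counting.
brute_centralities <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  ## sigma[s, t]: number of shortest s-t paths (DP by increasing distance)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (t in reach[order(d[s, reach])]) {
      if (t == s) next
      preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t]) || sigma[s, t] == 0) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  denom <- (n - 1) * (n - 2) / 2
  clo <- vapply(seq_len(n), function(v) {
    sum(1 / d[v, -v][is.finite(d[v, -v])]) / (n - 1)
  }, numeric(1))
  list(betweenness = if (denom > 0) btw / denom else btw * 0, closeness = clo)
}

## Direct (loop-based) implementation of the two fuzzy c-means update
## formulas, run from given initial centers.
fcm_reference <- function(x, centers, m, iters) {
  c_ <- nrow(centers)
  n <- nrow(x)
  u <- matrix(0, n, c_)
  for (it in seq_len(iters)) {
    for (k in seq_len(n)) {
      dk <- vapply(seq_len(c_), function(i) sqrt(sum((x[k, ] - centers[i, ])^2)), numeric(1))
      if (any(dk < 1e-9)) {
        u[k, ] <- as.numeric(dk < 1e-9) / sum(dk < 1e-9)
      } else {
        for (i in seq_len(c_)) {
          u[k, i] <- 1 / sum((dk[i] / dk)^(2 / (m - 1)))
        }
      }
    }
    for (i in seq_len(c_)) {
      w <- u[, i]^m
      centers[i, ] <- colSums(w * x) / sum(w)
    }
  }
  list(centers = centers, membership = u)
}

## Random small transaction db under the current RNG state.
random_db <- function(n_items = 6, n_trans = 10) {
  items <- LETTERS[seq_len(n_items)]
  tr <- lapply(seq_len(n_trans), function(i) {
    items[runif(n_items) < 0.45]
  })
  tr <- tr[vapply(tr, length, integer(1)) > 0]
  names(tr) <- paste0("t", seq_along(tr))
  transaction_db(tr)
}
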