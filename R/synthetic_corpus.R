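## Deterministic generator of annotated corpora with planted structure:
## gene communities with intra/inter co-mention rates, per-country
## preferred genes, per-year trending genes, itemsets planted into a fixed
## fraction of year transactions, and affiliation strings rendered as raw
## comma-delimited text so the country resolver has real work to do.

default_synthetic_countries <- function() {
  mk <- function(name, alias, city, inst) {
    list(name = name, alias = alias, city = city, institute = inst)
  }
  list(
    mk("United States", "USA", "Boston", "Beacon Cancer Institute"),
    mk("United Kingdom", "UK", "Cambridge", "Fenland Oncology Centre"),
    mk("China", "China", "Shanghai", "Huangpu Medical University"),
    mk("Japan", "Japan", "Osaka", "Kansai Genomics Institute"),
    mk("Germany", "Germany", "Heidelberg", "Neckar Tumor Biology Unit"),
    mk("Canada", "AB Canada", "Calgary", "Foothills Research Hospital"),
    mk("Turkey", "Turkey", "Ankara", "Anatolia University"),
    mk("France", "France", "Lyon", "Rhone Institute of Oncology")
  )
}

#' Specification for a synthetic annotated corpus
#'
#' The defaults define the reference study conditions used throughout the
#' test suite: 2,000 records, three planted co-mention communities of 15
#' genes each with intra-block rate `p_in = 0.6` and inter-block rate
#' `p_out = 0.02`, eight countries (one preferred gene each, boosted with
#' probability 0.5 in that country's records), twenty publication years
#' with one late-trending gene, and one three-gene itemset planted into
#' 80% of year transactions via genes that occur nowhere else.
#'
#' @param n_records Number of abstracts.
#' @param n_communities,genes_per_community Planted block structure.
#' @param p_in,p_out Per-gene inclusion probabilities for a record's own
#'   community and for foreign communities.
#' @param countries List of country descriptors (`name`, `alias`, `city`,
#'   `institute`); preferred genes are assigned round-robin from the
#'   community genes.
#' @param pref_boost Probability that a record additionally mentions its
#'   country's preferred gene.
#' @param second_country_prob Probability that a record is affiliated
#'   with two countries (otherwise one).
#' @param years Integer vector of publication years, sampled uniformly.
#' @param trend_gene,trend_years,trend_boost A gene given extra inclusion
#'   probability in the listed years.
#' @param planted_itemsets List of `list(items =, fraction =)`; item
#'   symbols outside the community blocks are generated only by planting.
#' @param genes_per_abstract Poisson mean for the no-community sampling
#'   mode (`n_communities = 0`), truncated at a minimum of 1.
#' @param seed Integer; the generator is a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 2000L,
                           n_communities = 3L,
                           genes_per_community = 15L,
                           p_in = 0.6,
                           p_out = 0.02,
                           countries = default_synthetic_countries(),
                           pref_boost = 0.5,
                           second_country_prob = 0.1,
                           years = 1995:2014,
                           trend_gene = NULL,
                           trend_years = 2010:2014,
                           trend_boost = 0.3,
                           planted_itemsets = list(
                             list(items = c("PX01", "PX02", "PX03"), fraction = 0.8)
                           ),
                           genes_per_abstract = 2,
                           seed = 42L) {
  stopifnot(
    n_records >= 1, p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
    second_country_prob >= 0, second_country_prob <= 1,
    pref_boost >= 0, pref_boost <= 1, length(countries) >= 1
  )
  comm_genes <- if (n_communities > 0) {
    lapply(seq_len(n_communities), function(b) {
      sprintf("G%s%02d", LETTERS[b], seq_len(genes_per_community))
    })
  } else {
    list()
  }
  ## without communities, sampling falls back to a background gene pool
  ## drawn with the truncated-Poisson genes_per_abstract count
  genes <- if (n_communities > 0) {
    unlist(comm_genes)
  } else {
    sprintf("BG%02d", seq_len(20L))
  }
  if (length(genes) == 0L && length(planted_itemsets) == 0L) {
    stop("infeasible spec: no genes at all", call. = FALSE)
  }
  if (is.null(trend_gene) && length(genes)) trend_gene <- genes[1]
  for (ps in planted_itemsets) {
    stopifnot(ps$fraction >= 0, ps$fraction <= 1, length(ps$items) >= 1)
  }
  prefs <- if (length(genes)) {
    genes[((seq_along(countries) - 1L) %% length(genes)) + 1L]
  } else {
    rep(NA_character_, length(countries))
  }
  structure(
    list(
      n_records = as.integer(n_records),
      communities = comm_genes,
      genes = genes,
      p_in = p_in, p_out = p_out,
      countries = countries,
      preferred = stats::setNames(
        prefs,
        vapply(countries, `[[`, character(1), "name")
      ),
      pref_boost = pref_boost,
      second_country_prob = second_country_prob,
      years = as.integer(years),
      trend_gene = trend_gene,
      trend_years = as.integer(trend_years),
      trend_boost = trend_boost,
      planted_itemsets = planted_itemsets,
      genes_per_abstract = genes_per_abstract,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d records, %d communities x %d genes (p_in %.2g, p_out %.2g), %d countries, years %d-%d, %d planted itemset(s), seed %d\n",
    x$n_records, length(x$communities),
    if (length(x$communities)) length(x$communities[[1]]) else 0L,
    x$p_in, x$p_out, length(x$countries),
    min(x$years), max(x$years), length(x$planted_itemsets), x$seed
  ))
  invisible(x)
}

render_affiliation <- function(country, style) {
  if (style == 1L) {
    sprintf(
      "Department of Oncology, %s, %s, %s",
      country$institute, country$city, country$alias
    )
  } else {
    sprintf("%s, %s, %s", country$institute, country$city, country$alias)
  }
}

render_text <- function(genes) {
  if (length(genes) == 0L) {
    return(list(
      title = "Psychosocial aspects of breast cancer care.",
      abstract = paste(
        "We surveyed quality of life in a breast cancer cohort.",
        "No molecular markers were assessed in this study."
      )
    ))
  }
  lead <- genes[1]
  rest <- genes[-1]
  list(
    title = sprintf("Expression of %s in breast cancer.", lead),
    abstract = paste0(
      "We analysed ", paste(genes, collapse = ", "),
      " in breast tumour samples. Expression of ", lead,
      " was associated with clinical outcome."
    )
  )
}

#' Generate a synthetic annotated corpus
#'
#' Each record draws a country set (one country with probability
#' `1 - second_country_prob`, two otherwise), a year, and a gene set by
#' sampling a community and including its genes at rate `p_in` and
#' foreign genes at rate `p_out`, plus country-preference and year-trend
#' boosts. Affiliations are rendered as raw comma-delimited strings and
#' must be re-parsed by the country resolver; gene mentions are embedded
#' in the abstract text so the dictionary matcher has real input. Planted
#' itemsets are injected into one record of each selected year so that
#' their year-transaction support hits the target fraction exactly
#' (their genes occur nowhere else). Fully determined by `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `corpus` (an annotated, unresolved [corpus()]:
#'   gene sets filled, countries left for the resolver) and `truth`
#'   (class `planted_truth`: `community` per gene, `preferred` gene per
#'   country, `planted_years` per itemset, `record_countries`,
#'   `record_genes`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_records
    B <- length(spec$communities)
    country_names <- vapply(spec$countries, `[[`, character(1), "name")
    rec_comm <- if (B > 0) sample.int(B, n, replace = TRUE) else rep(0L, n)
    rec_year <- sample(spec$years, n, replace = TRUE)
    rec_genes <- vector("list", n)
    rec_countries <- vector("list", n)
    for (i in seq_len(n)) {
      k <- if (runif(1) < spec$second_country_prob && length(spec$countries) >= 2) 2L else 1L
      cs <- sample(country_names, k)
      rec_countries[[i]] <- sort(cs)
      g <- character()
      if (B > 0) {
        for (b in seq_len(B)) {
          p <- if (b == rec_comm[i]) spec$p_in else spec$p_out
          block <- spec$communities[[b]]
          g <- c(g, block[runif(length(block)) < p])
        }
      } else if (length(spec$genes)) {
        n_g <- max(1L, stats::rpois(1, spec$genes_per_abstract))
        g <- sample(spec$genes, min(n_g, length(spec$genes)))
      }
      for (cn in cs) {
        pg <- spec$preferred[[cn]]
        if (!is.na(pg) && runif(1) < spec$pref_boost) g <- c(g, pg)
      }
      if (!is.null(spec$trend_gene) && rec_year[i] %in% spec$trend_years &&
        runif(1) < spec$trend_boost) {
        g <- c(g, spec$trend_gene)
      }
      rec_genes[[i]] <- sort(unique(g))
    }
    ## plant itemsets into a fixed fraction of year transactions
    planted_years <- list()
    present_years <- sort(unique(rec_year))
    for (ps in spec$planted_itemsets) {
      n_sel <- round(ps$fraction * length(present_years))
      sel <- sort(sample(present_years, n_sel))
      planted_years[[paste(sort(ps$items), collapse = ",")]] <- sel
      for (y in sel) {
        idx <- which(rec_year == y)
        target <- idx[sample.int(length(idx), 1L)]
        rec_genes[[target]] <- sort(unique(c(rec_genes[[target]], ps$items)))
      }
    }
    records <- lapply(seq_len(n), function(i) {
      txt <- render_text(rec_genes[[i]])
      authors <- lapply(rec_countries[[i]], function(cn) {
        ctry <- spec$countries[[match(cn, country_names)]]
        author(
          given = sprintf("Author%02d", (i %% 40L) + 1L),
          family = sprintf("Lastname%02d", (i %% 25L) + 1L),
          affiliations = render_affiliation(ctry, style = (i %% 2L) + 1L)
        )
      })
      r <- abstract_record(
        record_id = sprintf("SYN%06d", i),
        title = txt$title,
        abstract = txt$abstract,
        year = rec_year[i],
        journal = "Journal of Synthetic Oncology",
        authors = authors
      )
      r$genes <- rec_genes[[i]]
      r
    })
    community <- stats::setNames(
      rep(seq_along(spec$communities), vapply(spec$communities, length, integer(1))),
      unlist(spec$communities)
    )
    truth <- structure(
      list(
        community = community,
        preferred = spec$preferred,
        planted_years = planted_years,
        record_countries = rec_countries,
        record_genes = rec_genes
      ),
      class = "planted_truth"
    )
    list(
      corpus = corpus(records, provenance = sprintf("synthetic(seed=%d)", spec$seed)),
      truth = truth
    )
  })
}

#' Lexicon and gazetteer matching a synthetic spec
#'
#' The lexicon maps every spec gene to itself plus a `<symbol> protein`
#' synonym; the gazetteer rows cover the spec countries' aliases. Both
#' are exactly what the downstream annotate/resolve stages need to
#' recover the generator's planted annotations from rendered text.
#'
#' @param spec A [synthetic_spec()].
#' @return A data frame suitable for [build_lexicon()] /
#'   [build_gazetteer()].
#' @export
synthetic_lexicon_rows <- function(spec) {
  genes <- sort(unique(c(
    spec$genes,
    unlist(lapply(spec$planted_itemsets, `[[`, "items"))
  )))
  data.frame(
    symbol = rep(genes, 2L),
    synonym = c(genes, paste(genes, "protein")),
    stringsAsFactors = FALSE
  )
}

#' @rdname synthetic_lexicon_rows
#' @export
synthetic_gazetteer_rows <- function(spec) {
  do.call(rbind, lapply(spec$countries, function(ctry) {
    data.frame(
      alias = unique(c(ctry$name, ctry$alias)),
      canonical = ctry$name,
      kind = "alias",
      stringsAsFactors = FALSE
    )
  }))
}

#' Analytic expected transaction support under the generator model
#'
#' For a planted itemset, the expected (here: exact) fraction of year
#' transactions containing it is its planted fraction, because its genes
#' are generated only by planting. For itemsets of community genes the
#' probability that a transaction of `k` records contains every item is
#' computed by inclusion-exclusion over the items,
#' `sum_S (-1)^|S| [P(one record misses all of S)]^k`, with the
#' per-record miss probability conditioned on the record's community.
#' Country-preference and year-trend boosts are not folded in; use specs
#' without boosts when exactness matters.
#'
#' @param spec A [synthetic_spec()].
#' @param items Character vector of gene symbols.
#' @param k Number of records in the transaction.
#' @return Probability in `[0, 1]`.
#' @export
expected_support <- function(spec, items, k) {
  stopifnot(inherits(spec, "synthetic_spec"), length(items) >= 1)
  for (ps in spec$planted_itemsets) {
    if (setequal(items, ps$items)) return(ps$fraction)
  }
  planted_only <- unlist(lapply(spec$planted_itemsets, `[[`, "items"))
  if (any(items %in% setdiff(planted_only, spec$genes))) {
    return(0)
  }
  if (!all(items %in% spec$genes)) return(0)
  B <- length(spec$communities)
  p_gene_given_comm <- function(g, b) {
    if (g %in% spec$communities[[b]]) spec$p_in else spec$p_out
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(items)))
  total <- 0
  for (s in seq_len(nrow(subsets))) {
    sel <- items[unlist(subsets[s, ])]
    miss_one <- mean(vapply(seq_len(B), function(b) {
      prod(vapply(sel, function(g) 1 - p_gene_given_comm(g, b), numeric(1)))
    }, numeric(1)))
    total <- total + (-1)^length(sel) * miss_one^k
  }
  ## inclusion-exclusion of "all items present": sum over S of (-1)^|S| P(miss S)^k
  total
}
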