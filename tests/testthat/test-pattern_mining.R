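test_that("country transactions pool genes per resolved country", {
  cp <- corpus(list(
    make_record("1", genes = c("A", "B"), countries = "US"),
    make_record("2", genes = "B", countries = c("US", "CN")),
    make_record("3", genes = "B", countries = "US"), # set semantics
    make_record("4", genes = "C", countries = character()) # unresolved: dropped
  ))
  db <- build_country_transactions(cp)
  expect_identical(db$n, 2L)
  expect_identical(db$transactions$US, c("A", "B"))
  expect_identical(db$transactions$CN, "B")
  expect_identical(build_country_transactions(corpus(list(
    make_record("x", genes = "A", countries = character())
  )))$n, 0L)
})

test_that("year transactions pool genes per year and count skipped records", {
  cp <- corpus(list(
    make_record("1", genes = c("A", "B"), year = 2001, countries = "US"),
    make_record("2", genes = "B", year = 2002, countries = "US"),
    make_record("3", genes = "C", year = 2001, countries = "US"),
    make_record("4", genes = "D", year = NA, countries = "US")
  ))
  db <- build_year_transactions(cp)
  expect_identical(db$n, 2L)
  expect_identical(db$transactions$`2001`, c("A", "B", "C"))
  expect_identical(db$transactions$`2002`, "B")
  expect_identical(attr(db, "n_skipped"), 1L)
})

test_that("support_pct rounds half-even to two decimals", {
  expect_identical(support_pct(77, 159), 48.43)
  expect_identical(support_pct(43, 52), 82.69)
  expect_identical(support_pct(0, 10), 0)
  expect_identical(support_pct(10, 10), 100)
  expect_error(support_pct(1, 0), "n = 0")
  expect_error(support_pct(5, 4))
})

test_that("mine_frequent reproduces the worked four-transaction example", {
  db <- transaction_db(list(t1 = c("A", "B"), t2 = c("A", "B"), t3 = "A", t4 = "B"))
  fi <- mine_frequent(db, 50)
  got <- setNames(fi$support_pct, fi$items)
  expect_identical(got[["A"]], 75)
  expect_identical(got[["B"]], 75)
  expect_identical(got[["A,B"]], 50)
  expect_identical(nrow(fi), 3L)
  flagged <- filter_closed_maximal(fi)
  expect_identical(flagged$maximal[flagged$items == "A,B"], TRUE)
  expect_identical(flagged$closed[flagged$items == "A"], TRUE)
  expect_identical(flagged$maximal[flagged$items == "A"], FALSE)
  ## 100% threshold keeps only itemsets present in every transaction
  expect_identical(nrow(mine_frequent(db, 100)), 0L)
  db2 <- transaction_db(list(t1 = c("A", "B"), t2 = c("A", "B")))
  expect_identical(sort(mine_frequent(db2, 100)$items), c("A", "A,B", "B"))
  ## singleton db: every subset at 100%
  db3 <- transaction_db(list(only = c("X", "Y")))
  fi3 <- mine_frequent(db3, 100)
  expect_setequal(fi3$items, c("X", "Y", "X,Y"))
  expect_true(all(fi3$support_pct == 100))
  ## identical transactions: only the full set is maximal
  db4 <- transaction_db(list(a = c("A", "B", "C"), b = c("A", "B", "C")))
  f4 <- filter_closed_maximal(mine_frequent(db4, 50))
  expect_identical(f4$items[f4$maximal], "A,B,C")
})

test_that("miner matches brute-force enumeration on random databases", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      db <- random_db(n_items = sample(3:7, 1), n_trans = sample(4:12, 1))
      if (db$n == 0) next
      thr <- sample(c(20, 30, 50, 75), 1)
      oracle <- brute_itemsets(db, thr)
      got <- filter_closed_maximal(mine_frequent(db, thr))
      o <- oracle[order(oracle$items), ]
      g <- got[order(got$items), c("items", "support_count", "closed", "maximal")]
      expect_identical(plain_df(g), plain_df(o))
      ## closed-itemset route agrees with the filtered frequent route
      mc <- mine_maximal_closed(db, thr)
      expect_setequal(mc$items, got$items[got$closed])
      expect_identical(
        sort(mc$items[mc$maximal]),
        sort(got$items[got$maximal])
      )
      expect_identical(
        mc$support_count[order(mc$items)],
        got$support_count[got$closed][order(got$items[got$closed])]
      )
    }
  })
})

test_that("anti-monotonicity and maximal-implies-closed hold on mined output", {
  withr::with_seed(31, {
    db <- random_db(n_items = 7, n_trans = 12)
    fi <- filter_closed_maximal(mine_frequent(db, 25))
    sets <- strsplit(fi$items, ",", fixed = TRUE)
    supp <- setNames(fi$support_count, fi$items)
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      if (length(s) > 1) {
        for (drop in seq_along(s)) {
          sub <- paste(s[-drop], collapse = ",")
          expect_true(sub %in% fi$items) # subsets of frequent are frequent
          expect_gte(supp[[sub]], supp[[fi$items[i]]])
        }
      }
    }
    expect_true(all(!fi$maximal | fi$closed))
  })
})

test_that("basket files round-trip transaction databases", {
  db <- transaction_db(list(US = c("B", "A"), `2001` = "C"))
  path <- withr::local_tempfile(fileext = ".basket")
  write_baskets(db, path)
  back <- read_baskets(path)
  expect_identical(back$transactions[sort(names(back$transactions))],
    db$transactions[sort(names(db$transactions))])
  writeLines("broken line with no tab", path)
  expect_error(read_baskets(path), "malformed")
})

test_that("mining input contracts are enforced", {
  db <- transaction_db(list(t1 = "A"))
  expect_error(mine_frequent(db, 0), "min_support_pct")
  expect_error(mine_frequent(db, 101), "min_support_pct")
  expect_identical(nrow(mine_frequent(transaction_db(list()), 50)), 0L)
  expect_error(transaction_db(list(a = "X", a = "Y")), "duplicate")
})
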