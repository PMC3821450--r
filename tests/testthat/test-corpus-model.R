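# Domain types, readers/writers and packaged fixtures.

test_that("whitespace tokenization and default candidate gaps", {
  tx <- phenotext("todo lo traduzco a mi estado.")
  expect_equal(nrow(tx$tokens), 6L)
  expect_equal(tx$candidate_boundaries, 1:5)
  # offsets recover the tokens exactly
  expect_equal(substring(tx$raw, tx$tokens$start, tx$tokens$end),
               tx$tokens$token)

  one <- phenotext("palabra")
  expect_length(one$candidate_boundaries, 0L)

  expect_error(phenotext("   "), "empty")
  expect_error(phenotext("a b c", candidate_boundaries = c(2, 1)),
               "increasing")
  expect_error(phenotext("a b c", candidate_boundaries = 5), "outside")
})

test_that("plain-text reading with line-derived boundaries", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("uno dos tres", "cuatro cinco"), p)
  tx <- read_text(p, candidate_boundaries = "lines")
  expect_equal(tx$candidate_boundaries, c(3L, 5L))  # last = terminus
  tx2 <- read_text(p)
  expect_equal(tx2$candidate_boundaries, 1:4)
})

test_that("text JSON round-trip is field-identical", {
  tx <- phenotext("el encuentro de cualquier frase,", text_id = "t1",
                  language = "es", candidate_boundaries = c(2L, 4L))
  p <- withr::local_tempfile(fileext = ".json")
  write_text(tx, p)
  expect_equal(read_text(p), tx)
})

test_that("segmentation protocol validation and round-trips", {
  expect_error(segmentation_protocol(matrix(2, 1, 1)), "binary")
  expect_error(segmentation_protocol(matrix(nrow = 0, ncol = 3)), "judge")

  m <- matrix(0L, 2, 3)
  p <- segmentation_protocol(m, boundaries = c(1L, 3L, 5L))
  expect_equal(unname(colSums(p$marks)), c(0, 0, 0))

  f_csv <- withr::local_tempfile(fileext = ".csv")
  f_json <- withr::local_tempfile(fileext = ".json")
  pr <- segmentation_protocol(random_marks(5, 4), boundaries = c(2, 4, 6, 8),
                              text_id = "rt")
  write_segmentation_protocol(pr, f_csv)
  got <- read_segmentation_protocol(f_csv)
  got$text_id <- pr$text_id  # csv derives id from filename
  expect_equal(got, pr)
  write_segmentation_protocol(pr, f_json)
  expect_equal(read_segmentation_protocol(f_json), pr)

  # write-read-write is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_segmentation_protocol(got, f2)
  expect_identical(readLines(f_csv), readLines(f2))

  # boundary ids are checked against the text
  tx <- phenotext("a b c d e")
  bad <- segmentation_protocol(random_marks(2, 2), boundaries = c(3, 9))
  f3 <- withr::local_tempfile(fileext = ".json")
  write_segmentation_protocol(bad, f3)
  expect_error(read_segmentation_protocol(f3, text = tx), "not candidates")
})

test_that("attribution protocol invariants and round-trips", {
  sch <- scheme_lanes4()
  expect_error(
    attribution_protocol(counts = matrix(5L, 1, 4), n = 3L, scheme = sch),
    "counts"
  )
  # counts derived from a judge-level indicator tensor
  ind <- array(0L, dim = c(3, 2, 4))
  ind[1, 1, 2] <- 1L; ind[2, 1, 2] <- 1L; ind[3, 2, 4] <- 1L
  ap <- attribution_protocol(n = c(3L, 3L), scheme = sch, indicators = ind,
                             judges_total = 3L)
  expect_equal(unname(ap$counts[1, ]), c(0L, 2L, 0L, 0L))
  expect_equal(unname(ap$counts[2, ]), c(0L, 0L, 0L, 1L))

  # n = 0 is valid but reported as unrecognized
  ap0 <- attribution_protocol(counts = matrix(0L, 1, 4), n = 0L,
                              scheme = sch, judges_total = 5L)
  expect_equal(unrecognized_segments(ap0), 1L)

  f_csv <- withr::local_tempfile(fileext = ".csv")
  f_json <- withr::local_tempfile(fileext = ".json")
  ap2 <- attribution_protocol(counts = rbind(c(1L, 0L, 3L, 2L),
                                             c(0L, 4L, 1L, 0L)),
                              n = c(3L, 4L), scheme = sch,
                              judges_total = 5L, text_id = "rt")
  write_attribution_protocol(ap2, f_csv)
  got <- read_attribution_protocol(f_csv)
  expect_equal(unname(got$counts), unname(ap2$counts))
  expect_equal(got$n, ap2$n)
  expect_equal(got$scheme$codes, sch$codes)
  write_attribution_protocol(ap2, f_json)
  got2 <- read_attribution_protocol(f_json)
  expect_equal(got2$counts, ap2$counts)
  expect_equal(got2$judges_total, 5L)
})

test_that("coded stream validation and JSON round-trip", {
  sch <- scheme_lanes4()
  good <- list(
    list(index = 1L, contents = data.frame(label = "anger", category = "E"),
         causes_next = TRUE),
    list(index = 2L, contents = data.frame(label = c("sensation", "wish"),
                                           category = c("S", "T")),
         causes_next = NA)
  )
  cs <- coded_stream(good, sch, text_id = "mini")
  f <- withr::local_tempfile(fileext = ".json")
  write_coded_stream(cs, f)
  back <- read_coded_stream(f)
  expect_equal(length(back$entries), 2L)
  expect_equal(back$entries[[2]]$contents$category, c("S", "T"))
  # write-read-write byte-stable
  f2 <- withr::local_tempfile(fileext = ".json")
  write_coded_stream(back, f2)
  expect_identical(readLines(f), readLines(f2))

  bad_cat <- good
  bad_cat[[1]]$contents$category <- "X"
  expect_error(coded_stream(bad_cat, sch), "unknown categories")
  bad_idx <- good
  bad_idx[[2]]$index <- 5L
  expect_error(coded_stream(bad_idx, sch), "consecutive")
  bad_cn <- good
  bad_cn[[1]]$causes_next <- NA
  expect_error(coded_stream(bad_cn, sch), "causes_next")
})

test_that("category schemes and mappings", {
  m7 <- scheme_mental7()
  l4 <- scheme_lanes4()
  expect_equal(length(m7$codes), 7L)
  expect_equal(l4$codes, c("S", "E", "T", "I"))
  expect_equal(map_categories(c("Se", "Pr", "Im", "Re"), m7),
               c("S", "S", "I", "T"))
  expect_error(map_categories("XX", m7), "not in parent_map")
  expect_error(category_scheme("x", c("A", "A")), "unique")
  expect_error(category_scheme("x", c("A", "B"), parent_map = c(A = "Z")),
               "total")
})

test_that("journal fixture reconstructs the printed panel", {
  fx <- load_fixture("unamuno_journal")
  expect_length(fx$text$candidate_boundaries, 16L)
  expect_equal(dim(fx$segmentation$marks), c(16L, 16L))
  expect_length(fx$printed$indices, 16L)
  # boundary 4 ("lo que dice mi hijo,"): printed 0.625 -> 10 of 16 judges
  expect_equal(sum(fx$segmentation$marks[, 4]), 10L)
  # per-boundary counts reproduce printed indices within rounding slack
  expect_true(all(abs(colSums(fx$segmentation$marks) / 16 -
                        fx$printed$indices) <= 0.5 / 16 + 0.005))
  expect_equal(fx$attribution$n, c(10L, 14L, 16L, 16L, 15L, 16L, 11L, 16L, 16L))
  # discrepancies: only the three cells not expressible as k/n at 2 decimals
  expect_setequal(fx$discrepancies$location,
                  c("segment 7, In", "segment 8, In", "segment 9, Th"))
  expect_equal(fx$translations[7], "I translate everything to my state.")
})

test_that("monolog fixture has 30 entries and six causality breaks", {
  fx <- load_fixture("joyce_penelope")
  st <- fx$stream
  expect_length(st$entries, 30L)
  cn <- vapply(st$entries[1:29], function(e) e$causes_next, logical(1))
  expect_equal(which(!cn), c(4L, 13L, 16L, 17L, 22L, 26L))
  # entry 7: single emotion content
  expect_equal(st$entries[[7]]$contents,
               data.frame(label = "anger", category = "E",
                          stringsAsFactors = FALSE))
  # entry 5: two simultaneous contents, sensation + wish
  expect_equal(st$entries[[5]]$contents$label, c("sensation", "wish"))
  expect_equal(st$entries[[5]]$contents$category, c("S", "T"))
  # every mappable label agrees with the stored lane
  expect_equal(nrow(fx$discrepancies), 0L)
  expect_true(all(c("label", "category") %in% names(fx$label_map)))
  expect_equal(map_labels(c("ANGER", "fantasy ends"), fx$label_map),
               c("E", "I"))
  expect_true(is.na(map_labels("same", fx$label_map)))
  expect_error(load_fixture("nope"))
})
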