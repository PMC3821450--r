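# Stream model construction, micro-episode detection and exports.

test_that("one place per content, binding only on multi-content segments", {
  fx <- load_fixture("joyce_penelope")
  m <- build_stream(fx$stream)
  expect_equal(m$n_segments, 30L)
  expect_equal(nrow(m$places),
               sum(vapply(fx$stream$entries,
                          function(e) nrow(e$contents), integer(1))))
  # segment 5: two places (S sensation, T wish) in one binding group
  p5 <- m$places[m$places$t == 5, ]
  expect_equal(nrow(p5), 2L)
  expect_equal(p5$lane, c("S", "T"))  # scheme lane order
  expect_true(any(vapply(m$bindings,
                         function(b) setequal(b, p5$id), logical(1))))
  # segment 7: single emotion place, no binding group
  p7 <- m$places[m$places$t == 7, ]
  expect_equal(nrow(p7), 1L)
  expect_equal(p7$lane, "E")
  expect_false(any(vapply(m$bindings, function(b) p7$id %in% b, logical(1))))
  # binding never crosses time steps
  for (b in m$bindings) {
    expect_length(unique(m$places$t[match(b, m$places$id)]), 1L)
  }
  # causal arcs connect consecutive segments only (t -> t + 1 by design)
  expect_true(all(m$causal_arcs >= 1 & m$causal_arcs <= 29))
  expect_length(m$causal_arcs, 23L)
})

test_that("unknown categories are rejected at construction", {
  sch <- scheme_lanes4()
  e <- list(list(index = 1L,
                 contents = data.frame(label = "x", category = "Q"),
                 causes_next = NA))
  expect_error(coded_stream(e, sch), "unknown")
})

test_that("episodes split exactly at causality breaks", {
  fx <- load_fixture("joyce_penelope")
  ep <- detect_episodes(build_stream(fx$stream))
  expect_equal(nrow(ep), 7L)
  expect_equal(ep$start, c(1L, 5L, 14L, 17L, 18L, 23L, 27L))
  expect_equal(ep$end, c(4L, 13L, 16L, 17L, 22L, 26L, 30L))
})

test_that("episode edge cases: no arcs, full chain, empty stream", {
  sch <- scheme_lanes4()
  mk <- function(S, links) {
    entries <- lapply(seq_len(S), function(i) {
      list(index = i, contents = data.frame(label = "x", category = "E"),
           causes_next = if (i < S) links[i] else NA)
    })
    build_stream(coded_stream(entries, sch))
  }
  no_arcs <- mk(5, rep(FALSE, 4))
  expect_equal(detect_episodes(no_arcs),
               data.frame(start = 1:5, end = 1:5))
  chain <- mk(5, rep(TRUE, 4))
  expect_equal(detect_episodes(chain), data.frame(start = 1L, end = 5L))
  single <- mk(1, logical(0))
  expect_equal(detect_episodes(single), data.frame(start = 1L, end = 1L))
})

test_that("episodes equal connected components of the chain graph", {
  skip_if_not_installed("igraph")
  for (seed in 1:15) {
    st <- random_stream(S = sample(2:50, 1), seed = seed)
    m <- build_stream(st)
    ep <- detect_episodes(m)
    # tiles [1, S]
    expect_equal(ep$start[1], 1L)
    expect_equal(ep$end[nrow(ep)], m$n_segments)
    expect_true(all(ep$start <= ep$end))
    if (nrow(ep) > 1) expect_equal(ep$start[-1], ep$end[-nrow(ep)] + 1L)
    got <- lapply(seq_len(nrow(ep)), function(i) ep$start[i]:ep$end[i])
    oracle <- oracle_episodes_igraph(m$n_segments, m$causal_arcs)
    expect_equal(unname(lapply(got, as.integer)),
                 unname(lapply(oracle, as.integer)))
  }
})

test_that("DOT export has one node per place and is deterministic", {
  fx <- load_fixture("joyce_penelope")
  m <- build_stream(fx$stream)
  dot <- to_dot(m)
  expect_equal(length(gregexpr("[label=", dot, fixed = TRUE)[[1]]),
               nrow(m$places))
  # byte-identical on rebuild
  m2 <- build_stream(load_fixture("joyce_penelope")$stream)
  expect_identical(to_dot(m2), dot)
  expect_identical(to_pnml(m2), to_pnml(m))

  # 2-place bound pair: 2 nodes, 1 undirected-styled edge
  sch <- scheme_lanes4()
  pair <- build_stream(coded_stream(list(
    list(index = 1L,
         contents = data.frame(label = c("a", "b"), category = c("S", "E")),
         causes_next = NA)), sch))
  d <- to_dot(pair)
  expect_equal(length(gregexpr("dir=none", d, fixed = TRUE)[[1]]), 1L)
  expect_false(grepl("-> p1_E_1;", d))  # no directed arcs
})

test_that("PNML realizes each causal link as place -> transition -> place", {
  sch <- scheme_lanes4()
  mini <- build_stream(coded_stream(list(
    list(index = 1L, contents = data.frame(label = "a", category = "E"),
         causes_next = TRUE),
    list(index = 2L, contents = data.frame(label = "b", category = "T"),
         causes_next = NA)), sch))
  doc <- xml2::read_xml(to_pnml(mini))
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:place", ns), 2L)
  expect_length(xml2::xml_find_all(doc, "//d1:transition", ns), 1L)
  arcs <- xml2::xml_find_all(doc, "//d1:arc", ns)
  expect_length(arcs, 2L)
  # bipartite: every arc joins a place and a transition
  pl_ids <- xml2::xml_attr(xml2::xml_find_all(doc, "//d1:place", ns), "id")
  tr_ids <- xml2::xml_attr(xml2::xml_find_all(doc, "//d1:transition", ns), "id")
  for (a in arcs) {
    s <- xml2::xml_attr(a, "source"); t <- xml2::xml_attr(a, "target")
    expect_true((s %in% pl_ids) != (s %in% tr_ids))
    expect_true((s %in% pl_ids && t %in% tr_ids) ||
                  (s %in% tr_ids && t %in% pl_ids))
  }

  # monolog fixture: one transition per causes_next = TRUE entry
  m <- build_stream(load_fixture("joyce_penelope")$stream)
  doc2 <- xml2::read_xml(to_pnml(m))
  ns2 <- xml2::xml_ns(doc2)
  expect_length(xml2::xml_find_all(doc2, "//d1:transition", ns2), 23L)
  expect_length(xml2::xml_find_all(doc2, "//d1:place", ns2), nrow(m$places))
})

test_that("layout: x increases with t, lanes in scheme order, 7 bands", {
  fx <- load_fixture("joyce_penelope")
  m <- build_stream(fx$stream)
  ly <- stream_layout(m)
  expect_equal(nrow(ly$episodes), 7L)
  expect_equal(ly$lanes$lane, c("S", "E", "T", "I"))
  expect_true(all(diff(ly$lanes$y) < 0))  # top lane first
  agg <- tapply(ly$places$x, ly$places$t, unique)
  expect_true(all(diff(unlist(agg)) > 0))
  # binding verticals sit at their segment's x
  expect_equal(nrow(ly$bindings), length(m$bindings))
  # word-count weighting changes spacing but not order
  lyw <- stream_layout(m, time_weight = "words")
  xw <- vapply(sort(unique(m$places$t)),
               function(t) unique(lyw$places$x[lyw$places$t == t]),
               numeric(1))
  expect_true(all(diff(xw) > 0))
  expect_false(isTRUE(all.equal(diff(xw), rep(1, 29))))
  # plot renders without error
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf, width = 800, height = 400)
  expect_no_error(plot(m))
  grDevices::dev.off()
})

test_that("model writers emit parseable dot/pnml/json", {
  m <- build_stream(load_fixture("joyce_penelope")$stream)
  fd <- withr::local_tempfile(fileext = ".dot")
  fp <- withr::local_tempfile(fileext = ".pnml")
  fj <- withr::local_tempfile(fileext = ".json")
  write_stream_model(m, fd)
  write_stream_model(m, fp)
  write_stream_model(m, fj)
  expect_match(readLines(fd, n = 1), "^digraph")
  expect_s3_class(xml2::read_xml(fp), "xml_document")
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(js$n_segments, 30L)
  expect_equal(nrow(js$episodes), 7L)
  expect_error(write_stream_model(m, "x.bogus"), "unknown")
})
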