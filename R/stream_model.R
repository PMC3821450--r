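# Petri-net-style dynamic model of a coded stream of consciousness.
# Each content detected in a segment is a place at time t (one arbitrary
# unit per segment); simultaneous contents of one segment are bound into a
# single state (vertical line); annotator-asserted causal links become
# arcs from the state at t to the state at t + 1; maximal runs of causally
# linked segments are micro-episodes. PNML export inserts one explicit
# transition per causal link to honor Petri-net bipartiteness.

#' Build the stream model of a coded stream
#'
#' @param coded a [coded_stream()].
#' @return object of class `stream_model`: list with `scheme`,
#'   `n_segments`, `places` (data frame `id`, `t`, `lane`, `label`,
#'   ordered by `t` then scheme lane order), `bindings` (list of integer
#'   place-id vectors, one per segment with >= 2 places), `causal_arcs`
#'   (integer vector of segment indices `t` with a causal link to
#'   `t + 1`), `episodes` (data frame `start`, `end`), and `segment_texts`
#'   (character, `NA` when the coding carries no text).
#' @examples
#' fx <- load_fixture("joyce_penelope")
#' m <- build_stream(fx$stream)
#' nrow(m$episodes)  # 7
#' @export
build_stream <- function(coded) {
  stopifnot(is_coded_stream(coded))
  scheme <- coded$scheme
  S <- length(coded$entries)
  places <- NULL
  bindings <- list()
  texts <- character(S)
  for (e in coded$entries) {
    ct <- e$contents
    ord <- order(match(ct$category, scheme$codes), ct$label)
    ct <- ct[ord, , drop = FALSE]
    ids <- seq_len(nrow(ct)) + if (is.null(places)) 0L else nrow(places)
    places <- rbind(places, data.frame(
      id = ids, t = e$index, lane = ct$category, label = ct$label,
      stringsAsFactors = FALSE))
    if (nrow(ct) >= 2L) bindings[[length(bindings) + 1L]] <- ids
    texts[e$index] <- if (is.null(e$text) || is.na(e$text)) NA_character_
                      else e$text
  }
  causal_arcs <- if (S > 1L) {
    which(vapply(coded$entries[seq_len(S - 1L)],
                 function(e) isTRUE(e$causes_next), logical(1)))
  } else integer(0)
  model <- structure(
    list(scheme = scheme, n_segments = S,
         places = if (is.null(places)) {
           data.frame(id = integer(0), t = integer(0),
                      lane = character(0), label = character(0))
         } else places,
         bindings = bindings, causal_arcs = as.integer(causal_arcs),
         segment_texts = texts, text_id = coded$text_id),
    class = "stream_model")
  model$episodes <- detect_episodes(model)
  model
}

#' @export
print.stream_model <- function(x, ...) {
  cat(sprintf(
    "<stream_model '%s': %d segments, %d places, %d bindings, %d causal arcs, %d episodes>\n",
    x$text_id, x$n_segments, nrow(x$places), length(x$bindings),
    length(x$causal_arcs), nrow(x$episodes)))
  invisible(x)
}

#' Detect micro-episodes at causality breaks
#'
#' A micro-episode is a maximal run of consecutive segments connected by
#' causal arcs; the stream splits exactly where no causal arc crosses a
#' consecutive-segment boundary. Equivalent to the connected components
#' of the chain graph whose edges are the causal arcs.
#'
#' @param model a [build_stream()] result (or a [coded_stream()], which is
#'   built first).
#' @return data frame with columns `start`, `end`, one row per episode,
#'   tiling `[1, n_segments]`.
#' @export
detect_episodes <- function(model) {
  if (is_coded_stream(model)) model <- build_stream(model)
  stopifnot(inherits(model, "stream_model"))
  S <- model$n_segments
  if (S == 0L) return(data.frame(start = integer(0), end = integer(0)))
  breaks <- setdiff(seq_len(S - 1L), model$causal_arcs)
  start <- c(1L, breaks + 1L)
  end <- c(breaks, S)
  data.frame(start = start, end = end)
}

place_node_id <- function(places) {
  sprintf("p%d_%s_%d", places$t, places$lane, stats::ave(
    seq_len(nrow(places)), places$t, places$lane, FUN = seq_along))
}

#' Export a stream model as a Graphviz DOT digraph
#'
#' One node per place (content), ranked by segment time; binding rendered
#' as undirected-styled (dashed, arrowless) edges inside a segment; causal
#' links as directed edges from every place at `t` to every place at
#' `t + 1`. Output is deterministic: identical models yield byte-identical
#' strings.
#'
#' @param model a [build_stream()] result.
#' @return DOT source as a single string.
#' @export
to_dot <- function(model) {
  stopifnot(inherits(model, "stream_model"))
  pl <- model$places
  ids <- place_node_id(pl)
  lines <- c(
    sprintf("digraph \"%s\" {", model$text_id),
    "  rankdir=LR;",
    "  node [shape=circle];"
  )
  for (i in seq_len(nrow(pl))) {
    lines <- c(lines, sprintf("  %s [label=\"%s\\n%s\"];",
                              ids[i], pl$lane[i], pl$label[i]))
  }
  for (t in sort(unique(pl$t))) {
    same <- ids[pl$t == t]
    lines <- c(lines, sprintf("  { rank=same; %s }",
                              paste0(same, ";", collapse = " ")))
  }
  for (b in model$bindings) {
    bi <- match(b, pl$id)
    for (j in seq_len(length(bi) - 1L)) {
      lines <- c(lines, sprintf(
        "  %s -> %s [dir=none, style=dashed, constraint=false];",
        ids[bi[j]], ids[bi[j + 1L]]))
    }
  }
  for (t in model$causal_arcs) {
    fr <- ids[pl$t == t]
    to <- ids[pl$t == t + 1L]
    for (a in fr) for (b in to) {
      lines <- c(lines, sprintf("  %s -> %s;", a, b))
    }
  }
  lines <- c(lines, "}")
  paste0(paste(lines, collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a stream model as PNML (place/transition net)
#'
#' Petri nets are bipartite, so each annotator-asserted causal link from
#' the state at `t` to the state at `t + 1` is realized as an explicit
#' transition: arcs run from every place of segment `t` into transition
#' `tr<t>` and from it to every place of segment `t + 1`. The document
#' follows the basic PNML place/transition-net structure (net, page,
#' place, transition, arc) and parses with standard XML tooling.
#'
#' @param model a [build_stream()] result.
#' @return PNML XML as a single string.
#' @export
to_pnml <- function(model) {
  stopifnot(inherits(model, "stream_model"))
  pl <- model$places
  ids <- place_node_id(pl)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<pnml xmlns=\"http://www.pnml.org/version-2009/grammar/pnml\">",
    sprintf("  <net id=\"%s\" type=\"http://www.pnml.org/version-2009/grammar/ptnet\">",
            xml_escape(model$text_id)),
    "    <page id=\"page1\">"
  )
  for (i in seq_len(nrow(pl))) {
    out <- c(out, sprintf(
      "      <place id=\"%s\"><name><text>%s</text></name></place>",
      ids[i], xml_escape(paste0(pl$lane[i], ": ", pl$label[i]))))
  }
  arcs <- character(0)
  n_arc <- 0L
  for (t in model$causal_arcs) {
    tr <- sprintf("tr%d", t)
    out <- c(out, sprintf(
      "      <transition id=\"%s\"><name><text>state %d to %d</text></name></transition>",
      tr, t, t + 1L))
    for (a in ids[pl$t == t]) {
      n_arc <- n_arc + 1L
      arcs <- c(arcs, sprintf(
        "      <arc id=\"a%d\" source=\"%s\" target=\"%s\"/>", n_arc, a, tr))
    }
    for (b in ids[pl$t == t + 1L]) {
      n_arc <- n_arc + 1L
      arcs <- c(arcs, sprintf(
        "      <arc id=\"a%d\" source=\"%s\" target=\"%s\"/>", n_arc, tr, b))
    }
  }
  out <- c(out, arcs, "    </page>", "  </net>", "</pnml>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Plot layout for a stream model
#'
#' Computes the two-dimensional layout of the stream diagram: abscissa is
#' segment time (one arbitrary unit per segment, optionally weighted by
#' the segment's word or character count), ordinate is the category lane
#' in scheme order. Co-located places (same segment, same lane) are
#' offset vertically. Returns plain data frames so any graphics backend
#' can render them; [plot.stream_model()] uses base graphics.
#'
#' @param model a [build_stream()] result.
#' @param time_weight `"unit"` (default), `"words"` or `"chars"`;
#'   non-unit weights require segment texts in the coding and rescale the
#'   x spacing without changing the order.
#' @return list with `places` (`id`, `t`, `lane`, `label`, `x`, `y`),
#'   `bindings` (`x`, `y0`, `y1` vertical binding lines), `arcs`
#'   (`x0`, `y0`, `x1`, `y1` one row per place pair on a causal link),
#'   `episodes` (`start`, `end`, `x0`, `x1` bands), `lanes` (`lane`,
#'   `label`, `y`).
#' @export
stream_layout <- function(model, time_weight = c("unit", "words", "chars")) {
  stopifnot(inherits(model, "stream_model"))
  time_weight <- match.arg(time_weight)
  S <- model$n_segments
  if (time_weight == "unit" || S == 0L) {
    xs <- seq_len(S)
  } else {
    txt <- model$segment_texts
    if (anyNA(txt)) stop("time weighting needs segment texts in the coding")
    w <- switch(time_weight,
                words = vapply(strsplit(txt, "\\s+"), length, integer(1)),
                chars = nchar(gsub("\\s", "", txt)))
    w <- pmax(w, 1L)
    # place each segment at the midpoint of its span so order is preserved
    cum <- cumsum(w)
    xs <- cum - w / 2
  }
  lanes <- data.frame(lane = model$scheme$codes, label = model$scheme$labels,
                      y = rev(seq_along(model$scheme$codes)),
                      stringsAsFactors = FALSE)
  pl <- model$places
  y <- lanes$y[match(pl$lane, lanes$lane)]
  # offset places sharing one (t, lane) cell
  if (nrow(pl)) {
    dup_rank <- stats::ave(seq_len(nrow(pl)), pl$t, pl$lane, FUN = seq_along)
    dup_n <- stats::ave(seq_len(nrow(pl)), pl$t, pl$lane,
                        FUN = function(z) length(z))
    y <- y + (dup_rank - (dup_n + 1) / 2) * 0.3
  }
  places <- data.frame(id = pl$id, t = pl$t, lane = pl$lane,
                       label = pl$label, x = xs[pl$t], y = y,
                       stringsAsFactors = FALSE)
  bindings <- do.call(rbind, lapply(model$bindings, function(b) {
    yy <- places$y[match(b, places$id)]
    data.frame(x = places$x[match(b[1L], places$id)],
               y0 = min(yy), y1 = max(yy))
  }))
  if (is.null(bindings)) {
    bindings <- data.frame(x = numeric(0), y0 = numeric(0), y1 = numeric(0))
  }
  arcs <- NULL
  for (t in model$causal_arcs) {
    from <- places[places$t == t, ]
    to <- places[places$t == t + 1L, ]
    arcs <- rbind(arcs, expand.grid(i = seq_len(nrow(from)),
                                    j = seq_len(nrow(to))) |>
                    (\(g) data.frame(x0 = from$x[g$i], y0 = from$y[g$i],
                                     x1 = to$x[g$j], y1 = to$y[g$j]))())
  }
  if (is.null(arcs)) {
    arcs <- data.frame(x0 = numeric(0), y0 = numeric(0),
                       x1 = numeric(0), y1 = numeric(0))
  }
  ep <- model$episodes
  half <- if (S > 1L) min(diff(xs)) / 2 else 0.5
  episodes <- data.frame(start = ep$start, end = ep$end,
                         x0 = xs[ep$start] - half, x1 = xs[ep$end] + half)
  list(places = places, bindings = bindings, arcs = arcs,
       episodes = episodes, lanes = lanes)
}

#' Plot a stream model
#'
#' Renders the stream diagram with base graphics: content places as open
#' circles per category lane, binding as vertical lines, causal links as
#' arrows, micro-episode bands along the top line.
#'
#' @param x a [build_stream()] result.
#' @param time_weight passed to [stream_layout()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return the layout, invisibly.
#' @export
plot.stream_model <- function(x, time_weight = "unit", ...) {
  ly <- stream_layout(x, time_weight = time_weight)
  ymax <- max(ly$lanes$y) + 1
  graphics::plot(NA, xlim = range(c(ly$episodes$x0, ly$episodes$x1, 1)),
                 ylim = c(0.5, ymax + 0.5), xlab = "time (segments)",
                 ylab = "", yaxt = "n", bty = "n", ...)
  graphics::axis(2, at = ly$lanes$y, labels = ly$lanes$lane, las = 1)
  with(ly$episodes, {
    graphics::segments(x0, ymax, x1, ymax, lwd = 3)
    graphics::text((x0 + x1) / 2, ymax + 0.3,
                   labels = seq_along(x0), cex = 0.7)
  })
  if (nrow(ly$arcs)) {
    suppressWarnings(graphics::arrows(
      ly$arcs$x0, ly$arcs$y0, ly$arcs$x1, ly$arcs$y1,
      length = 0.08, col = "grey40"))
  }
  if (nrow(ly$bindings)) {
    graphics::segments(ly$bindings$x, ly$bindings$y0,
                       ly$bindings$x, ly$bindings$y1, lwd = 2)
  }
  graphics::points(ly$places$x, ly$places$y, pch = 21, bg = "white",
                   cex = 1.4)
  invisible(ly)
}

#' Write a stream model to disk
#'
#' @param model a [build_stream()] result.
#' @param path output path; format chosen by extension: `.dot`, `.pnml`
#'   (or `.xml`), `.json` (places/bindings/arcs/episodes dump).
#' @export
write_stream_model <- function(model, path) {
  stopifnot(inherits(model, "stream_model"))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "dot") {
    writeLines(to_dot(model), path, useBytes = TRUE)
  } else if (ext %in% c("pnml", "xml")) {
    writeLines(to_pnml(model), path, useBytes = TRUE)
  } else if (ext == "json") {
    obj <- list(schema_version = SCHEMA_VERSION, type = "stream_model",
                text_id = model$text_id,
                scheme = list(name = model$scheme$name,
                              codes = model$scheme$codes),
                n_segments = model$n_segments,
                places = model$places, bindings = model$bindings,
                causal_arcs = model$causal_arcs, episodes = model$episodes)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else {
    stop("unknown stream model format: .", ext)
  }
  invisible(path)
}
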