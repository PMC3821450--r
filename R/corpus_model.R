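# Domain types and file I/O for phenomenological texts, judge protocols and
# coded streams. All offsets are 1-based and inclusive (substr() convention);
# a candidate boundary at position p lies in the gap between tokens p and
# p + 1, and p = n_tokens denotes the text terminus (it never splits).

SCHEMA_VERSION <- "1.0"

## ---- PhenomenologicalText ---------------------------------------------

#' Construct a phenomenological text
#'
#' A phenomenological text is a first-person verbal report of ongoing
#' conscious experience. The constructor tokenizes `raw` on whitespace and
#' records candidate segmentation boundaries as inter-token gap positions:
#' position `p` is the gap after token `p`, and `p = n_tokens` marks the end
#' of the text (a legal candidate that can never split the text).
#'
#' @param raw UTF-8 text string (may contain newlines).
#' @param text_id identifier string.
#' @param language ISO-639-1 language code.
#' @param candidate_boundaries integer vector of gap positions in
#'   `[1, n_tokens]`, strictly increasing; `"gaps"` (default) uses every
#'   internal inter-token gap; `"lines"` uses the cumulative token count at
#'   the end of each line of `raw` (the final line yields the terminus).
#' @return object of class `phenotext` with fields `text_id`, `language`,
#'   `raw`, `tokens` (data frame `token`, `start`, `end`) and
#'   `candidate_boundaries`.
#' @examples
#' tx <- phenotext("todo lo traduzco a mi estado.")
#' nrow(tx$tokens)               # 6
#' tx$candidate_boundaries      # 1 2 3 4 5
#' @export
phenotext <- function(raw, text_id = "text", language = "und",
                      candidate_boundaries = "gaps") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single character string")
  }
  if (!nzchar(trimws(raw))) stop("text is empty")
  m <- gregexpr("\\S+", raw, perl = TRUE)[[1L]]
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  tokens <- data.frame(
    token = substring(raw, starts, ends),
    start = starts, end = ends,
    stringsAsFactors = FALSE
  )
  n <- nrow(tokens)
  cb <- candidate_boundaries
  if (identical(cb, "gaps")) {
    cb <- if (n > 1L) seq_len(n - 1L) else integer(0)
  } else if (identical(cb, "lines")) {
    lines <- strsplit(raw, "\n", fixed = TRUE)[[1L]]
    per_line <- vapply(lines, function(l) {
      length(regmatches(l, gregexpr("\\S+", l, perl = TRUE))[[1L]])
    }, integer(1), USE.NAMES = FALSE)
    cb <- cumsum(per_line)
    cb <- cb[per_line > 0L]
  } else {
    cb <- as.integer(cb)
  }
  x <- structure(
    list(text_id = as.character(text_id), language = as.character(language),
         raw = raw, tokens = tokens,
         candidate_boundaries = as.integer(cb)),
    class = "phenotext"
  )
  validate_phenotext(x)
}

#' @export
print.phenotext <- function(x, ...) {
  cat(sprintf("<phenotext '%s' [%s]: %d tokens, %d candidate boundaries>\n",
              x$text_id, x$language, nrow(x$tokens),
              length(x$candidate_boundaries)))
  invisible(x)
}

validate_phenotext <- function(x) {
  tk <- x$tokens
  if (nrow(tk) == 0L) stop("text has no tokens")
  if (any(tk$start > tk$end)) stop("token with negative extent")
  if (nrow(tk) > 1L && any(diff(tk$start) <= 0)) {
    stop("token offsets must be strictly increasing")
  }
  if (nrow(tk) > 1L && any(tk$start[-1L] <= tk$end[-nrow(tk)])) {
    stop("token offsets overlap")
  }
  if (max(tk$end) > nchar(x$raw)) stop("token offset beyond end of raw text")
  cb <- x$candidate_boundaries
  if (length(cb)) {
    if (any(diff(cb) <= 0)) stop("candidate boundaries must be strictly increasing")
    if (min(cb) < 1L || max(cb) > nrow(tk)) {
      stop("candidate boundary outside [1, n_tokens]")
    }
  }
  x
}

#' Read a phenomenological text from disk
#'
#' @param path file path (UTF-8).
#' @param format `"plain"` for raw text, `"json"` for the package's JSON
#'   schema, `"auto"` (default) decides by extension.
#' @param ... passed to [phenotext()] for plain files (`text_id`,
#'   `language`, `candidate_boundaries`).
#' @return a [phenotext()] object.
#' @export
read_text <- function(path, format = c("auto", "plain", "json"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "plain"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "plain") {
    raw <- readChar(path, file.size(path), useBytes = TRUE)
    Encoding(raw) <- "UTF-8"
    if (!validUTF8(raw)) stop("file is not valid UTF-8: ", path)
    raw <- sub("\n+$", "", raw)
    args <- list(...)
    if (is.null(args$text_id)) {
      args$text_id <- sub("\\.[^.]*$", "", basename(path))
    }
    do.call(phenotext, c(list(raw = raw), args))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    phenotext(obj$raw, text_id = obj$text_id,
              language = if (is.null(obj$language)) "und" else obj$language,
              candidate_boundaries =
                if (is.null(obj$candidate_boundaries)) "gaps"
                else as.integer(obj$candidate_boundaries))
  }
}

#' Write a phenomenological text as JSON
#' @param x a [phenotext()] object.
#' @param path output path.
#' @export
write_text <- function(x, path) {
  stopifnot(inherits(x, "phenotext"))
  obj <- list(schema_version = SCHEMA_VERSION, type = "phenotext",
              text_id = x$text_id, language = x$language, raw = x$raw,
              candidate_boundaries = x$candidate_boundaries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- CategoryScheme ----------------------------------------------------

#' Construct a category scheme
#'
#' An ordered list of mental-content categories used when coding segments.
#' `parent_map` optionally maps the codes of a finer scheme onto this one
#' (for instance the seven textbook categories onto four plotting lanes).
#'
#' @param name scheme name.
#' @param codes unique category codes, in lane order.
#' @param labels display names (defaults to codes).
#' @param parent_map named character vector mapping this scheme's codes
#'   (names) onto the codes of a coarser scheme (values); must be total
#'   over this scheme's codes when present.
#' @return object of class `category_scheme`.
#' @export
category_scheme <- function(name, codes, labels = codes, parent_map = NULL) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("category codes must be unique")
  if (length(labels) != length(codes)) stop("labels/codes length mismatch")
  if (!is.null(parent_map)) {
    if (is.null(names(parent_map)) || any(!nzchar(names(parent_map)))) {
      stop("parent_map must be a named character vector")
    }
    if (!setequal(names(parent_map), codes)) {
      stop("parent_map must be total over this scheme's codes")
    }
  }
  structure(list(name = name, codes = codes,
                 labels = as.character(labels), parent_map = parent_map),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat(sprintf("<category_scheme '%s': %s>\n", x$name,
              paste(x$codes, collapse = ", ")))
  invisible(x)
}

#' The seven textbook mental categories
#'
#' Sensation, perception, emotion, thought, image, recall and intention --
#' broad-spectrum terms of common use in general psychology, used by the
#' sixteen-judge attribution panel. Carries a `parent_map` onto the
#' four-lane plotting scheme of [scheme_lanes4()]: sensation and perception
#' collapse to S, thought/recall/intention to T, image to I.
#'
#' @return a [category_scheme()].
#' @export
scheme_mental7 <- function() {
  category_scheme(
    "mental7",
    codes = c("Se", "Pr", "Em", "Th", "Im", "Re", "In"),
    labels = c("sensation", "perception", "emotion", "thought",
               "image", "recall", "intention"),
    parent_map = c(Se = "S", Pr = "S", Em = "E", Th = "T",
                   Im = "I", Re = "T", In = "T")
  )
}

#' The four plotting lanes of the stream diagram
#'
#' S sensations (and perceptions), E emotions, T thoughts (including
#' recollections and plans), I mental images (including fantasies).
#'
#' @return a [category_scheme()].
#' @export
scheme_lanes4 <- function() {
  category_scheme(
    "lanes4",
    codes = c("S", "E", "T", "I"),
    labels = c("sensations", "emotions", "thoughts", "mental images")
  )
}

#' Map fine category codes onto a coarser scheme
#'
#' @param codes character vector of codes from the finer scheme.
#' @param scheme the finer [category_scheme()] carrying a `parent_map`.
#' @return character vector of coarse codes.
#' @export
map_categories <- function(codes, scheme = scheme_mental7()) {
  pm <- scheme$parent_map
  if (is.null(pm)) stop("scheme '", scheme$name, "' has no parent_map")
  bad <- setdiff(codes, names(pm))
  if (length(bad)) stop("codes not in parent_map: ", paste(bad, collapse = ", "))
  unname(pm[codes])
}

## ---- SegmentationProtocol ---------------------------------------------

#' Construct a segmentation protocol
#'
#' Binary marks of a judge panel over the candidate boundaries of a text:
#' `marks[j, b] = 1` when judge `j` placed a break at candidate boundary
#' `b`.
#'
#' @param marks J x B binary matrix (rows judges, columns candidate
#'   boundaries).
#' @param boundaries integer vector of boundary positions (column ids);
#'   defaults to `1:B`.
#' @param judges judge identifiers; defaults to `judge01`, ...
#' @param text_id id of the segmented text.
#' @return object of class `seg_protocol`.
#' @export
segmentation_protocol <- function(marks, boundaries = NULL, judges = NULL,
                                  text_id = "text") {
  marks <- as.matrix(marks)
  if (nrow(marks) < 1L) stop("protocol needs at least one judge")
  if (ncol(marks) < 1L) stop("protocol needs at least one candidate boundary")
  if (!all(marks %in% c(0, 1))) stop("marks must be binary (0/1)")
  storage.mode(marks) <- "integer"
  if (is.null(boundaries)) boundaries <- seq_len(ncol(marks))
  boundaries <- as.integer(boundaries)
  if (length(boundaries) != ncol(marks)) stop("boundaries/marks mismatch")
  if (any(diff(boundaries) <= 0)) stop("boundary ids must be strictly increasing")
  if (is.null(judges)) judges <- sprintf("judge%02d", seq_len(nrow(marks)))
  dimnames(marks) <- list(judges, paste0("b", boundaries))
  structure(list(text_id = text_id, judges = as.character(judges),
                 boundaries = boundaries, marks = marks),
            class = "seg_protocol")
}

#' @export
print.seg_protocol <- function(x, ...) {
  cat(sprintf("<seg_protocol '%s': %d judges x %d boundaries>\n",
              x$text_id, nrow(x$marks), ncol(x$marks)))
  invisible(x)
}

#' Read a segmentation protocol
#'
#' CSV layout: one row per judge, first column `judge`, remaining columns
#' `b<position>` holding 0/1 marks.
#'
#' @param path file path.
#' @param format `"csv"`, `"json"` or `"auto"` (by extension).
#' @param text a [phenotext()]; when given, boundary ids are checked
#'   against its candidate boundaries.
#' @return a [segmentation_protocol()].
#' @export
read_segmentation_protocol <- function(path, format = c("auto", "csv", "json"),
                                       text = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
    if (nrow(df) == 0L) stop("protocol has no judges")
    judges <- as.character(df[[1L]])
    marks <- as.matrix(df[, -1L, drop = FALSE])
    bcols <- colnames(marks)
    if (!all(grepl("^b[0-9]+$", bcols))) {
      stop("boundary columns must be named b<position>")
    }
    boundaries <- as.integer(sub("^b", "", bcols))
    p <- segmentation_protocol(marks, boundaries, judges,
                               text_id = sub("\\.[^.]*$", "", basename(path)))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    p <- segmentation_protocol(obj$marks, obj$boundaries, obj$judges,
                               text_id = obj$text_id)
  }
  if (!is.null(text)) {
    stopifnot(inherits(text, "phenotext"))
    bad <- setdiff(p$boundaries, text$candidate_boundaries)
    if (length(bad)) {
      stop("protocol boundaries not candidates of text '", text$text_id,
           "': ", paste(bad, collapse = ", "))
    }
    p$text_id <- text$text_id
  }
  p
}

#' Write a segmentation protocol
#' @param x a [segmentation_protocol()].
#' @param path output path.
#' @param format `"csv"`, `"json"` or `"auto"` (by extension).
#' @export
write_segmentation_protocol <- function(x, path,
                                        format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "seg_protocol"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- data.frame(judge = x$judges, x$marks, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    obj <- list(schema_version = SCHEMA_VERSION, type = "seg_protocol",
                text_id = x$text_id, judges = x$judges,
                boundaries = x$boundaries,
                marks = unname(x$marks))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

## ---- AttributionProtocol ----------------------------------------------

#' Construct an attribution protocol
#'
#' Per-segment, per-category attribution counts from a judge panel.
#' `n` holds, for every segment, the number of judges who identified and
#' interpreted that segment; counts are bounded by it. When the full
#' judge-level indicator tensor is available, counts are derived from it.
#'
#' @param counts S x K integer matrix of attributions (columns ordered as
#'   `scheme$codes`), or `NULL` when `indicators` is given.
#' @param n integer S-vector of per-segment recognizer counts.
#' @param scheme a [category_scheme()].
#' @param judges_total size of the full panel (>= `max(n)`).
#' @param indicators optional J x S x K binary array of judge-level
#'   attributions; when present, `counts` is its judge-sum.
#' @param text_id source text id.
#' @param printed optional metadata list carrying externally printed
#'   proportions/flags (fields `proportions`, `flags`, `notes`) that are
#'   stored verbatim, never recomputed.
#' @return object of class `attr_protocol`.
#' @export
attribution_protocol <- function(counts = NULL, n, scheme, judges_total = max(n),
                                 indicators = NULL, text_id = "text",
                                 printed = NULL) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (!is.null(indicators)) {
    stopifnot(length(dim(indicators)) == 3L)
    if (!all(indicators %in% c(0, 1))) stop("indicators must be binary")
    derived <- apply(indicators, c(2L, 3L), sum)
    if (is.null(counts)) counts <- derived
    else if (!isTRUE(all.equal(unname(as.matrix(counts)), unname(derived)))) {
      stop("counts do not equal the judge-sum of indicators")
    }
  }
  if (is.null(counts)) stop("either counts or indicators must be supplied")
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  n <- as.integer(n)
  if (length(n) != nrow(counts)) stop("n must have one entry per segment")
  if (ncol(counts) != length(scheme$codes)) {
    stop("counts must have one column per scheme category")
  }
  if (any(n < 0L) || any(n > judges_total)) {
    stop("recognizer counts n must lie in [0, judges_total]")
  }
  if (any(counts < 0L) || any(counts > n)) {
    stop("counts must satisfy 0 <= counts[s,k] <= n_s")
  }
  dimnames(counts) <- list(seq_len(nrow(counts)), scheme$codes)
  structure(list(text_id = text_id, scheme = scheme,
                 counts = counts, n = n,
                 judges_total = as.integer(judges_total),
                 indicators = indicators, printed = printed),
            class = "attr_protocol")
}

#' @export
print.attr_protocol <- function(x, ...) {
  cat(sprintf(
    "<attr_protocol '%s': %d segments x %d categories, panel of %d>\n",
    x$text_id, nrow(x$counts), ncol(x$counts), x$judges_total))
  unrec <- which(x$n == 0L)
  if (length(unrec)) {
    cat("  unrecognized segments:", paste(unrec, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Segments no judge recognized
#' @param x an [attribution_protocol()].
#' @return integer vector of segment indices with `n = 0`.
#' @export
unrecognized_segments <- function(x) {
  stopifnot(inherits(x, "attr_protocol"))
  which(x$n == 0L)
}

#' Read an attribution protocol
#'
#' CSV layout: one row per segment with columns `segment`, `n`, then one
#' count column per category code; the scheme is matched against the count
#' column names (`scheme` may override).
#'
#' @param path file path.
#' @param format `"csv"`, `"json"` or `"auto"`.
#' @param scheme a [category_scheme()]; default matches columns against
#'   [scheme_mental7()] then [scheme_lanes4()].
#' @return an [attribution_protocol()].
#' @export
read_attribution_protocol <- function(path, format = c("auto", "csv", "json"),
                                      scheme = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
    ccols <- setdiff(colnames(df), c("segment", "n"))
    if (is.null(scheme)) {
      for (cand in list(scheme_mental7(), scheme_lanes4())) {
        if (setequal(ccols, cand$codes)) { scheme <- cand; break }
      }
      if (is.null(scheme)) scheme <- category_scheme("custom", ccols)
    }
    attribution_protocol(
      counts = as.matrix(df[, scheme$codes, drop = FALSE]),
      n = df$n, scheme = scheme,
      judges_total = max(df$n),
      text_id = sub("\\.[^.]*$", "", basename(path))
    )
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    sch <- category_scheme(obj$scheme$name, obj$scheme$codes,
                           obj$scheme$labels,
                           parent_map = {
                             pm <- obj$scheme$parent_map
                             if (length(pm)) unlist(pm) else NULL
                           })
    attribution_protocol(counts = obj$counts, n = obj$n, scheme = sch,
                         judges_total = obj$judges_total,
                         text_id = obj$text_id)
  }
}

#' Write an attribution protocol
#' @param x an [attribution_protocol()].
#' @param path output path.
#' @param format `"csv"`, `"json"` or `"auto"`.
#' @export
write_attribution_protocol <- function(x, path,
                                       format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "attr_protocol"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- data.frame(segment = seq_along(x$n), n = x$n, x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    obj <- list(schema_version = SCHEMA_VERSION, type = "attr_protocol",
                text_id = x$text_id,
                scheme = list(name = x$scheme$name, codes = x$scheme$codes,
                              labels = x$scheme$labels,
                              parent_map = as.list(x$scheme$parent_map)),
                n = x$n, judges_total = x$judges_total,
                counts = unname(x$counts))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

## ---- CodedStream -------------------------------------------------------

#' Construct a coded stream
#'
#' The ordered result of hand-coding a text: one entry per segment, each
#' holding one or more contents (a free-text label plus a scheme category)
#' and a `causes_next` flag asserting a causal link from this segment's
#' mental state to the next one. Causal links are annotator judgments
#' stored as data; the package never infers them from text.
#'
#' @param entries list; each element a list with fields `index`,
#'   `contents` (data frame with columns `label`, `category`), optional
#'   `text` and `linguistic` annotations, and `causes_next` (logical;
#'   required for all but the last entry).
#' @param scheme a [category_scheme()] the content categories belong to.
#' @param text_id source text id.
#' @return object of class `coded_stream`.
#' @export
coded_stream <- function(entries, scheme, text_id = "text") {
  stopifnot(inherits(scheme, "category_scheme"))
  S <- length(entries)
  for (i in seq_len(S)) {
    e <- entries[[i]]
    if (!identical(as.integer(e$index), i)) {
      stop("entry indices must be consecutive from 1 (entry ", i, ")")
    }
    ct <- e$contents
    if (!is.data.frame(ct) || nrow(ct) < 1L ||
        !all(c("label", "category") %in% names(ct))) {
      stop("entry ", i, ": contents must be a data frame with label, category")
    }
    bad <- setdiff(ct$category, scheme$codes)
    if (length(bad)) {
      stop("entry ", i, ": unknown categories ", paste(bad, collapse = ", "))
    }
    if (i < S && (is.null(e$causes_next) || is.na(e$causes_next))) {
      stop("entry ", i, ": causes_next must be TRUE or FALSE")
    }
  }
  structure(list(text_id = text_id, scheme = scheme, entries = entries),
            class = "coded_stream")
}

#' @export
print.coded_stream <- function(x, ...) {
  nb <- sum(!vapply(x$entries[-length(x$entries)],
                    function(e) isTRUE(e$causes_next), logical(1)))
  cat(sprintf("<coded_stream '%s': %d segments, %d causality breaks>\n",
              x$text_id, length(x$entries), nb))
  invisible(x)
}

#' @rdname coded_stream
#' @param x object to test or print.
#' @export
is_coded_stream <- function(x) inherits(x, "coded_stream")

#' Read a coded stream from JSON
#' @param path file path.
#' @return a [coded_stream()].
#' @export
read_coded_stream <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sch_codes <- vapply(obj$scheme$codes, identity, character(1))
  sch_labels <- if (!is.null(obj$scheme$labels)) {
    vapply(obj$scheme$labels, identity, character(1))
  } else sch_codes
  scheme <- category_scheme(obj$scheme$name, sch_codes, sch_labels)
  entries <- lapply(obj$entries, function(e) {
    ct <- do.call(rbind, lapply(e$contents, function(c0) {
      data.frame(label = c0$label, category = c0$category,
                 stringsAsFactors = FALSE)
    }))
    list(index = as.integer(e$index),
         text = if (is.null(e$text)) NA_character_ else e$text,
         linguistic = if (is.null(e$linguistic)) NA_character_ else e$linguistic,
         contents = ct,
         causes_next = if (is.null(e$causes_next)) NA else isTRUE(e$causes_next))
  })
  coded_stream(entries, scheme, text_id = obj$text_id)
}

#' Write a coded stream to JSON
#' @param x a [coded_stream()].
#' @param path output path.
#' @export
write_coded_stream <- function(x, path) {
  stopifnot(is_coded_stream(x))
  entries <- lapply(x$entries, function(e) {
    out <- list(index = e$index)
    if (!is.null(e$text) && !is.na(e$text)) out$text <- e$text
    if (!is.null(e$linguistic) && !is.na(e$linguistic)) {
      out$linguistic <- e$linguistic
    }
    out$contents <- lapply(seq_len(nrow(e$contents)), function(i) {
      list(label = e$contents$label[i], category = e$contents$category[i])
    })
    if (!is.null(e$causes_next) && !is.na(e$causes_next)) {
      out$causes_next <- e$causes_next
    }
    out
  })
  obj <- list(schema_version = SCHEMA_VERSION, type = "coded_stream",
              text_id = x$text_id,
              scheme = list(name = x$scheme$name, codes = x$scheme$codes,
                            labels = x$scheme$labels),
              entries = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Map free-text content labels to category codes
#'
#' Applies a label-to-category lookup table (such as the shipped
#' four-lane map, [joyce_label_map()]). Matching is case-insensitive.
#'
#' @param labels character vector of content labels.
#' @param map data frame with columns `label`, `category`.
#' @return character vector of category codes (`NA` where unmapped).
#' @export
map_labels <- function(labels, map) {
  stopifnot(is.data.frame(map), all(c("label", "category") %in% names(map)))
  idx <- match(tolower(trimws(labels)), tolower(trimws(map$label)))
  as.character(map$category[idx])
}
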