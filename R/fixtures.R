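# Packaged reconstructions of the two in-package annotation datasets.
# Printed agreement indices, proportions and significance flags are stored
# verbatim as metadata; integer judge marks and attribution counts are
# reconstructed from them deterministically (round half up), and any cell
# whose reconstruction cannot reproduce the printed value within half a
# printed decimal is reported in a discrepancies table, never silently
# corrected.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "phenostream")
  if (!nzchar(p)) stop("fixture file not found: ", file)
  p
}

round_half_up <- function(x) as.integer(floor(x + 0.5 + 1e-9))

#' Load a packaged annotation dataset
#'
#' Two datasets are shipped. `"unamuno_journal"` is a 107-token Spanish
#' journal excerpt with 16 candidate boundaries (the printed line breaks),
#' a 16-judge segmentation panel reconstructed from the printed
#' per-boundary agreement indices, and a 9-segment x 7-category attribution
#' protocol reconstructed from the printed proportion table (with the
#' printed high/low significance flags kept as metadata).
#' `"joyce_penelope"` is a 30-sentence interior-monolog excerpt coded into
#' the four content lanes S/E/T/I, with intra-segment binding implied by
#' multi-content entries and annotator-asserted causal links broken at six
#' positions.
#'
#' Judge-level marks are not published; the reconstruction assigns, for a
#' boundary marked by `m` of 16 judges, the mark to judges `1..m`. Column
#' sums (and hence every agreement statistic) are unaffected by which
#' judges carry the marks.
#'
#' @param name `"unamuno_journal"` or `"joyce_penelope"`.
#' @return For `"unamuno_journal"`: list with `text` ([phenotext()]),
#'   `segmentation` ([segmentation_protocol()]), `attribution`
#'   ([attribution_protocol()]), `printed` (verbatim printed indices,
#'   stars, proportions, flags), `translations`, and `discrepancies`
#'   (data frame of printed-vs-reconstructed mismatches). For
#'   `"joyce_penelope"`: list with `stream` ([coded_stream()]),
#'   `label_map` and `discrepancies`.
#' @examples
#' fx <- load_fixture("unamuno_journal")
#' fx$attribution$n     # 10 14 16 16 15 16 11 16 16
#' @export
load_fixture <- function(name = c("unamuno_journal", "joyce_penelope")) {
  name <- match.arg(name)
  if (name == "unamuno_journal") load_unamuno() else load_joyce()
}

load_unamuno <- function() {
  text <- read_text(fixture_path("unamuno_journal.txt"), format = "plain",
                    text_id = "unamuno_journal", language = "es",
                    candidate_boundaries = "lines")
  bd <- utils::read.csv(fixture_path("unamuno_boundaries.csv"),
                        fileEncoding = "UTF-8")
  J <- 16L
  printed_idx <- bd$index
  starred <- bd$starred == 1L
  m <- round_half_up(printed_idx * J)
  marks <- matrix(0L, nrow = J, ncol = length(m))
  for (b in seq_along(m)) if (m[b] > 0L) marks[seq_len(m[b]), b] <- 1L
  seg <- segmentation_protocol(marks, boundaries = text$candidate_boundaries,
                               text_id = "unamuno_journal")

  disc <- data.frame(dataset = character(0), location = character(0),
                     printed = numeric(0), reconstructed = numeric(0),
                     diff = numeric(0), stringsAsFactors = FALSE)
  slack_b <- 0.5 / J + 0.005   # half a judge plus half a printed decimal
  db <- abs(m / J - printed_idx)
  for (b in which(db > slack_b)) {
    disc <- rbind(disc, data.frame(
      dataset = "unamuno_journal", location = sprintf("boundary %d", b),
      printed = printed_idx[b], reconstructed = m[b] / J, diff = db[b]))
  }

  at <- utils::read.csv(fixture_path("unamuno_attributions.csv"),
                        fileEncoding = "UTF-8",
                        colClasses = c(note = "character"))
  scheme <- scheme_mental7()
  segs <- sort(unique(at$segment))
  S <- length(segs)
  K <- length(scheme$codes)
  n <- counts <- NULL
  n <- integer(S)
  counts <- matrix(0L, S, K, dimnames = list(segs, scheme$codes))
  props <- matrix(NA_real_, S, K, dimnames = list(segs, scheme$codes))
  flags <- matrix("none", S, K, dimnames = list(segs, scheme$codes))
  notes <- matrix("", S, K, dimnames = list(segs, scheme$codes))
  for (i in seq_len(nrow(at))) {
    s <- at$segment[i]; k <- at$category[i]
    n[s] <- at$n[i]
    props[s, k] <- at$proportion[i]
    flags[s, k] <- at$flag[i]
    notes[s, k] <- ifelse(is.na(at$note[i]), "", at$note[i])
    counts[s, k] <- round_half_up(at$proportion[i] * at$n[i])
  }
  # reconstruction fidelity: half of the printed 2-decimal precision
  dk <- abs(counts / n - props)
  bad <- which(dk > 0.005 + 1e-9, arr.ind = TRUE)
  if (nrow(bad)) {
    disc <- rbind(disc, data.frame(
      dataset = "unamuno_journal",
      location = sprintf("segment %s, %s", rownames(props)[bad[, 1]],
                         colnames(props)[bad[, 2]]),
      printed = props[bad], reconstructed = (counts / n)[bad],
      diff = dk[bad]))
  }
  attribution <- attribution_protocol(
    counts = counts, n = n, scheme = scheme, judges_total = J,
    text_id = "unamuno_journal",
    printed = list(proportions = props, flags = flags, notes = notes)
  )
  list(
    text = text,
    segmentation = seg,
    attribution = attribution,
    printed = list(indices = printed_idx, starred = starred,
                   proportions = props, flags = flags, notes = notes),
    translations = bd$translation,
    discrepancies = disc
  )
}

load_joyce <- function() {
  stream <- read_coded_stream(fixture_path("joyce_penelope.json"))
  label_map <- utils::read.csv(fixture_path("joyce_label_map.csv"),
                               fileEncoding = "UTF-8")
  # labels resolvable through the shipped map must agree with the stored
  # category ("same" is anaphoric and intentionally absent from the map)
  disc <- data.frame(dataset = character(0), location = character(0),
                     printed = character(0), reconstructed = character(0),
                     stringsAsFactors = FALSE)
  for (e in stream$entries) {
    mapped <- map_labels(e$contents$label, label_map)
    mism <- which(!is.na(mapped) & mapped != e$contents$category)
    for (i in mism) {
      disc <- rbind(disc, data.frame(
        dataset = "joyce_penelope",
        location = sprintf("segment %d, '%s'", e$index, e$contents$label[i]),
        printed = e$contents$category[i], reconstructed = mapped[i]))
    }
  }
  list(stream = stream, label_map = label_map, discrepancies = disc)
}

#' Shipped label-to-lane mapping for the interior-monolog fixture
#'
#' Editable table mapping fine content labels (irritation, fantasy,
#' recollection, ...) to the four lanes of [scheme_lanes4()]. Affect words
#' map to E; sensation to S; recollections, thoughts, conjectures and
#' wishes/plans to T; images and fantasies to I. The anaphoric label
#' `"same"` is deliberately unmapped.
#'
#' @return data frame with columns `label`, `category`.
#' @export
joyce_label_map <- function() {
  utils::read.csv(fixture_path("joyce_label_map.csv"),
                  fileEncoding = "UTF-8")
}
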