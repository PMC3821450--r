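# Per-boundary inter-observer agreement and mean-threshold consensus
# segmentation. The agreement index of a candidate boundary is the plain
# fraction of judges marking it; a boundary is kept when its index is
# strictly greater than the threshold (by default the unrounded mean index
# over all candidates). No chance correction is applied: the procedure is
# a fraction plus a mean threshold, nothing more.

#' Per-boundary agreement indices of a judge panel
#'
#' @param protocol a [segmentation_protocol()].
#' @return object of class `agreement_vector`: list with `indices`
#'   (numeric vector named by boundary position, full precision),
#'   `boundaries` and `n_judges`.
#' @examples
#' p <- segmentation_protocol(rbind(c(1, 0), c(1, 1)))
#' boundary_agreement(p)$indices  # 1.0 0.5
#' @export
boundary_agreement <- function(protocol) {
  stopifnot(inherits(protocol, "seg_protocol"))
  J <- nrow(protocol$marks)
  if (J < 1L) stop("protocol has no judges")
  idx <- colSums(protocol$marks) / J
  names(idx) <- paste0("b", protocol$boundaries)
  structure(list(indices = unname(idx), boundaries = protocol$boundaries,
                 n_judges = J, text_id = protocol$text_id),
            class = "agreement_vector")
}

#' Construct an agreement vector directly from indices
#'
#' Used when only published per-boundary indices (not judge-level marks)
#' are available.
#'
#' @param indices numeric vector in `[0, 1]`.
#' @param boundaries boundary positions (defaults to `1:B`).
#' @param n_judges panel size the indices refer to.
#' @param text_id source text id.
#' @return an `agreement_vector`.
#' @export
agreement_vector <- function(indices, boundaries = seq_along(indices),
                             n_judges = NA_integer_, text_id = "text") {
  indices <- as.numeric(indices)
  if (length(indices) < 1L) stop("empty agreement vector")
  if (any(indices < 0 | indices > 1)) stop("indices must lie in [0, 1]")
  if (length(boundaries) != length(indices)) {
    stop("boundaries/indices length mismatch")
  }
  structure(list(indices = indices, boundaries = as.integer(boundaries),
                 n_judges = as.integer(n_judges), text_id = text_id),
            class = "agreement_vector")
}

#' @export
print.agreement_vector <- function(x, ...) {
  cat(sprintf("<agreement_vector '%s': %d boundaries, %s judges>\n",
              x$text_id, length(x$indices),
              ifelse(is.na(x$n_judges), "?", x$n_judges)))
  print(round(stats::setNames(x$indices, paste0("b", x$boundaries)), 3))
  invisible(x)
}

#' Mean inter-observer agreement
#'
#' Arithmetic mean of the per-boundary agreement indices, at full
#' precision (rounding, e.g. to two decimals for display, is presentation
#' only and never enters threshold comparisons).
#'
#' @param v an `agreement_vector` (or numeric vector of indices).
#' @return single numeric value.
#' @export
mean_agreement <- function(v) {
  idx <- if (inherits(v, "agreement_vector")) v$indices else as.numeric(v)
  if (length(idx) < 1L) stop("empty agreement vector")
  mean(idx)
}

#' Consensus segmentation by the mean-threshold rule
#'
#' Keeps every candidate boundary whose agreement index is strictly
#' greater than the threshold and tiles the text into the resulting
#' segments. With `threshold = "mean"` the unrounded mean agreement is
#' used, so that under homogeneous marking no boundary exceeds it and the
#' text stays whole. A kept boundary at the text terminus (position
#' `n_tokens`) is reported among `kept_boundaries` but cannot split.
#'
#' Candidate boundaries of the text that the agreement vector does not
#' cover are treated as index 0 (never kept).
#'
#' @param text a [phenotext()].
#' @param v an `agreement_vector` aligned with (a subset of) the text's
#'   candidate boundaries.
#' @param threshold `"mean"` (default) or a number in `[0, 1]`.
#' @return object of class `consensus_result`: list with `threshold`
#'   (numeric value used), `threshold_spec`, `kept_boundaries`, and
#'   `segments` (data frame `index`, `from`, `to` token span [from, to],
#'   `text`).
#' @examples
#' fx <- load_fixture("unamuno_journal")
#' v <- boundary_agreement(fx$segmentation)
#' nrow(consensus_segments(fx$text, v)$segments)  # 9
#' @export
consensus_segments <- function(text, v, threshold = "mean") {
  stopifnot(inherits(text, "phenotext"), inherits(v, "agreement_vector"))
  bad <- setdiff(v$boundaries, text$candidate_boundaries)
  if (length(bad)) {
    stop("agreement vector refers to non-candidate boundaries: ",
         paste(bad, collapse = ", "))
  }
  if (identical(threshold, "mean")) {
    thr <- mean_agreement(v)
  } else {
    thr <- as.numeric(threshold)
    if (is.na(thr) || thr < 0 || thr > 1) stop("threshold must be in [0, 1]")
  }
  kept <- v$boundaries[v$indices > thr]
  n_tok <- nrow(text$tokens)
  splits <- kept[kept < n_tok]          # terminus never splits
  from <- c(1L, splits + 1L)
  to <- c(splits, n_tok)
  seg_text <- vapply(seq_along(from), function(i) {
    substr(text$raw, text$tokens$start[from[i]], text$tokens$end[to[i]])
  }, character(1))
  # segments must tile the token range
  stopifnot(identical(from[1L], 1L), identical(to[length(to)], n_tok),
            all(from[-1L] == to[-length(to)] + 1L))
  segments <- data.frame(index = seq_along(from), from = from, to = to,
                         text = seg_text, stringsAsFactors = FALSE)
  structure(list(threshold = thr,
                 threshold_spec = if (identical(threshold, "mean")) "mean"
                                  else "fixed",
                 kept_boundaries = kept, segments = segments,
                 text_id = text$text_id),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result '%s': threshold %.4f (%s), %d kept boundaries, %d segments>\n",
    x$text_id, x$threshold, x$threshold_spec, length(x$kept_boundaries),
    nrow(x$segments)))
  invisible(x)
}

#' Per-boundary segmentation report
#'
#' One row per candidate boundary: agreement index and whether it was kept
#' by the consensus rule.
#'
#' @param v an `agreement_vector`.
#' @param result a [consensus_segments()] result.
#' @return data frame `boundary`, `index`, `kept`.
#' @export
segmentation_report <- function(v, result) {
  stopifnot(inherits(v, "agreement_vector"),
            inherits(result, "consensus_result"))
  data.frame(boundary = v$boundaries, index = v$indices,
             kept = v$boundaries %in% result$kept_boundaries)
}

#' Write consensus segments as JSON
#' @param result a [consensus_segments()] result.
#' @param path output path.
#' @export
write_segments <- function(result, path) {
  stopifnot(inherits(result, "consensus_result"))
  obj <- list(schema_version = SCHEMA_VERSION, type = "segments",
              text_id = result$text_id, threshold = result$threshold,
              threshold_spec = result$threshold_spec,
              kept_boundaries = result$kept_boundaries,
              segments = result$segments)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
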