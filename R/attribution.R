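# Attribution statistics: proportion matrix per consensus segment and
# exact-binomial high/low flagging of cells. Each cell holds the count of
# judges (out of the n_s who recognized the segment) attributing category k
# to segment s. Two one-sided exact binomial tests against a null
# attribution probability p0 flag cells whose count is significantly high
# (P(X >= k) < alpha) or significantly low (P(X <= k) < alpha).

#' Proportion matrix of category attributions
#'
#' Divides each attribution count by the per-segment recognizer count
#' `n_s` (not the total panel size). Full precision; two-decimal rounding
#' is display only. Segments with `n_s = 0` are excluded with a warning.
#'
#' @param protocol an [attribution_protocol()].
#' @return object of class `proportion_matrix`: list with `proportions`
#'   (S x K numeric matrix), `n`, `segments` (retained indices), `scheme`.
#' @examples
#' fx <- load_fixture("unamuno_journal")
#' pm <- proportion_matrix(fx$attribution)
#' pm$proportions[8, "Em"]   # 1.0  (16 of 16 judges)
#' pm$proportions[4, "Th"]   # 0.8125, displays as 0.81
#' @export
proportion_matrix <- function(protocol) {
  stopifnot(inherits(protocol, "attr_protocol"))
  keep <- protocol$n >= 1L
  if (any(!keep)) {
    warning("excluding unrecognized segments (n = 0): ",
            paste(which(!keep), collapse = ", "))
  }
  counts <- protocol$counts[keep, , drop = FALSE]
  n <- protocol$n[keep]
  props <- sweep(counts, 1L, n, "/")
  structure(list(proportions = props, n = n, segments = which(keep),
                 scheme = protocol$scheme, text_id = protocol$text_id),
            class = "proportion_matrix")
}

#' @export
print.proportion_matrix <- function(x, ...) {
  cat(sprintf("<proportion_matrix '%s': %d segments x %d categories>\n",
              x$text_id, nrow(x$proportions), ncol(x$proportions)))
  print(round(x$proportions, 2))
  invisible(x)
}

#' One-sided exact binomial tail probability
#'
#' Exact tail summation of the Binomial(n, p0) probability mass function:
#' `side = "greater"` gives P(X >= k), `side = "less"` gives P(X <= k).
#' This is the per-cell test behind the high/low flags; no normal
#' approximation and no continuity correction are involved.
#'
#' @param k observed count(s), vectorized.
#' @param n number of trials (judges who recognized the segment).
#' @param p0 null attribution probability, in (0, 1).
#' @param side `"greater"` or `"less"`.
#' @return numeric vector of tail probabilities in `[0, 1]`.
#' @examples
#' exact_binomial_pvalue(16, 16, 0.5, "greater")  # 2^-16
#' @export
exact_binomial_pvalue <- function(k, n, p0, side = c("greater", "less")) {
  side <- match.arg(side)
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) ||
      p0 <= 0 || p0 >= 1) {
    stop("p0 must be a single number in (0, 1)")
  }
  k <- as.integer(k)
  if (length(n) == 1L) n <- rep.int(as.integer(n), length(k))
  if (any(n < 1L)) stop("n must be >= 1")
  if (any(k < 0L | k > n)) stop("k must lie in [0, n]")
  vapply(seq_along(k), function(i) {
    j <- if (side == "greater") k[i]:n[i] else 0L:k[i]
    sum(stats::dbinom(j, n[i], p0))
  }, numeric(1))
}

#' Flag significantly high/low attribution cells
#'
#' Applies the two one-sided exact tests to every cell of an attribution
#' protocol: a cell is `high` when P(X >= k) < alpha, `low` when
#' P(X <= k) < alpha, else `none` (for alpha <= 0.5 the two cannot both
#' hold). No multiple-testing correction is applied by default; the
#' per-cell level is the convention of the source table
#' (`correction = "bonferroni"` divides alpha by the number of cells).
#'
#' @param protocol an [attribution_protocol()].
#' @param p0 null attribution probability (default 0.5: attribution vs
#'   non-attribution coin; `1/K` is a documented alternative).
#' @param alpha per-cell significance level, default 0.01.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return object of class `flag_matrix`: list with `flags` (S x K
#'   character matrix in {"high","low","none"}), `p_high`, `p_low`
#'   (matrices of tail probabilities), `alpha`, `p0`, `source`
#'   (`"computed"`), `n`, `segments`, `scheme`.
#' @export
flag_matrix <- function(protocol, p0 = 0.5, alpha = 0.01,
                        correction = c("none", "bonferroni")) {
  stopifnot(inherits(protocol, "attr_protocol"))
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  keep <- protocol$n >= 1L
  counts <- protocol$counts[keep, , drop = FALSE]
  n <- protocol$n[keep]
  S <- nrow(counts); K <- ncol(counts)
  alpha_eff <- if (correction == "bonferroni") alpha / (S * K) else alpha
  p_high <- p_low <- matrix(NA_real_, S, K, dimnames = dimnames(counts))
  for (s in seq_len(S)) {
    p_high[s, ] <- exact_binomial_pvalue(counts[s, ], n[s], p0, "greater")
    p_low[s, ] <- exact_binomial_pvalue(counts[s, ], n[s], p0, "less")
  }
  flags <- matrix("none", S, K, dimnames = dimnames(counts))
  flags[p_high < alpha_eff] <- "high"
  flags[p_low < alpha_eff] <- "low"
  structure(list(flags = flags, p_high = p_high, p_low = p_low,
                 alpha = alpha, alpha_effective = alpha_eff, p0 = p0,
                 correction = correction, source = "computed",
                 n = n, segments = which(keep), scheme = protocol$scheme,
                 text_id = protocol$text_id),
            class = "flag_matrix")
}

#' Wrap externally printed flags as a flag matrix
#'
#' Published significance flags are stored verbatim (`source =
#' "printed"`); they are metadata, never recomputed. Useful to summarize a
#' published table whose null proportion was not stated.
#'
#' @param protocol an [attribution_protocol()] whose `printed` metadata
#'   carries a `flags` matrix.
#' @param alpha the level the source reported (default 0.01).
#' @return a `flag_matrix` with `source = "printed"`.
#' @export
printed_flag_matrix <- function(protocol, alpha = 0.01) {
  stopifnot(inherits(protocol, "attr_protocol"))
  fl <- protocol$printed$flags
  if (is.null(fl)) stop("protocol carries no printed flags")
  structure(list(flags = fl, p_high = NULL, p_low = NULL,
                 alpha = alpha, alpha_effective = alpha, p0 = NA_real_,
                 correction = "none", source = "printed",
                 n = protocol$n, segments = seq_along(protocol$n),
                 scheme = protocol$scheme, text_id = protocol$text_id),
            class = "flag_matrix")
}

#' @export
print.flag_matrix <- function(x, ...) {
  cat(sprintf("<flag_matrix '%s' (%s): alpha = %g, p0 = %s>\n",
              x$text_id, x$source, x$alpha,
              ifelse(is.na(x$p0), "unstated", x$p0)))
  print(x$flags, quote = FALSE)
  invisible(x)
}

#' Segments whose state is a composite of several categories
#'
#' Indices of segments with at least two significantly high category
#' attributions -- evidence that a single conscious state binds several
#' mental factors.
#'
#' @param flags a [flag_matrix()] (computed or printed).
#' @return ascending integer vector of segment indices.
#' @examples
#' fx <- load_fixture("unamuno_journal")
#' composite_states(printed_flag_matrix(fx$attribution))  # 1 7 8 9
#' @export
composite_states <- function(flags) {
  stopifnot(inherits(flags, "flag_matrix"))
  nh <- rowSums(flags$flags == "high")
  sort(flags$segments[nh >= 2L])
}

#' Segments with no significant attribution
#'
#' Indices of segments with zero significantly high attributions --
#' stretches of text the panel could not agree to place in any mental
#' category.
#'
#' @param flags a [flag_matrix()].
#' @return ascending integer vector of segment indices.
#' @examples
#' fx <- load_fixture("unamuno_journal")
#' empty_segments(printed_flag_matrix(fx$attribution))  # 2 5 6
#' @export
empty_segments <- function(flags) {
  stopifnot(inherits(flags, "flag_matrix"))
  nh <- rowSums(flags$flags == "high")
  sort(flags$segments[nh == 0L])
}

#' Computed-versus-printed flag differences
#'
#' Cell-by-cell comparison of a computed flag matrix against the printed
#' one. Published flag patterns need not be reproducible from any single
#' null proportion; this report makes the differences explicit instead of
#' force-fitting them.
#'
#' @param computed a [flag_matrix()] with `source = "computed"`.
#' @param printed a [flag_matrix()] with `source = "printed"`.
#' @return data frame `segment`, `category`, `printed`, `computed`,
#'   `p_high`, `p_low`; zero rows when the patterns agree.
#' @export
flag_diff <- function(computed, printed) {
  stopifnot(inherits(computed, "flag_matrix"),
            inherits(printed, "flag_matrix"))
  common <- intersect(computed$segments, printed$segments)
  ci <- match(common, computed$segments)
  pi <- match(common, printed$segments)
  K <- ncol(computed$flags)
  out <- NULL
  for (i in seq_along(common)) {
    for (k in seq_len(K)) {
      cf <- computed$flags[ci[i], k]
      pf <- printed$flags[pi[i], k]
      if (cf != pf) {
        out <- rbind(out, data.frame(
          segment = common[i], category = colnames(computed$flags)[k],
          printed = pf, computed = cf,
          p_high = computed$p_high[ci[i], k],
          p_low = computed$p_low[ci[i], k],
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(segment = integer(0), category = character(0),
                      printed = character(0), computed = character(0),
                      p_high = numeric(0), p_low = numeric(0))
  }
  out
}

#' Write an attribution table (proportions, flags, n) as TSV
#'
#' Emits one row per segment: `segment`, `n`, then per category the
#' proportion rounded to two decimals with a `*` suffix on high flags and
#' a `-` suffix on low flags.
#'
#' @param pm a [proportion_matrix()].
#' @param flags a [flag_matrix()] on the same protocol.
#' @param path output path.
#' @export
write_attribution_table <- function(pm, flags, path) {
  stopifnot(inherits(pm, "proportion_matrix"), inherits(flags, "flag_matrix"))
  common <- intersect(pm$segments, flags$segments)
  pi <- match(common, pm$segments)
  fi <- match(common, flags$segments)
  mark <- c(high = "*", low = "-", none = "")
  cells <- matrix("", length(common), ncol(pm$proportions))
  for (i in seq_along(common)) {
    cells[i, ] <- paste0(sprintf("%.2f", pm$proportions[pi[i], ]),
                         mark[flags$flags[fi[i], ]])
  }
  df <- data.frame(segment = common, n = pm$n[pi], cells,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("segment", "n", colnames(pm$proportions))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
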