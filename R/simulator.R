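# Synthetic judge panels. Judges are exchangeable and independent across
# judges, boundaries, segments and categories -- the undifferentiated
# "assembly of judges" the agreement statistics assume. The generator is
# used to calibrate the mean-threshold rule and the exact-test flags
# (type-I error, power) without external data; a seed is mandatory and
# fixes all randomness.

with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a segmentation judge panel
#'
#' Each judge marks candidate boundary `b` independently with probability
#' `boundary_probs[b]`.
#'
#' @param n_judges panel size (>= 1).
#' @param boundary_probs per-boundary marking probabilities in `[0, 1]`.
#' @param seed integer seed (mandatory; fixes all randomness).
#' @param boundaries boundary positions (defaults to `1:B`).
#' @param text_id id for the simulated protocol.
#' @return a [segmentation_protocol()].
#' @examples
#' p <- simulate_segmentation_panel(16, rep(0.5, 10), seed = 1)
#' dim(p$marks)  # 16 10
#' @export
simulate_segmentation_panel <- function(n_judges, boundary_probs, seed,
                                        boundaries = seq_along(boundary_probs),
                                        text_id = "simulated") {
  n_judges <- as.integer(n_judges)
  if (is.na(n_judges) || n_judges < 1L) stop("n_judges must be >= 1")
  if (any(boundary_probs < 0 | boundary_probs > 1)) {
    stop("boundary_probs must lie in [0, 1]")
  }
  B <- length(boundary_probs)
  if (B < 1L) stop("boundary_probs is empty")
  marks <- with_seed(seed, {
    matrix(stats::rbinom(n_judges * B, 1L,
                         rep(boundary_probs, each = n_judges)),
           nrow = n_judges, ncol = B)
  })
  segmentation_protocol(marks, boundaries = boundaries, text_id = text_id)
}

#' Simulate an attribution judge panel
#'
#' Each judge recognizes segment `s` independently with probability
#' `recognition_probs[s]`; conditional on recognition, attributes
#' category `k` with probability `attach_probs[s, k]`. The per-segment
#' recognizer count `n_s` is the number of recognizing judges.
#'
#' @param n_judges panel size.
#' @param recognition_probs S-vector in `[0, 1]`.
#' @param attach_probs S x K matrix in `[0, 1]` (columns in scheme order).
#' @param seed integer seed (mandatory).
#' @param scheme a [category_scheme()]; defaults to anonymous codes
#'   `C1..CK`.
#' @param text_id id for the simulated protocol.
#' @return an [attribution_protocol()] carrying the full judge-level
#'   indicator tensor.
#' @export
simulate_attribution_panel <- function(n_judges, recognition_probs,
                                       attach_probs, seed, scheme = NULL,
                                       text_id = "simulated") {
  n_judges <- as.integer(n_judges)
  if (is.na(n_judges) || n_judges < 1L) stop("n_judges must be >= 1")
  attach_probs <- as.matrix(attach_probs)
  S <- length(recognition_probs)
  K <- ncol(attach_probs)
  if (nrow(attach_probs) != S) stop("attach_probs rows must match segments")
  if (any(recognition_probs < 0 | recognition_probs > 1) ||
      any(attach_probs < 0 | attach_probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (is.null(scheme)) {
    scheme <- category_scheme("simulated", sprintf("C%d", seq_len(K)))
  }
  stopifnot(length(scheme$codes) == K)
  sim <- with_seed(seed, {
    rec <- matrix(stats::rbinom(n_judges * S, 1L,
                                rep(recognition_probs, each = n_judges)),
                  nrow = n_judges, ncol = S)
    ind <- array(0L, dim = c(n_judges, S, K))
    for (s in seq_len(S)) {
      js <- which(rec[, s] == 1L)
      if (length(js)) {
        ind[js, s, ] <- stats::rbinom(length(js) * K, 1L,
                                      rep(attach_probs[s, ], each = length(js)))
      }
    }
    list(rec = rec, ind = ind)
  })
  n <- colSums(sim$rec)
  counts <- apply(sim$ind, c(2L, 3L), sum)
  attribution_protocol(counts = counts, n = n, scheme = scheme,
                       judges_total = n_judges, indicators = sim$ind,
                       text_id = text_id)
}

#' Monte-Carlo power curve of the high flag
#'
#' For each true attribution probability, simulates `reps` independent
#' cells with `n_judges` recognizing judges and estimates the rate at
#' which the one-sided exact test flags the cell high at level `alpha`
#' against null `p0`. At `true_p = p0` the rate is the type-I error
#' (bounded by `alpha`; the exact test is conservative).
#'
#' @param n_judges recognizing judges per cell.
#' @param p0 null attribution probability.
#' @param alpha significance level.
#' @param true_p vector of true attribution probabilities.
#' @param reps simulated cells per `true_p` value (>= 100).
#' @param seed integer seed (mandatory).
#' @return data frame `true_p`, `power` (high-flag rate), `se`
#'   (Monte-Carlo standard error).
#' @examples
#' power_curve(16, 0.5, 0.01, c(0.5, 1), reps = 200, seed = 1)
#' @export
power_curve <- function(n_judges, p0, alpha, true_p, reps = 1000L, seed) {
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 100L) stop("reps must be >= 100")
  if (any(true_p < 0 | true_p > 1)) stop("true_p must lie in [0, 1]")
  # the high flag only depends on the count, so the critical value can be
  # precomputed: flag iff k >= k_min where P(X >= k_min) < alpha
  p_ge <- exact_binomial_pvalue(0L:n_judges, n_judges, p0, "greater")
  k_min <- match(TRUE, p_ge < alpha)  # NA when no attainable count is significant
  rates <- with_seed(seed, {
    vapply(true_p, function(p) {
      k <- stats::rbinom(reps, n_judges, p)
      if (is.na(k_min)) 0 else mean(k >= (k_min - 1L))
    }, numeric(1))
  })
  data.frame(true_p = true_p, power = rates,
             se = sqrt(rates * (1 - rates) / reps))
}
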