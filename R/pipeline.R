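# End-to-end pipeline (segment -> attribute -> stream) and a thin
# command-line front-end. Results go to files; the configuration used is
# serialized alongside every output bundle for provenance.

#' Assemble a run configuration
#'
#' Validated defaults for the whole pipeline: per-cell significance level
#' `alpha = 0.01`, null attribution probability `p0 = 0.5`, consensus
#' threshold `"mean"`, unit time weighting.
#'
#' @param alpha significance level in (0, 1).
#' @param p0 null attribution probability in (0, 1).
#' @param threshold `"mean"` or a number in `[0, 1]`.
#' @param time_weight `"unit"`, `"words"` or `"chars"`.
#' @param seed optional integer seed (only simulation consumes it).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(alpha = 0.01, p0 = 0.5, threshold = "mean",
                       time_weight = "unit", seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (!identical(threshold, "mean")) {
    threshold <- as.numeric(threshold)
    if (is.na(threshold) || threshold < 0 || threshold > 1) {
      stop("threshold must be 'mean' or a number in [0, 1]")
    }
  }
  time_weight <- match.arg(time_weight, c("unit", "words", "chars"))
  structure(list(alpha = alpha, p0 = p0, threshold = threshold,
                 time_weight = time_weight, seed = seed,
                 package_version = as.character(utils::packageVersion("phenostream"))),
            class = "run_config")
}

#' Run the full narrative-coding pipeline
#'
#' Three stages on whatever inputs are available: consensus segmentation
#' (needs `text` + `seg_protocol`), attribution statistics (needs
#' `attr_protocol`), stream model (needs `coded`). `fixture` loads a
#' packaged dataset and fills the corresponding inputs. Outputs are
#' written under `out_dir` (created if needed) together with a
#' machine-readable `summary.json` recording the configuration.
#'
#' @param config a [run_config()].
#' @param fixture optional fixture name for [load_fixture()].
#' @param text,seg_protocol,attr_protocol,coded explicit stage inputs
#'   (override fixture components).
#' @param out_dir output directory; `NULL` computes everything but writes
#'   nothing.
#' @return list with (depending on inputs) `agreement`, `consensus`,
#'   `proportions`, `flags`, `flags_printed`, `flag_differences`,
#'   `composite_states`, `empty_segments`, `model`, plus `config` and
#'   `files` (paths written).
#' @examples
#' res <- run_pipeline(run_config(), fixture = "unamuno_journal")
#' nrow(res$consensus$segments)  # 9
#' @export
run_pipeline <- function(config = run_config(), fixture = NULL,
                         text = NULL, seg_protocol = NULL,
                         attr_protocol = NULL, coded = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(fixture)) {
    fx <- load_fixture(fixture)
    if (is.null(text)) text <- fx$text
    if (is.null(seg_protocol)) seg_protocol <- fx$segmentation
    if (is.null(attr_protocol)) attr_protocol <- fx$attribution
    if (is.null(coded)) coded <- fx$stream
  }
  if (is.null(text) && is.null(attr_protocol) && is.null(coded)) {
    stop("no inputs: supply a fixture, or a text/protocol/coded stream")
  }
  out <- list(config = config, files = character(0))
  emit <- function(writer, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, name)
      writer(path)
      out$files <<- c(out$files, path)
    }
  }
  if (!is.null(seg_protocol)) {
    if (is.null(text)) stop("segmentation stage needs the text input")
    out$agreement <- boundary_agreement(seg_protocol)
    out$consensus <- consensus_segments(text, out$agreement,
                                        threshold = config$threshold)
    report <- segmentation_report(out$agreement, out$consensus)
    emit(function(p) write_segments(out$consensus, p), "segments.json")
    emit(function(p) utils::write.table(report, p, sep = "\t",
                                        row.names = FALSE, quote = FALSE),
         "segmentation_report.tsv")
  }
  if (!is.null(attr_protocol)) {
    out$proportions <- proportion_matrix(attr_protocol)
    out$flags <- flag_matrix(attr_protocol, p0 = config$p0,
                             alpha = config$alpha)
    out$composite_states <- composite_states(out$flags)
    out$empty_segments <- empty_segments(out$flags)
    if (!is.null(attr_protocol$printed$flags)) {
      out$flags_printed <- printed_flag_matrix(attr_protocol,
                                               alpha = config$alpha)
      out$flag_differences <- flag_diff(out$flags, out$flags_printed)
    }
    emit(function(p) write_attribution_table(out$proportions, out$flags, p),
         "attribution_table.tsv")
    if (!is.null(out$flag_differences)) {
      emit(function(p) utils::write.table(out$flag_differences, p,
                                          sep = "\t", row.names = FALSE,
                                          quote = FALSE),
           "flag_differences.tsv")
    }
  }
  if (!is.null(coded)) {
    out$model <- build_stream(coded)
    emit(function(p) write_stream_model(out$model, p), "model.dot")
    emit(function(p) write_stream_model(out$model, p), "model.pnml")
    emit(function(p) write_stream_model(out$model, p), "model.json")
  }
  if (!is.null(out_dir)) {
    summary <- list(
      config = unclass(config),
      fixture = fixture,
      n_segments = if (!is.null(out$consensus)) nrow(out$consensus$segments),
      mean_agreement = if (!is.null(out$agreement)) {
        mean_agreement(out$agreement)
      },
      composite_states = out$composite_states,
      empty_segments = out$empty_segments,
      n_episodes = if (!is.null(out$model)) nrow(out$model$episodes),
      files = basename(out$files)
    )
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$files <- c(out$files, path)
  }
  out
}

## ---- command line ------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: phenostream <command> [options]",
    "",
    "commands:",
    "  segment    --text FILE --protocol FILE [--threshold mean|X]",
    "             [--out FILE.json] [--report FILE.tsv]",
    "  attribute  --protocol FILE [--p0 X] [--alpha X] [--out FILE.tsv]",
    "  stream     --coded FILE.json [--out FILE.{dot,pnml,json}]",
    "             [--time-weight unit|words|chars]",
    "  simulate   segmentation|power --seed N [...]",
    "  run        --fixture NAME [--out-dir DIR] [--threshold ...]",
    "             [--p0 X] [--alpha X]",
    "  fixtures   (list packaged datasets)",
    sep = "\n")
}

cli_opts <- function(args) {
  opts <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Thin front-end over the package functions, used by the
#' `inst/exec/phenostream` script: subcommands `segment`, `attribute`,
#' `stream`, `simulate`, `run` and `fixtures`. Logs to stderr, writes
#' results to files only.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[[1L]] %in% c("-h", "--help", "help")) {
    message(cli_usage())
    return(invisible(0L))
  }
  cmd <- args[[1L]]
  opts <- cli_opts(args[-1L])
  thr <- function() {
    t <- opts$threshold
    if (is.null(t) || identical(t, "mean")) "mean" else as.numeric(t)
  }
  if (cmd == "fixtures") {
    cat("unamuno_journal\njoyce_penelope\n")
  } else if (cmd == "segment") {
    text <- read_text(opts$text)
    prot <- read_segmentation_protocol(opts$protocol, text = text)
    v <- boundary_agreement(prot)
    res <- consensus_segments(text, v, threshold = thr())
    message(sprintf("mean agreement %.4f; %d segments",
                    mean_agreement(v), nrow(res$segments)))
    if (!is.null(opts$out)) write_segments(res, opts$out)
    if (!is.null(opts$report)) {
      utils::write.table(segmentation_report(v, res), opts$report,
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  } else if (cmd == "attribute") {
    prot <- read_attribution_protocol(opts$protocol)
    p0 <- if (is.null(opts$p0)) 0.5 else as.numeric(opts$p0)
    alpha <- if (is.null(opts$alpha)) 0.01 else as.numeric(opts$alpha)
    pm <- proportion_matrix(prot)
    fl <- flag_matrix(prot, p0 = p0, alpha = alpha)
    message(sprintf("composite states: %s; empty segments: %s",
                    paste(composite_states(fl), collapse = ","),
                    paste(empty_segments(fl), collapse = ",")))
    if (!is.null(opts$out)) write_attribution_table(pm, fl, opts$out)
  } else if (cmd == "stream") {
    coded <- read_coded_stream(opts$coded)
    model <- build_stream(coded)
    message(sprintf("%d segments, %d places, %d episodes",
                    model$n_segments, nrow(model$places),
                    nrow(model$episodes)))
    if (!is.null(opts$out)) write_stream_model(model, opts$out)
  } else if (cmd == "simulate") {
    what <- opts$positional[1L]
    seed <- as.integer(opts$seed)
    if (identical(what, "segmentation")) {
      p <- simulate_segmentation_panel(
        as.integer(opts$judges),
        rep(as.numeric(opts$prob), as.integer(opts$boundaries)),
        seed = seed)
      if (!is.null(opts$out)) write_segmentation_protocol(p, opts$out)
    } else if (identical(what, "power")) {
      pc <- power_curve(as.integer(opts$judges),
                        if (is.null(opts$p0)) 0.5 else as.numeric(opts$p0),
                        if (is.null(opts$alpha)) 0.01 else as.numeric(opts$alpha),
                        true_p = seq(0, 1, by = 0.1),
                        reps = if (is.null(opts$reps)) 1000L
                               else as.integer(opts$reps),
                        seed = seed)
      if (!is.null(opts$out)) {
        utils::write.table(pc, opts$out, sep = "\t", row.names = FALSE,
                           quote = FALSE)
      }
    } else stop("unknown simulate target: ", what)
  } else if (cmd == "run") {
    cfg <- run_config(
      alpha = if (is.null(opts$alpha)) 0.01 else as.numeric(opts$alpha),
      p0 = if (is.null(opts$p0)) 0.5 else as.numeric(opts$p0),
      threshold = thr(),
      seed = if (is.null(opts$seed)) NULL else as.integer(opts$seed))
    run_pipeline(cfg, fixture = opts$fixture,
                 out_dir = if (is.null(opts$out_dir)) "." else opts$out_dir)
  } else {
    message(cli_usage())
    stop("unknown command: ", cmd)
  }
  invisible(0L)
}
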