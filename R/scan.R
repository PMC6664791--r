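# Sliding-window scanning of long sequences: Q_MFE profiles and
# model-probability profiles with threshold calling.

scan_starts <- function(L, window, step, partial_final = FALSE, min_len = 1L) {
  if (L < window) stop("degenerate input: sequence shorter than window",
                       call. = FALSE)
  starts <- seq(1L, L - window + 1L, by = step)
  if (partial_final) {
    nxt <- starts[length(starts)] + step
    if (nxt <= L && (L - nxt + 1L) >= min_len) starts <- c(starts, nxt)
  }
  starts
}

new_scan_profile <- function(df, value_kind, window, step) {
  structure(list(windows = df, value_kind = value_kind,
                 window = window, step = step),
            class = "scan_profile")
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf("<scan_profile> %s, %d windows (window=%d, step=%d)\n",
              x$value_kind, nrow(x$windows), x$window, x$step))
  invisible(x)
}

#' Q_MFE profile along a long sequence
#'
#' Computes [qmfe()] for fixed-length windows (default 200 bases) starting
#' every `step` bases (default half a window), giving a structure profile:
#' window minima flag regions with more predicted secondary structure than
#' their dinucleotide-shuffled nulls.
#'
#' @param seq An [rna_sequence()] at least one window long.
#' @param window Window length in bases (default 200).
#' @param step Step between window starts (default `window / 2`).
#' @param N Shuffles per window.
#' @param engine Folding engine.
#' @param rng_seed Integer seed; per-window null draws are derived from it.
#' @param partial_final Include a final truncated window (length >= 2)?
#' @return A `scan_profile` whose `windows` data.frame has columns
#'   `start`, `end` (1-based inclusive) and `value` (Q_MFE).
#' @export
scan_qmfe <- function(seq, window = 200L, step = max(1L, window %/% 2L),
                      N = 100L, engine = baseline_engine(), rng_seed = 1L,
                      partial_final = FALSE) {
  stopifnot(inherits(seq, "rna_sequence"))
  window <- as.integer(window); step <- as.integer(step)
  starts <- scan_starts(seq$length, window, step, partial_final, min_len = 2L)
  vals <- vapply(seq_along(starts), function(i) {
    s <- starts[i]
    e <- min(s + window - 1L, seq$length)
    sub <- rna_sequence(sprintf("%s:%d-%d", seq$id, s, e),
                        substr(seq$residues, s, e))
    tryCatch(
      qmfe(sub, N = N, engine = engine, rng_seed = rng_seed + i)$qmfe,
      error = function(err) {
        stop(sprintf("engine error in window %d-%d: %s", s, e,
                     conditionMessage(err)), call. = FALSE)
      })
  }, numeric(1))
  ends <- pmin(starts + window - 1L, seq$length)
  new_scan_profile(data.frame(start = starts, end = ends, value = vals),
                   "qmfe", window, step)
}

#' Model-probability profile and threshold calls along a sequence
#'
#' Slides a window (default the model's training insert length) along the
#' sequence, assembles features for each window exactly as at training
#' time (selection, kmer space, window config, engine and N are taken from
#' the model metadata unless overridden), predicts the IRES probability,
#' and calls windows whose probability exceeds the threshold. Overlapping
#' or adjacent calls are merged, keeping the maximal probability.
#'
#' @param seq An [rna_sequence()].
#' @param model An `ires_model` from [train_ires_model()].
#' @param window Window length (default 173).
#' @param step Step between window starts (default 10).
#' @param threshold Probability call threshold (default 0.1).
#' @param engine Folding engine if the model uses structural features.
#' @param N,rng_seed QMFE null parameters for structural features.
#' @return List with elements `profile` (a `scan_profile`, value kind
#'   `"probability"`) and `calls` (data.frame `start`, `end`, `value` of
#'   merged calls; attribute `threshold`).
#' @export
scan_predict <- function(seq, model, window = 173L, step = 10L,
                         threshold = 0.1, engine = NULL,
                         N = 100L, rng_seed = 1L) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(model, "ires_model"))
  window <- as.integer(window); step <- as.integer(step)
  selection <- model$metadata$selection
  if (is.null(selection)) selection <- "global-kmer"
  if ("structural" %in% selection && is.null(engine)) {
    stop("config error: model uses structural features; supply an engine",
         call. = FALSE)
  }
  starts <- scan_starts(seq$length, window, step, partial_final = FALSE)
  subs <- lapply(starts, function(s) {
    rna_sequence(sprintf("%s:%d-%d", seq$id, s, s + window - 1L),
                 substr(seq$residues, s, s + window - 1L))
  })
  m <- assemble_features(subs, selection = selection,
                         engine = engine, N = N, rng_seed = rng_seed)
  if (!identical(colnames(m), model$feature_names)) {
    stop("config error: window features do not match the model's feature ",
         "schema (window length vs training insert length?)", call. = FALSE)
  }
  p <- predict(model, m)
  prof <- data.frame(start = starts, end = starts + window - 1L, value = p)
  calls <- merge_calls(prof[prof$value > threshold, , drop = FALSE])
  attr(calls, "threshold") <- threshold
  list(profile = new_scan_profile(prof, "probability", window, step),
       calls = calls)
}

# merge overlapping/adjacent called windows, keeping the extremal value
merge_calls <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), value = numeric(0)))
  }
  df <- df[order(df$start), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(out)
    if (df$start[i] <= out$end[last] + 1L) {
      out$end[last] <- max(out$end[last], df$end[i])
      out$value[last] <- max(out$value[last], df$value[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a scan profile as TSV
#'
#' @param profile A `scan_profile`.
#' @param path Output path (or `""` for standard output).
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "scan_profile"))
  utils::write.table(profile$windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export calls as BED
#'
#' Converts 1-based inclusive call coordinates to BED's 0-based half-open
#' convention; the BED score column is the call value scaled to 0-1000.
#'
#' @param calls Call data.frame from [scan_predict()].
#' @param seq_id Chromosome/sequence name for column 1.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls_bed <- function(calls, seq_id, path) {
  bed <- data.frame(chrom = rep(seq_id, nrow(calls)),
                    start = calls$start - 1L,  # 0-based half-open
                    end = calls$end,
                    name = sprintf("call%d", seq_len(max(nrow(calls), 0L))),
                    score = round(pmin(pmax(calls$value, 0), 1) * 1000))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
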